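test_that("TIFF round-trip preserves data and requires spacing", {
  set.seed(101)
  g <- voxel_grid(array(sample(0:65535, 4 * 5 * 6, TRUE), c(4, 5, 6)),
                  spacing = c(10, 6.5, 6.5))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(g, path, "tiff")
  g2 <- read_volume(path, "tiff", spacing = c(10, 6.5, 6.5))
  expect_identical(g2$data, g$data + 0)  # numeric, bit-identical values
  expect_equal(g2$spacing, g$spacing)
  expect_error(read_volume(path, "tiff"), "spacing")
})

test_that("binary masks survive 8-bit TIFF serialization (0/255, re-threshold at > 0)", {
  set.seed(102)
  m <- array(stats::runif(3 * 8 * 8) < 0.3, c(3, 8, 8))
  g <- voxel_grid(array(as.numeric(m) * 255, dim(m)), c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(g, path, "tiff", bits = 8L)
  back <- read_volume(path, "tiff", spacing = c(1, 1, 1))
  expect_identical(back$data > 0, m)
  expect_setequal(unique(as.vector(back$data)), c(0, 255)[c(TRUE, any(m))])
})

test_that("HDF5 round-trips float volumes exactly and carries spacing attribute", {
  set.seed(103)
  g <- voxel_grid(array(stats::rnorm(4 * 5 * 6), c(4, 5, 6)),
                  spacing = c(10, 6.5, 6.5))
  path <- withr::local_tempfile(fileext = ".h5")
  write_volume(g, path, "hdf5")
  g2 <- read_volume(path, "hdf5")  # spacing from element_size_um attribute
  expect_identical(g2$data, g$data)
  expect_equal(g2$spacing, c(10, 6.5, 6.5))
  g3 <- read_volume(path, "hdf5", spacing = c(2, 1, 1))  # argument overrides
  expect_equal(g3$spacing, c(2, 1, 1))
})

test_that("invalid grids and spacings are rejected with informative messages", {
  expect_error(voxel_grid(array(1, c(2, 2, 2)), c(0, 1, 1)), "spacing")
  expect_error(voxel_grid(array(1, c(2, 2, 2)), c(1, 1, Inf)), "spacing")
  expect_error(voxel_grid(matrix(1, 2, 2), c(1, 1, 1)), "3D")
})

test_that("annotation CSVs parse, validate labels, bounds and duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("z,y,x,label", "0,0,0,signal", "0,0,1,background"), path)
  ann <- read_annotations(path, shape = c(2, 2, 2))
  expect_equal(nrow(ann), 2L)
  expect_setequal(unique(ann$label), c("signal", "background"))

  writeLines(c("z,y,x,label", "0,0,0,tumor"), path)
  expect_error(read_annotations(path, c(2, 2, 2)), "allowed labels")

  writeLines(c("z,y,x,label", "0,0,0,signal", "0,0,0,background"), path)
  expect_error(read_annotations(path, c(2, 2, 2)), "duplicate")

  writeLines(c("z,y,x,label", "5,0,0,signal"), path)
  expect_error(read_annotations(path, c(2, 2, 2)), "out of bounds")
})
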