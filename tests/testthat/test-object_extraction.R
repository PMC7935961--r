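mask_from_voxels <- function(shape, vox, spacing = c(1, 1, 1)) {
  m <- array(FALSE, shape)
  m[vox + 1L] <- TRUE  # vox: matrix of 0-based (z, y, x)
  binary_mask(m, spacing)
}

test_that("connectivity definitions split or join diagonal voxels as stated", {
  m <- mask_from_voxels(c(3, 3, 3), rbind(c(0, 0, 0), c(1, 1, 1)))
  m$data <- array(FALSE, c(3, 3, 3))
  m$data[1, 1, 1] <- TRUE; m$data[2, 2, 2] <- TRUE
  expect_equal(label_components(m, 26)$n_components, 1L)
  expect_equal(label_components(m, 6)$n_components, 2L)
  # edge-adjacent (two axes differ) joins at 18 but not 6
  m2 <- binary_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))
  m2$data[1, 1, 1] <- TRUE; m2$data[1, 2, 2] <- TRUE
  expect_equal(label_components(m2, 18)$n_components, 1L)
  expect_equal(label_components(m2, 6)$n_components, 2L)
})

test_that("well-separated blobs are counted and labelled canonically", {
  m <- binary_mask(array(FALSE, c(8, 8, 8)), c(1, 1, 1))
  m$data[2:3, 2:3, 2:3] <- TRUE
  m$data[6:7, 6:7, 6:7] <- TRUE
  lab <- label_components(m)
  expect_equal(lab$n_components, 2L)
  # raster-scan canonical: first blob (lower linear index) is label 1
  expect_equal(lab$data[2, 2, 2], 1L)
  expect_equal(lab$data[6, 6, 6], 2L)
  # empty mask
  empty <- binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(label_components(empty)$n_components, 0L)
  expect_equal(nrow(extract_objects(label_components(empty))), 0L)
})

test_that("centroids, volumes and bounding boxes follow their definitions", {
  # symmetric object spanning x voxels 0..2 at unit spacing: centroid (0,0,1)
  m2 <- mask_from_voxels(c(1, 1, 3),
                         rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)))
  tab2 <- extract_objects(label_components(m2, 6))
  expect_equal(c(tab2$z_um, tab2$y_um, tab2$x_um), c(0, 0, 1))
  # volume = voxel count x voxel volume, spacing (2, 1, 1)
  m3 <- mask_from_voxels(c(2, 1, 1), rbind(c(0, 0, 0), c(1, 0, 0)),
                         spacing = c(2, 1, 1))
  tab3 <- extract_objects(label_components(m3))
  expect_equal(tab3$volume_um3, 4)
  expect_equal(tab3$voxels, 2L)
  expect_equal(c(tab3$bbox_z0, tab3$bbox_z1), c(0L, 1L))
})

test_that("min_voxels filter drops small objects and re-indexes ids", {
  m <- binary_mask(array(FALSE, c(8, 8, 8)), c(1, 1, 1))
  m$data[2:3, 2:3, 2:3] <- TRUE            # 8-voxel blob
  m$data[6, 2, 2] <- TRUE                  # singletons
  m$data[2, 6, 6] <- TRUE
  m$data[6, 6, 2] <- TRUE
  tab <- extract_objects(label_components(m), min_voxels = 2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$id, 1L)
  expect_equal(tab$voxels, 8L)
})

test_that("voxel counts are conserved across objects and summaries add up", {
  set.seed(77)
  m <- random_mask(c(12, 12, 12), p = 0.2)
  lab <- label_components(m)
  tab <- extract_objects(lab)
  expect_equal(sum(tab$voxels), sum(m$data))
  s <- summarize_objects(tab, channel = "cancer")
  expect_equal(s$count, nrow(tab))
  expect_equal(s$total_volume_um3, sum(tab$volume_um3))
  empty <- summarize_objects(extract_objects(label_components(
    binary_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1)))))
  expect_equal(empty$count, 0L)
  expect_equal(empty$total_volume_um3, 0)
})

test_that("phantom colonies are recovered with centroids within one voxel", {
  dv <- designed_vessel_phantom()
  ph <- generate_phantom(dv$spec, seed = 5)
  truth_mask <- binary_mask(ph$truth$labels$cancer == 1L, dv$spec$spacing)
  tab <- extract_objects(label_components(truth_mask))
  expect_equal(nrow(tab), nrow(dv$centers))
  # match each recovered object to its nearest designed centre
  for (i in seq_len(nrow(tab))) {
    d <- sqrt((dv$centers[, 1] - tab$z_um[i])^2 +
              (dv$centers[, 2] - tab$y_um[i])^2 +
              (dv$centers[, 3] - tab$x_um[i])^2)
    j <- which.min(d)
    expect_lte(abs(dv$centers[j, 1] - tab$z_um[i]), dv$spec$spacing[1])
    expect_lte(abs(dv$centers[j, 2] - tab$y_um[i]), dv$spec$spacing[2])
    expect_lte(abs(dv$centers[j, 3] - tab$x_um[i]), dv$spec$spacing[3])
  }
})
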