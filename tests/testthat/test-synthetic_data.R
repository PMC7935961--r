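test_that("phantom catalog reflects requested object counts", {
  ph <- generate_phantom(small_phantom_spec(), seed = 1)
  cat_tab <- ph$truth$catalog
  expect_equal(sum(cat_tab$channel == "cancer" & cat_tab$class == "signal"), 4L)
  expect_equal(sum(cat_tab$channel == "vessel" & cat_tab$class == "signal"), 1L)
  expect_equal(sum(cat_tab$channel == "puncta" & cat_tab$class == "signal"), 5L)
  expect_true(all(cat_tab$voxels >= 1))
  ext <- (dim(ph$channels[[1]]$data) - 1L) * ph$truth$spacing
  expect_true(all(cat_tab$z_um >= 0 & cat_tab$z_um <= ext[1]))
  expect_true(all(cat_tab$y_um >= 0 & cat_tab$y_um <= ext[2]))
  expect_true(all(cat_tab$x_um >= 0 & cat_tab$x_um <= ext[3]))
})

test_that("identical seeds give bit-identical phantoms; different seeds differ", {
  sp <- small_phantom_spec()
  a <- generate_phantom(sp, seed = 7)
  b <- generate_phantom(sp, seed = 7)
  expect_identical(a$channels$cancer$data, b$channels$cancer$data)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$truth$catalog, b$truth$catalog)
  c3 <- generate_phantom(sp, seed = 8)
  expect_false(identical(a$channels$cancer$data, c3$channels$cancer$data))
})

test_that("noise-free intensity at a pinned colony centre is background + amplitude", {
  spec <- phantom_spec(
    shape = c(24L, 48L, 48L), spacing = c(10, 6.5, 6.5),
    colonies = list(radius_um = 20, amplitude = 2000,
                    centers_um = rbind(c(100, 130, 130))),
    vessels = list(count = 0L), puncta = list(count = 0L),
    artifacts = list(z_leakage_fraction = 0, af_tube_count = 0L),
    noise = list(poisson = FALSE, read_sd = 0))
  ph <- generate_phantom(spec, seed = 1)
  # centre (100, 130, 130) um = voxel (10, 20, 20), 0-based
  expect_equal(ph$channels$cancer$data[11, 21, 21], 100 + 2000)
  # far corner is pure background
  expect_equal(ph$channels$cancer$data[1, 1, 1], 100)
})

test_that("truth labels and intensities are consistent per class", {
  ph <- generate_phantom(small_phantom_spec(), seed = 3)
  for (ch in names(ph$truth$labels)) {
    img <- ph$channels[[ch]]$data
    lab <- ph$truth$labels[[ch]]
    expect_true(mean(img[lab == 1L]) > mean(img[lab == 4L]))
    expect_true(all(lab %in% 1:4))  # exactly one class per voxel
  }
  # leakage and autofluorescence sit between signal and background (cancer)
  img <- ph$channels$cancer$data
  lab <- ph$truth$labels$cancer
  expect_true(mean(img[lab == 3L]) > mean(img[lab == 4L]))
})

test_that("class precedence puts signal above artifact labels where objects overlap", {
  # a colony straddling a designed autofluorescent-free region plus leakage:
  # the leakage streak starts below the colony and never relabels signal
  spec <- phantom_spec(
    shape = c(40L, 32L, 32L), spacing = c(10, 6.5, 6.5),
    colonies = list(radius_um = 20, amplitude = 2000,
                    centers_um = rbind(c(100, 100, 100))),
    vessels = list(count = 0L), puncta = list(count = 0L),
    artifacts = list(z_leakage_fraction = 1, leakage_decay_vox = 4,
                     af_tube_count = 0L),
    noise = list(poisson = FALSE, read_sd = 0))
  ph <- generate_phantom(spec, seed = 2)
  lab <- ph$truth$labels$cancer
  expect_true(any(lab == 2L))               # streak exists
  zs <- which(apply(lab == 2L, 1, any)) - 1L
  expect_true(all(zs * 10 > 100))           # only below the colony (larger z)
  expect_true(any(lab == 1L))               # colony labels intact
})

test_that("annotation sampling honours counts, truth labels and seeds", {
  ph <- generate_phantom(small_phantom_spec(), seed = 5)
  ann <- sample_annotations(ph$truth, "cancer", 50, seed = 9)
  expect_equal(nrow(ann), 200L)
  expect_equal(unname(table(ann$label)["signal"]), 50)
  lab <- ph$truth$labels$cancer
  looked_up <- lab[cbind(ann$z + 1L, ann$y + 1L, ann$x + 1L)]
  expect_equal(c("signal", "z_leakage", "autofluorescence",
                 "background")[looked_up], ann$label)
  expect_identical(sample_annotations(ph$truth, "cancer", 50, seed = 9), ann)
  # requesting more voxels than a class has is an error reporting the count
  n_leak <- sum(lab == 2L)
  expect_error(sample_annotations(ph$truth, "cancer", n_leak + 1, seed = 1,
                                  classes = "z_leakage"),
               as.character(n_leak))
})

test_that("phantom specs read from YAML override defaults and pin geometry", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "shape: [16, 32, 32]",
    "spacing: [10, 6.5, 6.5]",
    "colonies:",
    "  radius_um: 12",
    "  centers_um:",
    "    - [80, 100, 100]",
    "    - [80, 100, 160]",
    "vessels: {count: 0}",
    "puncta: {count: 0}",
    "artifacts: {af_tube_count: 0, z_leakage_fraction: 0}",
    "noise: {poisson: false, read_sd: 0}"), yml)
  spec <- read_phantom_spec(yml)
  expect_s3_class(spec, "phantom_spec")
  expect_equal(spec$shape, c(16L, 32L, 32L))
  expect_equal(nrow(spec$colonies$centers_um), 2L)
  ph <- generate_phantom(spec, seed = 1)
  expect_equal(sum(ph$truth$catalog$class == "signal"), 2L)
})

test_that("overcrowded specs fail with a message naming the channel", {
  spec <- phantom_spec(shape = c(16L, 24L, 24L),
                       colonies = list(count = 60L, radius_um = c(30, 40)),
                       vessels = list(count = 0L), puncta = list(count = 0L),
                       artifacts = list(af_tube_count = 0L))
  expect_error(generate_phantom(spec, seed = 1), "cancer")
})
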