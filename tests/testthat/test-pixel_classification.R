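test_that("default filter bank expands to 61 features with the stated scales", {
  cfg <- default_feature_config()
  nms <- tmeprofiler:::feature_names(cfg)
  expect_length(nms, 61L)  # 7 + 3 * 6 + 2 * 6 * 3
  gs <- cfg$scale[cfg$family == "gaussian_smoothing"]
  expect_equal(min(gs), 0.3)
  for (f in unique(cfg$family))
    expect_equal(max(cfg$scale[cfg$family == f]), 10)
  expect_error(feature_config("gaussian_smoothing", -1), "positive")
  expect_error(feature_config("sobel", 1), "unknown")
})

test_that("derivative features vanish on a constant volume; smoothing preserves it", {
  g <- voxel_grid(array(7, c(12, 12, 12)), c(1, 1, 1))
  cfg <- feature_config(
    c("gaussian_smoothing", "laplacian_of_gaussian",
      "gaussian_gradient_magnitude", "difference_of_gaussians",
      "hessian_of_gaussian_eigenvalues"), rep(1.6, 5))
  fs <- compute_feature_stack(g, cfg)
  expect_equal(unname(fs$values[, 1]), rep(7, 12^3))
  for (j in 2:ncol(fs$values))
    expect_equal(unname(fs$values[, j]), rep(0, 12^3), tolerance = 1e-10)
})

test_that("gaussian smoothing of an interior impulse preserves total intensity", {
  arr <- array(0, c(15, 15, 15)); arr[8, 8, 8] <- 1000
  g <- voxel_grid(arr, c(1, 1, 1))
  fs <- compute_feature_stack(g, feature_config("gaussian_smoothing", 1.6))
  expect_equal(sum(fs$values[, 1]), 1000, tolerance = 1e-3)
})

test_that("gradient magnitude of a single bright voxel is mirror-symmetric", {
  arr <- array(0, c(11, 11, 11)); arr[6, 6, 6] <- 100
  g <- voxel_grid(arr, c(1, 1, 1))
  fs <- compute_feature_stack(g, feature_config("gaussian_gradient_magnitude", 1))
  ggm <- array(fs$values[, 1], c(11, 11, 11))
  mirrored <- ggm[11:1, 11:1, 11:1]
  expect_equal(ggm, mirrored, tolerance = 1e-12)
})

test_that("training reproduces its own annotations and is deterministic", {
  ph <- generate_phantom(small_phantom_spec(), seed = 21)
  fs <- compute_feature_stack(ph$channels$cancer)
  ann <- sample_annotations(ph$truth, "cancer", 100, seed = 22)
  m1 <- train_pixel_classifier(fs, ann, seed = 23)
  pm <- predict_probabilities(m1, fs)
  # training-set accuracy on the annotated voxels
  pred <- classify_argmax(pm)
  at <- cbind(ann$z + 1L, ann$y + 1L, ann$x + 1L)
  acc <- mean(m1$classes[pred[at]] == ann$label)
  expect_gte(acc, 0.95)
  # same seed => identical probe predictions; annotation order irrelevant
  m2 <- train_pixel_classifier(fs, ann, seed = 23)
  perm <- ann[sample(nrow(ann)), ]
  class(perm) <- class(ann)
  m3 <- train_pixel_classifier(fs, perm, seed = 23)
  probe <- fs$values[seq(1, nrow(fs$values), length.out = 500), ]
  p1 <- stats::predict(m1$model, data = as.data.frame(probe),
                       num.threads = 1)$predictions
  p2 <- stats::predict(m2$model, data = as.data.frame(probe),
                       num.threads = 1)$predictions
  p3 <- stats::predict(m3$model, data = as.data.frame(probe),
                       num.threads = 1)$predictions
  expect_identical(p1, p2)
  expect_identical(p1, p3)
})

test_that("degenerate annotation sets are rejected", {
  ph <- generate_phantom(small_phantom_spec(), seed = 31)
  fs <- compute_feature_stack(
    ph$channels$cancer, feature_config("gaussian_smoothing", c(1, 3.5)))
  ann <- sample_annotations(ph$truth, "cancer", 30, seed = 1,
                            classes = "signal")
  expect_error(train_pixel_classifier(fs, ann), "two distinct classes")
  few <- sample_annotations(ph$truth, "cancer", 4, seed = 1,
                            classes = c("signal", "background"))
  expect_error(train_pixel_classifier(fs, few), "at least 10")
})

test_that("probabilities are normalized and feature mismatches are caught", {
  ph <- generate_phantom(small_phantom_spec(), seed = 41)
  cfg <- feature_config(c("gaussian_smoothing", "gaussian_gradient_magnitude"),
                        c(1.6, 1.6))
  fs <- compute_feature_stack(ph$channels$cancer, cfg)
  ann <- sample_annotations(ph$truth, "cancer", 60, seed = 42)
  m <- train_pixel_classifier(fs, ann, seed = 43)
  pm <- predict_probabilities(m, fs)
  sums <- apply(pm$data, c(2, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(pm$data >= 0 & pm$data <= 1))
  other <- compute_feature_stack(ph$channels$cancer,
                                 feature_config("gaussian_smoothing", 5))
  expect_error(predict_probabilities(m, other), "missing")
})

test_that("binarization is inclusive at the threshold and monotone in it", {
  arr <- array(0, c(4, 1, 2, 2))
  arr[1, , , ] <- c(0.5, 0.2, 0.9, 0.35)
  arr[4, , , ] <- 1 - arr[1, , , ]
  pm <- structure(list(data = arr,
                       classes = c("signal", "z_leakage",
                                   "autofluorescence", "background"),
                       spacing = c(1, 1, 1)),
                  class = "probability_map")
  m50 <- binarize_probability(pm, "signal", 0.5)
  expect_identical(as.vector(m50$data), c(TRUE, FALSE, TRUE, FALSE))
  m90 <- binarize_probability(pm, "signal", 0.9)   # P = 0.9 is foreground
  expect_identical(as.vector(m90$data), c(FALSE, FALSE, TRUE, FALSE))
  expect_true(all(m50$data[m90$data]))             # mask(t2) subset of mask(t1)
  expect_error(binarize_probability(pm, "signal", 1.2), "threshold")
  expect_error(binarize_probability(pm, "tumor"), "unknown class")
  am <- binarize_probability(pm, "signal", mode = "argmax")
  expect_identical(as.vector(am$data), c(TRUE, FALSE, TRUE, FALSE))
})
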