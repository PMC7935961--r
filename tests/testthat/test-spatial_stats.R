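test_that("centroid-to-mask distances follow the anisotropic Euclidean formula", {
  src <- object_table(0, 0, 0)
  m <- binary_mask(array(FALSE, c(1, 1, 4)), c(1, 1, 1))
  m$data[1, 1, 4] <- TRUE  # voxel (0, 0, 3)
  expect_equal(min_distance_to_mask(src, m)$distance_um, 3)

  m2 <- binary_mask(array(FALSE, c(2, 2, 2)), c(10, 1, 1))
  m2$data[2, 2, 1] <- TRUE  # voxel (1, 1, 0) at spacing (10, 1, 1)
  expect_equal(min_distance_to_mask(object_table(0, 0, 0, c(10, 1, 1)),
                                    m2)$distance_um,
               sqrt(101))
  empty <- binary_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1))
  expect_error(min_distance_to_mask(src, empty), "target structure empty")
})

test_that("kd-tree distances to masks equal the exhaustive-scan oracle exactly", {
  set.seed(11)
  for (rep in 1:5) {
    m <- random_mask(c(32, 32, 32), p = 0.02, spacing = c(10, 6.5, 6.5))
    pts <- cbind(stats::runif(50, 0, 310), stats::runif(50, 0, 200),
                 stats::runif(50, 0, 200))
    src <- object_table(pts[, 1], pts[, 2], pts[, 3], c(10, 6.5, 6.5))
    ds <- min_distance_to_mask(src, m)
    expect_identical(ds$distance_um, brute_force_min_dist(pts, m))
  }
})

test_that("object-to-object distances match brute force and handle self-pairs", {
  set.seed(12)
  src <- object_table(stats::runif(30, 0, 100), stats::runif(30, 0, 100),
                      stats::runif(30, 0, 100))
  tgt <- object_table(stats::runif(30, 0, 100), stats::runif(30, 0, 100),
                      stats::runif(30, 0, 100))
  ds <- min_distance_between_objects(src, tgt)
  expect_identical(ds$distance_um,
                   brute_force_pairwise_min(tmeprofiler:::centroid_matrix(src),
                                            tmeprofiler:::centroid_matrix(tgt)))
  # nearest of two targets
  s1 <- object_table(0, 0, 0)
  t2 <- object_table(c(0, 0), c(0, 0), c(15, 40))
  expect_equal(min_distance_between_objects(s1, t2)$distance_um, 15)
  # self-comparison requires exclude_self and is symmetric for two objects
  two <- object_table(c(0, 0), c(0, 0), c(0, 25))
  expect_error(min_distance_between_objects(two, two), "exclude_self")
  dss <- min_distance_between_objects(two, two, exclude_self = TRUE)
  expect_equal(dss$distance_um, c(25, 25))
  expect_error(min_distance_between_objects(two, object_table(numeric(0),
                                                              numeric(0),
                                                              numeric(0))),
               "empty")
})

test_that("scaling the spacing scales every distance by the same factor", {
  set.seed(13)
  m <- random_mask(c(16, 16, 16), p = 0.05, spacing = c(2, 1, 1))
  pts <- cbind(stats::runif(20, 0, 30), stats::runif(20, 0, 15),
               stats::runif(20, 0, 15))
  d1 <- min_distance_to_mask(object_table(pts[, 1], pts[, 2], pts[, 3],
                                          c(2, 1, 1)), m)$distance_um
  m3 <- binary_mask(m$data, c(6, 3, 3))
  d3 <- min_distance_to_mask(object_table(3 * pts[, 1], 3 * pts[, 2],
                                          3 * pts[, 3], c(6, 3, 3)),
                             m3)$distance_um
  expect_equal(d3, 3 * d1, tolerance = 1e-12)
})

test_that("the ECDF is the sort-and-rank step function", {
  ec <- ecdf_curve(distance_set(c(3, 1, 2)))
  expect_equal(ec$x, c(1, 2, 3))
  expect_equal(ec$F, c(1, 2, 3) / 3)
  same <- ecdf_curve(distance_set(c(5, 5, 5)))
  expect_equal(same$x, 5)
  expect_equal(same$F, 1)
  set.seed(14)
  r <- ecdf_curve(distance_set(stats::rexp(100, 0.02)))
  expect_true(all(diff(r$F) > 0))
  expect_equal(r$F[length(r$F)], 1)
})

test_that("fraction_within and band_fraction use inclusive ECDF conventions", {
  ds <- distance_set(c(5, 10, 15))
  expect_equal(fraction_within(ds, 10), 2 / 3)   # inclusive at the threshold
  expect_equal(fraction_within(ds, 0), 0)
  expect_lte(fraction_within(ds, 4), fraction_within(ds, 12))
  b <- distance_set(c(50, 100, 300, 500))
  expect_equal(band_fraction(b, 75, 400), 0.5)   # lo < d <= hi
  expect_equal(band_fraction(b, 0, 75) + band_fraction(b, 75, 400) +
                 band_fraction(b, 400, Inf) + fraction_within(b, 0), 1)
  expect_error(band_fraction(b, 75, 75), "lo < hi")
})

test_that("co-localization applies the inclusive 20 um centroid rule", {
  s <- object_table(0, 0, 0)
  expect_equal(colocalization(s, object_table(0, 0, 15))$fraction, 1)
  expect_equal(colocalization(s, object_table(0, 0, 25))$fraction, 0)
  expect_equal(colocalization(s, object_table(0, 0, 20))$fraction, 1)  # d = 20
  co <- colocalization(object_table(c(0, 0, 0), c(0, 0, 0), c(0, 100, 200)),
                       object_table(0, 0, 15))
  expect_equal(co$n_sources, 3L)
  expect_equal(co$n_colocalized, 1L)
  expect_equal(co$fraction, 1 / 3)
  # threshold -> infinity captures everything; monotone in threshold
  expect_equal(colocalization(s, object_table(0, 0, 1e5),
                              threshold_um = Inf)$fraction, 1)
})

test_that("density curves integrate to one and find the right modes", {
  set.seed(15)
  d <- distance_set(c(stats::rnorm(200, 50, 10), stats::rnorm(200, 250, 10)))
  dc <- density_curve(d)
  expect_length(dc$modes_um, 2L)
  expect_lte(abs(dc$modes_um[1] - 50), 10)
  expect_lte(abs(dc$modes_um[2] - 250), 10)
  ny <- length(dc$density)
  grid_int <- sum((dc$density[-1] + dc$density[-ny]) / 2) * diff(dc$x[1:2])
  expect_lte(abs(grid_int - 1), 1e-3)
  uni <- density_curve(distance_set(stats::rnorm(300, 100, 8)),
                       bandwidth = 8)
  expect_length(uni$modes_um, 1L)
  expect_error(density_curve(distance_set(c(1))), "at least 2")
  expect_error(density_curve(distance_set(c(2, 2, 2))), "zero variance")
})
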