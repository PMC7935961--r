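# Four-class probabilistic pixel classification: a bank of Gaussian-derivative
# filter responses at multiple scales feeds a random forest trained on sparse
# voxel annotations, yielding per-voxel class probabilities that are then
# binarized. This mirrors the interactive pixel-classification workflow used
# on the original whole-lung stacks, reproduced here as a batch computation
# (annotations are an input, not a product of an interactive loop).

FEATURE_FAMILIES <- c("gaussian_smoothing", "laplacian_of_gaussian",
                      "gaussian_gradient_magnitude", "difference_of_gaussians",
                      "structure_tensor_eigenvalues",
                      "hessian_of_gaussian_eigenvalues")

EIGEN_FAMILIES <- c("structure_tensor_eigenvalues",
                    "hessian_of_gaussian_eigenvalues")

#' Default filter-bank configuration
#'
#' Gaussian smoothing at sigma 0.3, 0.7, 1.0, 1.6, 3.5, 5.0 and 10.0 px; the
#' five remaining families (Laplacian of Gaussian, Gaussian gradient
#' magnitude, difference of Gaussians, structure-tensor eigenvalues, Hessian
#' eigenvalues) at sigma 0.7 to 10 px. These are the standard preset scales
#' spanning exactly the stated per-family ranges. Sigma is in pixel units
#' applied isotropically in index space.
#'
#' @return A data.frame of class `feature_config` with columns `family` and
#'   `scale`.
#' @export
default_feature_config <- function() {
  smooth_scales <- c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0)
  other_scales <- c(0.7, 1.0, 1.6, 3.5, 5.0, 10.0)
  df <- rbind(
    data.frame(family = "gaussian_smoothing", scale = smooth_scales),
    do.call(rbind, lapply(setdiff(FEATURE_FAMILIES, "gaussian_smoothing"),
                          function(f) data.frame(family = f,
                                                 scale = other_scales))))
  feature_config(df$family, df$scale)
}

#' Build a filter-bank configuration
#' @param family character vector of feature family names.
#' @param scale positive sigma in pixels, one per entry.
#' @return A `feature_config` data.frame.
#' @export
feature_config <- function(family, scale) {
  bad <- setdiff(unique(family), FEATURE_FAMILIES)
  if (length(bad)) stop("unknown feature family: ", paste(bad, collapse = ", "))
  if (any(scale <= 0)) stop("scales must be positive")
  df <- data.frame(family = as.character(family), scale = as.numeric(scale),
                   stringsAsFactors = FALSE)
  class(df) <- c("feature_config", "data.frame")
  df
}

# names of the expanded features, 3 per eigenvalue family entry, 1 otherwise
feature_names <- function(config) {
  unlist(lapply(seq_len(nrow(config)), function(i) {
    f <- config$family[i]; s <- config$scale[i]
    base <- sprintf("%s_s%g", f, s)
    if (f %in% EIGEN_FAMILIES) paste0(base, "_ev", 1:3) else base
  }))
}

## --- 1-D kernels (correlation convention: out[i] = sum_o k[o] in[i+o]) -----

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  o <- (-r):r
  k <- exp(-o^2 / (2 * sigma^2))
  k / sum(k)
}

# normalized so the response to a unit ramp along the axis is exactly 1
deriv1_kernel <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  o <- (-r):r
  k <- -o * exp(-o^2 / (2 * sigma^2))
  k / sum(k * o)
}

# normalized so the response to i^2 is exactly 2 (the second derivative)
deriv2_kernel <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  o <- (-r):r
  k <- (o^2 / sigma^2 - 1) * exp(-o^2 / (2 * sigma^2))
  k <- k - mean(k)
  k / (sum(k * o^2) / 2)
}

# apply one 1-D kernel per axis (Z, Y, X) in sequence, reflecting boundaries
sep_filter <- function(arr, kz, ky, kx) {
  d <- dim(arr)
  out <- .conv3_axis(arr, d, kz, 0L)
  out <- .conv3_axis(out, d, ky, 1L)
  .conv3_axis(out, d, kx, 2L)
}

# per-axis sigma: isotropic in index space unless anisotropy correction is on
axis_sigmas <- function(sigma, spacing, anisotropy) {
  if (anisotropy) sigma * min(spacing) / spacing else rep(sigma, 3L)
}

gauss3 <- function(arr, sigma, spacing, anisotropy) {
  s <- axis_sigmas(sigma, spacing, anisotropy)
  sep_filter(arr, gaussian_kernel(s[1]), gaussian_kernel(s[2]),
             gaussian_kernel(s[3]))
}

# first derivative along `axis` of the sigma-smoothed volume
dgauss3 <- function(arr, sigma, spacing, anisotropy, axis) {
  s <- axis_sigmas(sigma, spacing, anisotropy)
  ks <- lapply(s, gaussian_kernel)
  ks[[axis]] <- deriv1_kernel(s[axis])
  sep_filter(arr, ks[[1]], ks[[2]], ks[[3]])
}

# mixed/second derivative: d2_axes is a length-3 count of derivative order
ddgauss3 <- function(arr, sigma, spacing, anisotropy, orders) {
  s <- axis_sigmas(sigma, spacing, anisotropy)
  ks <- vector("list", 3L)
  for (a in 1:3)
    ks[[a]] <- switch(orders[a] + 1L, gaussian_kernel(s[a]),
                      deriv1_kernel(s[a]), deriv2_kernel(s[a]))
  sep_filter(arr, ks[[1]], ks[[2]], ks[[3]])
}

#' Compute the filter-bank feature stack of a volume
#'
#' Per family at scale sigma: `gaussian_smoothing` is the Gaussian blur;
#' `laplacian_of_gaussian` the Laplacian of the blurred volume;
#' `gaussian_gradient_magnitude` the L2 norm of the Gaussian gradient;
#' `difference_of_gaussians` is blur(sigma) - blur(0.66 sigma);
#' `structure_tensor_eigenvalues` the three descending eigenvalues of the
#' structure tensor (inner scale sigma, outer scale sigma/2);
#' `hessian_of_gaussian_eigenvalues` the three descending eigenvalues of the
#' scale-sigma Hessian. Boundaries are handled by reflection.
#'
#' @param grid a [voxel_grid()] with finite intensities.
#' @param config a [feature_config()]; default [default_feature_config()].
#' @param anisotropy_correction if TRUE, per-axis sigma is divided by the
#'   spacing ratio so the filter footprint is isotropic in physical space.
#' @return An object of class `feature_stack`: a voxels x features numeric
#'   matrix (`values`; voxel order = linear array order of the (Z, Y, X)
#'   volume) plus `shape`, `spacing`, `feature_names` and the config.
#' @export
compute_feature_stack <- function(grid, config = default_feature_config(),
                                  anisotropy_correction = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!all(is.finite(grid$data))) stop("volume contains non-finite values")
  shp <- dim(grid$data)
  if (any(shp < 3L) && max(config$scale) >= 1)
    warning("volume has fewer than 3 voxels along an axis; ",
            "large-scale features are dominated by boundary reflection")
  arr <- grid$data
  storage.mode(arr) <- "double"
  nms <- feature_names(config)
  vals <- matrix(NA_real_, length(arr), length(nms))
  colnames(vals) <- nms
  sp <- grid$spacing
  aniso <- anisotropy_correction
  col <- 0L

  for (i in seq_len(nrow(config))) {
    fam <- config$family[i]; sg <- config$scale[i]
    if (fam == "gaussian_smoothing") {
      col <- col + 1L
      vals[, col] <- gauss3(arr, sg, sp, aniso)
    } else if (fam == "laplacian_of_gaussian") {
      col <- col + 1L
      vals[, col] <- ddgauss3(arr, sg, sp, aniso, c(2L, 0L, 0L)) +
        ddgauss3(arr, sg, sp, aniso, c(0L, 2L, 0L)) +
        ddgauss3(arr, sg, sp, aniso, c(0L, 0L, 2L))
    } else if (fam == "gaussian_gradient_magnitude") {
      col <- col + 1L
      vals[, col] <- sqrt(dgauss3(arr, sg, sp, aniso, 1L)^2 +
                          dgauss3(arr, sg, sp, aniso, 2L)^2 +
                          dgauss3(arr, sg, sp, aniso, 3L)^2)
    } else if (fam == "difference_of_gaussians") {
      col <- col + 1L
      vals[, col] <- gauss3(arr, sg, sp, aniso) -
        gauss3(arr, 0.66 * sg, sp, aniso)
    } else if (fam == "structure_tensor_eigenvalues") {
      gz <- dgauss3(arr, sg, sp, aniso, 1L)
      gy <- dgauss3(arr, sg, sp, aniso, 2L)
      gx <- dgauss3(arr, sg, sp, aniso, 3L)
      so <- sg / 2  # outer (integration) scale
      ev <- .sym3_eigenvalues(
        gauss3(array(gz * gz, shp), so, sp, aniso),
        gauss3(array(gy * gy, shp), so, sp, aniso),
        gauss3(array(gx * gx, shp), so, sp, aniso),
        gauss3(array(gz * gy, shp), so, sp, aniso),
        gauss3(array(gz * gx, shp), so, sp, aniso),
        gauss3(array(gy * gx, shp), so, sp, aniso))
      for (k in 1:3) { col <- col + 1L; vals[, col] <- ev[[k]] }
    } else {  # hessian_of_gaussian_eigenvalues
      ev <- .sym3_eigenvalues(
        ddgauss3(arr, sg, sp, aniso, c(2L, 0L, 0L)),
        ddgauss3(arr, sg, sp, aniso, c(0L, 2L, 0L)),
        ddgauss3(arr, sg, sp, aniso, c(0L, 0L, 2L)),
        ddgauss3(arr, sg, sp, aniso, c(1L, 1L, 0L)),
        ddgauss3(arr, sg, sp, aniso, c(1L, 0L, 1L)),
        ddgauss3(arr, sg, sp, aniso, c(0L, 1L, 1L)))
      for (k in 1:3) { col <- col + 1L; vals[, col] <- ev[[k]] }
    }
  }
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("feature stack contains non-finite values")
  structure(list(values = vals, shape = shp, spacing = sp,
                 feature_names = nms, config = config),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d feature(s) over %s volume\n",
              length(x$feature_names), paste(x$shape, collapse = "x")))
  invisible(x)
}

# linear (column-major) index of 0-based (z, y, x) voxels
voxel_linear_index <- function(z, y, x, shape) {
  1L + z + shape[1L] * (y + shape[2L] * x)
}

#' Train the four-class random-forest pixel classifier
#'
#' Fits an ensemble of randomized decision trees on the feature vectors at
#' the annotated voxels only, with class-balanced sample weights. Annotations
#' are canonicalized (sorted by voxel index) before fitting, so permuting
#' their order does not change the model.
#'
#' @param features a [compute_feature_stack()] result.
#' @param ann a `voxel_annotations` object; at least two classes and at least
#'   `n_min` total annotations.
#' @param n_trees number of trees (default 100).
#' @param seed integer seed making training deterministic.
#' @param n_min minimum total annotations (default 10).
#' @return An object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(features, ann, n_trees = 100L, seed = 1L,
                                   n_min = 10L) {
  stopifnot(inherits(features, "feature_stack"),
            inherits(ann, "voxel_annotations"))
  if (nrow(ann) < n_min)
    stop("need at least ", n_min, " annotations, got ", nrow(ann))
  if (length(unique(ann$label)) < 2L)
    stop("annotations must contain at least two distinct classes")
  shp <- features$shape
  if (any(ann$z >= shp[1]) || any(ann$y >= shp[2]) || any(ann$x >= shp[3]))
    stop("annotated voxel outside the feature volume")
  ord <- order(ann$z, ann$y, ann$x)
  ann <- ann[ord, , drop = FALSE]
  idx <- voxel_linear_index(ann$z, ann$y, ann$x, shp)
  df <- as.data.frame(features$values[idx, , drop = FALSE])
  df$.class <- factor(ann$label, levels = ANNOTATION_CLASSES)
  w <- 1 / table(df$.class)[df$.class]
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, probability = TRUE, seed = seed,
    num.threads = 1L, case.weights = as.numeric(w))
  structure(list(model = fit,
                 classes = ANNOTATION_CLASSES,
                 feature_names = features$feature_names,
                 n_trees = n_trees, seed = seed,
                 config = features$config),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d trees, %d features, classes: %s\n",
              x$n_trees, length(x$feature_names),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict per-voxel class probabilities
#'
#' @param model a [train_pixel_classifier()] result.
#' @param features a [compute_feature_stack()] result computed with the same
#'   configuration (feature names must match exactly).
#' @param chunk_voxels prediction chunk size (memory control).
#' @return An object of class `probability_map`: 4D array `data` with axes
#'   (class, Z, Y, X), per-voxel probabilities summing to 1.
#' @export
predict_probabilities <- function(model, features, chunk_voxels = 262144L) {
  stopifnot(inherits(model, "pixel_classifier"),
            inherits(features, "feature_stack"))
  if (!identical(model$feature_names, features$feature_names)) {
    missing_f <- setdiff(model$feature_names, features$feature_names)
    extra_f <- setdiff(features$feature_names, model$feature_names)
    stop("feature stack does not match the model's training features; ",
         "missing: [", paste(missing_f, collapse = ", "),
         "], extra: [", paste(extra_f, collapse = ", "), "]")
  }
  n <- nrow(features$values)
  probs <- matrix(0, n, length(model$classes),
                  dimnames = list(NULL, model$classes))
  starts <- seq(1L, n, by = chunk_voxels)
  for (s in starts) {
    e <- min(n, s + chunk_voxels - 1L)
    pred <- stats::predict(model$model,
                           data = as.data.frame(
                             features$values[s:e, , drop = FALSE]),
                           num.threads = 1L)$predictions
    probs[s:e, colnames(pred)] <- pred
  }
  rs <- rowSums(probs)
  probs <- probs / rs
  shp <- features$shape
  arr <- array(0, c(length(model$classes), shp))
  for (k in seq_along(model$classes)) arr[k, , , ] <- probs[, k]
  structure(list(data = arr, classes = model$classes,
                 spacing = features$spacing), class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<probability_map> %d class(es) over %d x %d x %d\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Binary mask with provenance
#' @param data logical 3D array (Z, Y, X).
#' @param spacing voxel pitch in um.
#' @param provenance optional list (source channel, class, threshold, mode).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing, provenance = list()) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("mask data must be a logical 3D array")
  structure(list(data = data, spacing = as.numeric(spacing),
                 provenance = provenance), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d, %d foreground voxel(s)\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Binarize a probability map
#'
#' In `"threshold"` mode a voxel is foreground when P(target_class) is at
#' least `threshold` (inclusive). In `"argmax"` mode a voxel is foreground
#' when the target class has the highest probability.
#'
#' @param probmap a [predict_probabilities()] result.
#' @param target_class one of the four annotation classes (default
#'   `"signal"`).
#' @param threshold probability cutoff in (0, 1); default 0.5.
#' @param mode `"threshold"` or `"argmax"`.
#' @return A [binary_mask()].
#' @export
binarize_probability <- function(probmap, target_class = "signal",
                                 threshold = 0.5,
                                 mode = c("threshold", "argmax")) {
  stopifnot(inherits(probmap, "probability_map"))
  mode <- match.arg(mode)
  k <- match(target_class, probmap$classes)
  if (is.na(k)) stop("unknown class '", target_class, "'; classes are: ",
                     paste(probmap$classes, collapse = ", "))
  if (mode == "threshold" && (threshold <= 0 || threshold >= 1))
    stop("threshold must lie strictly inside (0, 1)")
  p <- probmap$data[k, , , ]
  fg <- if (mode == "threshold") p >= threshold else {
    mx <- probmap$data[1, , , ]
    for (k2 in seq_along(probmap$classes)[-1L])
      mx <- pmax(mx, probmap$data[k2, , , ])
    p >= mx
  }
  binary_mask(array(fg, dim(probmap$data)[-1L]), probmap$spacing,
              provenance = list(class = target_class, threshold = threshold,
                                mode = mode))
}

#' Per-voxel argmax class labels from a probability map
#'
#' @param probmap a `probability_map`.
#' @return Integer 3D array of class codes (1-based index into
#'   `probmap$classes`; ties resolved toward the earlier class).
#' @export
classify_argmax <- function(probmap) {
  stopifnot(inherits(probmap, "probability_map"))
  shp <- dim(probmap$data)[-1L]
  best <- array(1L, shp)
  best_p <- probmap$data[1, , , ]
  for (k in seq_along(probmap$classes)[-1L]) {
    pk <- probmap$data[k, , , ]
    upd <- pk > best_p
    best[upd] <- k
    best_p[upd] <- pk[upd]
  }
  array(best, shp)
}

#' Persist / restore a trained classifier
#' @param model a `pixel_classifier`.
#' @param path file path.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "pixel_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pixel_classifier")) stop("not a saved pixel_classifier")
  m
}
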