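# Minimal-distance spatial statistics between tumour-microenvironment
# components: per-object nearest distances (centroid to structure, or
# centroid to centroid), their ECDF and kernel density, distance-band
# fractions, and the 20 um co-localization rule. All distances are 3D
# Euclidean distances in physical micrometres, anisotropy-aware.

new_distance_set <- function(df, source_channel = NA, target_channel = NA,
                             mode = NA) {
  if (any(df$distance_um < 0) || any(!is.finite(df$distance_um)))
    stop("distances must be finite and non-negative")
  attr(df, "source_channel") <- source_channel
  attr(df, "target_channel") <- target_channel
  attr(df, "mode") <- mode
  class(df) <- c("distance_set", "data.frame")
  df
}

#' Build a distance set from raw minimal distances
#'
#' Wraps an already-measured vector of per-object minimal distances (um) so
#' the ECDF/density/fraction operations can be applied to it.
#'
#' @param distances_um non-negative finite distances, one per source object.
#' @return A `distance_set`.
#' @export
distance_set <- function(distances_um) {
  new_distance_set(data.frame(source_id = seq_along(distances_um),
                              distance_um = as.numeric(distances_um),
                              nearest_index = NA_integer_),
                   mode = "external")
}

centroid_matrix <- function(table) {
  stopifnot(inherits(table, "object_table"))
  as.matrix(table[, c("z_um", "y_um", "x_um")])
}

#' Minimal distance from object centroids to a target structure
#'
#' For each source centroid, the Euclidean distance (um) to the nearest
#' foreground voxel centre of the target mask (voxel position = 0-based index
#' times spacing). The nearest-neighbour query runs on a kd-tree and is exact:
#' results equal an exhaustive all-voxel scan.
#'
#' @param sources an `object_table` of source objects (centroids in um).
#' @param target a [binary_mask()] with at least one foreground voxel, on the
#'   same spacing as the sources.
#' @return A `distance_set` with one record per source object
#'   (`source_id`, `distance_um`, `nearest_index` = linear index into the
#'   mask, plus nearest voxel coordinates in um).
#' @export
min_distance_to_mask <- function(sources, target) {
  stopifnot(inherits(sources, "object_table"), inherits(target, "binary_mask"))
  sp_src <- attr(sources, "spacing")
  if (!is.null(sp_src) && !all(is.na(sources$voxels)) &&
      !isTRUE(all.equal(sp_src, target$spacing)))
    stop("sources and target have inconsistent voxel spacing")
  fg <- which(target$data)
  if (!length(fg)) stop("target structure empty")
  co <- (arrayInd(fg, dim(target$data)) - 1L)  # 0-based (z, y, x)
  pts <- cbind(co[, 1L] * target$spacing[1L],
               co[, 2L] * target$spacing[2L],
               co[, 3L] * target$spacing[3L])
  res <- .kd_nearest(centroid_matrix(sources), pts, FALSE)
  new_distance_set(data.frame(source_id = sources$id,
                              distance_um = res$distance,
                              nearest_index = fg[res$index],
                              nearest_z_um = pts[res$index, 1L],
                              nearest_y_um = pts[res$index, 2L],
                              nearest_x_um = pts[res$index, 3L]),
                   mode = "to_mask")
}

#' Minimal centroid-to-centroid distance between two object tables
#'
#' @param sources,targets `object_table`s. When comparing a table against
#'   itself, set `exclude_self = TRUE` so each object is matched to its
#'   nearest *other* object; self-comparison without it is an error.
#' @param exclude_self drop the identity pairing (requires equally sized
#'   tables, interpreted row-by-row as the same objects).
#' @return A `distance_set` with `source_id`, `distance_um` and
#'   `nearest_index` (row of the target table).
#' @export
min_distance_between_objects <- function(sources, targets,
                                         exclude_self = FALSE) {
  stopifnot(inherits(sources, "object_table"),
            inherits(targets, "object_table"))
  if (nrow(targets) < 1L) stop("target table is empty")
  if (nrow(sources) < 1L) stop("source table is empty")
  src <- centroid_matrix(sources)
  tgt <- centroid_matrix(targets)
  if (!exclude_self && identical(dim(src), dim(tgt)) && all(src == tgt))
    stop("self-comparison of a table requires exclude_self = TRUE")
  if (exclude_self && nrow(src) != nrow(tgt))
    stop("exclude_self requires sources and targets of equal size")
  if (exclude_self && nrow(tgt) < 2L)
    stop("self-comparison needs at least two objects")
  res <- .kd_nearest(src, tgt, exclude_self)
  new_distance_set(data.frame(source_id = sources$id,
                              distance_um = res$distance,
                              nearest_index = res$index),
                   mode = "to_centroids")
}

#' Empirical cumulative distribution function of minimal distances
#'
#' Right-continuous step ECDF: F(x) = (number of records with d <= x) / n.
#'
#' @param distances a `distance_set` with at least one record.
#' @return A list of class `ecdf_curve` with sorted unique `x` (um) and
#'   cumulative fractions `F`.
#' @export
ecdf_curve <- function(distances) {
  stopifnot(inherits(distances, "distance_set"))
  d <- distances$distance_um
  if (!length(d)) stop("distance set is empty")
  x <- sort(unique(d))
  Fx <- vapply(x, function(v) mean(d <= v), numeric(1))
  structure(list(x = x, F = Fx, n = length(d)), class = "ecdf_curve")
}

#' Fraction of objects within a distance threshold
#'
#' @param distances a `distance_set`.
#' @param d threshold in um (inclusive: records with distance <= d count).
#' @return Fraction in \[0, 1\].
#' @export
fraction_within <- function(distances, d) {
  stopifnot(inherits(distances, "distance_set"))
  if (!nrow(distances)) stop("distance set is empty")
  if (d < 0) stop("threshold must be >= 0")
  mean(distances$distance_um <= d)
}

#' Fraction of objects within a distance band
#'
#' Counts records with `lo < d <= hi`; band fractions over a partition of the
#' half-line therefore sum to 1 together with the share at or below the
#' partition origin.
#'
#' @param distances a `distance_set`.
#' @param lo,hi band limits in um, `lo < hi` (use `Inf` for an open top band).
#' @return Fraction in \[0, 1\].
#' @export
band_fraction <- function(distances, lo, hi) {
  stopifnot(inherits(distances, "distance_set"))
  if (lo >= hi) stop("band requires lo < hi")
  mean(distances$distance_um > lo & distances$distance_um <= hi)
}

#' Co-localization under a centroid-distance rule
#'
#' A source object is co-localized when its centroid lies within `threshold`
#' (inclusive) of some target object's centroid; the default threshold is
#' 20 um. The fraction is relative to all source objects.
#'
#' @param sources,targets non-empty `object_table`s.
#' @param threshold_um co-localization distance (default 20).
#' @param exclude_self see [min_distance_between_objects()].
#' @return A list of class `colocalization_result`: `threshold_um`,
#'   `n_sources`, `n_colocalized`, `fraction`, and the underlying
#'   `distance_set`.
#' @export
colocalization <- function(sources, targets, threshold_um = 20,
                           exclude_self = FALSE) {
  ds <- min_distance_between_objects(sources, targets,
                                     exclude_self = exclude_self)
  n_co <- sum(ds$distance_um <= threshold_um)
  structure(list(threshold_um = threshold_um,
                 n_sources = nrow(ds),
                 n_colocalized = n_co,
                 fraction = n_co / nrow(ds),
                 distances = ds),
            class = "colocalization_result")
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat(sprintf(
    "<colocalization> %d / %d source(s) within %.3g um (fraction %.3f)\n",
    x$n_colocalized, x$n_sources, x$threshold_um, x$fraction))
  invisible(x)
}

# Scott's rule bandwidth for a 1-D Gaussian KDE: sd(x) * n^(-1/5)
scott_bandwidth <- function(x) stats::sd(x) * length(x)^(-1 / 5)

#' Gaussian kernel density curve of minimal distances with mode detection
#'
#' Evaluates a Gaussian KDE on a uniform grid over \[0, 1.1 * max(d)\].
#' Bandwidth defaults to Scott's rule (sd * n^(-1/5)) and is echoed in the
#' result. Modes are the strict local maxima of the evaluated density.
#'
#' @param distances a `distance_set` with >= 2 records and nonzero variance.
#' @param bandwidth `"auto"` (Scott) or a bandwidth in um.
#' @param grid_points evaluation grid size (default 512).
#' @return A list of class `density_curve`: `x`, `density`, `bandwidth_um`,
#'   `modes_um`.
#' @export
density_curve <- function(distances, bandwidth = "auto", grid_points = 512L) {
  stopifnot(inherits(distances, "distance_set"))
  d <- distances$distance_um
  if (length(d) < 2L) stop("need at least 2 records for a density curve")
  if (stats::sd(d) == 0) stop("distances have zero variance")
  bw <- if (identical(bandwidth, "auto")) scott_bandwidth(d)
        else as.numeric(bandwidth)
  if (bw <= 0) stop("bandwidth must be positive")
  dens <- stats::density(d, bw = bw, kernel = "gaussian", from = 0,
                         to = max(d) * 1.1, n = grid_points)
  # renormalize over the evaluation grid: distances live on [0, Inf) and the
  # kernel mass leaking below zero would otherwise make the curve sum short
  y <- dens$y
  dx <- dens$x[2L] - dens$x[1L]
  trapz <- sum((y[-1L] + y[-length(y)]) / 2) * dx
  y <- y / trapz
  k <- 2:(length(y) - 1L)
  # strict local maxima; a floor at 0.1% of the peak rejects numerical
  # ripples in the far tails of the FFT-evaluated density
  is_mode <- y[k] > y[k - 1L] & y[k] > y[k + 1L] & y[k] >= max(y) * 1e-3
  structure(list(x = dens$x, density = y, bandwidth_um = bw,
                 modes_um = dens$x[k][is_mode], n = length(d)),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("<density_curve> bw = %.3g um, mode(s) at %s um\n",
              x$bandwidth_um,
              paste(signif(x$modes_um, 4), collapse = ", ")))
  invisible(x)
}

#' Write a distance set to CSV
#' @param distances a `distance_set`.
#' @param path output CSV path.
#' @export
write_distance_set <- function(distances, path) {
  utils::write.csv(as.data.frame(distances), path, row.names = FALSE)
  invisible(path)
}
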