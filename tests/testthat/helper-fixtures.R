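# Shared fixtures: tiny phantoms, random masks, and independent brute-force
# oracles against which the fast implementations are checked.

# a small, quickly rendered phantom
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(24L, 48L, 48L),
               colonies = list(count = 4L, radius_um = c(15, 25)),
               vessels = list(count = 1L),
               puncta = list(count = 5L),
               artifacts = list(af_tube_count = 1L),
               ...)
}

# noise-free variant for exact-geometry assertions
noiseless_phantom_spec <- function(...) {
  small_phantom_spec(noise = list(poisson = FALSE, read_sd = 0), ...)
}

random_mask <- function(shape, p = 0.1, spacing = c(1, 1, 1)) {
  binary_mask(array(stats::runif(prod(shape)) < p, shape), spacing)
}

# exhaustive-scan oracle: minimal Euclidean distance (um) from each query
# point to any foreground voxel centre of `mask`; plain vectorised R,
# independent of the kd-tree path
brute_force_min_dist <- function(points_um, mask) {
  fg <- which(mask$data)
  co <- arrayInd(fg, dim(mask$data)) - 1L
  tz <- co[, 1] * mask$spacing[1]
  ty <- co[, 2] * mask$spacing[2]
  tx <- co[, 3] * mask$spacing[3]
  vapply(seq_len(nrow(points_um)), function(i) {
    dz <- points_um[i, 1] - tz
    dy <- points_um[i, 2] - ty
    dx <- points_um[i, 3] - tx
    min(sqrt(dz^2 + dy^2 + dx^2))
  }, numeric(1))
}

# brute-force centroid-to-centroid nearest distance oracle
brute_force_pairwise_min <- function(src, tgt, exclude_self = FALSE) {
  vapply(seq_len(nrow(src)), function(i) {
    dz <- src[i, 1] - tgt[, 1]
    dy <- src[i, 2] - tgt[, 2]
    dx <- src[i, 3] - tgt[, 3]
    d <- sqrt(dz^2 + dy^2 + dx^2)
    if (exclude_self) d <- d[-i]
    min(d)
  }, numeric(1))
}

# Designed geometry: a straight vessel along Y (axis at z = 150 um,
# x = 104 um, radius 12 um), whose deepest mask voxels lie in the plane
# z = 160 um, plus colonies pinned directly below at z = 160 + d. Colony
# centres sit exactly on voxel centres and share the vessel's x, so the
# minimal centroid-to-mask distance of each colony is its designed d um
# exactly (the nearest vessel voxel is the one straight above it).
designed_vessel_phantom <- function(dists_um = c(10, 50, 100, 300),
                                    per_dist = 5L) {
  spacing <- c(10, 6.5, 6.5)
  shape <- c(52L, 96L, 32L)
  extent <- (shape - 1L) * spacing
  path <- rbind(c(150, 0, 104), c(150, extent[2], 104))
  ys <- 65 + (seq_len(per_dist) - 1) * 117  # multiples of 6.5, >= 2r apart
  centers <- do.call(rbind, lapply(dists_um, function(d)
    cbind(z = 160 + d, y = ys, x = 104)))
  spec <- phantom_spec(
    shape = shape, spacing = spacing,
    colonies = list(radius_um = 18, amplitude = 2000, centers_um = centers),
    vessels = list(radius_um = 12, paths_um = list(path)),
    puncta = list(count = 0L),
    artifacts = list(z_leakage_fraction = 0, af_tube_count = 0L),
    noise = list(poisson = FALSE, read_sd = 0))
  list(spec = spec, centers = centers,
       designed_dists = rep(dists_um, each = per_dist))
}
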