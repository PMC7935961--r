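# Synthetic multi-channel phantoms emulating cleared-lung light-sheet data:
# ellipsoidal metastatic colonies, tubular vessel networks, small puncta,
# plus the two artifact classes that must be annotated separately in real
# stacks (axial signal leakage, strong autofluorescent tubes) over a weak
# diffuse background.

#' Specification of a synthetic phantom
#'
#' Defaults define the reference phantom used throughout the test-bench:
#' a desk-scale anisotropic volume (64 x 128 x 128 voxels at 10 x 6.5 x 6.5
#' um) containing bright colonies, two vessel trees, puncta, axial leakage
#' under a fraction of the colonies, and autofluorescent tubes present in
#' every channel.
#'
#' @param shape volume shape (Z, Y, X) in voxels.
#' @param spacing voxel pitch (z, y, x) in micrometres.
#' @param colonies list: `count`, `radius_um` (length-2 range), `amplitude`,
#'   and optionally `centers_um` (matrix with columns z,y,x in um) to pin
#'   colony centres at designed positions.
#' @param vessels list: `count`, `radius_um`, `tortuosity` (0 = straight),
#'   `amplitude`, and optionally `paths_um` (list of waypoint matrices) to
#'   pin centrelines.
#' @param puncta list: `count`, `radius_um`, `amplitude`.
#' @param artifacts list: `z_leakage_fraction` of colonies trailing an axial
#'   streak, `leakage_decay_vox` (exponential decay length in voxels),
#'   `leakage_amplitude_fraction` of the colony amplitude,
#'   `af_tube_count` and `af_amplitude` for autofluorescent tubes.
#' @param background list: `mean` intensity (counts).
#' @param noise list: `poisson` (logical, shot noise) and `read_sd`
#'   (Gaussian read noise sd in counts); set both off for noise-free phantoms.
#' @param edge_width_um width of the Gaussian edge of every rendered object;
#'   the labelled extent ends where intensity falls to half the amplitude.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 128L, 128L),
                         spacing = c(10, 6.5, 6.5),
                         colonies = list(),
                         vessels = list(),
                         puncta = list(),
                         artifacts = list(),
                         background = list(),
                         noise = list(),
                         edge_width_um = NULL) {
  spec <- list(
    shape = as.integer(shape),
    spacing = as.numeric(spacing),
    colonies = utils::modifyList(
      list(count = 20L, radius_um = c(15, 40), amplitude = 2000,
           centers_um = NULL), colonies),
    vessels = utils::modifyList(
      list(count = 2L, radius_um = 12, tortuosity = 0.3, amplitude = 1500,
           paths_um = NULL), vessels),
    puncta = utils::modifyList(
      list(count = 30L, radius_um = 8, amplitude = 1200), puncta),
    artifacts = utils::modifyList(
      list(z_leakage_fraction = 0.5, leakage_decay_vox = 5,
           leakage_amplitude_fraction = 0.3,
           af_tube_count = 2L, af_amplitude = 800), artifacts),
    background = utils::modifyList(list(mean = 100), background),
    noise = utils::modifyList(list(poisson = TRUE, read_sd = 20), noise),
    edge_width_um = if (is.null(edge_width_um)) min(as.numeric(spacing))
                    else edge_width_um
  )
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (length(spec$shape) != 3L || any(spec$shape < 1L))
    stop("shape must be three positive integers (Z, Y, X)")
  if (any(spec$spacing <= 0)) stop("spacing must be strictly positive")
  counts <- c(spec$colonies$count, spec$vessels$count, spec$puncta$count,
              spec$artifacts$af_tube_count)
  if (any(counts < 0)) stop("object counts must be >= 0")
  if (any(c(spec$colonies$radius_um, spec$vessels$radius_um,
            spec$puncta$radius_um) <= 0))
    stop("radii must be > 0")
  amps <- c(spec$colonies$amplitude, spec$vessels$amplitude,
            spec$puncta$amplitude, spec$artifacts$af_amplitude)
  if (any(amps <= spec$background$mean))
    stop("object amplitudes must exceed the background mean")
  extent <- (spec$shape - 1L) * spec$spacing
  if (max(spec$colonies$radius_um) * 2 > max(extent))
    stop("shape too small to contain a colony of the largest radius")
  invisible(spec)
}

#' Read a phantom specification from YAML
#' @param path YAML file whose keys override [phantom_spec()] defaults.
#' @return A `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("shape", "spacing", "edge_width_um"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  for (nm in c("colonies", "vessels", "puncta", "artifacts", "background",
               "noise"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(args$colonies$centers_um))
    args$colonies$centers_um <- do.call(rbind, args$colonies$centers_um)
  if (!is.null(args$vessels$paths_um))
    args$vessels$paths_um <- lapply(args$vessels$paths_um,
                                    function(p) do.call(rbind, p))
  do.call(phantom_spec, args)
}

# run expr with a temporary RNG state seeded by `seed`
with_phantom_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# intensity profile: flat core of amplitude A out to (r - w), Gaussian edge
# such that intensity at distance r is exactly A/2; labels end at r.
edge_profile <- function(d, r, A, w) {
  w <- min(w, r / 2)
  sigma <- w / sqrt(2 * log(2))
  out <- numeric(length(d))
  core <- d <= (r - w)
  out[core] <- A
  out[!core] <- A * exp(-(d[!core] - (r - w))^2 / (2 * sigma^2))
  out
}

# class codes in the truth label volumes
PHANTOM_CLASS_CODES <- c(signal = 1L, z_leakage = 2L, autofluorescence = 3L,
                         background = 4L)

# stamp a sphere onto intensity/label arrays (in place via return)
stamp_sphere <- function(intens, labels, center_um, radius_um, amplitude,
                         spacing, edge_w, class_code) {
  shp <- dim(intens)
  reach <- radius_um + 3 * edge_w
  lo <- pmax(0L, floor((center_um - reach) / spacing))
  hi <- pmin(shp - 1L, ceiling((center_um + reach) / spacing))
  if (any(lo > hi)) return(list(intens = intens, labels = labels, voxels = 0L))
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  dz2 <- (iz * spacing[1] - center_um[1])^2
  dy2 <- (iy * spacing[2] - center_um[2])^2
  dx2 <- (ix * spacing[3] - center_um[3])^2
  d <- sqrt(outer(outer(dz2, dy2, `+`), dx2, `+`))
  add <- array(edge_profile(as.vector(d), radius_um, amplitude, edge_w), dim(d))
  intens[iz + 1L, iy + 1L, ix + 1L] <- intens[iz + 1L, iy + 1L, ix + 1L] + add
  inside <- d <= radius_um
  sub <- labels[iz + 1L, iy + 1L, ix + 1L]
  claim <- inside & (sub > class_code)  # precedence: lower code wins
  sub[claim] <- class_code
  labels[iz + 1L, iy + 1L, ix + 1L] <- sub
  list(intens = intens, labels = labels, voxels = sum(inside))
}

# persistent random walk centreline through the physical volume
random_centerline <- function(extent, tortuosity, step) {
  start <- c(stats::runif(1, 0, extent[1]), stats::runif(1, 0, extent[2]),
             stats::runif(1, 0, extent[3]))
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  n_steps <- ceiling(1.5 * max(extent) / step)
  pts <- matrix(NA_real_, n_steps + 1L, 3L)
  pts[1L, ] <- start
  p <- start
  for (i in seq_len(n_steps)) {
    dir <- dir + tortuosity * stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    p2 <- p + step * dir
    for (a in 1:3) {  # reflect at the physical boundary
      if (p2[a] < 0) { p2[a] <- -p2[a]; dir[a] <- -dir[a] }
      if (p2[a] > extent[a]) { p2[a] <- 2 * extent[a] - p2[a]; dir[a] <- -dir[a] }
    }
    p <- p2
    pts[i + 1L, ] <- p
  }
  pts
}

# resample a waypoint polyline at roughly `step` spacing
densify_path <- function(pts, step) {
  out <- list(pts[1L, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / step))
    tt <- seq_len(n) / n
    out[[i + 1L]] <- cbind(a[1] + tt * (b[1] - a[1]),
                           a[2] + tt * (b[2] - a[2]),
                           a[3] + tt * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

stamp_tube <- function(intens, labels, pts, radius_um, amplitude, spacing,
                       edge_w, class_code) {
  shp <- dim(intens)
  # min distance to the sampled centreline, maintained on a full grid
  dist <- array(Inf, shp)
  reach <- radius_um + 3 * edge_w
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    lo <- pmax(0L, floor((p - reach) / spacing))
    hi <- pmin(shp - 1L, ceiling((p + reach) / spacing))
    if (any(lo > hi)) next
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    dz2 <- (iz * spacing[1] - p[1])^2
    dy2 <- (iy * spacing[2] - p[2])^2
    dx2 <- (ix * spacing[3] - p[3])^2
    d <- sqrt(outer(outer(dz2, dy2, `+`), dx2, `+`))
    cur <- dist[iz + 1L, iy + 1L, ix + 1L]
    dist[iz + 1L, iy + 1L, ix + 1L] <- pmin(cur, d)
  }
  hit <- is.finite(dist) & dist <= reach
  if (any(hit)) {
    intens[hit] <- intens[hit] +
      edge_profile(dist[hit], radius_um, amplitude, edge_w)
    inside <- dist <= radius_um
    claim <- inside & labels > class_code
    labels[claim] <- class_code
    nvox <- sum(inside)
  } else nvox <- 0L
  list(intens = intens, labels = labels, voxels = nvox,
       center = colMeans(pts))
}

place_centers <- function(n, radii, extent, min_gap_um, max_tries = 2000L,
                          what = "object") {
  centers <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- c(stats::runif(1, radii[i], extent[1] - radii[i]),
                stats::runif(1, radii[i], extent[2] - radii[i]),
                stats::runif(1, radii[i], extent[3] - radii[i]))
      if (i == 1L) { ok <- TRUE } else {
        prev <- centers[seq_len(i - 1L), , drop = FALSE]
        sep <- sqrt(rowSums(sweep(prev, 2L, cand)^2))
        ok <- all(sep >= radii[seq_len(i - 1L)] + radii[i] + min_gap_um)
      }
      if (ok) { centers[i, ] <- cand; break }
    }
    if (!ok) stop("could not place ", what, " ", i, " of ", n,
                  " within the retry budget; channel too crowded")
  }
  centers
}

#' Generate a multi-channel phantom with ground truth
#'
#' Renders three channels — `cancer` (colonies), `vessel` (tubes), `puncta`
#' (small spheres) — over a uniform background. A stated fraction of colonies
#' trail an exponentially decaying streak along +Z (the axial signal-leakage
#' artifact of light-sheet stacks); autofluorescent tubes are added to every
#' channel. Per channel, every voxel carries exactly one truth class with
#' precedence signal > z_leakage > autofluorescence > background. Intensities
#' are the additive class renderings plus optional Poisson shot noise and
#' Gaussian read noise. The same seed reproduces the phantom bit-identically.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for all randomness in the generator.
#' @return A list with `channels` (a [channel_stack()]) and `truth`
#'   (class `phantom_truth`: per-channel label volumes coded
#'   signal=1, z_leakage=2, autofluorescence=3, background=4, an object
#'   `catalog` data.frame, and the seed used).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_phantom_seed(seed, {
    shp <- spec$shape
    sp <- spec$spacing
    extent <- (shp - 1L) * sp
    ew <- spec$edge_width_um
    bg_code <- PHANTOM_CLASS_CODES[["background"]]

    blank <- function() array(0, shp)
    labs <- function() array(bg_code, shp)
    intens <- list(cancer = blank(), vessel = blank(), puncta = blank())
    labels <- list(cancer = labs(), vessel = labs(), puncta = labs())
    catalog <- list()

    ## colonies (cancer channel)
    nc <- spec$colonies$count
    if (!is.null(spec$colonies$centers_um)) {
      centers <- spec$colonies$centers_um
      nc <- nrow(centers)
      radii <- rep_len(if (length(spec$colonies$radius_um) == 1L)
        spec$colonies$radius_um else mean(spec$colonies$radius_um), nc)
    } else if (nc > 0L) {
      rr <- spec$colonies$radius_um
      radii <- if (length(rr) == 1L) rep(rr, nc) else
        stats::runif(nc, rr[1], rr[2])
      centers <- place_centers(nc, radii, extent, 2 * max(sp),
                               what = "colony (cancer channel)")
    }
    if (nc > 0L) {
      for (i in seq_len(nc)) {
        st <- stamp_sphere(intens$cancer, labels$cancer, centers[i, ],
                           radii[i], spec$colonies$amplitude, sp, ew,
                           PHANTOM_CLASS_CODES[["signal"]])
        intens$cancer <- st$intens; labels$cancer <- st$labels
        catalog[[length(catalog) + 1L]] <- data.frame(
          channel = "cancer", class = "signal", id = i,
          z_um = centers[i, 1], y_um = centers[i, 2], x_um = centers[i, 3],
          radius_um = radii[i], voxels = st$voxels)
      }
      ## axial leakage below a fraction of colonies
      n_leak <- round(spec$artifacts$z_leakage_fraction * nc)
      if (n_leak > 0L) {
        leak_ids <- sort(sample.int(nc, n_leak))
        Ldec <- spec$artifacts$leakage_decay_vox
        A_leak <- spec$artifacts$leakage_amplitude_fraction *
          spec$colonies$amplitude
        leak_code <- PHANTOM_CLASS_CODES[["z_leakage"]]
        for (i in leak_ids) {
          c_um <- centers[i, ]; r <- radii[i]
          z0 <- floor((c_um[1] + r) / sp[1]) + 1L  # first voxel below colony
          zmax <- min(shp[1] - 1L, z0 + ceiling(4 * Ldec))
          if (z0 > zmax) next
          iy <- max(0L, floor((c_um[2] - r) / sp[2])):
                min(shp[2] - 1L, ceiling((c_um[2] + r) / sp[2]))
          ix <- max(0L, floor((c_um[3] - r) / sp[3])):
                min(shp[3] - 1L, ceiling((c_um[3] + r) / sp[3]))
          in_fp <- outer((iy * sp[2] - c_um[2])^2,
                         (ix * sp[3] - c_um[3])^2, `+`) <= r^2
          if (!any(in_fp)) next
          for (zi in z0:zmax) {
            amp <- A_leak * exp(-(zi - z0) / Ldec)
            pl <- intens$cancer[zi + 1L, iy + 1L, ix + 1L]
            pl[in_fp] <- pl[in_fp] + amp
            intens$cancer[zi + 1L, iy + 1L, ix + 1L] <- pl
            ll <- labels$cancer[zi + 1L, iy + 1L, ix + 1L]
            claim <- in_fp & ll > leak_code
            ll[claim] <- leak_code
            labels$cancer[zi + 1L, iy + 1L, ix + 1L] <- ll
          }
        }
      }
    }

    ## vessels (vessel channel)
    vpaths <- spec$vessels$paths_um
    nv <- if (!is.null(vpaths)) length(vpaths) else spec$vessels$count
    step <- min(sp) / 2
    if (nv > 0L) {
      for (i in seq_len(nv)) {
        pts <- if (!is.null(vpaths)) densify_path(vpaths[[i]], step)
               else random_centerline(extent, spec$vessels$tortuosity, step)
        st <- stamp_tube(intens$vessel, labels$vessel, pts,
                         spec$vessels$radius_um, spec$vessels$amplitude, sp,
                         ew, PHANTOM_CLASS_CODES[["signal"]])
        intens$vessel <- st$intens; labels$vessel <- st$labels
        catalog[[length(catalog) + 1L]] <- data.frame(
          channel = "vessel", class = "signal", id = i,
          z_um = st$center[1], y_um = st$center[2], x_um = st$center[3],
          radius_um = spec$vessels$radius_um, voxels = st$voxels)
      }
    }

    ## puncta (puncta channel)
    np <- spec$puncta$count
    if (np > 0L) {
      pr <- rep(spec$puncta$radius_um, np)
      pcenters <- place_centers(np, pr, extent, 2 * max(sp),
                                what = "punctum (puncta channel)")
      for (i in seq_len(np)) {
        st <- stamp_sphere(intens$puncta, labels$puncta, pcenters[i, ],
                           pr[i], spec$puncta$amplitude, sp, ew,
                           PHANTOM_CLASS_CODES[["signal"]])
        intens$puncta <- st$intens; labels$puncta <- st$labels
        catalog[[length(catalog) + 1L]] <- data.frame(
          channel = "puncta", class = "signal", id = i,
          z_um = pcenters[i, 1], y_um = pcenters[i, 2], x_um = pcenters[i, 3],
          radius_um = pr[i], voxels = st$voxels)
      }
    }

    ## autofluorescent tubes, added to ALL channels
    naf <- spec$artifacts$af_tube_count
    af_code <- PHANTOM_CLASS_CODES[["autofluorescence"]]
    if (naf > 0L) {
      for (i in seq_len(naf)) {
        pts <- random_centerline(extent, spec$vessels$tortuosity, step)
        for (ch in names(intens)) {
          st <- stamp_tube(intens[[ch]], labels[[ch]], pts,
                           spec$vessels$radius_um,
                           spec$artifacts$af_amplitude, sp, ew, af_code)
          intens[[ch]] <- st$intens; labels[[ch]] <- st$labels
          catalog[[length(catalog) + 1L]] <- data.frame(
            channel = ch, class = "autofluorescence", id = i,
            z_um = st$center[1], y_um = st$center[2], x_um = st$center[3],
            radius_um = spec$vessels$radius_um, voxels = st$voxels)
        }
      }
    }

    ## background offset + noise
    for (ch in names(intens)) {
      img <- intens[[ch]] + spec$background$mean
      if (isTRUE(spec$noise$poisson))
        img <- array(stats::rpois(length(img), lambda = img), dim(img))
      if (spec$noise$read_sd > 0)
        img <- img + stats::rnorm(length(img), 0, spec$noise$read_sd)
      intens[[ch]] <- pmax(array(img, dim(intens[[ch]])), 0)
    }

    channels <- channel_stack(lapply(intens, voxel_grid, spacing = sp))
    truth <- structure(list(
      labels = labels,
      classes = names(PHANTOM_CLASS_CODES),
      catalog = do.call(rbind, catalog),
      spacing = sp,
      seed = seed), class = "phantom_truth")
    list(channels = channels, truth = truth)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d object(s) across channels %s\n",
              nrow(x$catalog), paste(names(x$labels), collapse = ", ")))
  invisible(x)
}

#' Sample sparse training annotations from phantom ground truth
#'
#' Draws a uniform random sample without replacement of `n_per_class` voxels
#' per annotation class from one channel's truth label volume, emulating the
#' sparse scribbles a human annotator places to train the pixel classifier.
#'
#' @param truth a `phantom_truth`.
#' @param channel channel name.
#' @param n_per_class voxels to draw per class present in the volume.
#' @param seed integer seed.
#' @param classes which classes to sample (default: all four).
#' @return A `voxel_annotations` data.frame (0-based indices).
#' @export
sample_annotations <- function(truth, channel, n_per_class, seed = 1L,
                               classes = names(PHANTOM_CLASS_CODES)) {
  stopifnot(inherits(truth, "phantom_truth"))
  lab <- truth$labels[[channel]]
  if (is.null(lab)) stop("unknown channel: ", channel)
  shp <- dim(lab)
  with_phantom_seed(seed, {
    rows <- list()
    for (cls in classes) {
      code <- PHANTOM_CLASS_CODES[[cls]]
      idx <- which(lab == code)
      if (length(idx) < n_per_class)
        stop("class '", cls, "' has only ", length(idx),
             " voxels; cannot sample ", n_per_class)
      pick <- sample(idx, n_per_class)
      a <- arrayInd(pick, shp) - 1L  # 0-based (z, y, x)
      rows[[cls]] <- data.frame(z = a[, 1], y = a[, 2], x = a[, 3],
                                label = cls, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    annotations(df$z, df$y, df$x, df$label, shp)
  })
}
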