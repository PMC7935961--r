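# From binary masks to object tables: 3D connected components, centres of
# gravity in physical coordinates, colony counts and physical volumes.

#' Label connected components of a binary mask
#'
#' Maximal connected components under 6-, 18- or 26-connectivity (default 26:
#' anisotropic light-sheet voxels make 6-connectivity split diagonally
#' touching structures). Labels are canonical: components are numbered by the
#' raster-scan (linear array) order of their first voxel.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26.
#' @return An object of class `label_grid` with integer `data` (0 background,
#'   1..K objects), `spacing` and `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- .label_cc3(mask$data, dim(mask$data), as.integer(connectivity))
  structure(list(data = lab, spacing = mask$spacing,
                 n_components = attr(lab, "n_components"),
                 connectivity = as.integer(connectivity)),
            class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  cat(sprintf("<label_grid> %d component(s), connectivity %d\n",
              x$n_components, x$connectivity))
  invisible(x)
}

#' Extract per-object measurements from a label grid
#'
#' The centroid (centre of gravity) is the unweighted mean of the member
#' voxel-centre positions in micrometres (position = 0-based index times
#' spacing); the physical volume is voxel count times the voxel volume.
#' Objects below `min_voxels` are dropped and ids re-indexed contiguously.
#'
#' @param labels a [label_components()] result.
#' @param min_voxels minimum voxel count to keep an object (default 1 = no
#'   filter; no size filter is applied unless requested).
#' @return A data.frame of class `object_table` with columns `id`, `z_um`,
#'   `y_um`, `x_um`, `voxels`, `volume_um3` and bounding-box columns
#'   (0-based voxel indices). Spacing is carried in attribute `spacing`.
#' @export
extract_objects <- function(labels, min_voxels = 1L) {
  stopifnot(inherits(labels, "label_grid"))
  sp <- labels$spacing
  shp <- dim(labels$data)
  vox_vol <- prod(sp)
  idx <- which(labels$data > 0L)
  empty <- data.frame(id = integer(), z_um = numeric(), y_um = numeric(),
                      x_um = numeric(), voxels = integer(),
                      volume_um3 = numeric(),
                      bbox_z0 = integer(), bbox_z1 = integer(),
                      bbox_y0 = integer(), bbox_y1 = integer(),
                      bbox_x0 = integer(), bbox_x1 = integer())
  if (!length(idx)) {
    attr(empty, "spacing") <- sp
    class(empty) <- c("object_table", "data.frame")
    return(empty)
  }
  ids <- labels$data[idx]
  co <- arrayInd(idx, shp) - 1L  # 0-based (z, y, x)
  n <- tabulate(ids, nbins = labels$n_components)
  zc <- rowsum(co[, 1L], ids)[, 1L] / n
  yc <- rowsum(co[, 2L], ids)[, 1L] / n
  xc <- rowsum(co[, 3L], ids)[, 1L] / n
  agg <- function(f, col) as.integer(tapply(co[, col], ids, f))
  tab <- data.frame(
    id = seq_len(labels$n_components),
    z_um = zc * sp[1L], y_um = yc * sp[2L], x_um = xc * sp[3L],
    voxels = n, volume_um3 = n * vox_vol,
    bbox_z0 = agg(min, 1L), bbox_z1 = agg(max, 1L),
    bbox_y0 = agg(min, 2L), bbox_y1 = agg(max, 2L),
    bbox_x0 = agg(min, 3L), bbox_x1 = agg(max, 3L))
  tab <- tab[tab$voxels >= min_voxels, , drop = FALSE]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "spacing") <- sp
  attr(tab, "min_voxels") <- as.integer(min_voxels)
  class(tab) <- c("object_table", "data.frame")
  tab
}

#' Build an object table directly from centroid coordinates
#'
#' Convenience constructor for tables of point-like objects (e.g. designed
#' phantom geometry or external centroid lists).
#'
#' @param z_um,y_um,x_um centroid coordinates in micrometres.
#' @param spacing voxel pitch carried for downstream consistency checks.
#' @return An `object_table`.
#' @export
object_table <- function(z_um, y_um, x_um, spacing = c(1, 1, 1)) {
  n <- length(z_um)
  tab <- data.frame(id = seq_len(n), z_um = as.numeric(z_um),
                    y_um = as.numeric(y_um), x_um = as.numeric(x_um),
                    voxels = rep(NA_integer_, n),
                    volume_um3 = rep(NA_real_, n))
  attr(tab, "spacing") <- as.numeric(spacing)
  class(tab) <- c("object_table", "data.frame")
  tab
}

#' Summarize an object table into colony-level statistics
#'
#' @param table an `object_table`.
#' @param channel optional channel identity recorded in the summary.
#' @return A list of class `colony_summary`: `count`, `total_volume_um3`,
#'   `channel`.
#' @export
summarize_objects <- function(table, channel = NA_character_) {
  stopifnot(inherits(table, "object_table"))
  structure(list(count = nrow(table),
                 total_volume_um3 = if (nrow(table)) sum(table$volume_um3)
                                    else 0,
                 channel = channel),
            class = "colony_summary")
}

#' @export
print.colony_summary <- function(x, ...) {
  cat(sprintf("<colony_summary>%s count = %d, total volume = %.1f um^3\n",
              if (is.na(x$channel)) "" else paste0(" [", x$channel, "]"),
              x$count, x$total_volume_um3))
  invisible(x)
}

#' Write an object table to CSV
#' @param table an `object_table`.
#' @param path output CSV path.
#' @export
write_object_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
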