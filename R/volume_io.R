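#' @useDynLib tmeprofiler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The four annotation classes used throughout: true signal, signal leakage
# along the Z axis, strong autofluorescence (bronchi/vessels), and weak
# diffuse background.
ANNOTATION_CLASSES <- c("signal", "z_leakage", "autofluorescence", "background")

#' Single-channel 3D volume with physical voxel spacing
#'
#' A `voxel_grid` holds one channel of a 3D fluorescence volume as an array in
#' (Z, Y, X) axis order plus the anisotropic voxel spacing in micrometres.
#' Voxel indices are 0-based and a voxel's physical position is its centre,
#' `index * spacing`, so voxel (0,0,0) sits at the physical origin.
#'
#' @param data 3D numeric array, axis order (Z, Y, X). Raw channels are
#'   16-bit unsigned intensities; derived volumes may be float.
#' @param spacing numeric length-3, voxel pitch in micrometres as (z, y, x);
#'   strictly positive and finite.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array in (Z, Y, X) order")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("spacing must be three strictly positive finite values (z, y, x) in um")
  structure(list(data = data, spacing = spacing), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d (Z x Y x X), spacing %s um\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Multi-channel stack of co-registered volumes
#'
#' @param channels named list of [voxel_grid()] objects sharing shape and
#'   spacing, e.g. channels "mCherry", "GFP", "aSMA", "VEGFR3".
#' @return An object of class `channel_stack` (a named list of grids).
#' @export
channel_stack <- function(channels) {
  if (length(channels) < 1L) stop("at least one channel required")
  nm <- names(channels)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("channel names must be unique and non-empty")
  for (ch in channels)
    if (!inherits(ch, "voxel_grid")) stop("every channel must be a voxel_grid")
  ref <- channels[[1L]]
  for (ch in channels[-1L]) {
    if (!identical(dim(ch$data), dim(ref$data)))
      stop("all channels must share an identical shape")
    if (!isTRUE(all.equal(ch$spacing, ref$spacing)))
      stop("all channels must share an identical spacing")
  }
  structure(channels, class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x[[1L]]$data)
  cat(sprintf("<channel_stack> %d channel(s) [%s], %d x %d x %d\n",
              length(x), paste(names(x), collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}

#' Read a 3D volume from multi-page TIFF or HDF5
#'
#' TIFF carries no reliable spacing metadata, so `spacing` is mandatory for
#' TIFF input. HDF5 datasets may carry an `element_size_um` attribute (ZYX
#' order) which is used when `spacing` is not given; an explicit argument
#' always wins.
#'
#' @param path file to read.
#' @param fmt `"tiff"` or `"hdf5"`.
#' @param spacing voxel pitch (z, y, x) in micrometres; required for TIFF.
#' @param dataset HDF5 dataset name (default `"volume"`).
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path, fmt = c("tiff", "hdf5"), spacing = NULL,
                        dataset = "volume") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (fmt == "tiff") {
    if (is.null(spacing))
      stop("spacing is required for TIFF input (TIFF carries no spacing metadata)")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    shp <- dim(pages[[1L]])
    for (p in pages)
      if (!identical(dim(p), shp)) stop("ragged TIFF: pages differ in shape")
    arr <- array(0, dim = c(length(pages), shp[1L], shp[2L]))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    voxel_grid(arr, spacing)
  } else {
    dat <- rhdf5::h5read(path, dataset)
    if (length(dim(dat)) != 3L) stop("HDF5 dataset '", dataset, "' is not 3D")
    if (is.null(spacing)) {
      at <- rhdf5::h5readAttributes(path, dataset)
      if (!is.null(at$element_size_um)) spacing <- as.numeric(at$element_size_um)
      else stop("no spacing argument and no element_size_um attribute on '",
                dataset, "'")
    }
    voxel_grid(dat, spacing)
  }
}

#' Write a 3D volume to multi-page TIFF or HDF5
#'
#' TIFF output is for integer-valued volumes (8 or 16 bit); float volumes
#' (probability maps and other derived data) go to HDF5, which stores the
#' spacing as an `element_size_um` dataset attribute and round-trips exactly.
#' Binary masks are serialized as 8-bit with foreground 255.
#'
#' @param grid a [voxel_grid()].
#' @param path output file; the parent directory must exist.
#' @param fmt `"tiff"` or `"hdf5"`.
#' @param bits TIFF bit depth, 8 or 16 (ignored for HDF5).
#' @param dataset HDF5 dataset name (default `"volume"`).
#' @export
write_volume <- function(grid, path, fmt = c("tiff", "hdf5"), bits = 16L,
                         dataset = "volume") {
  fmt <- match.arg(fmt)
  stopifnot(inherits(grid, "voxel_grid"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  if (fmt == "tiff") {
    if (!bits %in% c(8L, 16L)) stop("TIFF bit depth must be 8 or 16")
    mx <- if (bits == 16L) 65535 else 255
    v <- grid$data
    if (any(v < 0) || any(v > mx) || any(v != round(v)))
      stop("TIFF output requires integer intensities in [0, ", mx,
           "]; use fmt = 'hdf5' for float volumes")
    pages <- lapply(seq_len(dim(v)[1L]), function(z) v[z, , ] / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(grid$data, path, dataset)
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, dataset)
    rhdf5::h5writeAttribute(grid$spacing, did, "element_size_um")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Read sparse voxel annotations from CSV
#'
#' The CSV must have header `z,y,x,label` with 0-based voxel indices and
#' labels drawn from the four-class vocabulary (`signal`, `z_leakage`,
#' `autofluorescence`, `background`).
#'
#' @param path CSV file.
#' @param shape integer length-3 volume shape (Z, Y, X) used for bounds
#'   validation.
#' @return A data.frame of class `voxel_annotations` with columns
#'   `z`, `y`, `x` (0-based) and `label`.
#' @export
read_annotations <- function(path, shape) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("z", "y", "x", "label") %in% names(df)))
    stop("annotation CSV must have header z,y,x,label")
  annotations(df$z, df$y, df$x, df$label, shape)
}

#' Construct validated sparse annotations
#'
#' @param z,y,x 0-based voxel indices.
#' @param label class labels, each one of `signal`, `z_leakage`,
#'   `autofluorescence`, `background`.
#' @param shape volume shape (Z, Y, X) for bounds checking.
#' @return A data.frame of class `voxel_annotations`.
#' @export
annotations <- function(z, y, x, label, shape) {
  df <- data.frame(z = as.integer(z), y = as.integer(y), x = as.integer(x),
                   label = as.character(label), stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$label), ANNOTATION_CLASSES)
  if (length(bad))
    stop("unknown label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed labels are: ", paste(ANNOTATION_CLASSES, collapse = ", "))
  shape <- as.integer(shape)
  if (any(df$z < 0L) || any(df$y < 0L) || any(df$x < 0L) ||
      any(df$z >= shape[1L]) || any(df$y >= shape[2L]) || any(df$x >= shape[3L]))
    stop("annotation voxel index out of bounds for shape ",
         paste(shape, collapse = "x"))
  key <- paste(df$z, df$y, df$x)
  if (anyDuplicated(key))
    stop("duplicate annotation voxel(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  attr(df, "shape") <- shape
  class(df) <- c("voxel_annotations", "data.frame")
  df
}

#' Write annotations to CSV
#' @param ann a `voxel_annotations` object.
#' @param path output CSV.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(ann[, c("z", "y", "x", "label")], path, row.names = FALSE)
  invisible(path)
}
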