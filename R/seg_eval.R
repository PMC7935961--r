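# Validation of automated segmentations against expert reference masks with
# the three overlap coefficients commonly used for segmentation tasks:
# Sorensen-Dice, Jaccard, and Szymkiewicz-Simpson (overlap).

overlap_from_counts <- function(na, nb, ni) {
  if (na == 0 && nb == 0) {
    # perfect agreement on emptiness: avoids NaN when a class is absent
    return(list(dice = 1, jaccard = 1, overlap = 1))
  }
  if (na == 0 || nb == 0) return(list(dice = 0, jaccard = 0, overlap = 0))
  list(dice = 2 * ni / (na + nb),
       jaccard = ni / (na + nb - ni),
       overlap = ni / min(na, nb))
}

#' Overlap scores between two segmentation masks
#'
#' Computes dice = 2|A&B| / (|A| + |B|), jaccard = |A&B| / |A|B|union|, and
#' the Szymkiewicz-Simpson overlap coefficient |A&B| / min(|A|, |B|),
#' voxelwise on whole volumes. Two empty masks score 1 on all three
#' coefficients (perfect agreement on emptiness); exactly one empty scores 0.
#'
#' @param predicted,reference [binary_mask()] objects of identical shape
#'   (e.g. the machine segmentation and the expert reference).
#' @param per_slice if TRUE, also return a data.frame of per-Z-slice scores.
#' @return A list of class `overlap_scores`: `dice`, `jaccard`, `overlap`,
#'   voxel counts `n_a`, `n_b`, `n_intersection`, and optionally `slices`.
#' @export
evaluate_segmentation <- function(predicted, reference, per_slice = FALSE) {
  stopifnot(inherits(predicted, "binary_mask"),
            inherits(reference, "binary_mask"))
  if (!identical(dim(predicted$data), dim(reference$data)))
    stop("mask shapes differ: ", paste(dim(predicted$data), collapse = "x"),
         " vs ", paste(dim(reference$data), collapse = "x"))
  a <- predicted$data; b <- reference$data
  na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  sc <- overlap_from_counts(na, nb, ni)
  out <- list(dice = sc$dice, jaccard = sc$jaccard, overlap = sc$overlap,
              n_a = na, n_b = nb, n_intersection = ni)
  if (per_slice) {
    nz <- dim(a)[1L]
    out$slices <- do.call(rbind, lapply(seq_len(nz), function(z) {
      sa <- sum(a[z, , ]); sb <- sum(b[z, , ]); si <- sum(a[z, , ] & b[z, , ])
      s <- overlap_from_counts(sa, sb, si)
      data.frame(z = z - 1L, dice = s$dice, jaccard = s$jaccard,
                 overlap = s$overlap)
    }))
  }
  structure(out, class = "overlap_scores")
}

#' @export
print.overlap_scores <- function(x, ...) {
  cat(sprintf(
    "<overlap_scores> dice = %.4f, jaccard = %.4f, overlap = %.4f (|A| = %d, |B| = %d, |A&B| = %d)\n",
    x$dice, x$jaccard, x$overlap, x$n_a, x$n_b, x$n_intersection))
  invisible(x)
}
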