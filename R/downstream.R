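#' Summed-probability paratope size proxy
#'
#' The sum of per-residue paratope probabilities over all supplied residues
#' (heavy plus light chain when both are given). Summing, rather than
#' thresholding and counting, preserves graded evidence and tracks physical
#' interface size more closely. Sizes computed from single-chain tracks are
#' not comparable with paired-chain sizes.
#'
#' @param p Numeric probability vector (concatenate chains before calling).
#' @return Scalar in `[0, length(p)]`.
#' @examples
#' paratope_size(c(0.9, 0.1, 0.5)) # 1.5
#' @export
paratope_size <- function(p) {
  if (length(p) == 0L) {
    warning("empty probability track; paratope size is 0")
    return(0)
  }
  stopifnot(all(p >= 0 & p <= 1))
  sum(p)
}

#' Pooled sequence embedding, unweighted or paratope-weighted
#'
#' Without probabilities, the unweighted mean of the residue embedding rows
#' (`e_avg`). With a probability track, the paratope-weighted mean
#' `e_para = sum_i w_i e_i` with normalized weights `w_i = p_i / sum_j p_j`,
#' which emphasises residues likely to contact the antigen. The weighted
#' vector always lies in the convex hull of the residue vectors and is
#' invariant to uniform rescaling of `p`.
#'
#' @param E Feature matrix, one row per residue.
#' @param p Optional probability track aligned with the rows of `E`.
#' @return Numeric vector of length `ncol(E)` with attribute `pooling`.
#' @examples
#' E <- rbind(c(1, 0), c(0, 1))
#' pooled_embedding(E, p = c(0.2, 0.6)) # weights 0.25 / 0.75
#' @export
pooled_embedding <- function(E, p = NULL) {
  E <- as.matrix(E)
  if (is.null(p)) {
    out <- colMeans(E)
    attr(out, "pooling") <- "unweighted"
    return(out)
  }
  if (length(p) != nrow(E)) {
    stop("probability track length (", length(p),
         ") does not match residue count (", nrow(E), ")")
  }
  s <- sum(p)
  if (s <= 0) stop("cannot normalize weights: probabilities sum to 0")
  out <- drop(crossprod(E, p / s))
  attr(out, "pooling") <- "paratope-weighted"
  out
}

#' Combine a region-restricted track with a full-length track
#'
#' Substitutes the probabilities of a region-restricted predictor (for
#' example a structure-based model limited to the CDR+/-2 positions) into a
#' full-length track at the masked positions, keeping the full-length
#' predictions everywhere else. The result is a single contiguous set of
#' residue probabilities spanning the entire sequence. Raw values are
#' substituted without rescaling at the region boundary.
#'
#' @param region_track Probabilities covering exactly the masked positions,
#'   in mask order.
#' @param full_track Probabilities covering every position.
#' @param mask Logical vector (or 0/1) over all positions; `TRUE` marks the
#'   region handled by `region_track`.
#' @return Numeric vector the length of `full_track`.
#' @examples
#' combine_tracks(c(0.9, 0.8), rep(0.1, 5), c(FALSE, TRUE, TRUE, FALSE, FALSE))
#' @export
combine_tracks <- function(region_track, full_track, mask) {
  mask <- as.logical(mask)
  if (length(mask) != length(full_track)) {
    stop("mask length does not match the full track")
  }
  if (length(region_track) != sum(mask)) {
    stop("region track covers ", length(region_track),
         " positions but the mask marks ", sum(mask))
  }
  out <- full_track
  out[mask] <- region_track
  out
}
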