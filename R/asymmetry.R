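#' Paratope set from a label track
#'
#' Represents a paratope (or epitope) as a set of `(amino acid, position)`
#' identifiers such as `"L63"`, the notation used for comparing the two
#' binding sites of an antibody's identical arms. With `use_aa = FALSE` the
#' identifiers are positions alone; for curated two-arm data the arm
#' sequences are identical so the two conventions coincide.
#'
#' @param track A `label_track` data frame, or a logical/binary vector of
#'   labels (positions are then sequential indices).
#' @param use_aa Prefix each position with its amino-acid letter.
#' @return Character vector of set members.
#' @export
paratope_set <- function(track, use_aa = TRUE) {
  if (is.data.frame(track)) {
    pos <- which(track$label == 1)
    if (use_aa) paste0(track$aa[pos], pos) else as.character(pos)
  } else {
    pos <- which(as.integer(track) == 1L)
    as.character(pos)
  }
}

#' Paratope (or epitope) asymmetry between two binding sites
#'
#' The number of residues present in exactly one of the two sets: the
#' cardinality of the symmetric difference `(P1 u P2) \ (P1 n P2)`.
#'
#' @param p1,p2 Character vectors of set members under one consistent
#'   numbering (e.g. `c("L63","Q64","G66")`).
#' @return Non-negative integer count.
#' @examples
#' paratope_asymmetry(c("L63", "Q64", "G66"), c("L63", "Q64", "A67")) # 2
#' @export
paratope_asymmetry <- function(p1, p2) {
  p1 <- unique(as.character(p1))
  p2 <- unique(as.character(p2))
  length(setdiff(union(p1, p2), intersect(p1, p2)))
}

#' Normalized asymmetry (Jaccard distance) between two binding sites
#'
#' The symmetric-difference count divided by the union size, which equals
#' one minus the Jaccard similarity. Defined only when the union is
#' non-empty; two empty sets raise an error rather than silently returning 0.
#'
#' @inheritParams paratope_asymmetry
#' @return Fraction in `[0, 1]`.
#' @export
normalized_asymmetry <- function(p1, p2) {
  p1 <- unique(as.character(p1))
  p2 <- unique(as.character(p2))
  u <- union(p1, p2)
  if (length(u) == 0L) {
    stop("normalized asymmetry is undefined for two empty sets")
  }
  paratope_asymmetry(p1, p2) / length(u)
}

#' Curate a two-arm antibody-antigen dataset
#'
#' Applies, in order, the four filters used to assemble a dataset of
#' complexes in which one antibody binds two identical antigens (one per
#' arm): (1) the antigen is a protein or peptide; (2) both heavy and light
#' chains are present (excludes nanobodies); (3) the antibody has exactly
#' two arms; (4) the two arms are identical in heavy, light and bound
#' antigen sequence. Filter (4) can be relaxed to a maximum Levenshtein
#' distance for sensitivity analyses.
#'
#' @param metadata Data frame with one row per antibody-antigen interaction
#'   and columns `pdb_id`, `antigen_type`, `Hchain`, `Lchain`,
#'   `antigen_chain`, `heavy_seq`, `light_seq`, `antigen_seq`.
#' @param max_arm_distance Maximum summed Levenshtein distance (heavy +
#'   light + antigen) tolerated between the two arms; 0 demands identity.
#' @return A list of class `curation_report`: `counts` (named vector of
#'   antibodies retained after each filter), `retained` (pdb ids),
#'   `metadata` (retained rows).
#' @export
curate_two_arm_dataset <- function(metadata, max_arm_distance = 0) {
  required <- c("pdb_id", "antigen_type", "Hchain", "Lchain", "antigen_chain",
                "heavy_seq", "light_seq", "antigen_seq")
  miss <- setdiff(required, names(metadata))
  if (length(miss)) {
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  }
  m <- metadata
  n_input <- length(unique(m$pdb_id))

  ok_type <- tolower(m$antigen_type) %in% c("protein", "peptide")
  m <- m[ok_type, , drop = FALSE]
  n_type <- length(unique(m$pdb_id))

  has_pair <- !is.na(m$Hchain) & !is.na(m$Lchain) &
    nzchar(m$Hchain) & nzchar(m$Lchain) &
    !is.na(m$heavy_seq) & !is.na(m$light_seq) &
    nzchar(m$heavy_seq) & nzchar(m$light_seq)
  drop_ids <- unique(m$pdb_id[!has_pair])
  m <- m[!(m$pdb_id %in% drop_ids), , drop = FALSE]
  n_pair <- length(unique(m$pdb_id))

  arms <- table(m$pdb_id)
  two_arm_ids <- names(arms)[arms == 2L]
  m <- m[m$pdb_id %in% two_arm_ids, , drop = FALSE]
  n_two <- length(unique(m$pdb_id))

  identical_ids <- vapply(unique(m$pdb_id), function(id) {
    rows <- m[m$pdb_id == id, , drop = FALSE]
    d <- utils::adist(rows$heavy_seq[1], rows$heavy_seq[2]) +
      utils::adist(rows$light_seq[1], rows$light_seq[2]) +
      utils::adist(rows$antigen_seq[1], rows$antigen_seq[2])
    d <= max_arm_distance
  }, logical(1))
  keep <- names(identical_ids)[identical_ids]
  m <- m[m$pdb_id %in% keep, , drop = FALSE]
  n_final <- length(unique(m$pdb_id))

  structure(list(
    counts = c(input = n_input, protein_or_peptide = n_type,
               heavy_and_light = n_pair, exactly_two_arms = n_two,
               identical_arms = n_final),
    retained = unique(m$pdb_id),
    metadata = m
  ), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("two-arm curation report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' Arm-vs-arm prediction upper bound
#'
#' Treats one arm's ground-truth labels as the truth and the other arm's as
#' predictions, and reports F1 and MCC. Because both tracks come from the
#' same antibody sequence bound to identical antigens, the result bounds how
#' well any sequence-only predictor can agree with a single-arm annotation.
#'
#' @param labels1,labels2 Binary label vectors of equal length (or
#'   `label_track` data frames), aligned position-wise.
#' @return Named numeric vector with elements `f1` and `mcc`.
#' @export
arm_upper_bound <- function(labels1, labels2) {
  if (is.data.frame(labels1)) labels1 <- labels1$label
  if (is.data.frame(labels2)) labels2 <- labels2$label
  if (length(labels1) != length(labels2)) {
    stop("arm label tracks differ in length (", length(labels1), " vs ",
         length(labels2), "); arms must be aligned position-wise")
  }
  cc <- confusion_counts(labels1, labels2)
  c(f1 = f1_score(cc), mcc = mcc_score(cc))
}

#' Correlation between normalized paratope and epitope asymmetry
#'
#' Pearson correlation (with the standard two-sided t approximation for the
#' p-value) across complexes between the normalized paratope asymmetry and
#' the normalized epitope asymmetry.
#'
#' @param records Data frame with columns `normalized_paratope_asymmetry`
#'   and `normalized_epitope_asymmetry`, or a list of such records.
#' @return List with elements `r`, `p` and `n`.
#' @export
asymmetry_correlation <- function(records) {
  if (!is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, as.data.frame))
  }
  x <- records$normalized_paratope_asymmetry
  y <- records$normalized_epitope_asymmetry
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop("need at least 3 finite records for a correlation")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in one margin")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
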