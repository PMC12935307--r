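#' Exact Shapley values by coalition enumeration
#'
#' Computes, for every feature `i`, the average marginal contribution
#' `phi_i = sum over S not containing i of |S|!(n-|S|-1)!/n! *
#' (f(S u {i}) - f(S))`, enumerating all `2^n` coalitions. Features absent
#' from a coalition are replaced by their baseline values. Limited to
#' `n <= 12` features; larger inputs must use [approx_shapley()].
#'
#' @param f Value function: takes a numeric vector (one instance) and
#'   returns a scalar prediction.
#' @param x Numeric instance vector to explain.
#' @param baseline Numeric vector of baseline feature values (same length
#'   as `x`), substituted for absent features.
#' @return Object of class `shapley_attribution`: list with `phi`
#'   (per-feature values), `f_full`, `f_baseline`.
#' @examples
#' f <- function(v) sum(v * c(2, -1, 3))
#' exact_shapley(f, x = c(1, 1, 1), baseline = c(0, 0, 0))$phi # 2 -1 3
#' @export
exact_shapley <- function(f, x, baseline) {
  n <- length(x)
  stopifnot(length(baseline) == n)
  if (n > 12) {
    stop("exact enumeration limited to 12 features (2^n coalitions); ",
         "use approx_shapley() for larger inputs")
  }
  # value of every coalition, indexed by bitmask
  n_coal <- 2L^n
  vals <- numeric(n_coal)
  for (m in 0:(n_coal - 1L)) {
    members <- bitwAnd(bitwShiftR(m, 0:(n - 1L)), 1L) == 1L
    v <- baseline
    v[members] <- x[members]
    vals[m + 1L] <- f(v)
  }
  sizes <- vapply(0:(n_coal - 1L),
                  function(m) sum(bitwAnd(bitwShiftR(m, 0:(n - 1L)), 1L)),
                  numeric(1))
  wgt <- factorial(0:(n - 1)) * factorial(n - (0:(n - 1)) - 1) / factorial(n)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(n_coal - 1L), bit) == 0L) - 1L
    s <- sizes[without + 1L]
    phi[i] <- sum(wgt[s + 1L] * (vals[without + bit + 1L] - vals[without + 1L]))
  }
  structure(list(phi = phi, f_full = vals[n_coal], f_baseline = vals[1L]),
            class = "shapley_attribution")
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat("Shapley attribution over", length(x$phi), "features\n")
  cat(sprintf("  f(full) = %.4f, f(baseline) = %.4f, sum(phi) = %.4f\n",
              x$f_full, x$f_baseline, sum(x$phi)))
  invisible(x)
}

#' Sampling-based Shapley value estimate
#'
#' Monte-Carlo estimator averaging marginal contributions over random
#' feature permutations: for each sampled permutation the features are
#' switched from baseline to observed values one at a time and the
#' prediction increments are credited to the switched feature. Converges to
#' [exact_shapley()] (with the same baseline) as `n_samples` grows and
#' satisfies the efficiency property exactly for every sample.
#'
#' @inheritParams exact_shapley
#' @param background Numeric matrix of background instances; the baseline is
#'   its column mean. A plain vector is used as the baseline directly.
#' @param n_samples Number of permutations to sample.
#' @param seed Integer seed for reproducibility.
#' @return Object of class `shapley_attribution`.
#' @export
approx_shapley <- function(f, x, background, n_samples = 200, seed = 1L) {
  n <- length(x)
  baseline <- if (is.matrix(background)) colMeans(background) else as.numeric(background)
  stopifnot(length(baseline) == n, n_samples >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  phi <- numeric(n)
  f_baseline <- f(baseline)
  for (s in seq_len(n_samples)) {
    perm <- sample.int(n)
    v <- baseline
    prev <- f_baseline
    for (i in perm) {
      v[i] <- x[i]
      cur <- f(v)
      phi[i] <- phi[i] + (cur - prev)
      prev <- cur
    }
  }
  structure(list(phi = phi / n_samples, f_full = f(x),
                 f_baseline = f_baseline),
            class = "shapley_attribution")
}

#' Per-backend importance profile from Shapley attributions
#'
#' Aggregates per-dimension Shapley values into per-backend scores: the raw
#' score of a backend sums the absolute Shapley values of all its embedding
#' dimensions; the mean score divides by the backend's dimensionality to
#' control for unequal embedding sizes. Scores are normalized to sum to 1
#' (`I_k / sum_j I_j`). Absolute values are used by default so importance
#' is non-negative and the normalization is well defined; `signed = TRUE`
#' sums signed values instead.
#'
#' @param attribution A `shapley_attribution` (or plain numeric vector of
#'   per-dimension values).
#' @param block_index Named list mapping backend name to `c(start, end)`
#'   column range, as stored on a [build_features()] matrix.
#' @param mode `"raw"` (sum over dimensions) or `"mean"` (average over
#'   dimensions).
#' @param signed Sum signed rather than absolute Shapley values.
#' @return Object of class `importance_profile`: data frame with columns
#'   `backend`, `score`, `normalized`.
#' @export
backend_importance <- function(attribution, block_index,
                               mode = c("raw", "mean"), signed = FALSE) {
  mode <- match.arg(mode)
  phi <- if (inherits(attribution, "shapley_attribution")) attribution$phi else as.numeric(attribution)
  idx <- sort(as.integer(unlist(lapply(block_index,
                                       function(r) r[["start"]]:r[["end"]]))))
  if (!identical(unname(idx), seq_along(phi))) {
    stop("block ranges must partition the feature dimensions 1..", length(phi))
  }
  score <- vapply(block_index, function(r) {
    v <- phi[r[["start"]]:r[["end"]]]
    v <- if (signed) v else abs(v)
    if (mode == "raw") sum(v) else mean(v)
  }, numeric(1))
  total <- sum(score)
  if (total == 0) stop("cannot normalize: all importance scores are zero")
  structure(data.frame(backend = names(block_index), score = unname(score),
                       normalized = unname(score / total),
                       stringsAsFactors = FALSE),
            class = c("importance_profile", "data.frame"))
}

#' Aggregate importance profiles
#'
#' Averages normalized per-backend importance across residues, sequences or
#' positions, then renormalizes so the aggregate sums to 1. Profiles need
#' not all cover the same entities (e.g. a sequence position present in
#' only some sequences is averaged over the profiles that contain it).
#'
#' @param profiles List of `importance_profile` objects (or data frames
#'   with `backend` and `normalized` columns).
#' @return An `importance_profile` over the union of backends.
#' @export
aggregate_importance <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to aggregate")
  long <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(backend = p$backend, normalized = p$normalized,
               stringsAsFactors = FALSE)
  }))
  agg <- tapply(long$normalized, long$backend, mean)
  score <- as.numeric(agg)
  structure(data.frame(backend = names(agg), score = score,
                       normalized = score / sum(score),
                       stringsAsFactors = FALSE),
            class = c("importance_profile", "data.frame"))
}

#' Shapley attribution of one residue's prediction to feature dimensions
#'
#' Convenience wrapper tying the attribution machinery to a fitted
#' classifier: explains the paratope probability of one residue (row of a
#' feature matrix) with [approx_shapley()], using a background feature
#' matrix (typically the training features) for the baseline.
#'
#' @param model A fitted [paratope_mlp()].
#' @param features Feature matrix; row `row` is explained.
#' @param row Row index of the residue to explain.
#' @param background Background feature matrix for the baseline (defaults
#'   to `features`).
#' @param n_samples Permutations for the estimator.
#' @param seed Seed.
#' @return A `shapley_attribution`.
#' @export
explain_residue <- function(model, features, row, background = features,
                            n_samples = 200, seed = 1L) {
  f <- function(v) predict(model, matrix(v, nrow = 1))
  approx_shapley(f, as.numeric(features[row, ]), as.matrix(background),
                 n_samples = n_samples, seed = seed)
}
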