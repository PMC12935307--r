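# Independent oracles, written as plain loops so they stay auditable and
# share no code with the implementation paths they check.

# exhaustive all-pairs contact labeling on a structure_complex
brute_force_labels <- function(complex, query_chain, target_chains,
                               cutoff = 4.5, inclusive = TRUE) {
  atoms <- complex$atoms
  qry <- atoms[atoms$chain == query_chain & !atoms$hydrogen, ]
  tgt <- atoms[atoms$chain %in% target_chains & !atoms$hydrogen, ]
  res <- unique(qry[, c("resno", "insert")])
  res <- res[order(res$resno, res$insert), ]
  labels <- integer(nrow(res))
  for (r in seq_len(nrow(res))) {
    ra <- qry[qry$resno == res$resno[r] & qry$insert == res$insert[r], ]
    hit <- FALSE
    for (i in seq_len(nrow(ra))) {
      d <- sqrt((ra$x[i] - tgt$x)^2 + (ra$y[i] - tgt$y)^2 +
                  (ra$z[i] - tgt$z)^2)
      if ((inclusive && any(d <= cutoff)) || (!inclusive && any(d < cutoff))) {
        hit <- TRUE
        break
      }
    }
    labels[r] <- as.integer(hit)
  }
  labels
}

# concordance-count ROC AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counting one half
concordance_roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Shapley values by averaging marginal contributions over all n! orderings
permutation_shapley <- function(f, x, baseline) {
  n <- length(x)
  perms <- .all_permutations(n)
  phi <- numeric(n)
  for (p in seq_len(nrow(perms))) {
    v <- baseline
    prev <- f(v)
    for (i in perms[p, ]) {
      v[i] <- x[i]
      cur <- f(v)
      phi[i] <- phi[i] + (cur - prev)
      prev <- cur
    }
  }
  phi / nrow(perms)
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# write a toy complex to a temp PDB and parse it back
parse_toy <- function(toy) {
  f <- tempfile(fileext = ".pdb")
  writeLines(toy$pdb, f)
  read_complex(f)
}

# small planted-signal training set shared by the model tests
small_training_set <- function(seed = 7, beta = 4, n_sequences = 20) {
  generate_training_set(n_sequences = n_sequences,
                        length_range = c(60, 80), beta = beta, seed = seed)
}
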