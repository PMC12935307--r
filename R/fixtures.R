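.pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                           occ = 1, b = 20, element) {
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_f, resname, chain, resno, x, y, z, occ, b, element)
}

.sample_resnames <- function(n) {
  three <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
  sample(three, n, replace = TRUE)
}

# backbone-like atoms for one toy residue centred at (cx, cy, cz); offsets
# stay within ~2.5 A so the 12 A residue spacing isolates each contact
.toy_residue_atoms <- function(serial0, resname, chain, resno, cx, cy, cz) {
  list(
    lines = c(
      .pdb_atom_line(serial0,     "N",  resname, chain, resno, cx - 1.3, cy + 0.4, cz, element = "N"),
      .pdb_atom_line(serial0 + 1, "CA", resname, chain, resno, cx,       cy,       cz, element = "C"),
      .pdb_atom_line(serial0 + 2, "C",  resname, chain, resno, cx + 1.3, cy - 0.4, cz, element = "C")
    ),
    next_serial = serial0 + 3
  )
}

.emit_arm <- function(ab_chain, ag_chain, resnames, contacts, contact_distance,
                      decoy_distance, y_offset, serial0) {
  n <- length(resnames)
  lines <- character(0)
  serial <- serial0
  for (i in seq_len(n)) {
    ra <- .toy_residue_atoms(serial, resnames[i], ab_chain, i,
                             cx = 12 * i, cy = y_offset, cz = 0)
    lines <- c(lines, ra$lines)
    serial <- ra$next_serial
  }
  # antigen: one carbon per antibody residue, at contact distance opposite
  # contact positions and at decoy distance elsewhere
  for (i in seq_len(n)) {
    dz <- if (i %in% contacts) contact_distance else decoy_distance
    lines <- c(lines, .pdb_atom_line(serial, "CA", "GLY", ag_chain, i,
                                     12 * i, y_offset, dz, element = "C"))
    serial <- serial + 1
  }
  list(lines = lines, next_serial = serial)
}

#' Generate a toy antibody-antigen complex
#'
#' Emits PDB-format text for a minimal synthetic complex whose ground-truth
#' contact labels are known by construction: antibody residues sit on a
#' 12 Angstrom lattice (chain `H`), and the antigen (chain `A`) carries one
#' carbon atom per antibody residue, placed at `contact_distance` opposite
#' contact positions and at `decoy_distance` elsewhere. With the default
#' distances (4.0 / 6.0 around the 4.5 cutoff) the intended labels are
#' exactly the contact positions. Deterministic for a given seed.
#'
#' @param n_residues Number of antibody residues.
#' @param contacts Either an integer vector of contact positions or a
#'   single count (positions then sampled under `seed`).
#' @param contact_distance Antigen-atom distance at contact positions
#'   (Angstrom, below the intended cutoff).
#' @param decoy_distance Antigen-atom distance elsewhere (above the cutoff).
#' @param seed Integer seed (residue identities and sampled contacts).
#' @return List with `pdb` (character vector of file lines), `labels`
#'   (intended 0/1 vector over antibody residues), `contacts` (positions),
#'   `assignment` (a [chain_assignment()] for the complex) and `spec`.
#' @examples
#' toy <- generate_toy_complex(n_residues = 20, contacts = c(3, 7), seed = 1)
#' which(toy$labels == 1)
#' @export
generate_toy_complex <- function(n_residues = 20, contacts = 3,
                                 contact_distance = 4.0, decoy_distance = 6.0,
                                 seed = 1L) {
  stopifnot(n_residues >= 1, contact_distance < decoy_distance,
            contact_distance > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (length(contacts) == 1L && contacts <= n_residues) {
    contacts <- sort(sample.int(n_residues, contacts))
  }
  stopifnot(all(contacts >= 1), all(contacts <= n_residues))
  resnames <- .sample_resnames(n_residues)
  arm <- .emit_arm("H", "A", resnames, contacts, contact_distance,
                   decoy_distance, y_offset = 0, serial0 = 1L)
  labels <- as.integer(seq_len(n_residues) %in% contacts)
  list(pdb = c(arm$lines, "END"),
       labels = labels, contacts = contacts,
       assignment = chain_assignment(heavy = "H", antigen = "A"),
       spec = list(n_residues = n_residues,
                   contact_distance = contact_distance,
                   decoy_distance = decoy_distance, seed = seed))
}

#' Generate a two-arm complex with planted paratope asymmetry
#'
#' Duplicates a toy antibody-antigen pair into two arms with identical
#' antibody sequences (chains `H` and `J`, antigens `A` and `B`) and
#' perturbs the antigen placement of arm 2 so that exactly `k` antibody
#' positions flip contact membership between the arms: the planted paratope
#' asymmetry equals `k`.
#'
#' @inheritParams generate_toy_complex
#' @param k Planted asymmetry (number of positions in exactly one arm's
#'   paratope).
#' @return List with `pdb`, per-arm `labels` (list of two 0/1 vectors),
#'   `contacts` (list of two position vectors), `assignments` (list of two
#'   [chain_assignment()]s) and `k`.
#' @export
generate_two_arm_complex <- function(n_residues = 20, contacts = 4, k = 2,
                                     contact_distance = 4.0,
                                     decoy_distance = 6.0, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (length(contacts) == 1L && contacts <= n_residues) {
    contacts <- sort(sample.int(n_residues, contacts))
  }
  n_drop <- k %/% 2
  n_add <- k - n_drop
  free <- setdiff(seq_len(n_residues), contacts)
  if (n_drop > length(contacts) || n_add > length(free)) {
    stop("planted asymmetry k = ", k, " is infeasible for ", length(contacts),
         " contacts over ", n_residues, " residues")
  }
  contacts2 <- sort(c(setdiff(contacts, contacts[seq_len(n_drop)]),
                      if (n_add > 0) free[seq_len(n_add)]))
  resnames <- .sample_resnames(n_residues)
  arm1 <- .emit_arm("H", "A", resnames, contacts, contact_distance,
                    decoy_distance, y_offset = 0, serial0 = 1L)
  arm2 <- .emit_arm("J", "B", resnames, contacts2, contact_distance,
                    decoy_distance, y_offset = 100, serial0 = arm1$next_serial)
  list(pdb = c(arm1$lines, arm2$lines, "END"),
       labels = list(as.integer(seq_len(n_residues) %in% contacts),
                     as.integer(seq_len(n_residues) %in% contacts2)),
       contacts = list(contacts, contacts2),
       assignments = list(chain_assignment(heavy = "H", antigen = "A", arm = 0L),
                          chain_assignment(heavy = "J", antigen = "B", arm = 1L)),
       k = k)
}

#' Generate a labeled synthetic training set with a planted signal
#'
#' Draws random antibody-like sequences, assigns paratope labels clustered
#' in CDR-like windows (three windows per chain by default) at a target
#' prevalence, embeds the sequences through synthetic backends that shift a
#' designated dimension subset by `beta` at positive positions, and splits
#' the sequences into disjoint train / validation / test subsets. With
#' `beta = 0` the features carry no label information (a null set).
#'
#' @param n_sequences Number of sequences.
#' @param length_range Inclusive range of sequence lengths.
#' @param prevalence Target positive-label fraction (positives are drawn
#'   Bernoulli within the windows, so the empirical fraction fluctuates
#'   binomially around the target).
#' @param beta Planted effect size on the signal dimensions.
#' @param signal_dims Dimensions (of the first default backend) carrying
#'   the signal.
#' @param backends Optional list of `embedding_backend`s; defaults to two
#'   synthetic backends of dimensions 16 and 8, the first carrying the
#'   signal.
#' @param n_windows Number of label windows per sequence.
#' @param window_frac Fraction of each sequence covered by windows.
#' @param split Named fractions for `train`, `validation`, `test`.
#' @param seed Integer seed; fixes sequences, labels, embeddings and split
#'   membership.
#' @return Object of class `training_set`: list with `train`,
#'   `validation`, `test` (each `x`, `y`, `groups`), `sequences`, `labels`,
#'   `split` (sequence indices), `prevalence` (empirical) and `spec`.
#' @export
generate_training_set <- function(n_sequences = 40,
                                  length_range = c(90, 130),
                                  prevalence = 0.12, beta = 4,
                                  signal_dims = 1:2, backends = NULL,
                                  n_windows = 3, window_frac = 0.3,
                                  split = c(train = 0.6, validation = 0.2,
                                            test = 0.2),
                                  seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, window_frac > prevalence,
            window_frac <= 1, n_sequences >= 3)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (is.null(backends)) {
    backends <- list(
      synthetic_backend("plmA", 16L, seed = seed,
                        signal = if (beta != 0) list(dims = signal_dims,
                                                     beta = beta) else NULL),
      synthetic_backend("plmB", 8L, seed = seed + 1L)
    )
  }
  p_in <- prevalence / window_frac
  seqs <- character(n_sequences)
  labels <- vector("list", n_sequences)
  feats <- vector("list", n_sequences)
  for (s in seq_len(n_sequences)) {
    len <- sample(length_range[1]:length_range[2], 1L)
    chars <- sample(AA_ALPHABET, len, replace = TRUE)
    seqs[s] <- paste(chars, collapse = "")
    # CDR-like windows: equal spans at evenly spaced starts
    span <- max(1L, round(window_frac * len / n_windows))
    starts <- pmax(1L, round(seq(0.1, 0.8, length.out = n_windows) * len))
    in_window <- rep(FALSE, len)
    for (w in starts) in_window[seq(w, min(len, w + span - 1L))] <- TRUE
    y <- integer(len)
    y[in_window] <- stats::rbinom(sum(in_window), 1L, p_in)
    labels[[s]] <- y
    feats[[s]] <- build_features(seqs[s], backends = backends,
                                 mode = "single",
                                 marked = list(heavy = y == 1L))
  }
  x <- do.call(rbind, lapply(feats, unclass))
  y_all <- unlist(labels)
  groups <- rep(seq_len(n_sequences), vapply(labels, length, integer(1)))

  ord <- sample.int(n_sequences)
  n_train <- max(1L, round(split[["train"]] * n_sequences))
  n_val <- max(1L, round(split[["validation"]] * n_sequences))
  idx <- list(train = sort(ord[seq_len(n_train)]),
              validation = sort(ord[n_train + seq_len(n_val)]),
              test = sort(ord[(n_train + n_val + 1):n_sequences]))
  subset_of <- function(ids) {
    keep <- groups %in% ids
    list(x = x[keep, , drop = FALSE], y = y_all[keep], groups = groups[keep])
  }
  structure(list(train = subset_of(idx$train),
                 validation = subset_of(idx$validation),
                 test = subset_of(idx$test),
                 sequences = seqs, labels = labels, split = idx,
                 prevalence = mean(y_all),
                 block_index = attr(feats[[1]], "block_index"),
                 spec = list(n_sequences = n_sequences,
                             length_range = length_range,
                             prevalence = prevalence, beta = beta,
                             signal_dims = signal_dims,
                             n_windows = n_windows,
                             window_frac = window_frac, seed = seed)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("synthetic training set: %d sequences (train %d / val %d / test %d)\n",
              length(x$sequences), length(x$split$train),
              length(x$split$validation), length(x$split$test)))
  cat(sprintf("  empirical prevalence %.3f, planted beta %g on dims {%s}\n",
              x$prevalence, x$spec$beta,
              paste(x$spec$signal_dims, collapse = ",")))
  invisible(x)
}
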