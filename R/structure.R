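#' Read an antibody-antigen complex structure
#'
#' Parses a PDB or mmCIF file into a flat atom table. Alternate-location
#' duplicates are resolved to the highest-occupancy conformer (ties broken by
#' altloc identifier order), waters and non-polymer heteroatoms are excluded
#' from polymer chains, and element symbols are normalised (inferred from the
#' atom name for legacy records that omit them).
#'
#' @param path Path to a structure file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"cif"`.
#' @return An object of class `structure_complex`: a list with `atoms`
#'   (data frame with columns `chain`, `resno`, `insert`, `resid`, `elety`,
#'   `elesy`, `o`, `x`, `y`, `z`, `hydrogen`) and `source` (the input path).
#' @examples
#' toy <- generate_toy_complex(n_residues = 5, contacts = 2, seed = 1)
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(toy$pdb, pdb)
#' cx <- read_complex(pdb)
#' nrow(cx$atoms)
#' @export
read_complex <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") {
      bio3d::read.cif(path, verbose = FALSE)
    } else {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) stop("failed to parse ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- parsed$atom
  # polymer chains: ATOM records only; drop waters however they were typed
  atoms <- atoms[atoms$type == "ATOM" & !(atoms$resid %in% c("HOH", "DOD", "WAT")), ,
                 drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("empty structure: no polymer atoms in '", path, "'")
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$elesy[is.na(atoms$elesy)] <- ""
  atoms <- .resolve_altloc(atoms)
  atoms$elesy <- .normalize_element(atoms$elesy, atoms$elety)
  atoms$hydrogen <- atoms$elesy %in% c("H", "D")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates in '", path, "'")
  }
  out <- list(
    atoms = atoms[, c("chain", "resno", "insert", "resid", "elety", "elesy",
                      "o", "x", "y", "z", "hydrogen")],
    source = path
  )
  class(out) <- "structure_complex"
  out
}

# Keep the highest-occupancy conformer per (chain, resno, insert, atom name);
# ties broken by altloc identifier order.
.resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

# Element from the element column when present, else from the atom-name
# convention (strip leading digits; first letter is the element for H/D).
.normalize_element <- function(elesy, elety) {
  elesy <- toupper(trimws(elesy))
  missing <- elesy == ""
  if (any(missing)) {
    # legacy PDB convention: strip leading digits of the atom name, first
    # letter is the element; sufficient to separate H/D from heavy atoms
    nm <- toupper(sub("^[0-9]+", "", trimws(elety[missing])))
    elesy[missing] <- substr(nm, 1L, 1L)
  }
  elesy
}

#' @export
print.structure_complex <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat("structure_complex:", nrow(x$atoms), "atoms,", length(ch), "chains\n")
  cat("  chains:", paste(sprintf("%s (%d atoms)", names(ch), as.integer(ch)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Chain assignment for one antibody-antigen interaction
#'
#' Records which chains of a complex form the antibody arm (heavy and,
#' optionally, light chain) and which chains are the bound antigen.
#'
#' @param heavy Heavy-chain identifier.
#' @param light Light-chain identifier, or `NULL` for single-domain inputs.
#' @param antigen Character vector of antigen chain identifiers.
#' @param arm Arm index (0 or 1) when a complex carries two arms.
#' @return An object of class `chain_assignment`.
#' @export
chain_assignment <- function(heavy, light = NULL, antigen, arm = 0L) {
  antigen <- as.character(antigen)
  ab <- c(heavy, light)
  if (!is.null(light) && identical(heavy, light)) {
    stop("heavy and light chain identifiers must differ")
  }
  if (any(antigen %in% ab)) {
    stop("antigen chain identifiers must be disjoint from antibody chains")
  }
  structure(list(heavy = heavy, light = light, antigen = antigen,
                 arm = as.integer(arm)),
            class = "chain_assignment")
}

.three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# residue table for one chain, ordered by author numbering with
# insertion-code lexicographic tie-break
.chain_residues <- function(atoms, chain_id) {
  ca <- atoms[atoms$chain == chain_id, , drop = FALSE]
  if (nrow(ca) == 0L) {
    stop("chain '", chain_id, "' not present in structure")
  }
  key <- paste(ca$resno, ca$insert, sep = "\r")
  first <- !duplicated(key)
  res <- ca[first, c("resno", "insert", "resid"), drop = FALSE]
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract the one-letter sequence of a chain
#'
#' Residues are ordered by author-assigned numbering with insertion codes
#' breaking ties lexicographically. Nonstandard residue names are mapped to
#' `X` (with a warning) so structural tracks stay aligned with
#' sequence-model tracks.
#'
#' @param complex A `structure_complex`.
#' @param chain_id Chain identifier.
#' @return A list with `sequence` (one-letter string) and `keys` (data frame
#'   with `chain`, `resno`, `insert`).
#' @export
fv_sequence <- function(complex, chain_id) {
  res <- .chain_residues(complex$atoms, chain_id)
  aa <- unname(.three_to_one[res$resid])
  if (anyNA(aa)) {
    warning("nonstandard residue(s) mapped to X in chain ", chain_id, ": ",
            paste(unique(res$resid[is.na(aa)]), collapse = ", "))
    aa[is.na(aa)] <- "X"
  }
  list(sequence = paste(aa, collapse = ""),
       keys = data.frame(chain = chain_id, resno = res$resno,
                         insert = res$insert, stringsAsFactors = FALSE))
}

# minimum-distance contact labels of `query_chains` residues against all
# heavy atoms of `target_chains`
.contact_labels <- function(complex, query_chain, target_chains, cutoff,
                            exclude_hydrogen, boundary_inclusive) {
  atoms <- complex$atoms
  missing <- setdiff(c(query_chain, target_chains), unique(atoms$chain))
  if (length(missing)) {
    stop("assigned chain(s) not present in structure: ",
         paste(missing, collapse = ", "))
  }
  tgt <- atoms[atoms$chain %in% target_chains, , drop = FALSE]
  qry <- atoms[atoms$chain == query_chain, , drop = FALSE]
  if (exclude_hydrogen) {
    tgt <- tgt[!tgt$hydrogen, , drop = FALSE]
    qry <- qry[!qry$hydrogen, , drop = FALSE]
  }
  res <- .chain_residues(atoms, query_chain)
  seqinfo <- fv_sequence(complex, query_chain)
  n <- nrow(res)
  labels <- integer(n)
  if (nrow(tgt) > 0L && nrow(qry) > 0L) {
    tmat <- as.matrix(tgt[, c("x", "y", "z")])
    qmat <- as.matrix(qry[, c("x", "y", "z")])
    # squared all-pairs distances via the Gram expansion; fixtures and curated
    # Fv complexes are small enough that this stays well within memory
    d2 <- outer(rowSums(qmat^2), rowSums(tmat^2), "+") - 2 * tcrossprod(qmat, tmat)
    mind2 <- apply(d2, 1L, min)
    mind2[mind2 < 0] <- 0
    hit <- if (boundary_inclusive) sqrt(mind2) <= cutoff else sqrt(mind2) < cutoff
    qkey <- paste(qry$resno, qry$insert, sep = "\r")
    rkey <- paste(res$resno, res$insert, sep = "\r")
    hit_res <- unique(qkey[hit])
    labels <- as.integer(rkey %in% hit_res)
  }
  # residues whose every atom is hydrogen (or zero resolved heavy atoms) keep
  # label 0 but remain in the track so sequence/label alignment holds
  track <- data.frame(chain = query_chain, resno = res$resno,
                      insert = res$insert,
                      aa = strsplit(seqinfo$sequence, "")[[1]],
                      label = labels, stringsAsFactors = FALSE)
  class(track) <- c("label_track", "data.frame")
  track
}

#' Ground-truth paratope labels from a complex structure
#'
#' An antibody residue is labeled 1 if any of its non-hydrogen atoms lies
#' within `cutoff` (default 4.5 Angstrom, boundary inclusive) of any
#' non-hydrogen atom of an assigned antigen chain; all other residues are
#' labeled 0. Hydrogen and deuterium are identified by element symbol.
#'
#' @param complex A `structure_complex`.
#' @param assignment A [chain_assignment()].
#' @param cutoff Contact distance cutoff in Angstrom.
#' @param exclude_hydrogen Ignore hydrogen/deuterium atoms on both sides.
#' @param boundary_inclusive Treat a distance exactly equal to `cutoff` as a
#'   contact.
#' @return A named list of `label_track` data frames (columns `chain`,
#'   `resno`, `insert`, `aa`, `label`), one per antibody chain.
#' @examples
#' toy <- generate_toy_complex(n_residues = 10, contacts = c(3, 7), seed = 1)
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(toy$pdb, pdb)
#' cx <- read_complex(pdb)
#' asn <- chain_assignment(heavy = "H", antigen = "A")
#' which(label_paratope(cx, asn)$H$label == 1)
#' @export
label_paratope <- function(complex, assignment, cutoff = 4.5,
                           exclude_hydrogen = TRUE, boundary_inclusive = TRUE) {
  stopifnot(cutoff > 0)
  chains <- c(assignment$heavy, assignment$light)
  out <- lapply(chains, function(ch) {
    .contact_labels(complex, ch, assignment$antigen, cutoff,
                    exclude_hydrogen, boundary_inclusive)
  })
  names(out) <- chains
  out
}

#' Ground-truth epitope labels from a complex structure
#'
#' Mirror of [label_paratope()] with antibody and antigen roles swapped: an
#' antigen residue is labeled 1 if any of its non-hydrogen atoms is within
#' `cutoff` of any non-hydrogen atom of the antibody chains.
#'
#' @inheritParams label_paratope
#' @return A named list of `label_track` data frames, one per antigen chain.
#' @export
label_epitope <- function(complex, assignment, cutoff = 4.5,
                          exclude_hydrogen = TRUE, boundary_inclusive = TRUE) {
  stopifnot(cutoff > 0)
  ab <- c(assignment$heavy, assignment$light)
  out <- lapply(assignment$antigen, function(ch) {
    .contact_labels(complex, ch, ab, cutoff, exclude_hydrogen,
                    boundary_inclusive)
  })
  names(out) <- assignment$antigen
  out
}

#' Write label tracks to CSV
#'
#' @param tracks A list of `label_track` data frames as returned by
#'   [label_paratope()] or [label_epitope()].
#' @param path Output CSV path.
#' @return The combined data frame, invisibly.
#' @export
write_label_tracks <- function(tracks, path) {
  combined <- do.call(rbind, lapply(tracks, as.data.frame))
  names(combined) <- c("chain_id", "residue_number", "insertion_code", "aa", "label")
  utils::write.csv(combined, path, row.names = FALSE)
  invisible(combined)
}
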