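test_that("a minimal PDB fixture reads back atom by atom", {
  lines <- c(
    "ATOM      1  N   GLY H   1      10.000  10.000  10.000  1.00 20.00           N",
    "ATOM      2  CA  ALA A   5       0.000   0.000   0.000  1.00 20.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  cx <- read_complex(f)
  expect_equal(nrow(cx$atoms), 2)
  expect_setequal(unique(cx$atoms$chain), c("H", "A"))
})

test_that("altloc duplicates resolve to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  CA AGLY H   1      11.000  10.000  10.000  0.40 20.00           C",
    "ATOM      2  CA BGLY H   1      12.000  10.000  10.000  0.60 20.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  cx <- read_complex(f)
  expect_equal(nrow(cx$atoms), 1)
  expect_equal(cx$atoms$x, 12)  # the occupancy-0.6 B conformer wins
})

test_that("waters and unreadable files are handled", {
  lines <- c(
    "ATOM      1  CA  GLY H   1      11.000  10.000  10.000  1.00 20.00           C",
    "HETATM    2  O   HOH A 101       5.000   5.000   5.000  1.00 20.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_equal(nrow(read_complex(f)$atoms), 1)
  expect_error(read_complex(tempfile()), "not found")
})

test_that("generated toy complexes parse with the generator's atom count", {
  toy <- generate_toy_complex(n_residues = 30, contacts = c(3, 7, 21), seed = 4)
  cx <- parse_toy(toy)
  # 3 backbone atoms per antibody residue + 1 antigen atom per residue
  expect_equal(nrow(cx$atoms), 30 * 3 + 30)
  expect_identical(parse_toy(generate_toy_complex(30, c(3, 7, 21), seed = 4))$atoms,
                   cx$atoms)  # same seed, same bytes
})

test_that("contact labeling honors the distance cutoff boundary", {
  mk <- function(z_antigen, element = "C") {
    lines <- c(
      "ATOM      1  CA  GLY H   1       0.000   0.000   0.000  1.00 20.00           C",
      sprintf("ATOM      2  CA  GLY A   1       0.000   0.000%8.3f  1.00 20.00          %2s",
              z_antigen, element),
      "END")
    f <- tempfile(fileext = ".pdb")
    writeLines(lines, f)
    read_complex(f)
  }
  asn <- chain_assignment(heavy = "H", antigen = "A")
  expect_equal(label_paratope(mk(4.4), asn)$H$label, 1L)
  expect_equal(label_paratope(mk(4.6), asn)$H$label, 0L)
  expect_equal(label_paratope(mk(4.5), asn)$H$label, 1L)  # inclusive boundary
  expect_equal(label_paratope(mk(4.5), asn, boundary_inclusive = FALSE)$H$label, 0L)
  # a hydrogen at 1.0 A is ignored
  expect_equal(label_paratope(mk(1.0, element = "H"), asn)$H$label, 0L)
})

test_that("labeling equals the brute-force all-pairs oracle on random toys", {
  for (s in 1:20) {
    n <- sample(10:40, 1)
    toy <- generate_toy_complex(n_residues = n, contacts = sample(1:4, 1),
                                contact_distance = runif(1, 3, 4.4),
                                decoy_distance = runif(1, 4.6, 8), seed = s)
    cx <- parse_toy(toy)
    got <- label_paratope(cx, toy$assignment)$H$label
    expect_equal(got, brute_force_labels(cx, "H", "A"), info = paste("seed", s))
    expect_equal(got, toy$labels, info = paste("seed", s))
  }
})

test_that("paratope sets are monotone decreasing in the cutoff", {
  for (s in 1:5) {
    toy <- generate_toy_complex(n_residues = 25, contacts = 5,
                                contact_distance = 3.5, decoy_distance = 5.5,
                                seed = s)
    cx <- parse_toy(toy)
    prev <- NULL
    for (cutoff in c(6.5, 5.0, 4.5, 3.6, 2.0)) {
      cur <- which(label_paratope(cx, toy$assignment, cutoff = cutoff)$H$label == 1)
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("adding hydrogen atoms never changes labels", {
  toy <- generate_toy_complex(n_residues = 15, contacts = c(2, 9), seed = 3)
  base <- label_paratope(parse_toy(toy), toy$assignment)$H$label
  # plant hydrogens right next to every antibody residue, on the antigen chain
  h_lines <- sprintf(
    "ATOM  %5d  H   GLY A %3d    %8.3f%8.3f%8.3f  1.00 20.00           H",
    900 + seq_len(15), 100 + seq_len(15), 12 * seq_len(15), 0.5, 0.5)
  toy$pdb <- c(setdiff(toy$pdb, "END"), h_lines, "END")
  with_h <- label_paratope(parse_toy(toy), toy$assignment)$H$label
  expect_equal(with_h, base)
})

test_that("epitope labeling mirrors paratope labeling under role swap", {
  toy <- generate_toy_complex(n_residues = 12, contacts = c(4, 8), seed = 9)
  cx <- parse_toy(toy)
  ep <- label_epitope(cx, toy$assignment)$A
  expect_equal(ep$label, brute_force_labels(cx, "A", "H"))
  # swapped-role paratope call reproduces the epitope track
  swapped <- chain_assignment(heavy = "A", antigen = "H")
  expect_equal(label_paratope(cx, swapped)$A$label, ep$label)
  # far-apart chains yield an all-zero track
  far <- generate_toy_complex(n_residues = 8, contacts = integer(0),
                              decoy_distance = 30, seed = 1)
  expect_true(all(label_epitope(parse_toy(far), far$assignment)$A$label == 0))
})

test_that("sequence extraction maps residues, insertion codes and MSE", {
  lines <- c(
    "ATOM      1  CA  GLY H 100       0.000   0.000   0.000  1.00 20.00           C",
    "ATOM      2  CA  ALA H 100A      4.000   0.000   0.000  1.00 20.00           C",
    "ATOM      3  CA  LYS H 101       8.000   0.000   0.000  1.00 20.00           C",
    "ATOM      4  CA  MSE H 102      12.000   0.000   0.000  1.00 20.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  cx <- read_complex(f)
  expect_warning(fv <- fv_sequence(cx, "H"), "MSE")
  expect_equal(fv$sequence, "GAKX")
  expect_equal(fv$keys$resno, c(100, 100, 101, 102))
  expect_equal(fv$keys$insert, c("", "A", "", ""))
  expect_error(fv_sequence(cx, "Z"), "not present")
})

test_that("label tracks stay aligned with sequences and export to CSV", {
  toy <- generate_toy_complex(n_residues = 18, contacts = 4, seed = 2)
  cx <- parse_toy(toy)
  tracks <- label_paratope(cx, toy$assignment)
  fv <- fv_sequence(cx, "H")
  expect_equal(nrow(tracks$H), nchar(fv$sequence))
  expect_equal(paste(tracks$H$aa, collapse = ""), fv$sequence)
  out <- tempfile(fileext = ".csv")
  write_label_tracks(tracks, out)
  back <- read.csv(out)
  expect_equal(back$label, tracks$H$label)
  expect_equal(names(back), c("chain_id", "residue_number", "insertion_code",
                              "aa", "label"))
})
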