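test_that("FASTA parsing extracts accession and taxon from UniProt headers", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">sp|P02754|LACB_BOVIN Beta-lactoglobulin OS=Bos taurus OX=9913 GN=LGB",
    "MKCLLLALAL",
    ">PLAINACC some plain header",
    "TCGAQALIVTQTMK"
  ), fa)
  db <- read_fasta(fa)
  expect_equal(db$accession, c("P02754", "PLAINACC"))
  expect_equal(db$taxon, c("Bos taurus", "unknown"))
  expect_equal(db$source_class, c("unknown", "unknown"))
  expect_equal(db$sequence[1], "MKCLLLALAL")
})

test_that("FASTA edge cases: empty file warns, duplicates and malformed error", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_warning(db <- read_fasta(empty), "empty")
  expect_equal(nrow(db), 0L)

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|A_X OS=Bos taurus", "MKAY", ">sp|P1|B_X", "MKTW"), dup)
  expect_error(read_fasta(dup), "duplicate accession")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKAY", ">sp|P1|A_X", "MKTW"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("FASTA round-trips through write_fasta", {
  db <- read_fasta(toy_proteome_path())
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db, out)
  back <- read_fasta(out)
  expect_equal(back$accession, db$accession)
  expect_equal(back$taxon, db$taxon)
  expect_equal(back$sequence, db$sequence)
})

test_that("modified-sequence parsing places events on the right residues", {
  ev <- parse_modified_sequence("_AN(de)SQK_", "ANSQK")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mod_type, "deamidation")
  expect_equal(ev$position, 2L)
  expect_equal(ev$residue, "N")

  multi <- parse_modified_sequence("_N(de)M(ox)Q(de)K_", "NMQK")
  expect_equal(multi$position, c(1L, 2L, 3L))
  expect_equal(multi$mod_type, c("deamidation", "oxidation_M", "deamidation"))

  leading <- parse_modified_sequence("_(gl)QSTK_", "QSTK")
  expect_equal(leading$position, 1L)
  expect_equal(leading$mod_type, "pyro_glu")

  expect_equal(nrow(parse_modified_sequence("_ANSQK_", "ANSQK")), 0L)
  expect_error(parse_modified_sequence("_AN(zz)SQK_", "ANSQK"), "unknown modification")
  expect_error(parse_modified_sequence("_AS(de)TGK_", "ASTGK"), "non-N/Q")
  expect_error(parse_modified_sequence("_ANSQK_", "ANSQR"), "does not match")
})

test_that("event positions always point at the recorded residue", {
  seqs <- c("NQNQK", "ANSQK", "QQQQR", "MNPQR")
  for (s in seqs) {
    nq <- which(strsplit(s, "")[[1]] %in% c("N", "Q"))
    ms <- build_modified_sequence(
      s, tibble::tibble(mod_type = "deamidation", position = nq)
    )
    ev <- parse_modified_sequence(ms, s)
    expect_equal(substring(s, ev$position, ev$position), ev$residue)
  }
})

test_that("MaxQuant evidence dialect parses and applies the score threshold", {
  tsv <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    paste("id", "Raw file", "Sequence", "Modified sequence", "Modifications",
          "Proteins", "Intensity", "Score", sep = "\t"),
    paste("1", "run1", "ANSQK", "_AN(de)SQK_", "Deamidation (NQ)",
          "P1;P2", "1000", "85.2", sep = "\t"),
    paste("2", "run1", "AGSTK", "_AGSTK_", "Unmodified",
          "P1", "500", "39", sep = "\t"),
    paste("3", "run2", "TESTKK", "_TESTKK_", "Unmodified",
          "P2", "", "64", sep = "\t")
  ), tsv)
  suppressMessages(ev <- read_evidence(tsv, "maxquant_evidence"))
  # the score-39 row is below the default threshold of 40
  expect_equal(ev$obs_id, c("1", "3"))
  expect_equal(attr(ev, "n_dropped_score"), 1L)
  expect_equal(ev$protein_accessions[[1]], c("P1", "P2"))
  expect_equal(ev$modifications[[1]]$position, 2L)
  expect_true(is.na(ev$intensity[2])) # retained despite missing intensity
  expect_equal(ev$sample_id, c("run1", "run2"))
})

test_that("missing required evidence columns are reported by name", {
  tsv <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    paste("Sequence", "Modified sequence", "Proteins", "Intensity", "Score",
          sep = "\t"),
    paste("ANSQK", "_ANSQK_", "P1", "10", "80", sep = "\t")
  ), tsv)
  expect_error(read_evidence(tsv, "maxquant_evidence"), "Modifications")
})

test_that("unparseable modification tokens report the row number", {
  tsv <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    paste("Sequence", "Modified sequence", "Modifications", "Proteins",
          "Intensity", "Score", sep = "\t"),
    paste("ANSQK", "_ANSQK_", "Unmodified", "P1", "10", "80", sep = "\t"),
    paste("ANSQK", "_AN(qq)SQK_", "?", "P1", "10", "80", sep = "\t")
  ), tsv)
  expect_error(suppressMessages(read_evidence(tsv, "maxquant_evidence")),
               "row 2")
})

test_that("generic CSV dialect round-trips losslessly", {
  ev <- make_evidence(
    c("ANSQK", "NNGKL", "AGSTK"),
    deam_positions = list(2L, 1L, NULL),
    intensity = c(100, 250.5, 80),
    score = c(90, 72.25, 66)
  )
  ev$preceding_residue <- c("K", "R", "-")
  ev$following_residue <- c("A", "-", "K")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_evidence(ev, csv, dialect = "generic_csv")
  suppressMessages(back <- read_evidence(csv, "generic_csv"))
  expect_equal(back$sequence, ev$sequence)
  expect_equal(back$modified_sequence, ev$modified_sequence)
  expect_equal(back$intensity, ev$intensity)
  expect_equal(back$score, ev$score)
  expect_equal(back$protein_accessions, ev$protein_accessions)
  expect_equal(back$modifications, ev$modifications)
  expect_equal(back$preceding_residue, ev$preceding_residue)
})

test_that("dropped plus retained rows account for every input row", {
  tsv <- withr::local_tempfile(fileext = ".txt")
  rows <- c(
    paste("Sequence", "Modified sequence", "Modifications", "Proteins",
          "Intensity", "Score", sep = "\t"),
    paste("ANSQK", "_ANSQK_", "Unmodified", "P1", "10", "80", sep = "\t"),
    paste("AGSTK", "_AGSTK_", "Unmodified", "P1", "10", "12", sep = "\t"),
    paste("AK", "_AK_", "Unmodified", "P1", "10", "80", sep = "\t"),
    paste("NNGKL", "_NNGKL_", "Unmodified", "P1", "10", "95", sep = "\t")
  )
  writeLines(rows, tsv)
  suppressMessages(ev <- read_evidence(tsv, "maxquant_evidence"))
  n_dropped <- attr(ev, "n_dropped_score") + attr(ev, "n_dropped_short") +
    attr(ev, "n_dropped_unmapped")
  expect_equal(nrow(ev) + n_dropped, length(rows) - 1L)
})
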