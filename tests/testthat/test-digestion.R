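test_that("tryptic digestion reproduces hand-enumerated fragments", {
  d0 <- digest("MKAYNDRTESTK", max_missed = 0)
  expect_equal(d0$peptide, c("MK", "AYNDR", "TESTK"))
  expect_equal(d0$start, c(1L, 3L, 8L))
  expect_equal(d0$end, c(2L, 7L, 12L))
  expect_equal(d0$missed_cleavages, c(0L, 0L, 0L))

  d1 <- digest("MKAYNDRTESTK", max_missed = 1)
  extra <- dplyr::anti_join(d1, d0, by = c("peptide", "start", "end"))
  expect_setequal(extra$peptide, c("MKAYNDR", "AYNDRTESTK"))
  expect_true(all(extra$missed_cleavages == 1L))

  no_site <- digest("AAAA")
  expect_equal(no_site$peptide, "AAAA")
  expect_equal(no_site[c("start", "end")], tibble::tibble(start = 1L, end = 4L))

  expect_equal(nrow(digest("")), 0L)
})

test_that("digest output grows monotonically with allowed missed cleavages", {
  set.seed(11)
  for (rep in 1:5) {
    prot <- random_protein(sample(30:120, 1))
    prev <- digest(prot, max_missed = 0)
    for (m in 1:4) {
      cur <- digest(prot, max_missed = m)
      expect_equal(nrow(dplyr::semi_join(prev, cur, by = c("start", "end"))),
                   nrow(prev))
      expect_true(all(cur$missed_cleavages <= m))
      prev <- cur
    }
  }
})

test_that("proline rule suppresses K/R-P cleavage when enabled", {
  # K at 2 is followed by P: with the rule on it is not a site
  expect_equal(digest("MKPAYR", max_missed = 0)$peptide, c("MK", "PAYR"))
  expect_equal(digest("MKPAYR", max_missed = 0, proline_rule = TRUE)$peptide,
               "MKPAYR")
  cls <- classify_termini("MKPAYR", 3, 6, proline_rule = TRUE)
  expect_equal(cls$nterm_class, "nonspecific_other")
  expect_equal(cls$missed_cleavages, 0L)
})

test_that("locate_peptide reports all occurrences including overlaps", {
  expect_equal(locate_peptide("MKAYNDRTESTK", "TESTK"),
               tibble::tibble(start = 8L, end = 12L))
  expect_equal(nrow(locate_peptide("MKAYNDRTESTK", "WWW")), 0L)
  expect_equal(locate_peptide("AAAA", "AA"),
               tibble::tibble(start = 1:3, end = 2:4))
})

test_that("terminus classification follows the cleavage-chemistry rules", {
  # TESTK: tryptic N-terminus (R at 7); the C-terminal K coincides with the
  # protein end, where the protein-terminus rule takes precedence
  full <- classify_termini("MKAYNDRTESTK", 8, 12)
  expect_equal(full$nterm_class, "tryptic")
  expect_equal(full$cterm_class, "protein_terminus")
  expect_equal(full$specificity, "full_tryptic")
  expect_equal(full$missed_cleavages, 0L)
  expect_false(full$diagenetic)
  # internal tryptic C-terminus away from the protein end
  mid <- classify_termini("MKAYNDRTESTKGGA", 8, 12)
  expect_equal(mid$cterm_class, "tryptic")

  semi <- classify_termini("MKAYNDRTESTK", 6, 12)
  expect_equal(semi$nterm_class, "diagenetic_NDQE") # N at 5
  expect_equal(semi$specificity, "semi_tryptic")
  expect_equal(semi$missed_cleavages, 1L) # R at 7
  expect_true(semi$diagenetic)

  span <- classify_termini("MKAYNDRTESTK", 1, 12)
  expect_equal(span$nterm_class, "protein_terminus")
  expect_equal(span$cterm_class, "protein_terminus")
  expect_equal(span$specificity, "full_tryptic")

  # aspecific enzymatic N-terminus: Y at 4 precedes position 5
  asp <- classify_termini("MKAYNDRTESTK", 5, 12)
  expect_equal(asp$nterm_class, "aspecific_YWF")
  expect_equal(asp$specificity, "semi_tryptic")
  expect_false(asp$diagenetic)
  # diagenetic C-terminus: D at 6
  dia <- classify_termini("MKAYNDRTESTK", 3, 6)
  expect_equal(dia$cterm_class, "diagenetic_NDQE")
  expect_true(dia$diagenetic)
  yw <- classify_termini("MKAYNDRTESTK", 4, 12)
  expect_equal(yw$nterm_class, "nonspecific_other") # A at 3

  # Met-excision: start 2 behind initiator M is a protein terminus
  expect_equal(classify_termini("MKAYNDR", 2, 7)$nterm_class, "protein_terminus")
  expect_equal(classify_termini("MKAYNDR", 2, 7, met_excision = FALSE)$nterm_class,
               "nonspecific_other")

  expect_error(classify_termini("MKAYNDR", 0, 3), "out of range")
  expect_error(classify_termini("MKAYNDR", 3, 9), "out of range")
})

test_that("every digested peptide is fully tryptic with bounded missed cleavages", {
  set.seed(7)
  for (rep in 1:5) {
    prot <- random_protein(sample(40:150, 1))
    m <- sample(0:3, 1)
    d <- digest(prot, max_missed = m)
    cls <- classify_termini(prot, d$start, d$end)
    expect_true(all(cls$specificity == "full_tryptic"))
    expect_true(all(cls$missed_cleavages == d$missed_cleavages))
    expect_true(all(cls$missed_cleavages <= m))
    expect_false(any(cls$diagenetic))
  }
})

test_that("classification agrees with the brute-force oracle on random substrings", {
  set.seed(23)
  for (rep in 1:10) {
    prot <- random_protein(sample(20:80, 1))
    n <- nchar(prot)
    for (k in 1:25) {
      s <- sample.int(n, 1)
      e <- s + sample.int(n - s + 1L, 1L) - 1L
      got <- classify_termini(prot, s, e)
      want <- oracle_classify(prot, s, e)
      expect_equal(got$nterm_class, want$nterm_class)
      expect_equal(got$cterm_class, want$cterm_class)
      expect_equal(got$missed_cleavages, want$missed_cleavages)
      expect_equal(got$specificity, want$specificity)
      expect_equal(got$diagenetic, want$diagenetic)
    }
  }
})

test_that("classify_observations picks the most specific mapping and flags ambiguity", {
  proteins <- tibble::tibble(
    accession = c("PA", "PB"),
    taxon = "Bos taurus",
    source_class = "unknown",
    # TESTK is tryptic in PA (after R) but mid-sequence non-tryptic in PB
    sequence = c("MKAYNDRTESTK", "MAGTESTKAGAGAR")
  )
  ev <- make_evidence(c("TESTK"), proteins = list(c("PA", "PB")))
  out <- classify_observations(ev, proteins)
  expect_equal(out$specificity, "full_tryptic")
  expect_equal(out$matched_accession, "PA")
  expect_true(out$specificity_ambiguous)

  # single protein, single locus: that locus's verdict, no ambiguity
  one <- classify_observations(make_evidence("TESTK", proteins = list("PA")),
                               proteins)
  expect_equal(one$specificity, "full_tryptic")
  expect_false(one$specificity_ambiguous)

  # absent from all mapped proteins and no context: unmappable
  gone <- suppressMessages(
    classify_observations(make_evidence("WWWHHH", proteins = list("PA")),
                          proteins)
  )
  expect_true(gone$unmappable)
  expect_true(is.na(gone$specificity))
})

test_that("sequence context substitutes when the database lacks the protein", {
  proteins <- tibble::tibble(
    accession = "PA", taxon = "Homo sapiens", source_class = "unknown",
    sequence = "MKAYNDRTESTK"
  )
  ev <- make_evidence("GGHHLLK", proteins = list("MISSING"))
  ev$preceding_residue <- "N"
  ev$following_residue <- "A"
  out <- classify_observations(ev, proteins)
  expect_false(out$unmappable)
  expect_equal(out$nterm_class, "diagenetic_NDQE")
  expect_equal(out$cterm_class, "tryptic") # peptide's own K
  expect_equal(out$specificity, "semi_tryptic")
  expect_true(out$diagenetic)

  ev$preceding_residue <- "-"
  ev$following_residue <- "-"
  out2 <- classify_observations(ev, proteins)
  expect_equal(out2$nterm_class, "protein_terminus")
  expect_equal(out2$cterm_class, "protein_terminus")
  expect_equal(out2$specificity, "full_tryptic")
})
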