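test_that("deamidation counting matches manual tallies", {
  ev <- make_evidence(
    c("ANSQK", "AGSTK", "NNGKL"),
    deam_positions = list(2L, NULL, 1L)
  )
  out <- count_deamidation(ev)
  expect_equal(out$n_asn, c(1L, 0L, 2L))
  expect_equal(out$n_asn_deam, c(1L, 0L, 1L))
  expect_equal(out$n_gln, c(1L, 0L, 0L))
  expect_equal(out$n_gln_deam, c(0L, 0L, 0L))
})

test_that("the weighted percentage equals the hand-computed example", {
  # (1 N fully deamidated, I=100) + (1/2, I=100) + (0, I=200) -> 37.5%
  ev <- make_evidence(
    c("ANSTK", "NNGKL", "ANGKL"),
    deam_positions = list(2L, 1L, NULL),
    intensity = c(100, 100, 200)
  )
  expect_equal(weighted_deamidation_pct(ev, "N"), 37.5)
})

test_that("weighted percentage agrees with the brute-force oracle on enumerated tables", {
  set.seed(99)
  pool <- c("ANSTK", "NNGKL", "QNQPK", "AGSTK", "NQNQR", "QSSTK")
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    seqs <- sample(pool, n, replace = TRUE)
    deam <- lapply(seqs, function(s) {
      nq <- which(strsplit(s, "")[[1]] %in% c("N", "Q"))
      if (length(nq) == 0) return(NULL)
      k <- sample.int(length(nq) + 1L, 1L) - 1L
      sort(nq[sample.int(length(nq))[seq_len(k)]])
    })
    inten <- round(runif(n, 1, 1000))
    ev <- make_evidence(seqs, deam, intensity = inten)
    ev <- count_deamidation(ev)
    for (res in c("N", "Q")) {
      tot <- if (res == "N") ev$n_asn else ev$n_gln
      dm <- if (res == "N") ev$n_asn_deam else ev$n_gln_deam
      keep <- tot > 0
      want <- oracle_weighted_pct(dm[keep], tot[keep], inten[keep])
      if (is.na(want)) {
        expect_warning(got <- weighted_deamidation_pct(ev, res), "undefined")
        expect_true(is.na(got))
      } else {
        expect_equal(weighted_deamidation_pct(ev, res), want)
      }
    }
  }
})

test_that("equal intensities reduce to the unweighted mean of fractions", {
  ev <- make_evidence(
    c("ANSTK", "NNGKL"),
    deam_positions = list(2L, 1L),
    intensity = c(5, 5)
  )
  expect_equal(weighted_deamidation_pct(ev, "N"), 100 * mean(c(1, 0.5)))
})

test_that("bounds: fully deamidated is 100%, zero events is 0%", {
  full <- make_evidence(c("NNK", "NQK"), deam_positions = list(c(1L, 2L), c(1L, 2L)))
  expect_equal(weighted_deamidation_pct(full, "N"), 100)
  none <- make_evidence(c("NNK", "NQK"))
  expect_equal(weighted_deamidation_pct(none, "N"), 0)
})

test_that("the statistic is invariant to intensity rescaling", {
  set.seed(3)
  ev <- make_evidence(
    c("ANSTK", "NNGKL", "NQNQR", "QSSTK"),
    deam_positions = list(2L, 1L, c(1L, 2L), NULL),
    intensity = runif(4, 10, 1e6)
  )
  base_n <- weighted_deamidation_pct(ev, "N")
  base_q <- weighted_deamidation_pct(ev, "Q")
  for (k in c(1e-6, 0.5, 3, 1e8)) {
    scaled <- ev
    scaled$intensity <- scaled$intensity * k
    expect_equal(weighted_deamidation_pct(scaled, "N"), base_n)
    expect_equal(weighted_deamidation_pct(scaled, "Q"), base_q)
  }
})

test_that("N and Q statistics are independent", {
  ev <- make_evidence(
    c("ANSTK", "NNGKL", "QSSTK", "QQGPR"),
    deam_positions = list(2L, 1L, 1L, NULL),
    intensity = c(10, 20, 30, 40)
  )
  with_q <- weighted_deamidation_pct(ev, "N")
  no_q <- weighted_deamidation_pct(ev[1:2, ], "N")
  expect_equal(with_q, no_q)
})

test_that("missing intensities are excluded from the weighted statistic", {
  ev <- make_evidence(
    c("ANSTK", "NNGKL"),
    deam_positions = list(2L, 1L),
    intensity = c(100, NA)
  )
  expect_equal(weighted_deamidation_pct(ev, "N"), 100)
})

test_that("bootstrap on identical observations is degenerate", {
  ev <- make_evidence(rep("ANSTK", 10), deam_positions = rep(list(2L), 10),
                      intensity = rep(50, 10))
  est <- bootstrap_deamidation(ev, "N", n_iter = 200, seed = 1)
  expect_equal(est$boot_sd_pct, 0)
  expect_equal(est$ci95_low_pct, est$point_pct)
  expect_equal(est$ci95_high_pct, est$point_pct)
})

test_that("bootstrap is reproducible for a fixed seed", {
  set.seed(5)
  ev <- make_evidence(
    sample(c("NASTK", "NNGKL", "NQNQR"), 40, replace = TRUE),
    deam_positions = replicate(40, if (runif(1) < 0.3) 1L else NULL,
                               simplify = FALSE),
    intensity = runif(40, 10, 1000)
  )
  a <- bootstrap_deamidation(ev, "N", n_iter = 300, seed = 42)
  b <- bootstrap_deamidation(ev, "N", n_iter = 300, seed = 42)
  expect_identical(a, b)
  c <- bootstrap_deamidation(ev, "N", n_iter = 300, seed = 43)
  expect_false(identical(a$boot_mean_pct, c$boot_mean_pct))
})

test_that("bootstrap mean converges to the point estimate", {
  set.seed(17)
  ev <- make_evidence(
    sample(c("NASTK", "NNGKL", "NQNQR"), 60, replace = TRUE),
    deam_positions = replicate(60, if (runif(1) < 0.3) 1L else NULL,
                               simplify = FALSE),
    intensity = exp(runif(60, 4, 10))
  )
  point <- weighted_deamidation_pct(ev, "N")
  big <- bootstrap_deamidation(ev, "N", n_iter = 10000, seed = 2)
  expect_lt(abs(big$boot_mean_pct - point), 0.5)
})

test_that("per-group estimation keeps groups and residues separate", {
  ev <- dplyr::bind_rows(
    make_evidence(c("ANSTK", "NNGKL"), deam_positions = list(2L, 1L),
                  sample_id = "s1"),
    make_evidence(c("ANSTK", "QSSTK"), deam_positions = list(NULL, 1L),
                  sample_id = "s2")
  )
  ev$class <- "food"
  est <- estimate_deamidation(ev, by = c("sample_id", "class"),
                              n_iter = 50, seed = 0)
  expect_equal(nrow(est), 4L)
  s1n <- est[est$sample_id == "s1" & est$residue_type == "N", ]
  expect_equal(s1n$point_pct, 75)
  s2q <- est[est$sample_id == "s2" & est$residue_type == "Q", ]
  expect_equal(s2q$point_pct, 100)
})

test_that("damage profile counts non-deamidation modifications", {
  ev <- make_evidence(c("AMSTK", "AMSTK", "AGSTK", "AGSTK", "AGSTK",
                        "AGSTK", "AGSTK", "AGSTK", "AGSTK", "AGSTK"))
  ev$modifications[[1]] <- tibble::tibble(
    mod_type = "oxidation_M", position = 2L, residue = "M"
  )
  ev$modifications[[2]] <- tibble::tibble(
    mod_type = "oxidation_M", position = 2L, residue = "M"
  )
  prof <- damage_profile(ev)
  expect_equal(prof$mod_type, "oxidation_M")
  expect_equal(prof$n_events, 2L)
  expect_equal(prof$rate, 0.2)

  expect_equal(nrow(damage_profile(make_evidence("AGSTK"))), 0L)

  # with classes, per-class counts sum to the global count
  ev$class <- rep(c("food", "contaminant"), 5)
  by_class <- damage_profile(ev)
  expect_equal(sum(by_class$n_events), 2L)
})
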