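#' Count deamidation-relevant residues per observation
#'
#' For every observation, counts the asparagine and glutamine residues in
#' the peptide and how many of each carry a deamidation event. Peptides
#' without N (or Q) are later excluded from the corresponding statistic:
#' the deamidated fraction is only defined for peptides containing the
#' residue.
#'
#' @param evidence Observation tibble (see [read_evidence()]).
#' @return `evidence` with appended integer columns `n_asn`,
#'   `n_asn_deam`, `n_gln`, `n_gln_deam`.
#' @export
count_deamidation <- function(evidence) {
  deam_counts <- purrr::map(evidence$modifications, function(m) {
    d <- m[m$mod_type == "deamidation", , drop = FALSE]
    if (any(!d$residue %in% c("N", "Q"))) {
      abort("deamidation event recorded on a non-N/Q residue (parse inconsistency)")
    }
    c(N = sum(d$residue == "N"), Q = sum(d$residue == "Q"))
  })
  evidence$n_asn <- stringr::str_count(evidence$sequence, stringr::fixed("N"))
  evidence$n_asn_deam <- vapply(deam_counts, `[[`, numeric(1), "N") |> as.integer()
  evidence$n_gln <- stringr::str_count(evidence$sequence, stringr::fixed("Q"))
  evidence$n_gln_deam <- vapply(deam_counts, `[[`, numeric(1), "Q") |> as.integer()
  bad <- evidence$n_asn_deam > evidence$n_asn | evidence$n_gln_deam > evidence$n_gln
  if (any(bad)) {
    abort("more deamidation events than residues in at least one peptide")
  }
  evidence
}

deam_columns <- function(residue_type) {
  residue_type <- match.arg(residue_type, c("N", "Q"))
  if (residue_type == "N") c(total = "n_asn", deam = "n_asn_deam")
  else c(total = "n_gln", deam = "n_gln_deam")
}

# rows that enter the weighted statistic for one residue type
eligible_rows <- function(evidence, residue_type) {
  cols <- deam_columns(residue_type)
  if (!all(cols %in% names(evidence))) evidence <- count_deamidation(evidence)
  keep <- evidence[[cols[["total"]]]] > 0L & !is.na(evidence$intensity)
  evidence[keep, , drop = FALSE]
}

#' Intensity-weighted deamidation percentage
#'
#' The sample-level deamidation statistic: for each observation containing
#' the residue, the deamidated fraction (deamidated residues over total
#' residues of that type in the peptide) is weighted by the observation's
#' MS intensity; the weighted fractions are summed and normalised by the
#' summed intensity of all contributing observations:
#' \deqn{100 \cdot \frac{\sum_i I_i\, d_i / r_i}{\sum_i I_i}}
#' Observations lacking the residue or lacking an intensity do not enter
#' either sum. The statistic is invariant to rescaling all intensities.
#'
#' @param evidence Observation tibble; deamidation counts are added with
#'   [count_deamidation()] if absent.
#' @param residue_type `"N"` (asparagine) or `"Q"` (glutamine).
#' @return The weighted percentage in `[0, 100]`, or `NA` (with a
#'   warning) when no observation is eligible: the statistic is undefined
#'   there, which is distinct from an observed 0%.
#' @examples
#' ev <- tibble::tibble(
#'   obs_id = as.character(1:3), sample_id = "s", sequence = c("NK", "NNK", "NK"),
#'   modified_sequence = c("_N(de)K_", "_N(de)NK_", "_NK_"),
#'   intensity = c(100, 100, 200), score = 80
#' )
#' ev$modifications <- purrr::map2(ev$modified_sequence, ev$sequence,
#'                                 parse_modified_sequence)
#' weighted_deamidation_pct(ev, "N") # 37.5
#' @export
weighted_deamidation_pct <- function(evidence, residue_type = c("N", "Q")) {
  residue_type <- match.arg(residue_type)
  elig <- eligible_rows(evidence, residue_type)
  if (nrow(elig) == 0L) {
    warn(sprintf(
      "no eligible observation for residue type %s: statistic undefined",
      residue_type
    ))
    return(NA_real_)
  }
  cols <- deam_columns(residue_type)
  frac <- elig[[cols[["deam"]]]] / elig[[cols[["total"]]]]
  100 * sum(elig$intensity * frac) / sum(elig$intensity)
}

#' Bootstrap the weighted deamidation percentage
#'
#' Resamples evidence rows (the observation is the resampling unit, with
#' each row keeping its own intensity) with replacement, `n_iter` times,
#' recomputing [weighted_deamidation_pct()] per draw, and summarises the
#' bootstrap distribution: mean, standard deviation and percentile 95%
#' confidence bounds (2.5th and 97.5th percentiles). Reproducible for a
#' fixed `seed`.
#'
#' @inheritParams weighted_deamidation_pct
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed Integer seed for the resampling (default 0).
#' @return A one-row tibble: `residue_type`, `point_pct`,
#'   `boot_mean_pct`, `boot_sd_pct`, `ci95_low_pct`, `ci95_high_pct`,
#'   `n_observations` (eligible rows), `n_bootstrap`.
#' @export
bootstrap_deamidation <- function(evidence, residue_type = c("N", "Q"),
                                  n_iter = 1000L, seed = 0L) {
  residue_type <- match.arg(residue_type)
  elig <- eligible_rows(evidence, residue_type)
  point <- weighted_deamidation_pct(evidence, residue_type)
  n <- nrow(elig)
  if (n == 0L) {
    return(tibble::tibble(
      residue_type = residue_type, point_pct = NA_real_,
      boot_mean_pct = NA_real_, boot_sd_pct = NA_real_,
      ci95_low_pct = NA_real_, ci95_high_pct = NA_real_,
      n_observations = 0L, n_bootstrap = as.integer(n_iter)
    ))
  }
  cols <- deam_columns(residue_type)
  frac <- elig[[cols[["deam"]]]] / elig[[cols[["total"]]]]
  inten <- elig$intensity
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_iter, replace = TRUE), nrow = n)
  num <- colSums(matrix(inten[idx] * frac[idx], nrow = n))
  den <- colSums(matrix(inten[idx], nrow = n))
  stats <- 100 * num / den
  ci <- unname(quantile(stats, c(0.025, 0.975), names = FALSE))
  tibble::tibble(
    residue_type = residue_type,
    point_pct = point,
    boot_mean_pct = mean(stats),
    boot_sd_pct = sd(stats),
    ci95_low_pct = ci[1],
    ci95_high_pct = ci[2],
    n_observations = n,
    n_bootstrap = as.integer(n_iter)
  )
}

#' Per-group deamidation estimates
#'
#' Convenience wrapper computing [bootstrap_deamidation()] for both
#' residue types within each combination of grouping columns (typically
#' `sample_id` and `class`). Groups with no eligible observation yield a
#' row with `NA` estimates, marking the statistic undefined rather than
#' zero.
#'
#' @inheritParams bootstrap_deamidation
#' @param by Character vector of grouping column names; `NULL` pools all
#'   observations.
#' @return A tibble with one row per group and residue type.
#' @export
estimate_deamidation <- function(evidence, by = NULL,
                                 n_iter = 1000L, seed = 0L) {
  if (!all(c("n_asn", "n_gln") %in% names(evidence))) {
    evidence <- count_deamidation(evidence)
  }
  groups <- if (is.null(by)) list(`1` = evidence) else {
    split(evidence, interaction(evidence[by], drop = TRUE, sep = "\r"))
  }
  # order groups deterministically
  groups <- groups[order(names(groups))]
  res <- purrr::imap(groups, function(g, nm) {
    est <- dplyr::bind_rows(
      suppressWarnings(bootstrap_deamidation(g, "N", n_iter = n_iter, seed = seed)),
      suppressWarnings(bootstrap_deamidation(g, "Q", n_iter = n_iter, seed = seed + 1L))
    )
    if (!is.null(by)) {
      keys <- strsplit(nm, "\r", fixed = TRUE)[[1]]
      for (i in seq_along(by)) est[[by[i]]] <- keys[i]
      est <- dplyr::relocate(est, dplyr::all_of(by))
    }
    est
  })
  dplyr::bind_rows(res)
}

#' Tabulate non-deamidation damage modifications
#'
#' Descriptive counts and per-observation rates of every damage
#' modification other than deamidation (methionine oxidation, pyroglutamate
#' formation, hydroxyproline, kynurenine, carbonylation, ...). The fixed
#' laboratory alkylation (carbamidomethyl) is excluded. When the evidence
#' carries a `class` column the counts are also broken down by class;
#' class counts sum to the global count.
#'
#' @param evidence Observation tibble.
#' @return A tibble with columns `mod_type`, (`class`,) `n_events` and
#'   `rate` (events per observation); zero rows when no damage
#'   modification is present.
#' @export
damage_profile <- function(evidence) {
  ev_class <- if ("class" %in% names(evidence)) evidence$class else NULL
  mods <- purrr::map2(
    evidence$modifications,
    seq_len(nrow(evidence)),
    function(m, i) {
      m <- m[!m$mod_type %in% c("deamidation", "carbamidomethyl"), , drop = FALSE]
      if (nrow(m) > 0L && !is.null(ev_class)) m$class <- ev_class[i]
      m
    }
  )
  mods <- dplyr::bind_rows(mods)
  if (nrow(mods) == 0L) {
    out <- tibble::tibble(mod_type = character(0), n_events = integer(0),
                          rate = numeric(0))
    if (!is.null(ev_class)) out$class <- character(0)
    return(out)
  }
  n_obs <- nrow(evidence)
  grouping <- if (!is.null(ev_class)) c("mod_type", "class") else "mod_type"
  mods |>
    dplyr::count(dplyr::across(dplyr::all_of(grouping)), name = "n_events") |>
    dplyr::mutate(rate = .data$n_events / n_obs) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grouping)))
}
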