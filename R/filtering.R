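#' Validity-filter configuration
#'
#' Default thresholds for a valid protein identification: engine protein
#' score of at least 50%, sequence coverage strictly above 5%, and at
#' least two group-unique peptides each scoring at least 50%. The
#' coverage rule is strict ("above 5%") while the score rules are
#' inclusive ("a minimum of 50%"); the mixed wording of the source
#' conventions is recorded in the report parameters.
#'
#' @param min_protein_score_pct Minimum protein score (inclusive).
#' @param min_coverage_pct Coverage threshold (exclusive).
#' @param min_unique_peptides Minimum number of qualifying unique peptides.
#' @param min_peptide_score_pct Minimum individual peptide score
#'   (inclusive) for a unique peptide to qualify.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_protein_score_pct = 50,
                          min_coverage_pct = 5,
                          min_unique_peptides = 2L,
                          min_peptide_score_pct = 50) {
  stopifnot(
    min_protein_score_pct >= 0, min_coverage_pct >= 0,
    min_unique_peptides >= 0, min_peptide_score_pct >= 0
  )
  structure(
    list(
      min_protein_score_pct = min_protein_score_pct,
      min_coverage_pct = min_coverage_pct,
      min_unique_peptides = as.integer(min_unique_peptides),
      min_peptide_score_pct = min_peptide_score_pct
    ),
    class = "filter_config"
  )
}

#' Apply the protein validity filter
#'
#' Accepts a protein/group row when its score is at least
#' `min_protein_score_pct`, its coverage is strictly above
#' `min_coverage_pct`, and it has at least `min_unique_peptides` unique
#' peptides with individual scores of at least `min_peptide_score_pct`.
#' Rejections carry the first failing rule (checked in the order
#' unscored, protein score, coverage, unique peptides).
#'
#' `groups` must have columns `score` and `coverage_pct`, plus either a
#' `unique_peptides` list-column of peptide sequences (scored against
#' `peptide_scores`) or a pre-qualified `n_unique` count (used as-is when
#' `peptide_scores` is `NULL`, as in published summary tables where the
#' listed unique peptides are already high-confidence).
#'
#' @param groups Tibble of protein/group rows (see Details).
#' @param peptide_scores Optional tibble (`peptide`, `score`) of
#'   individual peptide percentage scores.
#' @param config A [filter_config()].
#' @return `groups` with appended `accepted` (logical) and
#'   `reject_reason` (`NA` when accepted).
#' @export
filter_groups <- function(groups, peptide_scores = NULL, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (!all(c("score", "coverage_pct") %in% names(groups))) {
    abort("groups must have columns score and coverage_pct")
  }
  n_qual_unique <- if (!is.null(peptide_scores) && "unique_peptides" %in% names(groups)) {
    score_of <- setNames(peptide_scores$score, peptide_scores$peptide)
    vapply(groups$unique_peptides, function(peps) {
      s <- score_of[peps]
      sum(!is.na(s) & s >= config$min_peptide_score_pct)
    }, numeric(1))
  } else if ("n_unique" %in% names(groups)) {
    groups$n_unique
  } else {
    abort("groups must carry either unique_peptides (with peptide_scores) or n_unique")
  }
  reason <- dplyr::case_when(
    is.na(groups$score) ~ "unscored",
    groups$score < config$min_protein_score_pct ~ "protein_score",
    groups$coverage_pct <= config$min_coverage_pct ~ "coverage",
    n_qual_unique < config$min_unique_peptides ~ "unique_peptides",
    TRUE ~ NA_character_
  )
  groups$accepted <- is.na(reason)
  groups$reject_reason <- reason
  groups
}
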