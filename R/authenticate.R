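#' Taxon class configuration
#'
#' Defines which taxa count as food sources and which as contamination.
#' Matching is by full taxon name or by genus (the first word), so
#' `"Triticum"` matches `"Triticum aestivum"`. Human material and common
#' laboratory contaminants (c-RAP-style accessions) are the default
#' contaminant background; accessions listed in `contaminant_accessions`
#' are classed contaminant regardless of taxon.
#'
#' @param food_taxa Character vector of food taxa or genera.
#' @param contaminant_taxa Character vector of contaminant taxa or genera.
#' @param contaminant_accessions Accessions always classed contaminant.
#' @return A list of class `class_config`.
#' @export
class_config <- function(food_taxa = c("Triticum", "Hordeum", "Secale",
                                       "Oryza", "Bos", "Bubalus", "Ovis"),
                         contaminant_taxa = "Homo sapiens",
                         contaminant_accessions = character(0)) {
  structure(
    list(
      food_taxa = food_taxa,
      contaminant_taxa = contaminant_taxa,
      contaminant_accessions = contaminant_accessions
    ),
    class = "class_config"
  )
}

taxon_matches <- function(taxon, patterns) {
  genus <- stringr::str_extract(taxon, "^\\S+")
  taxon %in% patterns | genus %in% patterns
}

#' Assign source classes to database proteins
#'
#' Sets the `source_class` column of a protein table from a
#' [class_config()]: food, contaminant or unknown.
#'
#' @param proteins Protein tibble.
#' @param config A [class_config()].
#' @return `proteins` with `source_class` filled in.
#' @export
assign_protein_class <- function(proteins, config = class_config()) {
  stopifnot(inherits(config, "class_config"))
  cls <- dplyr::case_when(
    proteins$accession %in% config$contaminant_accessions ~ "contaminant",
    taxon_matches(proteins$taxon, config$contaminant_taxa) ~ "contaminant",
    taxon_matches(proteins$taxon, config$food_taxa) ~ "food",
    TRUE ~ "unknown"
  )
  proteins$source_class <- cls
  proteins
}

#' Classify observations as food or contaminant
#'
#' Each observation is classed by the source classes of its mapped
#' proteins: all food taxa gives `food`, all contaminant taxa gives
#' `contaminant`, a mix gives `ambiguous` (excluded from the
#' authentication contrasts, with a logged count), and no classifiable
#' protein gives `unknown`.
#'
#' @param evidence Observation tibble.
#' @param proteins Protein tibble.
#' @param config A [class_config()].
#' @return `evidence` with an appended `class` column.
#' @export
assign_class <- function(evidence, proteins, config = class_config()) {
  proteins <- assign_protein_class(proteins, config)
  class_of <- setNames(proteins$source_class, proteins$accession)
  evidence$class <- vapply(evidence$protein_accessions, function(accs) {
    cls <- unique(c(
      unname(class_of[intersect(accs, names(class_of))]),
      if (any(accs %in% config$contaminant_accessions)) "contaminant"
    ))
    cls <- setdiff(cls, "unknown")
    if (length(cls) == 0L) "unknown"
    else if (length(cls) == 1L) cls
    else "ambiguous"
  }, character(1))
  n_amb <- sum(evidence$class == "ambiguous")
  if (n_amb > 0L) {
    inform(sprintf(
      "%d observation(s) map to both classes: marked ambiguous and excluded from contrasts",
      n_amb
    ))
  }
  evidence
}

#' Fraction of peptides arising from non-enzymatic cleavage
#'
#' Among the distinct peptide sequences of one class, the fraction whose
#' terminus classification is diagenetic (at least one non-enzymatic
#' N/D/Q/E cut). Counting is over distinct peptide sequences by default,
#' matching how degraded-peptide tallies are usually reported; set
#' `unit = "observation"` to count evidence rows instead.
#'
#' @param evidence Observation tibble carrying `class` and `diagenetic`
#'   columns (see [assign_class()], [classify_observations()]).
#' @param class Which classes to tabulate (default: every class present).
#' @param unit `"peptide"` (distinct sequences) or `"observation"`.
#' @return A tibble with columns `class`, `numerator`, `denominator` and
#'   `fraction`. An empty class yields `NA` (undefined) with a warning.
#' @export
nonenzymatic_fraction <- function(evidence,
                                  class = NULL,
                                  unit = c("peptide", "observation")) {
  unit <- match.arg(unit)
  if (!all(c("class", "diagenetic") %in% names(evidence))) {
    abort("evidence must carry class and diagenetic columns")
  }
  classes <- class %||% sort(unique(evidence$class))
  rows <- purrr::map(classes, function(cl) {
    sub <- evidence[!is.na(evidence$class) & evidence$class == cl &
                      !is.na(evidence$diagenetic), , drop = FALSE]
    if (unit == "peptide") {
      sub <- sub[!duplicated(sub$sequence), , drop = FALSE]
    }
    den <- nrow(sub)
    num <- sum(sub$diagenetic)
    if (den == 0L) {
      warn(sprintf("no classified peptides in class %s: fraction undefined", cl))
    }
    tibble::tibble(
      class = cl,
      numerator = as.integer(num),
      denominator = as.integer(den),
      fraction = if (den > 0L) num / den else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Deamidation fold ratio between classes
#'
#' Ratio of the food-class deamidation percentage to the contaminant-class
#' percentage. When the contaminant level is exactly zero the ratio is
#' undefined and `NA` is returned with the annotation attribute
#' `"note" = "contaminant level 0: food level exceeds any finite fold"`;
#' when either estimate is missing the result is `NA`.
#'
#' @param food_pct,contaminant_pct Deamidation percentages (numbers, or
#'   one-row estimate tibbles from [bootstrap_deamidation()], in which
#'   case `point_pct` is used).
#' @return A single numeric fold ratio (possibly `NA`).
#' @examples
#' fold_ratio(23, 4) # 5.75
#' @export
fold_ratio <- function(food_pct, contaminant_pct) {
  if (is.data.frame(food_pct)) food_pct <- food_pct$point_pct[1]
  if (is.data.frame(contaminant_pct)) contaminant_pct <- contaminant_pct$point_pct[1]
  if (is.na(food_pct) || is.na(contaminant_pct)) {
    return(NA_real_)
  }
  if (contaminant_pct == 0) {
    out <- NA_real_
    attr(out, "note") <- "contaminant level 0: food level exceeds any finite fold"
    return(out)
  }
  food_pct / contaminant_pct
}
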