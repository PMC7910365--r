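#' Run the full authentication pipeline
#'
#' End-to-end orchestration: terminus classification, class assignment,
#' deamidation counting and bootstrap estimation per sample and class,
#' non-enzymatic cleavage fractions, food-vs-contaminant fold ratios,
#' parsimony grouping with coverage / unique-peptide counts and the
#' validity filter, the damage-modification profile, and (optionally)
#' variant-site ambiguity flags. All configuration, including the seed,
#' is recorded in the report for provenance; two runs with the same
#' inputs and seed produce identical reports.
#'
#' Protein scores for the validity filter are engine quantities this
#' package does not compute; when `protein_scores` is `NULL` each
#' protein is summarised by the maximum score of its supporting
#' peptides, and that choice is recorded in the parameters.
#'
#' @param proteins Protein tibble (see [read_fasta()]).
#' @param evidence Observation tibble (see [read_evidence()]).
#' @param class_cfg A [class_config()].
#' @param filter_cfg A [filter_config()].
#' @param variant_sites Optional variant-site tibble
#'   (see [flag_variant_sites()]).
#' @param protein_scores Optional tibble (`accession`, `score`) of
#'   engine-supplied protein percentage scores.
#' @param n_iter Bootstrap iterations.
#' @param seed Integer seed for the bootstrap.
#' @param proline_rule,met_excision Digestion flags
#'   (see [classify_termini()]).
#' @param cleavage_unit Counting unit for [nonenzymatic_fraction()].
#' @return An object of class `auth_report`: a list of tibbles
#'   (`deamidation`, `cleavage`, `fold_ratios`, `groups`, `damage`,
#'   `variant_flags`, `counts`) plus `class_definitions` and
#'   `parameters`.
#' @export
run_authentication <- function(proteins, evidence,
                               class_cfg = class_config(),
                               filter_cfg = filter_config(),
                               variant_sites = NULL,
                               protein_scores = NULL,
                               n_iter = 1000L,
                               seed = 0L,
                               proline_rule = FALSE,
                               met_excision = TRUE,
                               cleavage_unit = c("peptide", "observation")) {
  cleavage_unit <- match.arg(cleavage_unit)
  if (nrow(proteins) == 0L) abort("stage read: empty protein database")
  if (nrow(evidence) == 0L) abort("stage read: empty evidence table")

  inform(sprintf("stage classify: %d observations, %d proteins",
                 nrow(evidence), nrow(proteins)))
  evidence <- classify_observations(evidence, proteins,
                                    proline_rule = proline_rule,
                                    met_excision = met_excision)
  evidence <- assign_class(evidence, proteins, class_cfg)
  evidence <- count_deamidation(evidence)

  contrast <- evidence[evidence$class %in% c("food", "contaminant"), , drop = FALSE]

  inform("stage deamidation: bootstrap estimates per sample and class")
  deam_by_sample <- estimate_deamidation(contrast, by = c("sample_id", "class"),
                                         n_iter = n_iter, seed = seed)
  deam_pooled <- estimate_deamidation(contrast, by = "class",
                                      n_iter = n_iter, seed = seed)
  deam_pooled$sample_id <- "(pooled)"
  deamidation <- dplyr::bind_rows(deam_by_sample, deam_pooled) |>
    dplyr::relocate("sample_id", "class", "residue_type")

  inform("stage cleavage: non-enzymatic fractions")
  cleave_by_sample <- contrast |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map(function(g) {
      out <- suppressWarnings(
        nonenzymatic_fraction(g, class = c("contaminant", "food"),
                              unit = cleavage_unit)
      )
      out$sample_id <- g$sample_id[1]
      out
    }) |>
    dplyr::bind_rows()
  cleave_pooled <- suppressWarnings(
    nonenzymatic_fraction(contrast, class = c("contaminant", "food"),
                          unit = cleavage_unit)
  )
  cleave_pooled$sample_id <- "(pooled)"
  cleavage <- dplyr::bind_rows(cleave_by_sample, cleave_pooled) |>
    dplyr::relocate("sample_id", "class")

  fold_ratios <- deamidation |>
    dplyr::select("sample_id", "class", "residue_type", "point_pct") |>
    tidyr::pivot_wider(names_from = "class", values_from = "point_pct")
  if (!"food" %in% names(fold_ratios)) fold_ratios$food <- NA_real_
  if (!"contaminant" %in% names(fold_ratios)) fold_ratios$contaminant <- NA_real_
  fold_ratios$fold <- purrr::map2_dbl(
    fold_ratios$food, fold_ratios$contaminant,
    function(f, c) as.numeric(fold_ratio(f, c))
  )
  fold_ratios$undefined_zero_contaminant <-
    !is.na(fold_ratios$food) & !is.na(fold_ratios$contaminant) &
    fold_ratios$contaminant == 0

  inform("stage inference: mapping, parsimony groups, validity filter")
  mapping <- map_peptides(contrast, proteins)
  groups <- parsimony_group(mapping, proteins)
  group_table <- protein_group_table(groups, mapping, proteins, protein_scores)
  peptide_scores <- contrast |>
    dplyr::group_by(peptide = .data$sequence) |>
    dplyr::summarise(
      score = if (all(is.na(.data$score))) NA_real_ else max(.data$score, na.rm = TRUE),
      .groups = "drop"
    )
  if (is.null(protein_scores)) {
    # summary score: maximum supporting-peptide score per lead protein
    lead_scores <- purrr::map_dbl(seq_len(nrow(groups)), function(i) {
      s <- peptide_scores$score[peptide_scores$peptide %in% groups$peptides[[i]]]
      if (length(s) == 0L) NA_real_ else max(s)
    })
    group_table$score <- lead_scores
  }
  unique_sets <- purrr::map(seq_len(nrow(groups)), function(i) {
    members <- groups$accessions[[i]]
    pep_to_acc <- split(mapping$accession, mapping$peptide)
    peps <- groups$peptides[[i]]
    peps[vapply(pep_to_acc[peps], function(a) all(unique(a) %in% members), logical(1))]
  })
  group_table$unique_peptides <- unique_sets
  group_table <- filter_groups(group_table, peptide_scores, filter_cfg)
  group_table$unique_peptides <- NULL

  damage <- damage_profile(contrast)

  variant_flags <- if (!is.null(variant_sites)) {
    flag_variant_sites(evidence, proteins, variant_sites)
  } else {
    tibble::tibble(
      obs_id = character(0), peptide = character(0), site = character(0),
      position_in_peptide = integer(0), observed_residue = character(0),
      reason = character(0), competing_assignments = character(0)
    )
  }

  counts <- evidence |>
    dplyr::count(.data$class, name = "n_observations") |>
    dplyr::left_join(
      evidence |>
        dplyr::distinct(.data$class, .data$sequence) |>
        dplyr::count(.data$class, name = "n_peptides"),
      by = "class"
    ) |>
    dplyr::arrange(.data$class)

  report <- structure(
    list(
      schema_version = 1L,
      deamidation = deamidation,
      cleavage = cleavage,
      fold_ratios = fold_ratios,
      groups = group_table,
      damage = damage,
      variant_flags = variant_flags,
      counts = counts,
      class_definitions = list(
        food_taxa = class_cfg$food_taxa,
        contaminant_taxa = class_cfg$contaminant_taxa,
        contaminant_accessions = class_cfg$contaminant_accessions
      ),
      parameters = list(
        seed = as.integer(seed),
        n_iter = as.integer(n_iter),
        proline_rule = proline_rule,
        met_excision = met_excision,
        cleavage_unit = cleavage_unit,
        diagenetic_terminus_rule = "at_least_one",
        coverage_rule = "strict_greater",
        score_rule = "greater_or_equal",
        protein_score_source = if (is.null(protein_scores)) {
          "max_supporting_peptide_score"
        } else {
          "engine_supplied"
        },
        min_protein_score_pct = filter_cfg$min_protein_score_pct,
        min_coverage_pct = filter_cfg$min_coverage_pct,
        min_unique_peptides = filter_cfg$min_unique_peptides,
        min_peptide_score_pct = filter_cfg$min_peptide_score_pct
      )
    ),
    class = "auth_report"
  )
  report
}

#' Write an authentication report
#'
#' `tsv` writes the tidy per-sample deamidation table; `json` serialises
#' the whole report (versioned schema). Output is deterministic: fixed
#' column and key order, numbers rendered to 4 significant digits, no
#' timestamps, so identical reports produce byte-identical files.
#'
#' @param report An `auth_report` from [run_authentication()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "auth_report"))
  if (format == "tsv") {
    out <- signif_numerics(tidy(report))
    readr::write_tsv(out, path, na = "NA")
    return(invisible(path))
  }
  ser <- report
  class(ser) <- NULL
  ser <- purrr::map(ser, function(x) {
    if (is.data.frame(x)) signif_numerics(x) else x
  })
  json <- jsonlite::toJSON(ser, dataframe = "columns", na = "null",
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

signif_numerics <- function(tbl, digits = 4L) {
  dplyr::mutate(tbl, dplyr::across(dplyr::where(is.double), ~ signif(.x, digits)))
}

#' Read back a JSON authentication report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return An `auth_report` object.
#' @export
read_report <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tables <- c("deamidation", "cleavage", "fold_ratios", "groups",
              "damage", "variant_flags", "counts")
  for (nm in tables) {
    raw[[nm]] <- tibble::as_tibble(as.data.frame(raw[[nm]], stringsAsFactors = FALSE))
  }
  structure(raw, class = "auth_report")
}

#' Load the bundled pottery identification table
#'
#' A published-style per-protein identification summary from an
#' archaeological pottery proteome survey (engine percentage score,
#' sequence coverage, supporting and unique peptide counts per sample),
#' bundled as a plain CSV for exercising the validity filter.
#'
#' @return A tibble with columns `sample`, `protein`, `accession`,
#'   `taxon`, `score`, `coverage_pct`, `n_peptides`, `n_unique`,
#'   `multispecies_taxa`.
#' @export
pottery_identifications <- function() {
  path <- system.file("extdata", "pottery_identifications.csv",
                      package = "paleopept", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    sample = readr::col_character(),
    protein = readr::col_character(),
    accession = readr::col_character(),
    taxon = readr::col_character(),
    score = readr::col_double(),
    coverage_pct = readr::col_double(),
    n_peptides = readr::col_integer(),
    n_unique = readr::col_integer(),
    multispecies_taxa = readr::col_character()
  ))
}

#' Load the bundled synthetic variant-site table
#'
#' A worked example of a taxon-discriminating variant site: the
#' beta-lactoglobulin D-vs-N position that separates Bovinae from sheep,
#' placed on synthetic protein sequences (coordinates and sequences are
#' constructed, not the real proteins).
#'
#' @return A variant-site tibble (see [flag_variant_sites()]).
#' @export
variant_sites_example <- function() {
  path <- system.file("extdata", "variant_sites_synthetic.tsv",
                      package = "paleopept", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    site = readr::col_character(),
    taxon = readr::col_character(),
    accession = readr::col_character(),
    position = readr::col_integer(),
    residue = readr::col_character()
  ))
}
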