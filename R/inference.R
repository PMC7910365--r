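#' Map peptides to database proteins
#'
#' Links every distinct peptide sequence in the evidence to every database
#' protein that contains it as an exact substring, independently of the
#' accessions declared by the search engine. Declared accessions that do
#' not actually contain the peptide are collected as discrepancies.
#'
#' @param evidence Observation tibble, or a character vector of peptide
#'   sequences.
#' @param proteins Protein tibble (see [read_fasta()]).
#' @return A tibble with one row per occurrence: `peptide`, `accession`,
#'   `start`, `end`. The attribute `"discrepancies"` holds a tibble of
#'   (`peptide`, `accession`) pairs declared in the evidence but not
#'   found by the substring search.
#' @export
map_peptides <- function(evidence, proteins) {
  if (is.data.frame(evidence)) {
    peptides <- unique(evidence$sequence)
    declared <- evidence |>
      dplyr::select("sequence", "protein_accessions") |>
      tidyr::unnest("protein_accessions") |>
      dplyr::distinct()
  } else {
    peptides <- unique(evidence)
    declared <- NULL
  }
  hits <- purrr::map(peptides, function(pep) {
    starts <- purrr::map(proteins$sequence, overlapping_matches, pattern = pep)
    n_hits <- lengths(starts)
    if (sum(n_hits) == 0L) {
      return(NULL)
    }
    tibble::tibble(
      peptide = pep,
      accession = rep(proteins$accession, n_hits),
      start = unlist(starts),
      end = unlist(starts) + nchar(pep) - 1L
    )
  })
  mapping <- dplyr::bind_rows(hits)
  if (nrow(mapping) == 0L) {
    mapping <- tibble::tibble(
      peptide = character(0), accession = character(0),
      start = integer(0), end = integer(0)
    )
  }
  mapping <- dplyr::arrange(mapping, .data$peptide, .data$accession, .data$start)
  if (!is.null(declared)) {
    found <- dplyr::distinct(mapping, peptide = .data$peptide, accession = .data$accession)
    disc <- dplyr::anti_join(
      declared |> dplyr::rename(peptide = "sequence", accession = "protein_accessions"),
      found,
      by = c("peptide", "accession")
    )
    # accessions absent from the database are not discrepancies, just unknown
    disc <- disc[disc$accession %in% proteins$accession, , drop = FALSE]
    attr(mapping, "discrepancies") <- disc
    if (nrow(disc) > 0L) {
      inform(sprintf(
        "%d declared peptide-protein assignment(s) not confirmed by substring search",
        nrow(disc)
      ))
    }
  }
  mapping
}

#' Group proteins by parsimony
#'
#' Proteins supported by identical peptide sets cannot be distinguished by
#' the observed evidence and are merged into one identification; when the
#' members belong to different taxa the group is reported as a
#' multispecies identification. Only this identical-set merge is
#' performed. A group whose peptide set is a strict subset of another
#' group's is annotated `subsumable_under` (it adds no independent
#' evidence) but is not removed.
#'
#' @param mapping Peptide-to-protein mapping from [map_peptides()].
#' @param proteins Protein tibble, used for taxa.
#' @return A tibble ordered by descending peptide count then accession:
#'   `group_id`, `accessions` (list), `taxa` (list of distinct taxa),
#'   `multispecies`, `peptides` (list), `n_peptides`, `n_proteins`,
#'   `subsumable_under`.
#' @export
parsimony_group <- function(mapping, proteins) {
  if (nrow(mapping) == 0L) {
    return(tibble::tibble(
      group_id = character(0), accessions = list(), taxa = list(),
      multispecies = logical(0), peptides = list(),
      n_peptides = integer(0), n_proteins = integer(0),
      subsumable_under = character(0)
    ))
  }
  pepsets <- mapping |>
    dplyr::distinct(.data$accession, .data$peptide) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(peptides = list(sort(unique(.data$peptide))), .groups = "drop")
  keys <- vapply(pepsets$peptides, paste, character(1), collapse = "\r")
  groups <- split(pepsets$accession, keys)
  # deterministic: order by descending peptide count, then first accession
  peptide_lists <- lapply(names(groups), function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  members <- lapply(groups, sort)
  ord <- order(-lengths(peptide_lists),
               vapply(members, `[`, character(1), 1))
  members <- members[ord]
  peptide_lists <- peptide_lists[ord]

  taxon_of <- setNames(proteins$taxon, proteins$accession)
  taxa <- lapply(members, function(m) sort(unique(unname(taxon_of[m]))))
  out <- tibble::tibble(
    group_id = sprintf("G%03d", seq_along(members)),
    accessions = unname(members),
    taxa = taxa,
    multispecies = lengths(taxa) >= 2L,
    peptides = peptide_lists,
    n_peptides = lengths(peptide_lists),
    n_proteins = lengths(members)
  )
  # strict-subset annotation
  out$subsumable_under <- vapply(seq_len(nrow(out)), function(i) {
    for (j in seq_len(nrow(out))) {
      if (i == j) next
      if (out$n_peptides[[j]] > out$n_peptides[[i]] &&
          all(out$peptides[[i]] %in% out$peptides[[j]])) {
        return(out$group_id[[j]])
      }
    }
    NA_character_
  }, character(1))
  out
}

#' Protein sequence coverage
#'
#' Percentage of a protein's residues covered by the union of the located
#' peptides; overlapping peptides count each residue once. Peptides not
#' found in the protein are skipped with a warning.
#'
#' @param protein Protein sequence string (or one-row protein tibble).
#' @param peptides Character vector of peptide sequences.
#' @return Coverage percentage in `[0, 100]`.
#' @examples
#' coverage(paste(rep("A", 100), collapse = ""), character(0)) # 0
#' @export
coverage <- function(protein, peptides) {
  if (is.data.frame(protein)) protein <- protein$sequence[1]
  n <- nchar(protein)
  covered <- logical(n)
  for (pep in unique(peptides)) {
    loci <- locate_peptide(protein, pep)
    if (nrow(loci) == 0L) {
      warn(sprintf("peptide %s not found in protein: skipped from coverage", pep))
      next
    }
    for (k in seq_len(nrow(loci))) {
      covered[loci$start[k]:loci$end[k]] <- TRUE
    }
  }
  100 * sum(covered) / n
}

#' Count group-unique peptides
#'
#' Number of distinct peptide sequences supporting a group that map to no
#' protein outside the group. Modification variants of one sequence count
#' once (the mapping is sequence-level, so this holds by construction).
#'
#' @param group One row of the [parsimony_group()] table (or a character
#'   vector of member accessions).
#' @param mapping Peptide-to-protein mapping from [map_peptides()].
#' @return Integer count of unique peptides.
#' @export
count_unique <- function(group, mapping) {
  members <- if (is.data.frame(group)) group$accessions[[1]] else group
  pep_to_acc <- split(mapping$accession, mapping$peptide)
  in_group <- vapply(pep_to_acc, function(a) all(unique(a) %in% members), logical(1))
  group_peps <- unique(mapping$peptide[mapping$accession %in% members])
  sum(in_group[group_peps])
}

#' Build a per-protein identification table
#'
#' One row per protein with its parsimony group, taxon, coverage,
#' supporting-peptide and group-unique-peptide counts, mirroring the usual
#' published identification summaries. An engine-supplied protein score
#' table (`accession`, `score`) is carried through when given.
#'
#' @param groups Group table from [parsimony_group()].
#' @param mapping Mapping from [map_peptides()].
#' @param proteins Protein tibble.
#' @param protein_scores Optional tibble (`accession`, `score`) of
#'   engine-supplied percentage scores.
#' @return A tibble with columns `accession`, `taxon`, `group_id`,
#'   `multispecies`, `multispecies_taxa`, `score`, `coverage_pct`,
#'   `n_peptides`, `n_unique`.
#' @export
protein_group_table <- function(groups, mapping, proteins, protein_scores = NULL) {
  if (nrow(groups) == 0L) {
    return(tibble::tibble(
      accession = character(0), taxon = character(0), group_id = character(0),
      multispecies = logical(0), multispecies_taxa = character(0),
      score = numeric(0), coverage_pct = numeric(0),
      n_peptides = integer(0), n_unique = integer(0)
    ))
  }
  seq_of <- setNames(proteins$sequence, proteins$accession)
  taxon_of <- setNames(proteins$taxon, proteins$accession)
  uniq_of <- vapply(seq_len(nrow(groups)), function(i) {
    count_unique(groups[i, ], mapping)
  }, numeric(1))
  rows <- purrr::map(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    accs <- g$accessions[[1]]
    lead <- accs[1] # representative member listed first
    other_taxa <- setdiff(g$taxa[[1]], taxon_of[[lead]])
    tibble::tibble(
      accession = lead,
      taxon = unname(taxon_of[lead]),
      group_id = g$group_id,
      multispecies = g$multispecies,
      multispecies_taxa = if (length(other_taxa) > 0L) {
        paste(other_taxa, collapse = "; ")
      } else {
        NA_character_
      },
      coverage_pct = coverage(seq_of[[lead]], g$peptides[[1]]),
      n_peptides = g$n_peptides,
      n_unique = as.integer(uniq_of[i])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(protein_scores)) {
    out <- dplyr::left_join(out, dplyr::rename(protein_scores, score = "score"),
                            by = "accession")
  } else {
    out$score <- NA_real_
  }
  dplyr::relocate(out, "accession", "taxon", "group_id", "multispecies",
                  "multispecies_taxa", "score")
}

#' Flag taxon-discriminating variant sites erased by deamidation
#'
#' A residue position whose letter differs between taxa (e.g. aspartate in
#' Bovinae where sheep carry asparagine) can discriminate species -- unless
#' deamidation makes the states indistinguishable: a deamidated N is
#' chemically D, so an observed D (or an observed N carrying a deamidation
#' event) at a D-vs-N site cannot be assigned to either taxon. The
#' analogous ambiguity holds for E vs deamidated Q.
#'
#' Variant sites are supplied as a configuration table with columns
#' `site`, `taxon`, `accession`, `position` (1-based in the protein whose
#' accession is given) and `residue`; rows sharing a `site` value describe
#' the same homologous position in different taxa.
#'
#' @param evidence Observation tibble.
#' @param proteins Protein tibble.
#' @param variant_sites Variant-site configuration tibble (see Details).
#' @return A tibble of flags: `obs_id`, `peptide`, `site`,
#'   `position_in_peptide`, `observed_residue`, `reason`
#'   (`"deamidation_D_vs_N"` or `"deamidation_E_vs_Q"`) and
#'   `competing_assignments` (collapsed `taxon=residue` string).
#' @export
flag_variant_sites <- function(evidence, proteins, variant_sites) {
  needed <- c("site", "taxon", "accession", "position", "residue")
  missing_cols <- setdiff(needed, names(variant_sites))
  if (length(missing_cols) > 0L) {
    abort(paste0("variant_sites is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  seq_db <- setNames(proteins$sequence, proteins$accession)
  flags <- list()
  site_split <- split(variant_sites, variant_sites$site)
  for (site_id in names(site_split)) {
    site <- site_split[[site_id]]
    residues <- unique(site$residue)
    reason <- if (all(c("D", "N") %in% residues)) {
      "deamidation_D_vs_N"
    } else if (all(c("E", "Q") %in% residues)) {
      "deamidation_E_vs_Q"
    } else {
      next # not a deamidation-confusable site
    }
    amide <- if (reason == "deamidation_D_vs_N") "N" else "Q"
    acid <- if (reason == "deamidation_D_vs_N") "D" else "E"
    competing <- paste(sprintf("%s=%s", site$taxon, site$residue), collapse = "; ")
    for (r in seq_len(nrow(site))) {
      acc <- site$accession[r]
      if (!acc %in% names(seq_db)) next
      pos <- site$position[r]
      for (i in seq_len(nrow(evidence))) {
        pep <- evidence$sequence[i]
        loci <- locate_peptide(seq_db[[acc]], pep)
        loci <- loci[loci$start <= pos & loci$end >= pos, , drop = FALSE]
        if (nrow(loci) == 0L) next
        pip <- pos - loci$start[1] + 1L
        observed <- substring(pep, pip, pip)
        deam_here <- any(
          evidence$modifications[[i]]$mod_type == "deamidation" &
            evidence$modifications[[i]]$position == pip
        )
        if (observed == acid || (observed == amide && deam_here)) {
          flags[[length(flags) + 1L]] <- tibble::tibble(
            obs_id = evidence$obs_id[i],
            peptide = pep,
            site = site_id,
            position_in_peptide = pip,
            observed_residue = observed,
            reason = reason,
            competing_assignments = competing
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(flags)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      obs_id = character(0), peptide = character(0), site = character(0),
      position_in_peptide = integer(0), observed_residue = character(0),
      reason = character(0), competing_assignments = character(0)
    ))
  }
  dplyr::distinct(out)
}
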