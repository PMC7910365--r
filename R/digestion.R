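#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to lysine and arginine and emits
#' every fragment containing up to `max_missed` internal (missed) cleavage
#' sites. With `proline_rule = TRUE` a K/R immediately followed by proline
#' is not treated as a cleavage site (engine defaults differ on this, so
#' it is off by default).
#'
#' @param sequence Protein amino-acid string.
#' @param max_missed Maximum number of missed cleavage sites (default 0).
#' @param proline_rule Suppress cleavage at K/R-P junctions?
#' @return A tibble with columns `peptide`, `start`, `end` (1-based,
#'   inclusive) and `missed_cleavages`, ordered by `start` then `end`.
#' @examples
#' digest("MKAYNDRTESTK", max_missed = 1)
#' @export
digest <- function(sequence, max_missed = 0L, proline_rule = FALSE) {
  stopifnot(max_missed >= 0L)
  if (is.na(sequence) || !nzchar(sequence)) {
    return(tibble::tibble(
      peptide = character(0), start = integer(0), end = integer(0),
      missed_cleavages = integer(0)
    ))
  }
  assert_sequence(sequence)
  n <- nchar(sequence)
  sites <- cleavage_sites(sequence, proline_rule)
  bounds <- c(0L, sites[sites < n], n) # fragment i spans bounds[i]+1 .. bounds[i+1]
  n_frag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(n_frag)) {
    for (m in 0:min(max_missed, n_frag - i)) {
      out[[length(out) + 1L]] <- c(bounds[i] + 1L, bounds[i + 1L + m], m)
    }
  }
  mat <- do.call(rbind, out)
  res <- tibble::tibble(
    peptide = substring(sequence, mat[, 1], mat[, 2]),
    start = as.integer(mat[, 1]),
    end = as.integer(mat[, 2]),
    missed_cleavages = as.integer(mat[, 3])
  )
  dplyr::arrange(res, .data$start, .data$end)
}

# 1-based positions i such that trypsin cleaves between i and i+1
cleavage_sites <- function(sequence, proline_rule = FALSE) {
  chars <- seq_chars(sequence)
  sites <- which(chars %in% TRYPTIC_RESIDUES)
  if (proline_rule) {
    nxt <- chars[pmin(sites + 1L, length(chars))]
    sites <- sites[!(sites < length(chars) & nxt == "P")]
  }
  sites
}

#' Locate a peptide within a protein
#'
#' All exact (possibly overlapping) occurrences of `peptide` in `protein`.
#'
#' @param protein Protein sequence string (or a one-row protein tibble).
#' @param peptide Peptide sequence string.
#' @return A tibble with columns `start` and `end` (1-based, inclusive);
#'   zero rows when the peptide is absent.
#' @export
locate_peptide <- function(protein, peptide) {
  if (is.data.frame(protein)) protein <- protein$sequence[1]
  starts <- overlapping_matches(protein, peptide)
  tibble::tibble(start = starts, end = starts + nchar(peptide) - 1L)
}

#' Classify peptide termini against a protein
#'
#' Applies the cleavage-chemistry rules to a peptide located at
#' `start..end` (1-based, inclusive) in `protein`. The N-terminus is
#' classified from the residue preceding the peptide, the C-terminus from
#' the peptide's own final residue (the residue whose carboxyl side was
#' cut): K/R is tryptic; Y/W/F aspecific enzymatic; N/D/Q/E diagenetic
#' non-enzymatic; anything else nonspecific. The protein's own ends count
#' as `protein_terminus`, as does `start = 2` behind an initiator
#' methionine when `met_excision = TRUE` (N-terminal Met excision is
#' routine biological processing). A peptide is `full_tryptic` when both
#' termini are tryptic or protein termini, `semi_tryptic` when exactly one
#' is, and `non_specific` otherwise; it is flagged `diagenetic` when at
#' least one terminus is a non-enzymatic N/D/Q/E cut.
#'
#' All arguments are vectorised over `start`/`end`.
#'
#' @param protein Protein sequence string (or one-row protein tibble).
#' @param start,end Peptide coordinates, 1-based inclusive.
#' @param proline_rule Suppress cleavage at K/R-P junctions?
#' @param met_excision Treat `start = 2` behind an initiator M as a
#'   protein terminus?
#' @return A tibble with columns `nterm_class`, `cterm_class`,
#'   `missed_cleavages`, `specificity` and `diagenetic`.
#' @examples
#' classify_termini("MKAYNDRTESTK", 8, 12) # TESTK: full tryptic
#' classify_termini("MKAYNDRTESTK", 6, 12) # DRTESTK: semi, diagenetic
#' @export
classify_termini <- function(protein, start, end,
                             proline_rule = FALSE, met_excision = TRUE) {
  if (is.data.frame(protein)) protein <- protein$sequence[1]
  n <- nchar(protein)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 1L | end > n | start > end)) {
    abort(sprintf(
      "peptide coordinates out of range for protein of length %d", n
    ))
  }
  chars <- seq_chars(protein)

  residue_class <- function(res, next_res) {
    cls <- dplyr::case_when(
      res %in% TRYPTIC_RESIDUES ~ "tryptic",
      res %in% ASPECIFIC_RESIDUES ~ "aspecific_YWF",
      res %in% DIAGENETIC_RESIDUES ~ "diagenetic_NDQE",
      TRUE ~ "nonspecific_other"
    )
    if (proline_rule) {
      cls[cls == "tryptic" & !is.na(next_res) & next_res == "P"] <- "nonspecific_other"
    }
    cls
  }

  prev_res <- ifelse(start > 1L, chars[pmax(start - 1L, 1L)], NA_character_)
  nterm <- ifelse(
    start == 1L | (met_excision & start == 2L & chars[1] == "M"),
    "protein_terminus",
    residue_class(prev_res, chars[start])
  )
  last_res <- chars[end]
  next_after_end <- ifelse(end < n, chars[pmin(end + 1L, n)], NA_character_)
  cterm <- ifelse(
    end == n,
    "protein_terminus",
    residue_class(last_res, next_after_end)
  )

  # internal K/R (positions start .. end-1) that trypsin failed to cut
  site_flag <- as.integer(chars %in% TRYPTIC_RESIDUES)
  if (proline_rule) {
    kp <- which(chars %in% TRYPTIC_RESIDUES)
    kp <- kp[kp < n & chars[kp + 1L] == "P"]
    site_flag[kp] <- 0L
  }
  cum <- c(0L, cumsum(site_flag))
  missed <- cum[pmax(end, start)] - cum[start] # sites in [start, end-1]

  tryptic_like <- function(x) x %in% c("tryptic", "protein_terminus")
  n_tryptic <- tryptic_like(nterm) + tryptic_like(cterm)
  specificity <- c("non_specific", "semi_tryptic", "full_tryptic")[n_tryptic + 1L]

  tibble::tibble(
    nterm_class = nterm,
    cterm_class = cterm,
    missed_cleavages = as.integer(missed),
    specificity = specificity,
    diagenetic = nterm == "diagenetic_NDQE" | cterm == "diagenetic_NDQE"
  )
}

#' Classify the termini of every evidence observation
#'
#' Binds evidence rows to the terminus rules of [classify_termini()]. Each
#' observation's peptide is searched in every protein it is declared
#' against; every occurrence is classified, and the verdict kept is the
#' most specific achievable (`full_tryptic` over `semi_tryptic` over
#' `non_specific`), ties broken by the lexicographically first accession
#' and then the earliest locus. When the classifications differ between
#' mapped proteins the observation is flagged `specificity_ambiguous`.
#'
#' When none of the declared proteins is in the database (or none contains
#' the peptide) the sequence-context columns `preceding_residue` /
#' `following_residue`, if present, are used as a fallback (`"-"` denotes
#' a protein terminus); otherwise the observation is marked `unmappable`
#' and carries `NA` classifications, excluded from specificity statistics.
#'
#' @param evidence Observation tibble (see [read_evidence()]).
#' @param proteins Protein tibble (see [read_fasta()]).
#' @inheritParams classify_termini
#' @return `evidence` with appended columns `matched_accession`,
#'   `nterm_class`, `cterm_class`, `missed_cleavages`, `specificity`,
#'   `diagenetic`, `specificity_ambiguous`, `unmappable`.
#' @export
classify_observations <- function(evidence, proteins,
                                  proline_rule = FALSE, met_excision = TRUE) {
  seq_db <- setNames(proteins$sequence, proteins$accession)
  has_context <- all(c("preceding_residue", "following_residue") %in% names(evidence))

  key <- paste(
    evidence$sequence,
    vapply(evidence$protein_accessions, function(a) paste(sort(a), collapse = ";"),
           character(1))
  )
  uniq <- !duplicated(key)
  results <- purrr::pmap(
    list(
      evidence$sequence[uniq],
      evidence$protein_accessions[uniq],
      if (has_context) evidence$preceding_residue[uniq] else rep(NA_character_, sum(uniq)),
      if (has_context) evidence$following_residue[uniq] else rep(NA_character_, sum(uniq))
    ),
    function(pep, accs, prev, nxt) {
      classify_one_peptide(pep, accs, seq_db, prev, nxt, proline_rule, met_excision)
    }
  )
  res_tbl <- dplyr::bind_rows(results)[match(key, key[uniq]), ]
  n_unmappable <- sum(res_tbl$unmappable[!duplicated(key)])
  if (n_unmappable > 0L) {
    inform(sprintf(
      "%d peptide(s) not found in any mapped protein: marked unmappable",
      n_unmappable
    ))
  }
  dplyr::bind_cols(evidence, res_tbl)
}

spec_rank <- function(x) match(x, c("non_specific", "semi_tryptic", "full_tryptic"))

classify_one_peptide <- function(pep, accs, seq_db, prev, nxt,
                                 proline_rule, met_excision) {
  unmatched <- tibble::tibble(
    matched_accession = NA_character_,
    nterm_class = NA_character_, cterm_class = NA_character_,
    missed_cleavages = NA_integer_, specificity = NA_character_,
    diagenetic = NA, specificity_ambiguous = FALSE, unmappable = TRUE
  )
  accs <- sort(intersect(accs, names(seq_db)))
  per_protein <- list()
  for (acc in accs) {
    loci <- locate_peptide(seq_db[[acc]], pep)
    if (nrow(loci) == 0L) next
    cls <- classify_termini(seq_db[[acc]], loci$start, loci$end,
                            proline_rule = proline_rule,
                            met_excision = met_excision)
    best <- which.max(spec_rank(cls$specificity)) # earliest locus wins ties
    per_protein[[acc]] <- cls[best, ]
  }
  if (length(per_protein) > 0L) {
    ranks <- vapply(per_protein, function(x) spec_rank(x$specificity), integer(1))
    pick <- which.max(ranks) # ties -> first accession lexicographically
    out <- per_protein[[pick]]
    out$matched_accession <- names(per_protein)[pick]
    out$specificity_ambiguous <- length(unique(ranks)) > 1L
    out$unmappable <- FALSE
    return(dplyr::relocate(out, "matched_accession"))
  }
  # evidence-context fallback when the database lacks the protein
  if (!is.na(prev) || !is.na(nxt)) {
    cls <- classify_from_context(pep, prev, nxt, proline_rule)
    return(cls)
  }
  unmatched
}

classify_from_context <- function(pep, prev, nxt, proline_rule) {
  chars <- seq_chars(pep)
  n <- length(chars)
  res_class <- function(res) {
    if (is.na(res)) return(NA_character_)
    if (res %in% TRYPTIC_RESIDUES) "tryptic"
    else if (res %in% ASPECIFIC_RESIDUES) "aspecific_YWF"
    else if (res %in% DIAGENETIC_RESIDUES) "diagenetic_NDQE"
    else "nonspecific_other"
  }
  nterm <- if (!is.na(prev) && prev %in% c("-", "")) "protein_terminus" else res_class(prev)
  if (!is.na(nterm) && nterm == "tryptic" && proline_rule && chars[1] == "P") {
    nterm <- "nonspecific_other"
  }
  cterm <- if (!is.na(nxt) && nxt %in% c("-", "")) "protein_terminus" else res_class(chars[n])
  if (!is.na(cterm) && cterm == "tryptic" && proline_rule && !is.na(nxt) && nxt == "P") {
    cterm <- "nonspecific_other"
  }
  missed <- sum(chars[-n] %in% TRYPTIC_RESIDUES)
  tryptic_like <- function(x) !is.na(x) && x %in% c("tryptic", "protein_terminus")
  n_tryp <- tryptic_like(nterm) + tryptic_like(cterm)
  specificity <- if (is.na(nterm) || is.na(cterm)) NA_character_ else {
    c("non_specific", "semi_tryptic", "full_tryptic")[n_tryp + 1L]
  }
  tibble::tibble(
    matched_accession = NA_character_,
    nterm_class = nterm, cterm_class = cterm,
    missed_cleavages = as.integer(missed),
    specificity = specificity,
    diagenetic = isTRUE(nterm == "diagenetic_NDQE") | isTRUE(cterm == "diagenetic_NDQE"),
    specificity_ambiguous = FALSE,
    unmappable = FALSE
  )
}
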