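#' Read a protein sequence database from FASTA
#'
#' Parses a FASTA file into a protein table. UniProt-style headers
#' (`>sp|P02754|LACB_BOVIN ... OS=Bos taurus ...`) are recognised: the
#' accession is the second `|`-delimited field and the taxon is taken from
#' the `OS=` token. Plain headers are accepted, in which case the accession
#' is the first whitespace-delimited word and the taxon is `"unknown"`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `accession`,
#'   `taxon`, `source_class` (initially `"unknown"`, see
#'   [assign_protein_class()]) and `sequence` (uppercase amino acids).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P00001|TOY_EX OS=Bos taurus", "MKAYNDRTESTK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble::tibble(
      accession = character(0), taxon = character(0),
      source_class = character(0), sequence = character(0)
    ))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(sprintf(
      "malformed FASTA record: line %d of %s does not start a record",
      nonblank[1], path
    ))
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  sequence <- toupper(as.character(aa))
  names(sequence) <- NULL

  accession <- parse_fasta_accession(headers)
  taxon <- parse_fasta_taxon(headers)

  if (any(!nzchar(sequence))) {
    abort(sprintf(
      "malformed FASTA record: empty sequence for %s",
      paste(accession[!nzchar(sequence)], collapse = ", ")
    ))
  }
  assert_sequence(sequence, "protein sequence")
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate accession(s) in FASTA: ", paste(dup, collapse = ", ")))
  }
  tibble::tibble(
    accession = accession,
    taxon = taxon,
    source_class = "unknown",
    sequence = sequence
  )
}

parse_fasta_accession <- function(headers) {
  uniprot <- stringr::str_match(headers, "^(?:sp|tr)\\|([^|\\s]+)\\|")[, 2]
  plain <- stringr::str_extract(headers, "^\\S+")
  dplyr::coalesce(uniprot, plain)
}

parse_fasta_taxon <- function(headers) {
  os <- stringr::str_match(headers, "OS=(.+?)(?:\\s+[A-Z]{2}=|$)")[, 2]
  dplyr::coalesce(stringr::str_trim(os), "unknown")
}

#' Write a protein table to FASTA
#'
#' Headers carry the accession plus an `OS=` taxon token so the file
#' round-trips through [read_fasta()].
#'
#' @param proteins Protein tibble as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- sprintf("%s OS=%s", proteins$accession, proteins$taxon)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Parse a modified peptide sequence
#'
#' Understands the MaxQuant inline dialect: the bare sequence wrapped in
#' underscores with lower-case tokens in parentheses after the modified
#' residue, e.g. `"_AN(de)SQK_"` is a deamidation on the N at position 2.
#' A token before the first residue (e.g. `"_(gl)QSK_"`) is attached to
#' residue 1. Unknown tokens are an error, never skipped: a silently
#' dropped deamidation token would bias the deamidation statistic.
#'
#' @param modified_sequence Annotated sequence string.
#' @param sequence Bare sequence; parsed letters must match it.
#' @return A tibble of modification events with columns `mod_type`,
#'   `position` (1-based within the peptide) and `residue`.
#' @examples
#' parse_modified_sequence("_AN(de)SQK_", "ANSQK")
#' @export
parse_modified_sequence <- function(modified_sequence, sequence) {
  body <- gsub("^_+|_+$", "", modified_sequence)
  tokens <- regmatches(body, gregexpr("\\(([a-z]+)\\)|.", body))[[1]]
  pos <- 0L
  letters_seen <- character(0)
  events <- list()
  for (tok in tokens) {
    if (grepl("^\\(", tok)) {
      code <- gsub("[()]", "", tok)
      mod_type <- unname(MOD_TOKEN_MAP[code])
      if (is.na(mod_type)) {
        abort(sprintf(
          "unknown modification token \"(%s)\" in modified sequence \"%s\"",
          code, modified_sequence
        ))
      }
      at <- max(pos, 1L) # leading token binds to residue 1
      events[[length(events) + 1L]] <- list(mod_type = mod_type, position = at)
    } else if (grepl("^[A-Z]$", tok)) {
      pos <- pos + 1L
      letters_seen[pos] <- tok
    } else {
      abort(sprintf(
        "unparseable character \"%s\" in modified sequence \"%s\"",
        tok, modified_sequence
      ))
    }
  }
  bare <- paste(letters_seen, collapse = "")
  if (!identical(bare, sequence)) {
    abort(sprintf(
      "modified sequence \"%s\" does not match sequence \"%s\"",
      modified_sequence, sequence
    ))
  }
  if (length(events) == 0L) {
    return(empty_modifications())
  }
  out <- tibble::tibble(
    mod_type = vapply(events, `[[`, character(1), "mod_type"),
    position = vapply(events, `[[`, integer(1), "position")
  )
  out$residue <- substring(sequence, out$position, out$position)
  bad_deam <- out$mod_type == "deamidation" & !out$residue %in% c("N", "Q")
  if (any(bad_deam)) {
    abort(sprintf(
      "deamidation on non-N/Q residue %s in \"%s\"",
      paste(out$residue[bad_deam], collapse = ", "), modified_sequence
    ))
  }
  out
}

#' Rebuild a modified-sequence string from events
#'
#' Inverse of [parse_modified_sequence()] for the inline token dialect.
#'
#' @param sequence Bare peptide sequence.
#' @param modifications Modification tibble (`mod_type`, `position`).
#' @return The annotated string, wrapped in underscores.
#' @export
build_modified_sequence <- function(sequence, modifications) {
  chars <- seq_chars(sequence)
  if (nrow(modifications) > 0L) {
    codes <- names(MOD_TOKEN_MAP)[match(modifications$mod_type, MOD_TOKEN_MAP)]
    if (anyNA(codes)) {
      abort(paste0(
        "no inline token for modification type: ",
        paste(unique(modifications$mod_type[is.na(codes)]), collapse = ", ")
      ))
    }
    ann <- vapply(split(codes, modifications$position), function(cc) {
      paste0("(", paste(sort(cc), collapse = ")("), ")")
    }, character(1))
    at <- as.integer(names(ann))
    chars[at] <- paste0(chars[at], ann)
  }
  paste0("_", paste(chars, collapse = ""), "_")
}

summarise_modifications <- function(modifications) {
  if (nrow(modifications) == 0L) {
    return("Unmodified")
  }
  counts <- table(MOD_DISPLAY_NAMES[modifications$mod_type])
  paste(
    ifelse(counts > 1L, paste(counts, names(counts)), names(counts)),
    collapse = ","
  )
}

#' Read a peptide evidence table
#'
#' Reads engine output into the shared observation model. Two dialects are
#' supported:
#' \describe{
#'   \item{`maxquant_evidence`}{Tab-separated with columns `Sequence`,
#'     `Modified sequence`, `Modifications`, `Proteins`, `Intensity`,
#'     `Score`; the sample is taken from `Raw file` (or `Sample` /
#'     `Experiment`) when present.}
#'   \item{`generic_csv`}{Comma-separated with columns `sample_id`,
#'     `sequence`, `modified_sequence`, `proteins`, `intensity`, `score`
#'     and optional `preceding_residue` / `following_residue` context
#'     columns.}
#' }
#' Modification events are parsed from the modified sequence (inline token
#' dialect, see [parse_modified_sequence()]). Rows with an engine score
#' below `min_score` (default 40, the usual threshold for modified and
#' unmodified peptides) are dropped and the count reported; likewise rows
#' shorter than `min_length` or with no protein mapping. Observations with
#' missing intensity are retained for counting but are excluded later from
#' intensity-weighted statistics.
#'
#' @param path Path to the evidence file.
#' @param dialect `"maxquant_evidence"` or `"generic_csv"`.
#' @param min_score Minimum engine score; lower-scoring rows are dropped.
#' @param min_length Minimum peptide length retained.
#' @return A tibble with one row per retained observation: `obs_id`,
#'   `sample_id`, `sequence`, `modified_sequence`, `modifications`
#'   (list-column of event tibbles), `protein_accessions` (list-column),
#'   `intensity`, `score` and, when present in the input,
#'   `preceding_residue` / `following_residue`. Drop counts are attached
#'   as attributes `n_dropped_score`, `n_dropped_short`,
#'   `n_dropped_unmapped`.
#' @export
read_evidence <- function(path,
                          dialect = c("maxquant_evidence", "generic_csv"),
                          min_score = 40,
                          min_length = 5L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("evidence file not found: ", path))
  }
  raw <- if (dialect == "maxquant_evidence") {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  }
  required <- if (dialect == "maxquant_evidence") {
    c("Sequence", "Modified sequence", "Modifications", "Proteins",
      "Intensity", "Score")
  } else {
    c("sample_id", "sequence", "modified_sequence", "proteins",
      "intensity", "score")
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "evidence file %s is missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }

  if (dialect == "maxquant_evidence") {
    sample_col <- intersect(c("Raw file", "Sample", "Experiment"), names(raw))
    obs <- tibble::tibble(
      obs_id = if ("id" %in% names(raw)) raw[["id"]] else as.character(seq_len(nrow(raw))),
      sample_id = if (length(sample_col) > 0L) raw[[sample_col[1]]] else "sample_1",
      sequence = toupper(raw[["Sequence"]]),
      modified_sequence = raw[["Modified sequence"]],
      proteins_raw = raw[["Proteins"]],
      intensity = suppressWarnings(as.numeric(raw[["Intensity"]])),
      score = suppressWarnings(as.numeric(raw[["Score"]]))
    )
  } else {
    obs <- tibble::tibble(
      obs_id = if ("obs_id" %in% names(raw)) raw[["obs_id"]] else as.character(seq_len(nrow(raw))),
      sample_id = raw[["sample_id"]],
      sequence = toupper(raw[["sequence"]]),
      modified_sequence = raw[["modified_sequence"]],
      proteins_raw = raw[["proteins"]],
      intensity = suppressWarnings(as.numeric(raw[["intensity"]])),
      score = suppressWarnings(as.numeric(raw[["score"]]))
    )
    if ("preceding_residue" %in% names(raw)) obs$preceding_residue <- raw[["preceding_residue"]]
    if ("following_residue" %in% names(raw)) obs$following_residue <- raw[["following_residue"]]
  }

  assert_sequence(obs$sequence, "peptide sequence")

  n_in <- nrow(obs)
  low <- !is.na(obs$score) & obs$score < min_score
  obs <- obs[!low, , drop = FALSE]
  short <- nchar(obs$sequence) < min_length
  obs <- obs[!short, , drop = FALSE]

  obs$protein_accessions <- lapply(
    strsplit(dplyr::coalesce(obs$proteins_raw, ""), ";", fixed = TRUE),
    function(x) x[nzchar(x)]
  )
  unmapped <- lengths(obs$protein_accessions) == 0L
  if (any(unmapped)) {
    warn(sprintf("dropping %d row(s) with no protein mapping", sum(unmapped)))
  }
  obs <- obs[!unmapped, , drop = FALSE]
  obs$proteins_raw <- NULL

  # parse per row so an unparseable token reports its row number
  obs$modifications <- purrr::pmap(
    list(obs$modified_sequence, obs$sequence, seq_len(nrow(obs))),
    function(ms, sq, i) {
      tryCatch(
        parse_modified_sequence(ms, sq),
        error = function(e) {
          abort(sprintf("row %d: %s", i, conditionMessage(e)))
        }
      )
    }
  )

  n_missing_intensity <- sum(is.na(obs$intensity))
  inform(sprintf(
    "read %d evidence rows from %s: kept %d (dropped %d below score %s, %d shorter than %d, %d unmapped); %d without intensity",
    n_in, basename(path), nrow(obs), sum(low), format(min_score), sum(short),
    min_length, sum(unmapped), n_missing_intensity
  ))
  obs <- dplyr::relocate(
    obs, "obs_id", "sample_id", "sequence", "modified_sequence",
    "modifications", "protein_accessions", "intensity", "score"
  )
  attr(obs, "n_dropped_score") <- sum(low)
  attr(obs, "n_dropped_short") <- sum(short)
  attr(obs, "n_dropped_unmapped") <- sum(unmapped)
  obs
}

#' Write an evidence table
#'
#' Writes observations back out in either supported dialect so that
#' simulated or filtered evidence can feed any downstream tool (and
#' re-parse through [read_evidence()] unchanged).
#'
#' @param evidence Observation tibble (see [read_evidence()]).
#' @param path Output path.
#' @param dialect `"maxquant_evidence"` (TSV) or `"generic_csv"` (CSV).
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path,
                           dialect = c("maxquant_evidence", "generic_csv")) {
  dialect <- match.arg(dialect)
  proteins <- vapply(evidence$protein_accessions, paste, character(1), collapse = ";")
  mods <- vapply(evidence$modifications, summarise_modifications, character(1))
  if (dialect == "maxquant_evidence") {
    out <- tibble::tibble(
      id = evidence$obs_id,
      `Raw file` = evidence$sample_id,
      Sequence = evidence$sequence,
      `Modified sequence` = evidence$modified_sequence,
      Modifications = mods,
      Proteins = proteins,
      Intensity = evidence$intensity,
      Score = evidence$score
    )
    readr::write_tsv(out, path, na = "")
  } else {
    out <- tibble::tibble(
      obs_id = evidence$obs_id,
      sample_id = evidence$sample_id,
      sequence = evidence$sequence,
      modified_sequence = evidence$modified_sequence,
      proteins = proteins,
      intensity = evidence$intensity,
      score = evidence$score
    )
    if ("preceding_residue" %in% names(evidence)) {
      out$preceding_residue <- evidence$preceding_residue
    }
    if ("following_residue" %in% names(evidence)) {
      out$following_residue <- evidence$following_residue
    }
    readr::write_csv(out, path, na = "")
  }
  invisible(path)
}
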