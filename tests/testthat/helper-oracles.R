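# Shared fixtures and independent brute-force oracles.

# build a minimal observation tibble from bare ingredients; deamidation
# positions index N/Q residues in the peptide
make_evidence <- function(sequences, deam_positions = vector("list", length(sequences)),
                          intensity = rep(1, length(sequences)),
                          score = rep(80, length(sequences)),
                          sample_id = "s1",
                          proteins = as.list(rep("P1", length(sequences)))) {
  mods <- lapply(seq_along(sequences), function(i) {
    pos <- deam_positions[[i]]
    if (is.null(pos) || length(pos) == 0L) {
      return(tibble::tibble(mod_type = character(0), position = integer(0),
                            residue = character(0)))
    }
    tibble::tibble(
      mod_type = "deamidation",
      position = as.integer(pos),
      residue = substring(sequences[i], pos, pos)
    )
  })
  tibble::tibble(
    obs_id = as.character(seq_along(sequences)),
    sample_id = sample_id,
    sequence = sequences,
    modified_sequence = unname(mapply(paleopept::build_modified_sequence,
                                      sequences, mods)),
    modifications = mods,
    protein_accessions = proteins,
    intensity = intensity,
    score = score
  )
}

# independent hand computation of the intensity-weighted deamidation %
oracle_weighted_pct <- function(deam, total, intensity) {
  num <- 0
  den <- 0
  for (i in seq_along(deam)) {
    if (is.na(intensity[i]) || total[i] == 0) next
    num <- num + intensity[i] * deam[i] / total[i]
    den <- den + intensity[i]
  }
  if (den == 0) return(NA_real_)
  100 * num / den
}

# independent scalar terminus classifier: straight-line restatement of the
# cleavage-chemistry rules, no shared code with classify_termini()
oracle_classify <- function(protein, start, end, met_excision = TRUE) {
  n <- nchar(protein)
  at <- function(i) substr(protein, i, i)
  residue_rule <- function(res) {
    if (res == "K" || res == "R") return("tryptic")
    if (res == "Y" || res == "W" || res == "F") return("aspecific_YWF")
    if (res == "N" || res == "D" || res == "Q" || res == "E") return("diagenetic_NDQE")
    "nonspecific_other"
  }
  nterm <- if (start == 1) {
    "protein_terminus"
  } else if (met_excision && start == 2 && at(1) == "M") {
    "protein_terminus"
  } else {
    residue_rule(at(start - 1))
  }
  cterm <- if (end == n) "protein_terminus" else residue_rule(at(end))
  missed <- 0
  if (end > start) {
    for (i in start:(end - 1)) {
      if (at(i) == "K" || at(i) == "R") missed <- missed + 1
    }
  }
  is_tryp <- function(x) x == "tryptic" || x == "protein_terminus"
  k <- is_tryp(nterm) + is_tryp(cterm)
  spec <- if (k == 2) "full_tryptic" else if (k == 1) "semi_tryptic" else "non_specific"
  list(
    nterm_class = nterm, cterm_class = cterm, missed_cleavages = missed,
    specificity = spec,
    diagenetic = nterm == "diagenetic_NDQE" || cterm == "diagenetic_NDQE"
  )
}

# vectorised version of the oracle over every substring of one protein,
# built from residue lookups only (independent of classify_termini)
oracle_classify_all_substrings <- function(protein, max_len = Inf) {
  n <- nchar(protein)
  chars <- strsplit(protein, "")[[1]]
  rule <- ifelse(chars %in% c("K", "R"), "tryptic",
          ifelse(chars %in% c("Y", "W", "F"), "aspecific_YWF",
          ifelse(chars %in% c("N", "D", "Q", "E"), "diagenetic_NDQE",
                 "nonspecific_other")))
  starts <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  ends <- unlist(lapply(seq_len(n), function(s) s:n))
  keep <- ends - starts + 1L <= max_len
  starts <- starts[keep]; ends <- ends[keep]
  nterm <- ifelse(starts == 1L | (starts == 2L & chars[1] == "M"),
                  "protein_terminus", rule[pmax(starts - 1L, 1L)])
  cterm <- ifelse(ends == n, "protein_terminus", rule[ends])
  kr <- cumsum(chars %in% c("K", "R"))
  missed <- (kr[pmax(ends - 1L, 1L)] - c(0, kr)[starts]) * (ends > starts)
  is_t <- function(x) x %in% c("tryptic", "protein_terminus")
  k <- is_t(nterm) + is_t(cterm)
  tibble::tibble(
    start = starts, end = ends,
    nterm_class = nterm, cterm_class = cterm,
    missed_cleavages = as.integer(missed),
    specificity = c("non_specific", "semi_tryptic", "full_tryptic")[k + 1L],
    diagenetic = nterm == "diagenetic_NDQE" | cterm == "diagenetic_NDQE"
  )
}

random_protein <- function(len) {
  paste0("M", paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                           len - 1L, replace = TRUE), collapse = ""))
}

toy_proteome_path <- function() {
  system.file("extdata", "toy_proteome_synthetic.fasta", package = "paleopept")
}
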