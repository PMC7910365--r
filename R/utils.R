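# Residue alphabets and cleavage chemistry shared across modules.
# I and L are kept distinct throughout: evidence sequences are engine output.

AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_ALLOWED <- c(AA_STANDARD, "X")

# trypsin cleaves C-terminal to K/R; aspecific enzymatic cleavage is most
# often seen after Y/W/F; spontaneous (diagenetic) backbone cleavage occurs
# at the carboxyl side of N/D/Q/E
TRYPTIC_RESIDUES <- c("K", "R")
ASPECIFIC_RESIDUES <- c("Y", "W", "F")
DIAGENETIC_RESIDUES <- c("N", "D", "Q", "E")

TERMINUS_CLASSES <- c(
  "tryptic", "protein_terminus", "aspecific_YWF",
  "diagenetic_NDQE", "nonspecific_other"
)
SPECIFICITY_LEVELS <- c("full_tryptic", "semi_tryptic", "non_specific")
PEPTIDE_CLASSES <- c("food", "contaminant", "ambiguous", "unknown")

# inline modification tokens of the MaxQuant modified-sequence dialect
MOD_TOKEN_MAP <- c(
  de = "deamidation",
  ox = "oxidation_M",
  gl = "pyro_glu",
  hy = "hydroxyproline",
  ky = "kynurenine",
  cl = "carbonylation",
  cm = "carbamidomethyl"
)

MOD_DISPLAY_NAMES <- c(
  deamidation = "Deamidation (NQ)",
  oxidation_M = "Oxidation (M)",
  pyro_glu = "Gln->pyro-Glu",
  hydroxyproline = "Hydroxyproline",
  kynurenine = "Kynurenine",
  carbonylation = "Carbonylation",
  carbamidomethyl = "Carbamidomethyl (C)"
)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_valid_sequence <- function(x) {
  grepl(paste0("^[", paste(AA_ALLOWED, collapse = ""), "]+$"), x)
}

assert_sequence <- function(x, what = "sequence") {
  bad <- !is_valid_sequence(x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains letters outside the amino-acid alphabet: %s",
      what, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

# all (overlapping) start positions of `pattern` within `subject`;
# both are plain amino-acid strings so no regex metacharacters occur
overlapping_matches <- function(subject, pattern) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

empty_modifications <- function() {
  tibble::tibble(
    mod_type = character(0),
    position = integer(0),
    residue = character(0)
  )
}
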