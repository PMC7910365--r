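---
title: "Authenticating ancient food peptides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating ancient food peptides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleopept)
```

## The problem

Shotgun proteomics of organic residues absorbed by archaeological pottery
recovers a mixture of peptides: some derive from the foods the vessel once
held, many more from modern handling (keratins and other human
skin-derived proteins deposited during excavation, storage and sampling).
Because the identification engines cannot distinguish provenance, the
analysis must authenticate: decide, after identification, which peptide
classes look ancient and which look modern.

`paleopept` implements the two damage-based lines of evidence used for
this decision, plus the supporting identification bookkeeping:

1. **Deamidation of Asn and Gln.** Asparagine and glutamine deamidate
   spontaneously over archaeological time (N faster than Q), so ancient
   peptides accumulate deamidation while modern contaminants show little
   to none.
2. **Non-enzymatic backbone cleavage.** Diagenesis cleaves the peptide
   backbone at the carboxyl side of N, D, Q and E. Peptides whose termini
   arise from such cuts, rather than from trypsin (after K/R) or the
   common aspecific tryptic activity (after Y/W/F), indicate degraded,
   i.e. old, protein.

Both signals are contrasted between a *food* class and a *contaminant*
class of peptides, assigned from the taxa of the mapped proteins.

## The deamidation statistic

For one sample, one class and one residue type (N or Q), each evidence
row $i$ contributes its deamidated fraction $d_i / r_i$ (deamidated over
total residues of that type in the peptide), weighted by the row's MS
intensity $I_i$:

$$
\widehat{p} \;=\; 100 \cdot
\frac{\sum_i I_i \, d_i / r_i}{\sum_i I_i},
$$

summing over rows that contain the residue and carry an intensity.
Peptides without the residue contribute to neither numerator nor
denominator — the fraction is undefined for them — and rows with missing
intensity are excluded from this statistic (but retained for counting).
When no row is eligible the statistic is reported as undefined (`NA`),
which is deliberately distinct from an observed 0 %.

Design choices, each recorded in the report parameters:

- **Resampling unit.** The bootstrap resamples *evidence rows*, not
  unique peptide sequences: each row keeps its own intensity, and no
  aggregation across charge states or repeated observations is
  performed. `estimate_deamidation()` exposes the grouping; row-level
  weighting is the default throughout.
- **Uncertainty.** `bootstrap_deamidation()` draws `n_iter = 1000`
  resamples of size $n$ (the number of eligible rows) with replacement
  and reports the bootstrap mean, SD, and the percentile 2.5th/97.5th
  bounds as a 95 % interval. The percentile method is the convention for
  this statistic; no bias correction is applied. The seed is an explicit
  argument (default 0) and lands in the report for provenance.
- **N and Q are independent statistics.** Removing all Q-containing
  peptides cannot change the N estimate, and vice versa.

The statistic is invariant to rescaling all intensities, bounded in
$[0, 100]$, and equals 0 exactly when no eligible row carries a
deamidation event. These properties, and agreement with a brute-force
re-computation on enumerated tables, are enforced by the test suite.

### Sampling variability

Intensity weighting costs precision: with log-normal intensities of
$\sigma = 1$ (natural log), the effective sample size is roughly
$n / (1 + \mathrm{CV}^2) \approx n / 2.7$. At 500 evidence rows of which
roughly half contain an N, the point estimate of a 30 % deamidation level
has a sampling SD near 4 percentage points (measured over replicate
synthetic datasets). The bootstrap interval reflects exactly this
spread — its ~95 % coverage of the generating probability is verified on
200 replicates — so downstream comparisons should lean on the interval,
not on the point estimate alone.

## Terminus classification

`classify_termini()` classifies a peptide located at `start..end` in its
protein:

- N-terminus from the residue *preceding* the peptide, C-terminus from
  the peptide's *own last* residue (in both cases, the residue whose
  carboxyl side was cut): K/R → `tryptic`, Y/W/F → `aspecific_YWF`,
  N/D/Q/E → `diagenetic_NDQE`, anything else → `nonspecific_other`.
  The residue sets are disjoint, so no precedence question arises among
  them.
- The protein's own ends are `protein_terminus`, and this takes
  precedence over the residue rules (a protein that happens to end in K
  was not cleaved there). `start = 2` behind an initiator methionine
  also counts as a protein terminus by default (`met_excision = TRUE`),
  since N-terminal Met excision is routine biological processing.
- `full_tryptic` requires both termini tryptic-or-protein-terminus,
  `semi_tryptic` exactly one, `non_specific` neither.
- A peptide is **diagenetic** when at least one terminus is
  `diagenetic_NDQE`. Requiring both termini would be the stricter
  alternative; one non-enzymatic cut already implies backbone damage, so
  "at least one" is the default and the rule is recorded in the report.
  A fully tryptic peptide is never diagenetic: the terminus class is
  evaluated on the cleavage residue only, not on residues adjacent to a
  legitimate tryptic cut.
- The K/R–P suppression rule (`proline_rule`) is **off** by default;
  search engines disagree on it, and the flag is part of the report
  parameters so a run's convention is always visible.

`classify_observations()` binds evidence rows to these rules: every
occurrence of the peptide in every declared protein is classified, the
most specific verdict wins (ties: lexicographically first accession,
then earliest locus), and disagreement between proteins sets an
ambiguity flag. When the database lacks the protein entirely, the
evidence table's preceding/following context residues are used if
present; otherwise the row is marked unmappable and excluded from
specificity statistics.

## Protein inference, coverage and the validity filter

Peptides are mapped to every database protein containing them as an
exact substring (`map_peptides()`; declared accessions that fail the
substring check are surfaced as discrepancies). Proteins supported by
*identical* peptide sets are indistinguishable and merge into one
parsimony group; if the members span taxa the group is a multispecies
identification. Only the identical-set merge is performed — full
minimal-set (Occam) inference is deliberately out of scope — but a group
whose peptides form a strict subset of another's is annotated
`subsumable_under` so a reader can discount it.

Coverage is the percentage of residues covered by the union of located
peptides (overlaps count once). Unique peptides are distinct sequences
mapping to no protein outside the group; modification variants of one
sequence count once by construction, since mapping is sequence-level.

The validity filter accepts a protein/group when

- engine protein score ≥ 50 %,
- sequence coverage **strictly** above 5 %, and
- at least 2 unique peptides with individual scores ≥ 50 %.

The mixed wording conventions around these thresholds ("a minimum of",
"above") force a choice at the boundaries: score rules are read as
inclusive (≥), the coverage rule as exclusive (>). The choice is
recorded in the report parameters rather than asserted as universal.
Protein scores are engine quantities this package does not recompute;
when none are supplied, a protein is summarised by the maximum score of
its supporting peptides, and the report says so.

## Class assignment and the authentication contrast

Taxa are classified by configuration (`class_config()`): food taxa
default to the genera Triticum, Hordeum, Secale, Oryza, Bos, Bubalus and
Ovis; contamination defaults to *Homo sapiens*, and c-RAP-style
contaminant accessions are always contaminant regardless of taxon.
A peptide mapping to both classes is `ambiguous` and excluded from the
contrasts, with a logged count; a peptide mapping to no classifiable
protein is `unknown`.

Non-enzymatic cleavage fractions are computed over **distinct peptide
sequences** per class (the convention in which degraded-peptide tallies
are reported), with row-level counting available as a toggle. The fold
ratio divides the food deamidation percentage by the contaminant one;
a zero contaminant level makes the ratio undefined (reported as "food
level exceeds any finite fold", not as infinity).

`flag_variant_sites()` covers a subtle failure mode of taxonomic
assignment: a position where taxa differ by D versus N (or E versus Q)
stops discriminating once deamidation enters, because a deamidated N is
chemically D. Sites come from a user-supplied table; the bundled example
(`variant_sites_example()`) reconstructs the classic β-lactoglobulin
D-vs-N case on synthetic sequences (labelled as such — the coordinates
are not the real proteins').

## The synthetic data generator

`simulate_evidence()` produces evidence tables with the statistical
structure the analysis assumes, so every stage is testable without any
raw MS data:

- Proteins are random sequences with realistic tryptic site density
  (K+R ≈ 10 %) and amide density (N+Q ≈ 8 %), each guaranteed a fully
  tryptic peptide of length ≥ 7.
- Peptides are drawn from the in-silico digest (length 7–40, up to 3
  missed cleavages). With the class's `diagenetic_rate` one terminus is
  replaced by a cut after an internal N/D/Q/E; otherwise with
  `aspecific_rate` by a cut after Y/W/F; impossible cuts fall back to
  tryptic and are recorded in the ground truth.
- Each N deamidates independently with `p_deam_N`, each Q with
  `p_deam_Q`. No positional kinetics are modelled, because the analysis
  treats residues exchangeably. Intensity is log-normal
  (`meanlog = 13`, `sdlog = 1`, i.e. a realistic order-of-magnitude
  spread) and independent of deamidation status; scores are uniform in
  50–100.
- The presets encode the study conditions the analysis targets:
  `food_fig3` uses the midpoints of deamidation ranges typical of
  ancient food peptides (N 28 %, Q 13 %) with a 10 % diagenetic terminus
  rate; `contaminant_fig3` the near-modern contaminant levels (N 2 %,
  Q 1.5 %) with a 2 % rate.

Every evidence row joins exactly one ground-truth row, the generated
tables re-parse through `read_evidence()` without warnings, and the
estimator recovers the generating probabilities without bias as the
evidence grows — all enforced by tests.

What the generator does **not** emulate: spectrum-level effects
(retention time, mass error, co-elution), charge-state splitting of one
peptide across rows, correlated deamidation along a sequence, homologous
sequence families, or intensity–damage correlation (an optional knob
would be the natural extension). Passing tests on synthetic data
therefore demonstrate the statistical machinery, not the behaviour of
any particular archaeological matrix.

### A note on distinct-peptide fractions

The generator's `diagenetic_rate` is a per-draw (per evidence row)
probability, while the reported cleavage fraction counts distinct
peptide sequences. Tryptic fragments recur across draws and collapse
under deduplication; randomly cut diagenetic peptides rarely recur. The
distinct-peptide fraction therefore runs somewhat above the per-row
rate (e.g. ≈ 14 % at a 10 % rate under the default preset), which is a
property of the counting unit, not a bias in the classifier.

## Numerical and degenerate-input conventions

- All peptide positions are 1-based; protein coordinates are 1-based
  inclusive. I and L are distinct letters everywhere (evidence
  sequences are engine output; no equivalence folding).
- Unknown modification tokens are an error, never skipped: silently
  dropping a deamidation token would bias the statistic. Evidence rows
  below the score threshold (default 40) are dropped with a logged
  count.
- Undefined statistics (no eligible rows, empty class, zero contaminant
  level) are `NA` with an explanatory signal — never silently 0.
- Reports are written with fixed column order and 4 significant digits,
  without timestamps, so identical runs produce byte-identical files.
- Bootstrap and generator draws are reproducible from explicit integer
  seeds; the generator derives one internal stream per stage so that
  proteome and evidence are jointly reproducible from the master seed.

## Problem sizes used in the test suite

The packaged checks run at desk scale by design: enumerated toy tables
(≤ 6 rows) against brute-force recomputation; terminus classification
against an independent substring classifier on 100 random proteins of
length ≤ 200 (every substring); bootstrap calibration on 200 replicate
datasets of 500 observations; parameter recovery at 500 peptides per
class; and an end-to-end determinism check on the bundled 200-row
synthetic fixture. The headline per-sample numbers of real surveys
derive from raw spectral data and engine searches, which are outside
this package's scope; the bundled published-style identification table
exercises only the validity filter.
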