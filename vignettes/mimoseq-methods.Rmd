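---
title: "mimoseq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mimoseq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimoseq)
```

This vignette is the package's own account of the science it implements: the
models behind each stage, the tunable parameters with their defaults and the
reasoning that fixed them, what the synthetic-data generators do and do not
emulate, and the numerical conventions. The README shows the worked example;
here we explain why the pieces look the way they do.

## 1. The repertoire pipeline

### Amplicon model

The single-cell protocol modelled here sorts one activated T cell per well of
a barcoded plate and amplifies both TCR chains by nested RT-PCR, appending
four DNA barcodes — group, plate, column, row — plus sequencing adapters. A
merged read is therefore

```
[group][plate][column][row]  V-region ... CDR3 junction ... J-region  C-region
```

with the four barcode fields at fixed offsets. The pipeline mirrors the
stages a practitioner would chain from FLASH, MIGEC and HighV-Quest, but as
small auditable functions:

1. **`merge_pairs`** — overlap assembly of R1/R2. The best candidate overlap
   is the one with the most matching bases among those of length at least
   `min_overlap` (default 10 nt) and mismatch fraction at most
   `max_mismatch_frac` (default 0.25). An exact tie between two candidate
   overlaps is reported `"ambiguous"` rather than guessed. Disagreeing bases
   take the higher-quality call, ties going to R1 (the typically
   higher-quality mate).
2. **`demultiplex`** — per-field Hamming matching with the *unique-best*
   rule: a read is assigned only if, in every field, exactly one barcode
   achieves the minimal distance and that distance is at most `max_mismatch`
   (default 1). Equidistant best matches leave the read unassigned with
   reason `"ambiguous"`. Within each field barcodes must be pairwise at
   Hamming distance ≥ 2; the default 96-well scheme is generated at distance
   ≥ 3 so one tolerated mismatch can never be ambiguous.
3. **`assign_chain`** — α/β segregation by local alignment of the TRAC/TRBC
   constant-region fragments (match +1, mismatch −1, gap −2). A chain is
   called when its score exceeds 60% of the reference length *and* beats the
   other chain by a margin of 5; otherwise `"unknown"`. The margin guards
   against chimeric or truncated reads.
4. **`collapse_reads`** — frequency-ratio absorption in place of UMI
   consensus (the protocol has no UMIs): a unique sequence is absorbed into a
   higher-count sequence within `max_mm` substitutions when the higher count
   is at least `ratio_threshold` times its own. Defaults are
   `ratio_threshold = 5`, `max_mm = 2`. These were derived from the error
   model the generator plants: at a 1% per-base substitution rate on a
   ~110–160 nt amplicon only ~20–35% of reads are error-free, so the
   error-free mode carries on the order of 8–17 of 50 reads while individual
   1-error variants reach 2–3 and 2-error variants survive as singletons. A
   10:1 absorption ratio with a 1-mismatch radius (the obvious first guess)
   leaves those variants standing and turns a fifth of wells into spurious
   "multiplets"; 5:1 with a 2-mismatch radius absorbs them while still
   refusing to merge genuinely distinct chains, which differ by far more
   than 2 nt.
5. **`pair_well`** — exactly one α and one β consensus make a paired cell;
   when a chain has several consensuses the dominant one is kept if its
   support is at least `dominance_threshold` (default 5, same derivation as
   above) times the runner-up's, else the well is a multiplet and excluded.
6. **`annotate_vj` / `extract_cdr3`** — best-scoring local alignment of every
   germline V and J segment (same scoring as above), ties broken
   lexicographically by segment name so results are reproducible. The CDR3
   spans the conserved V-region cysteine codon through the J anchor codon,
   inclusive, translated in the V frame. Coordinates are 0-based half-open
   internally and 1-based inclusive in outputs. One subtlety: when the
   junction's last residues coincide with J-germline-templated residues
   (common — e.g. CDR3β ending `...EVFF` over a J contributing `...F`), the
   locally optimal alignment can slide a gap and absorb the anchor into the
   junction. The anchor is therefore located through the germline-stable
   G-x-G block that follows it, which does not wobble.
7. **`call_clonotypes`** — cells sharing identical paired CDR3s *and* V/J
   usage form a clonal lineage. The default compares amino-acid CDR3s with
   allele-stripped gene names, matching how such clone tables are reported;
   `level = "nt"` switches to nucleotide identity, which splits convergently
   recombined lineages (the source study's wording supports either reading,
   so both are provided and the choice is explicit in the API).

Degenerate inputs are handled conservatively: reads shorter than the barcode
prefix are counted unassigned with reason, unannotatable consensuses drop the
chain rather than fabricate a call, junctions with frame breaks or internal
stops keep their translation but are flagged non-productive.

### What the plate generator emulates — and what it does not

`plate_truth` + `simulate_tcr_plate` plant one cell per well (by default the
published 14-clone table, one nucleotide rearrangement per clone), prepend
the barcode prefix, apply i.i.d. substitutions at `error_rate` (default 1%)
and optional indels at `indel_rate` (default 0 — nested-PCR amplicons are
substitution-dominated, and indel reads fall out as filter rejects), then
split into overlapping 150 nt mates with constant Q30 qualities (the pipeline
never uses qualities beyond merge tie-breaking, so richer quality models
would be untested decoration). Depth defaults to 50 reads per chain per well;
the protocol's true depth is not published, and 50 is a realistic plate-MiSeq
budget at which the collapse statistics above hold.

Not modelled: PCR bias and chimeras, index hopping, cross-well contamination,
quality-dependent errors, and allele-level germline variation. The germline
reference itself is synthetic — random segments wearing IMGT-like names with
the structural invariants the pipeline relies on (in-frame conserved Cys in
every V; J anchor followed by G-x-G). Consequently, passing tests demonstrate
that the *pipeline logic* recovers planted truth under realistic noise, not
that annotation against the true murine germline is accurate; for real data a
user-supplied germline FASTA is read by `read_germline_fasta`. One deliberate
deviation from convention: the synthetic TRAJ7 carries a leucine at its
anchor position, because the public CDR3α junctions it must reconstruct end
in L — TRAJ7 is an ORF-annotated, non-canonical J gene, and the printed
junctions outrank the F/W convention.

## 2. Tetramer-fraction enrichment

Antigen-specific lineages are selected by the deterministic two-threshold
rule: at least `min_cells = 3` cells in the tetramer-positive fraction and a
frequency fold

$$\mathrm{fold} = \frac{n_\mathrm{pos}/N_\mathrm{pos}}
{(n_\mathrm{neg}+c)/(N_\mathrm{neg}+c)} \ge \texttt{min\_fold} = 5,$$

with additive pseudocount `c = 1` on the negative fraction so lineages absent
there remain finite (whether the original analysis used a pseudocount is not
stated; the raw fold, `Inf` when `n_neg = 0`, is reported alongside). The
cell-count rule is applied to the tetramer-positive fraction, the sorted
population under analysis. No significance test is attached — the rule is a
deterministic filter, and that is what is implemented and property-tested
against brute force.

`simulate_tetramer_fractions` models sorting as two multinomials: the
positive fraction samples clonotypes with weight `freq × capture_p` for
planted specific clonotypes (default 0.9) and `freq × leak_p` otherwise
(default 0.01), the negative fraction with the complementary weights. At the
study's sorted-cell scale (thousands per fraction) the filter recovers
planted expanded specific lineages with ≥ 95% sensitivity and ≈ 100%
specificity in the test suite.

## 3. NNK library design and selection analysis

`design_library("KSPWFTTL", c(1, 4, 6, 7), "NNK")` reproduces the
`XSPXFXXL` design: NNK (N = A/C/G/T, K = G/T) at the diversified positions —
32 codons covering all 20 amino acids with TAG as the only stop — and fixed
codons elsewhere. The fixed codons default to one common mouse codon per
residue (`TCT`, `CCG`, `TTT`, `CTG` for the template's S, P, F, L); the
original oligo sequence is not published, and the choice only affects the
printed oligo, not any downstream statistic. `diversity` reports the counting
identities `32^k` nucleotide variants, `20^k` stop-free peptides and a stop
fraction of `1 − (31/32)^k`.

Selection-round reads are merged, the peptide-coding insert is cut out
between two flanking anchors (unique best Hamming match within `max_mm`,
wrong-length inserts rejected), translated, and filtered: any stop codon or a
non-template residue at a fixed position rejects the read. Counts are exact
tallies (`tally_peptides`); an optional absorption folds singleton peptides
into a ≥ 10× more abundant 1-mismatch neighbour, standing in for the
clustering step of the original workflow whose identity threshold is not
stated. Default off, since exact tallies are the transparent choice.

The two Fig-5A-style summaries are:

* `preference_matrix` — read-count-weighted amino-acid frequency per
  position, `weight(p, a) = Σ count(peptides with a at p) / depth`; every
  position's weights sum to 1. Matrices are per round (what the heat maps
  show round-over-round); `pooled_preference_matrix` sums counts over rounds
  for a one-matrix campaign summary, since whether the published heat maps
  pool rounds is ambiguous.
* `enrichment_trajectory` / `rank_mimotopes` — per-peptide frequencies with
  pseudocount 1 over the union of observed peptides,
  fold changes between consecutive rounds, and the cumulative fold
  `freq_last/freq_first`; candidates sort by cumulative fold, then final
  frequency, then lexicographically, so rankings are total and reproducible.

### The selection simulator

`selection_truth` plants an additive binding-energy landscape over the
design's stop-free peptide space: by default
`energy(p) = penalty × (#diversified positions where p differs from the
planted binder)`, with the wild-type template as binder and `penalty = 2`
(unitless). Additivity is the simplest landscape that reproduces the
qualitative published outcome — per-position convergence (e.g. position 4 to
tryptophan) with residual flexibility at weakly constrained positions.

Selection acts on latent pool frequencies with Boltzmann reweighting,

$$f_t(p) \propto f_{t-1}(p)\, e^{-s\,E(p)},$$

and sequencing draws `depth_per_round` reads (default 10^5) multinomially
from each round's pool. Expected counts therefore follow the intuitive
count-resampling recursion `E[count_t] ∝ count_{t−1} e^{−sE}` and the
cumulative enrichment ratio between two peptides matches the closed form
`exp(s·ΔE·rounds)` (property-tested). Resampling *observed counts* instead
would lose every peptide unseen in round 0 forever — at 10^5 reads over the
160,000-peptide NNK space the best binder itself has ~0.5 probability of
zero round-0 reads — which is physically wrong: bead selection acts on the
yeast pool, not on the sequencer's sample of it. Round 0 frequencies are
proportional to each residue's degenerate-codon multiplicity, as a uniform
draw over codon space implies. The space is enumerated, so at most 5
diversified positions are supported (20^5 = 3.2M peptides); the study's
design uses 4.

## 4. Quantitative assay fits

* **`fit_one_site`** — Levenberg–Marquardt least squares of
  `R(C) = Rmax·C/(K_D + C)` with both parameters constrained positive;
  starting values `Rmax = max(R)` and `K_D =` the concentration nearest
  half-max, which on a dilution series spanning the K_D converges in a few
  iterations. Responses are normalised to Rmax *after* fitting (the original
  software's order is ambiguous; fit-then-normalise keeps the fit on raw
  residuals and is scale-equivariant, which the tests assert to 1e-9).
  Steady-state only — no kinetic k_on/k_off model, matching the study's
  analysis.
* **`fit_tm`** — default method is the smoothed-derivative rule: centred
  moving average of width 5, central-difference dF/dT evaluated at the grid
  points, T_m at the maximum. On the instrument's 1 °C grid this localises a
  planted midpoint to ±0.5 °C. A Boltzmann sigmoid fit is offered for
  low-noise curves; both methods agree within 0.5 °C on clean sigmoids. Flat
  or never-rising curves are errors, not numbers.
* **`rout_outliers`** — the univariate (constant-model) case of the ROUT
  procedure, which is how it is applied to cytokine-staining replicates:
  centre = median, robust scale = the 68.27th-percentile *order statistic*
  of absolute residuals scaled by `n/(n−1)`, two-sided t p-values
  (df = n−1), Benjamini–Hochberg at `q_percent`/100 over the ranked
  residuals. The order statistic (rather than an interpolated quantile) is
  deliberate: at small n interpolation lets one gross outlier drag the scale
  up enough to mask itself. Calibration on clean normal data (n = 20, 10^4
  replicates) holds the flag rate well under 2% at Q = 1% while a 10σ
  outlier is flagged in ≥ 99% of replicates.
* **`specific_killing`** — `100 × (1 − ratio_vaccinated/ratio_control)` for
  CFSE/CellTrace dye ratios, clipped to [0, 100] with a flag when clipping
  occurred (sampling noise can push the raw value outside).

## 5. Reproducibility conventions and test scale

Every generator is a pure function of its parameters and an integer seed
(RNG state is saved and restored around each call), so whole runs are
byte-reproducible; `run_repertoire`/`run_display` write a manifest recording
package version, seed, all parameters and a parameter fingerprint, and
deliberately no wall-clock time. Sorting rules everywhere (clonotypes by size
then key; candidates by fold, frequency, lexicographic; collapse survivors by
support then sequence) make outputs order-independent of their inputs.

The test suite exercises the pipeline at deliberately desk-sized scales
chosen to keep the full suite around a minute while leaving the statistics
decisive: 96-well plates at 50 reads/chain/well over 10 seeds for end-to-end
recovery (≥ 95% of wells must return exactly their planted clonotype),
10^5-read selection rounds for binder recovery, 10^4 replicates for ROUT
calibration, and 10^3 random tables for the enrichment-filter brute-force
property. Larger inputs change runtimes, not code paths.

## 6. Known limitations

* The germline reference is synthetic; gene *names* are meaningful only
  relative to it. Real-data annotation quality depends on the user-supplied
  germline and has no oracle here.
* V/J scoring parameters differ from the external annotator used in the
  original workflow (whose configuration is unpublished); only fixture-truth
  behaviour is verifiable.
* The selection energy model is additive; epistatic peptide landscapes (and
  the tyrosine tolerance one selection showed at position 4) are outside it.
* The tetramer model treats capture as a per-clonotype Bernoulli with a
  single leak rate; avidity effects and doublets are not modelled.
* ROUT is implemented for the univariate case only, as used here — not for
  regression residuals.
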