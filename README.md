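# mimoseq

Paired-chain TCR repertoire analysis and mimotope library selection for
public anti-tumor T cell responses.

## The problem

Combination immunotherapy of poorly immunogenic tumors (e.g. B16F10 murine
melanoma under antibody + IL-2 + anti-PD-1 "AIP" therapy) expands
tumor-infiltrating CD8+ T cell clones whose antigen is usually unknown.
Plate-based single-cell TCR sequencing of sorted, activated TILs can reveal
*public* TCRs — near-identical paired α/β receptors recurring within and
across animals, formed by convergent recombination — that point at a shared
antigen. In the study this package models, those clones converge on two
TRAJ7-derived CDR3α junctions (CAAK/CAASDYSNNRLTL) and recognise p15E
(KSPWFTTL), an H-2K^b^-restricted endogenous-retrovirus peptide. Because
vaccination against a self-like ERV antigen is blunted by tolerance, the
follow-up step is engineering *mimotopes*: the putative TCR-contact positions
of the peptide (1, 4, 6, 7) are diversified with NNK codons on a yeast-display
pMHC library (template `XSPXFXXL`), selected against recombinant TCRs, and
deep-sequenced round-over-round to map positional amino-acid preferences and
rank candidate peptides.

`mimoseq` reimplements that computational pipeline end to end, as a tested R
package driven by seeded synthetic-data generators with planted ground truth:

* **Repertoire** — demultiplexing of group/plate/column/row barcoded
  paired-end amplicons, constant-region α/β segregation, frequency-ratio read
  collapse, V/J annotation by local alignment, CDR3 extraction (conserved Cys
  through the J anchor), pairing, clonotype calling, contamination flags,
  clonality summaries (`demultiplex`, `assign_chain`, `collapse_reads`,
  `annotate_vj`, `extract_cdr3`, `pair_well`, `call_clonotypes`, `clonality`).
* **Motif analytics** — CDR3 motif counts, shared-CDR3 grouping, gene usage,
  convergent-recombination index (`count_motif`, `group_shared_cdr3`,
  `gene_usage`, `convergence_index`).
* **Tetramer enrichment** — the "≥ 3 cells and ≥ 5-fold enriched in the
  tetramer-positive fraction" lineage filter
  (`fraction_frequencies`, `select_enriched`, `motif_share`).
* **Yeast display** — NNK library design and diversity accounting, read-pair
  merging, peptide-region extraction, translate-and-filter, count tables,
  read-count-weighted position-preference matrices (the Fig-5A-style heat
  maps) and enrichment-trajectory candidate ranking (`design_library`,
  `codon_table`, `diversity`, `merge_pairs`, `extract_region`,
  `translate_filter`, `tally_peptides`, `preference_matrix`,
  `enrichment_trajectory`, `rank_mimotopes`).
* **Assay fits** — steady-state one-site binding
  `R(C) = Rmax·C/(K_D + C)` for SPR affinities, thermal-melt midpoints
  (derivative and Boltzmann), univariate ROUT outlier flags at FDR Q, and the
  in-vivo specific-killing percentage (`fit_one_site`, `fit_tm`,
  `rout_outliers`, `specific_killing`).
* **Simulators** — every input above can be generated with planted truth:
  `generate_germline_reference`, `plate_truth` + `simulate_tcr_plate`,
  `selection_truth` + `simulate_selection_campaign`,
  `simulate_tetramer_fractions`, `simulate_binding_curve`,
  `simulate_melt_curve`. The published 14-clone table ships as
  `aip_clone_table()` and is the default plant for plate simulations.
* **Orchestration** — `run_repertoire()` / `run_display()` run whole stages
  from a JSON `run_config()` with a machine-readable manifest; a thin CLI
  wrapper lives at `inst/cli/mimoseq.R`.

## Worked example

```r
library(mimoseq)

# 1. synthetic germline + 96-well plate planted with the published clone table
ref    <- generate_germline_reference(n_per_kind = 4, seed = 1)
scheme <- default_barcode_scheme()
truth  <- plate_truth(ref, scheme, clones = aip_clone_table(),
                      error_rate = 0.01, depth = 50, seed = 42)
plate  <- simulate_tcr_plate(truth)

# 2. merge pairs, demultiplex, collapse, pair, annotate, call clonotypes
merged <- merge_pairs(plate$reads$r1, plate$reads$r2,
                      plate$reads$q1, plate$reads$q2)
res <- process_plate_reads(merged$merged[merged$status == "merged"],
                           scheme, ref)
clonotypes <- call_clonotypes(res$cells)
head(clonotypes[, c("clonotype_id", "cdr3_alpha_aa", "cdr3_beta_aa",
                    "v_alpha", "j_alpha", "v_beta", "size")], 5)
#>   clonotype_id cdr3_alpha_aa   cdr3_beta_aa v_alpha j_alpha v_beta size
#> 1        CT001 CAAKDYSNNRLTL   CASSPPGDTQYF TRAV7-2   TRAJ7  TRBV3   26
#> 2        CT002 CAAKDYSNNRLTL  CASSPPGGSEVFF  TRAV10   TRAJ7  TRBV5   22
#> 3        CT003 CAAKDYSNNRLTL CASSPPGSQNTLYF  TRAV10   TRAJ7  TRBV5   12
#> 4        CT004 CAASDYSNNRLTL CASSLELGGREQYF TRAV7-2   TRAJ7 TRBV16    9
#> 5        CT005 CAAKDYSNNRLTL CASSPPGQNTEVFF TRAV10D   TRAJ7  TRBV4    6

clonality(clonotypes, k = 3)
#> 90 cells in 14 clonotypes; top-3 clones hold 66.7% of cells
count_motif(clonotypes$cdr3_beta_aa, "PPG")
#> Motif PPG: 6 of 14 sequences
gene_usage(clonotypes, "TRAJ")
#> TRAJ usage (by_clone):
#>    gene count fraction
#> 1 TRAJ7    14        1
```

The simulated sequencing run is recovered exactly: 14 clonal lineages with
the printed clone sizes (largest 26), the PPG motif in 6 of 14 CDR3β, and
every lineage on TRAJ7.

```r
# 3. NNK mimotope library and a simulated 3-round selection
design <- design_library("KSPWFTTL", c(1, 4, 6, 7), "NNK")
design
#> Library XSPXFXXL (NNK at 1,4,6,7)
#> oligo: NNKTCTCCGNNKTTTNNKNNKCTG
tr   <- selection_truth(design, stringency = 1, depth_per_round = 1e5,
                        n_rounds = 3, seed = 20)
tabs <- simulate_selection_campaign(tr)
round(preference_matrix(tabs[[4]], design)[4, c("W", "Y", "F", "L")], 3)
#>     W     Y     F     L
#> 0.931 0.002 0.002 0.007
head(rank_mimotopes(enrichment_trajectory(tabs, pseudocount = 1))[, 1:4], 3)
#>   rank  peptide final_round_frequency cumulative_fold_enrichment
#> 1    1 KSPWFTTL           0.441878023                      80770
#> 2    2 KSPSFTTL           0.003178546                        581
#> 3    3 RSPWFTTL           0.003058188                        559
```

Position 4 converges to the wild-type tryptophan (weight 0.93 in the final
round) and the planted binder tops the candidate ranking.

```r
# 4. steady-state affinity fit on the SPR dilution series (0.35-266 uM)
curve <- simulate_binding_curve(kd = 26, rmax = 100,
                                concs = unique(c(0.35 * 2^(0:9), 266)))
fit_one_site(curve)
#> One-site specific binding fit: KD = 26 uM, Rmax = 100 RU (residual norm 1.59e-14)
```

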