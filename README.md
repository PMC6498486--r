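# bloodshift

Rupture of an intracranial aneurysm (IA) triggers a systemic response that
is readable in the peripheral-blood transcriptome: lymphocyte programs are
depressed, myeloid/inflammatory programs are activated, and part of every
bulk expression change is just arithmetic — blood is a cell mixture, so a
shift in leukocyte counts moves transcript abundances even when no cell
changes its transcription. `bloodshift` packages the analysis of that
response for a three-group cohort design — acute-phase patients (**RAA**,
first 72 h after rupture), chronic-phase patients (**RAC**, 3–15 months)
and controls (**C**) — together with a ground-truth cell-mixture simulator
so every statistic can be validated by planted-parameter recovery.

## What it computes

* **Quantification** — FPKM from fragment counts,
  `FPKM = count / (L_exon/10^3 · N/10^6)`, detection (mean FPKM ≥ 0.1) and
  basal-expression (mean FPKM > 0.5) filters, and the `log2(1 + x)`
  transform used for testing.
* **Differential screening** — per-transcript one-way ANOVA on the
  clinical-status factor with Benjamini–Hochberg FDR (gate `q < 10^-5`),
  pairwise linear fold changes with a pseudocount, hierarchical clustering
  of significant transcripts (distance `1 − r`, average linkage, `k = 2`)
  into a down-regulated pattern **A** and an up-regulated pattern **B**, and
  a Spearman time-course screen (`|R| > 0.7`, `p < 0.01`) of chronic-phase
  samples against months since the bleed.
* **L/MN index** — per sample, the ratio of mean standardized-fold
  expression of a lymphocyte gene set (*BCL11B, CCR7, CD2, CD27, CD3D,
  CD3E, CD8A, KLRB1*) to a monocyte-and-neutrophil set (*ANXA3, ARG1,
  CD14, GYG1, FCGR1A, FCGR2A, IRAK3, MMP9*), compared between groups with
  Welch t-tests. Low values read as lymphocyte depression with myeloid
  activation.
* **Transcript structure** — biotype composition profiles
  (protein-coding / retained-intron / processed-transcript / …) of
  regulated vs basal transcript sets, and a per-gene exon/intron ratio
  score `(Σ exonic + 1)/(Σ intronic + 1)` whose depression flags a larger
  unspliced pre-mRNA fraction; up vs down sets compared by Mann–Whitney U.
* **Attribution** — for a cell population, compares the flow-cytometry
  count fold with the geometric-mean expression fold of its marker
  transcripts: `discordance = |log2(fold_expr) − log2(fold_count)|`,
  verdict `composition_driven` (≤ 0.5 log2 units), `actively_regulated`
  (expression overshoots the count change in the same direction) or
  `indeterminate`.
* **Simulator** — transcript annotation with biotypes and exon/intron
  lengths, per-cell-type signatures with ≥10× marker specificity, Dirichlet
  per-sample cell proportions, gamma-noised absolute cell counts,
  negative-binomial bulk counts (mixture of signatures × count multipliers ×
  regulation multipliers, renormalized to constant library size) and a
  binomial exonic/intronic read split — all with closed-form expected folds
  in the returned truth object.

## Worked example

```r
library(bloodshift)

sim  <- simulate_scenario(seed = 7)   # 2000 transcripts, n = 19/20/20
fpkm <- compute_fpkm(sim$cohort$exonic, sim$annotation)

lmn_index(fpkm, sim$genesets)
#> L/MN index:
#>  group  n     mean         sd
#>      C 20 1.694974 0.30650662
#>    RAA 19 0.498580 0.09497118
#>    RAC 20 1.619129 0.42187786
#>  group_a group_b          t       df            p
#>      RAA     RAC -11.573752 21.01801 1.399650e-10
#>      RAA       C -16.635801 22.78866 3.067917e-14
#>      RAC       C  -0.650446 34.68730 5.196895e-01
```

The acute group's index collapses (0.50 vs 1.69 in controls, Welch
p ≈ 3e-14) while the chronic group is indistinguishable from controls —
the planted lymphopenia-plus-myeloid-activation signature, recovered.

```r
cc <- sim$cohort$cellcounts
attribute(count_fold(cc, "cd4", "RAA", "C"),
          marker_fold(fpkm, sim$marker_sets$CD4, "RAA", "C"),
          population = "CD4")
#> CD4: count fold 0.680, expression fold 0.678, discordance 0.005 log2 -> composition_driven
attribute(count_fold(cc, "monocytes", "RAA", "C"),
          marker_fold(fpkm, sim$marker_sets$MN, "RAA", "C"),
          population = "monocytes")
#> monocytes: count fold 1.114, expression fold 2.597, discordance 1.221 log2 -> actively_regulated
```

CD4 marker expression falls exactly as far as the CD4 count (a
composition effect), while monocyte marker expression rises far beyond the
monocyte count (active per-cell regulation) — the two planted attribution
regimes.

```r
raa <- which(sim$cohort$exonic$samples$group == "RAA")
exon_intron_score(sim$cohort$exonic, sim$cohort$intronic,
                  sim$up_set, sim$down_set, samples = raa)
#> exon/intron ratio score: median up = 9.087 , median down = 1.48 , Mann-Whitney p = 1.44e-14
```

The full pipeline (simulate → quantify → DE → L/MN → structure →
attribution, with TSV/JSON outputs and a checksummed run manifest) runs as

```sh
Rscript inst/cli/bloodshift.R all --seed 7 --outdir out/
```

or from R via `run_pipeline(default_run_config(seed = 7))`.

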