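---
title: "Models and design decisions in bloodshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in bloodshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodshift)
```

# The problem

Peripheral blood is a mixture of leukocyte populations, each with its own
transcriptional program. After an intracranial aneurysm ruptures, two
things happen at once: the composition of the mixture shifts (lymphopenia,
monocytosis) and individual cell types change their per-cell
transcription. A bulk RNA-seq measurement confounds the two. `bloodshift`
implements the analyses that characterize this response in a three-group
design — acute (RAA, ≤72 h), chronic (RAC, 3–15 months) and control (C) —
and, crucially, a generative model of the confounding itself, so that each
analysis can be validated by recovering parameters we planted.

# The cell-mixture model

The simulator is the package's reference model of how a bulk blood
transcriptome arises.

**Signatures.** Each transcript $t$ has a baseline expression
$B_{tc} \ge 0$ per cell type $c$ (log-normal across transcripts,
$\log \mathcal{N}(\log 5, 1.2)$ in arbitrary per-cell units). A transcript
planted as a *marker* of $c$ is forced to
$B_{tc} \ge s \cdot \max_{c' \ne c} B_{tc'}$ with specificity factor
$s = 10$ by default. Tissue atlases report "enriched" transcripts without a
numeric cutoff; a tenfold floor makes markers informative but not
perfectly pure, which is the realistic regime for attribution analyses.

**Cell counts and proportions.** Sample $i$ in group $g$ draws an absolute
count for cell type $c$ from a gamma distribution with mean
$W \, \pi_c \, m_{gc}$ (control WBC $W = 7000$ cells/µL, baseline
proportions $\pi$ neutrophil-dominated as in adult blood, count
multipliers $m_{gc} > 0$ with $m_{Cc} \equiv 1$) and shape
$\kappa \pi_c m_{gc}$, concentration $\kappa = 200$. Normalizing the
gamma draws makes the per-sample proportions Dirichlet around the group
means, so flow-cytometry-like noise (CV ≈ 18% for a 15% population at
$\kappa = 200$) is built in, and expected count folds equal the
multipliers exactly.

**Bulk expression.** The expected bulk abundance is the mixture

$$\mu_{ti} \;=\; N \cdot
  \frac{\sum_c p_{ci}\, B_{tc}\, r_{gct}}
       {\sum_{t'} \sum_c p_{ci}\, B_{t'c}\, r_{gct'}},$$

where $p_{ci}$ are the realized proportions, $r_{gct} > 0$ are per-cell
regulation multipliers ($r_{Cct} \equiv 1$) and $N$ is the library size
(default $10^6$ fragments). The renormalization to constant expected
library size mirrors the compositional nature of sequencing; its visible
consequence is that marker folds are *smaller* than the raw multipliers
(a 1/1.5 CD4 count drop appears as a ≈0.70 expression fold, because
removing CD4 RNA re-inflates everything else). `expected_folds()` returns
these closed-form group folds, which is what recovery tests compare
against.

**Noise and the exon/intron split.** Realized totals are negative binomial
with common dispersion $\phi = 0.1$ (variance $\mu + \phi\mu^2$), the
standard overdispersed choice for RNA-seq counts; $\phi = 0$ selects the
Poisson limit. Each transcript's total is then split binomially into
intronic reads with its pre-mRNA fraction $f_{tg} \in [0, 1)$ (baseline
0.1) and exonic reads as the remainder, so exonic + intronic reproduces
the total exactly. Per-cell RNA yield is treated as equal across cell
types; a `rna_yield` argument exposes this assumption.

**The canonical scenario.** `default_paper_scenario()` plants the acute
response: CD4 count ×(1/1.5), CD8 ×(1/1.3), classical and intermediate
monocytes ×1.3; per-cell upregulation ×2.5 of the MN gene-set transcripts
across the myeloid compartment; 40 broadly downregulated transcripts
(×0.5 everywhere, pre-mRNA fraction raised to 0.4 in RAA) and 40
upregulated (×2.0), both drawn with a 2.6:1 preference for protein-coding
biotypes; RAC multipliers identically 1, so the chronic group is a second
null. The regulated-block sizes (40 + 40 among 2000 transcripts) keep the
default cohort at desk scale while leaving the ANOVA screen a clear
signal.

## What the generator does and does not emulate

It emulates: three-group cohort structure (n = 19/20/20), compositional
count noise, overdispersed sequencing noise, marker specificity,
biotype mixtures (default: 50.2% protein-coding, 21.7% retained-intron,
12% processed-transcript, remainder lincRNA/antisense/other), pre-mRNA
read fractions, and months-since-event metadata for the chronic group.

It does not emulate: read-level artifacts (GC, mappability, positional
bias), isoform structure beyond a single transcript per gene, correlated
regulation programs across transcripts, batch effects, globin/granule RNA
degradation, or inter-individual baseline heterogeneity beyond
compositional noise. Passing recovery tests therefore demonstrates that
the statistics are implemented correctly and are sensitive at realistic
noise levels — not that they are robust to every artifact of real cohort
data.

# Analysis stages and their tunables

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| detection threshold | 0.1 (mean, ≥) | FPKM | detection floor |
| basal threshold | 0.5 (mean, >) | FPKM | basal-expression set |
| ANOVA FDR gate | $10^{-5}$ | q | genome-wide stringency |
| fold pseudocount | 0.1 | FPKM | stabilizes low-expression ratios |
| cluster count $k$ | 2 | — | down (A) / up (B) patterns |
| time-course gates | \|R\| > 0.7, p < 0.01 | — | rank-correlation screen |
| exon/intron pseudocount | 1 | reads | finite ratios at 0 intronic reads |
| attribution $\tau$ | 0.5 | log2 | see below |
| NB dispersion $\phi$ | 0.1 | — | typical bulk RNA-seq overdispersion |
| Dirichlet concentration | 200 | — | flow-count noise scale |
| marker specificity $s$ | 10 | fold | enriched-but-not-pure markers |

**ANOVA.** Classical fixed-effects one-way ANOVA on $\log_2(1 + \text{FPKM})$,
computed by vectorized sums of squares (identical to `anova(lm())` per
transcript, which the tests verify to $10^{-10}$). The FDR gate is exposed
because sources differ on whether the genome-wide gate is "0.001%" or
"0.01%"; the default is $10^{-5}$. A transcript constant across all
samples gets $F = 0, p = 1$; a transcript constant within groups but
separated between them gets $p = 0$ (perfect evidence, not an error).

**Detection.** The mean across samples is compared against the threshold
(an `any`-sample mode is available); using the mean is a choice — an
any-sample rule admits more transcripts at equal threshold.

**Folds.** Linear-scale group means with a pseudocount equal to the
detection floor. Log-scale means would give geometric-mean folds;
linear means match how FPKM group differences are usually reported.

**Patterns.** Transcript clustering uses distance $1 - r$ (Pearson,
across samples) with average linkage, cut at $k = 2$; labels are assigned
by the sign of the cluster's mean RAA−C shift, so "A" is always the
down-regulated pattern regardless of dendrogram orientation. Correlation
distance makes the assignment invariant to per-transcript affine
rescaling and to sample order (tested properties). Zero-variance rows are
excluded with a warning. If all pairwise distances are numerically zero
the cut is reported as degenerate (one cluster) instead of fabricating
two groups.

**Time course.** Spearman rank correlation of chronic-phase expression
against months since the event, with the threshold applied to $|R|$:
decaying responses produce *negative* correlations, so a one-sided
reading of "R > 0.7" would discard exactly the expected signal. The
asymptotic t approximation is used for p-values (`exact = FALSE`),
because tied counts are possible. A calibration note: with 13 time points
the null probability of $|R| > 0.7$ is ≈ 0.009 per transcript, so a
screen over hundreds of null transcripts should be expected to yield a
handful of chance hits; the thresholds control the per-transcript rate,
not the family-wise one.

**L/MN standardization.** "Standardized expression" admits several
readings; the default rule divides each gene's per-sample FPKM by its
all-sample mean (fold-over-mean), which keeps the index positive,
dimensionless and invariant to per-gene rescaling — the property the
tests assert. `zscore` (+1 shift) and `control_mean` rules are selectable
via `standardize_folds(rule =)`; the choice changes the index's absolute
scale, which is why recovery is asserted on direction and significance,
never on magnitudes.

**Exon/intron score.** The ratio is computed *per gene* (counts summed
over the selected samples, pseudocount 1) and the up/down sets compared
with a two-sided Mann–Whitney U on per-gene ratios; pooling reads across
a whole set before forming one ratio would let a few high-expression
genes dominate. Both the aggregation and pseudocount are parameters.

**Attribution.** The discordance threshold $\tau = 0.5$ log2 units
separates the canonical cases cleanly: a 1.5-fold count drop with a
2-fold expression drop gives discordance
$|\log_2 0.5 - \log_2(1/1.5)| \approx 0.415$ (composition), while a
1.3-fold count rise with a ≈2.9-fold marker rise gives ≈1.16 (active
regulation). The geometric mean aggregates marker folds because folds are
log-symmetric. The `indeterminate` verdict covers direction conflicts and
expression responses *smaller* than the count change beyond $\tau$ —
cases the simple two-way story cannot classify.

# Numerical choices and degenerate inputs

* Variance guards use absolute tolerances ($10^{-12}$) on sums of squares
  and row variances; "zero-variance" therefore means zero to machine
  precision, not "small".
* BH adjustment delegates to `p.adjust(method = "BH")`; the test suite
  holds it against a brute-force implementation of the step-up
  definition on random vectors.
* Welch comparisons of two *identical constant* groups are defined as
  $t = 0, p = 1$ (the statistic is 0/0; no evidence of a difference) —
  relevant for index values computed from degenerate fixtures.
* Group proportions, folds and mixture expectations are computed in
  closed form, never by sampling, so `expected_folds()` is exact and
  deterministic given a design.
* Every generator function takes a seed and restores the caller's RNG
  state; the pipeline derives per-stage streams from the single run seed,
  making manifests and checksums reproducible run-to-run.

# Validation problem sizes

The test and acceptance suites run at desk scale, chosen as the package's
own validation conditions: 2000-transcript cohorts with the design's
n = 19/20/20 for scenario recovery (100 seeds for the L/MN, attribution
and exon/intron recovery rates), 50 seeds × 2000 transcripts for ANOVA
calibration and FDR control, 20 seeds for clustering recovery at noise
sd 0.5, and 50 seeds of a 500-null time-course screen. Mixture-mean
convergence is asserted in the low-dispersion regime ($\phi = 0.01$),
where counting noise dominates and shrinks with depth; at the default
$\phi = 0.1$ the per-sample CV has a $\sqrt{\phi}$ floor that no library
size removes, which is a property of overdispersion, not of the
implementation.

# Known limitations

* FPKM uses plain exonic length; no effective-length or fragment-size
  correction, and no TPM/median-of-ratios alternatives.
* One transcript per gene in the generator: isoform-level phenomena
  (switching, alternative promoters) are out of scope.
* The attribution rule compares one count fold against one marker-set
  fold; it is not a deconvolution and cannot apportion a change across
  several simultaneously shifting populations.
* The L/MN index's absolute scale depends on the standardization rule and
  cohort composition; only directions and test decisions transfer across
  datasets.
* The time-course screen's thresholds control per-transcript error only;
  interpret hit lists from large screens accordingly.
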