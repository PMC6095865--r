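---
title: "Differential perturbation response in paired case-control transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential perturbation response in paired case-control transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darr)
```

## The design and the question

`darr` analyzes experiments in which each subject's cultured cells are
profiled by RNA-seq twice: once untreated (baseline) and once after a
chemical perturbation — the motivating application is dopamine exposure of
lymphoblastoid cell lines from schizophrenia cases and controls. Two
questions drive the analysis:

1. Which genes respond to the perturbation at all? Each subject acts as its
   own control, so this is a paired comparison.
2. For which genes does the *response* to the perturbation differ between
   cases and controls? The per-subject response — stimulated minus baseline
   on a covariate-adjusted, normalized scale — becomes a quantitative
   phenotype that is regressed on affection status.

The second question is the package's core statistic. Because each subject
serves as its own internal control, subject-level confounders cancel in the
response, which is precisely why a perturbation design can reveal
case-control differences that baseline profiling misses.

## Processing model

Expression starts as gene-level counts. RPKM is computed as
$\mathrm{RPKM}_{gs} = 10^9 c_{gs} / (L_g \, N_s)$ with $L_g$ the exonic
length of the gene's longest transcript and $N_s$ the sample's library size
(the count column sum — the only depth measure available once data arrive
as a count matrix). A gene is *expressed* when RPKM > 0 in at least half of
the baseline samples or at least half of the stimulated samples; the
either-condition rule deliberately keeps genes that are near-silent in one
condition but induced in the other, which are exactly the strong
responders. All samples are then quantile-normalized together (per-rank
mean reference; ties receive the mean of the reference values at their tied
ranks, which makes the transform idempotent).

Nuisance covariates are removed by per-gene least squares: affection
status (only where it is not the predictor of interest), sex, age,
sequencing batch, EBV load, ATP level and viable cell count, and five
genotypic ancestry PCs. Cell count and ATP level are harvest measurements
that exist per condition; both conditions' values are included by default
(`both_condition_covariates`), with the single-condition variant available
as a robustness check.

**Where the residualization happens matters.** For the paired test, the
covariates are regressed out of the *pooled* matrix of baseline and
stimulated samples jointly, with no condition term. Residualizing each
condition separately would be a mistake with a quiet failure mode: each
per-condition fit contains an intercept, so every gene's residual mean
would be exactly zero in both conditions, all within-subject differences
would sum to zero, and every paired t statistic would be identically 0.
Pooled residualization removes the same nuisance structure while leaving
the baseline-versus-stimulated contrast intact. For the case-control
analyses, by contrast, per-condition residualization is correct (the
contrast of interest lies across subjects, not across conditions) and is
what the package does.

The paired perturbation test is a per-gene one-sample Student t on the
within-subject residual differences, with Benjamini–Hochberg FDR across
genes. Fold change is the ratio of per-gene means of quantile-normalized
RPKM (stimulated over baseline); the mean-of-ratios per-subject variant is
available behind a flag. Because nearly every gene shows a small but
significant response in a large sample, enrichment analyses of responders
use a magnitude criterion instead of the FDR list: genes whose log2 FC lies
more than `fc_sd` (default 1) standard deviations from the mean log2 FC.

For case-control analyses, log2(RPKM + 1) values are residualized, then
rank-normalized per gene with the Blom offset,
$z_r = \Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ (ties get mean ranks).
The inverse-normal transform guards the per-gene regressions against the
heavy tails that survive the log transform; any strictly increasing
transform of the input yields identical output, a property the test suite
asserts. Each analysis is a simple per-gene regression of the adjusted
expression (or of the response difference) on status coded control = 0 /
case = 1, so $\beta_1$ is the case-minus-control mean difference; p-values
are two-sided, and BH-FDR is applied within each analysis separately. As a
robustness repeat, the top `pc_adjust` (default 5) principal components of
the per-condition residual matrices are regressed out before
rank-normalization — a guard against structure the measured covariates
failed to tag. Expression PCs are computed separately per condition; the
response is then rebuilt from the PC-adjusted values.

Genes with zero variance at any stage are flagged and dropped from that
analysis rather than imputed.

## Quality control

Four sample-level screens run before analysis:

* **Sex-marker concordance** — XIST versus the mean of seven Y-linked
  genes (RPS4Y1, ZFY, USP9Y, DDX3Y, UTY, KDM5D, EIF1AY), with thresholds
  of 1 RPKM on both margins and an indeterminate band when both margins
  are low or both high. The thresholds are a package choice; XIST and the
  Y panel are separated by orders of magnitude in typical data, so results
  are insensitive to the exact cut.
* **Genotype concordance** — fraction of matching calls between
  pre-called RNA-seq genotypes and array genotypes over jointly non-missing
  SNPs of an informative panel; samples below 0.8 are flagged as possible
  swaps, and a sample with no joint calls is indeterminate rather than
  discordant.
* **Completion rates** — the per-gene fraction of samples with positive
  expression, computed per affection group; a case/control correlation
  near 1 indicates no systematic detection bias.
* **Outlier screens** — (i) each sample's mean pairwise Spearman
  correlation with all other samples, z-scored, flagging z < −4; and
  (ii) absolute sample scores beyond 4 SD on either of the top two
  expression PCs. Both run on log2(RPKM + 1): Spearman is rank-based and
  indifferent, but PCA on the raw RPKM scale is dominated by a handful of
  highly expressed genes and flags their sampling noise as outliers
  (about 2 false flags per 120 null samples in simulation, versus a
  negligible rate on the log scale). Spearman rather than Pearson makes
  the correlation screen robust to the heavy-tailed expression scale.
  `z_cut = 4` keeps the null false-flag rate below one sample per screen
  at cohort sizes in the hundreds, verified over 20 simulation seeds.

Exclusion is one-shot (no iterative re-screening), happens before the
expressed-gene filter, and removes the flagged sample's subject entirely so
the pairing stays complete. The union of the two screens is excluded by
default; intersection is available.

## The simulator

`simulate_da_dataset()` generates the data structure the analysis assumes,
with known truth. On the log2 scale, gene $g$ in subject $i$ under
condition $c$ has expected expression

$$\eta_{gic} = b_g + x_{i(c)}^\top \beta_g + \gamma_{g,\mathrm{batch}(i)}
  + u_{gi} + \mathbb{1}[c=\mathrm{stim}]\,(d_g + \mathbb{1}[\mathrm{case}_i]\,\delta_g)$$

and counts are negative binomial with mean
$\mathrm{depth}_s \cdot 2^{\eta}$ and a single shared dispersion (default
0.1), the standard bulk RNA-seq noise model. Defaults mirror the motivating
study: 514 cases and 690 controls, five batches, near-universal small
perturbation effects ($d_g \sim N(0, 0.3^2)$ for 90% of genes), and a 5%
subset of genes carrying a case-specific response shift $\delta_g$ of 0.5
log2 units with random sign. The subject intercept $u_{gi} \sim N(0,
0.2^2)$ is shared between a subject's two samples; it induces the
within-subject correlation the paired design exploits and puts the
cross-condition correlation of per-gene mean expression above 0.99.
Covariates are drawn independently (age uniform 18–80, sex Bernoulli 1/2,
harvest covariates log-normal and correlated 0.6 across conditions,
ancestry PCs standard normal) with per-gene coefficients
$\beta_g \sim N(0, 0.1^2)$ on the standardized covariates; there is no
covariate–status confounding by default. Gene lengths are log-uniform in
[500, 20000] bp. An optional marker block wires XIST and the seven Y genes
to the simulated sex so the QC screen is exercisable; optional outlier
samples are planted by permuting a stimulated sample's count vector across
genes. One seed governs every draw, and identical seeds give identical
datasets byte for byte.

What the simulator does *not* emulate: gene-gene correlation beyond the
shared subject intercept, count overdispersion that varies by gene,
GC/length biases, isoform structure, or confounding between covariates and
case status (available only by explicitly planting it). Passing recovery
tests therefore demonstrate that the statistics do what they claim under
the assumed model — not that real data meet those assumptions.

## Enrichment

Gene lists are tested against curated sets with the two-sided Fisher exact
test, using the minimum-likelihood convention (all outcomes no more
probable than the observed table, with a 1e-7 relative tolerance at the
boundary). Every set is intersected with the background — the run's
expressed genes — before counting, and fold enrichment is
$(k/n)/(K/N)$. Two 2×2 constructions are supported: the default compares
the query list of size $n$ against the full background list
($[k, n-k; K, N-K]$, the reference-list convention of enrichment tools in
this field), and `query_in_background = FALSE` gives the classical
partitioned hypergeometric table. The default is the construction under
which the printed counts of the motivating study's enrichment table
reproduce its printed p-values; the classical construction satisfies the
textbook symmetry $p(N, K, n, k) = p(N, n, K, k)$ and is the one checked
against exhaustive enumeration in the tests. The hypergeometric PMF is
evaluated in log space, so backgrounds of tens of thousands of genes pose
no underflow risk.

## Numerical and scale choices

* Library size for RPKM is the count-matrix column sum; whether
  multi-mapped reads would be in a BAM-derived denominator is moot here
  since inputs arrive as count matrices.
* Quantile-normalization tie handling (mean of reference values at tied
  ranks) makes the transform idempotent to 1e-12, which the suite asserts.
* The Blom offset is one of several rank-normalization conventions; it is
  fixed here (not configurable) so that results are reproducible across
  runs, and the choice is immaterial for the two-sided tests because the
  transform is monotone for every convention.
* Residual orthogonality to the design is asserted at a tolerance scaled
  by the vector norms (1e-8 relative).
* Aliased design columns (e.g. a batch indicator confounded with another
  covariate) are dropped with a warning; a design still rank-deficient
  afterwards is an error rather than a silent pseudo-inverse.
* The problem sizes used by the shipped verification runs are 10,000 genes
  with 100+100 subjects (3 seeds) for null calibration and 10,000 genes
  with 200+200 subjects (5 seeds) for effect recovery — large enough that
  the binomial noise on a 5% type-I rate is a small fraction of the
  acceptance band, and the expected sensitivity margin is several standard
  errors.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_da_dataset(sim_config(
  n_cases = 100, n_controls = 100, n_genes = 2000,
  frac_diff_response = 0.05, seed = 42))

fit <- da_perturb(sim$counts_baseline, sim$counts_stimulated,
                  sim$samples, sim$annotation,
                  gene_sets = list(first500 = sim$truth$gene_id[1:500]))
summary(fit)

## per-gene differential-response coefficients
head(coef(fit, "response"))

## the response phenotype itself (genes x subjects)
resp <- residuals(fit, "response")
```

## Known limitations

* The linear-model framework has no empirical-Bayes variance moderation
  and no count-level model; with very few subjects the per-gene variance
  estimates are noisy and a moderated framework would be more powerful.
  The design target is cohorts of hundreds of subjects, where this is
  immaterial.
* Expression-PC adjustment is plain PCA, not a surrogate-variable method;
  it can absorb genuine signal when case-specific effects are both strong
  and widespread, which is visible in simulation as reduced sensitivity of
  the PC-adjusted repeat.
* Genotype concordance consumes pre-called genotype tables; calling
  genotypes from reads is out of scope.
* The enrichment machinery handles flat gene sets only — no ontology DAG,
  term clustering, or gene-ID mapping.
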