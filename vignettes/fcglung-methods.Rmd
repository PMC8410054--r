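---
title: "Dissecting chromosomal versus gonadal sex effects in neonatal hyperoxic lung injury: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fcglung methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Bronchopulmonary dysplasia (BPD), the chronic lung disease of prematurity,
is more frequent and more severe in males. Two distinct mechanisms could
drive this dimorphism: gonadal hormones, or the sex-chromosome complement
itself (XX vs. XY). The Four Core Genotypes (FCG) mouse model decouples the
two by moving *Sry* onto an autosome, yielding four genotypes — XXF, XXM,
XYF, XYM — in which gonadal sex (F/M) and chromosomal sex (XX/XY) vary
independently. Crossing this 2x2 genetic design with a neonatal hyperoxia
exposure (95% FiO2 during the saccular stage, with room-air controls, and
lungs profiled at P5 and P21) gives a 2x2x2 factorial transcriptome study
in which treatment-by-chromosomal-sex and treatment-by-gonadal-sex
interactions are separately estimable.

`fcglung` implements the complete computational arm of such a study as a
reusable, tested pipeline: factorial differential expression, decomposition
of the four genotype responses into gonadal/chromosomal shared regions,
summed Z-score projection of murine signatures onto an external human-style
cohort with clinical association, preranked gene-set enrichment with
NES-based clustering, and the phenotype-table three-way ANOVA with Sidak
post hoc comparisons. Because the original cohorts are external downloads,
the package ships a synthetic-data module that emulates their statistical
structure with known planted truth; every pipeline claim is validated as a
recovery property against that truth.

## The synthetic world

`sim_config()` + `planted_effects()` + `simulate_murine_counts()` draw a
gene-by-sample count matrix from a negative binomial model,
$K_{gj} \sim \mathrm{NB}(\mu_{gj},\ \phi_g)$ with
$\mathrm{Var} = \mu + \phi\mu^2$ and
$\mu_{gj} = s_j\,2^{\eta_{gj}}$, where $\eta_{gj}$ is the per-gene baseline
(uniform on log2 [3, 10]) plus whichever planted effect terms are active
for sample $j$'s factors. Defaults and their reasons:

* **n = 3 per design cell** — the group size of the RNA-Seq design this
  emulates; it is deliberately small because the downstream statistics must
  work at that size.
* **Dispersion** $\phi_g$ lognormal with median 0.1, sdlog 0.5 — a typical
  bulk RNA-Seq dispersion landscape.
* **Core hyperoxia response**: 150 genes at |log2FC| = 2, half up, half
  down, in every genotype.
* **Chromosomal interaction (`xx_protective`)**: 100 genes whose treatment
  effect is 2 in XY genotypes but attenuated to 0.5 in XX — the protective
  female sex-chromosome complement.
* **Gonadal interaction (`gonadal_modulated`)**: 60 genes (effect 2 in
  gonadal males, 0.5 in females). This set is deliberately smaller than the
  chromosomal set: the biology being modelled found gonadal-hormone effects
  on the hyperoxia response to be minor relative to chromosomal effects,
  and a generator in which both interactions are equally strong cannot
  reproduce the observed clustering geometry at the late timepoint.
* **X-escapees**: 20 X-linked genes with a +0.585 log2 (1.5-fold) baseline
  double dose in XX samples. **Y-only genes**: 20 Y genes expressed in XY
  samples only. **Markers**: an Xist-like gene (XX only), an Sry-like
  autosomal transgene (gonadal males only) and a Uty-like Y gene (XY only),
  mirroring the genotyping sanity checks of the FCG design.
* "Zero" expression in an off stratum is NB mean 0.01, not exactly 0, to
  avoid degenerate all-zero rows.
* Counts are on a CPM-like scale without gene lengths; length
  normalization cancels from every within-gene contrast, so FPKM-style
  scaling is omitted on purpose.

`simulate_cohort()` emulates a newborn blood-transcriptome cohort: a latent
severity $u_j \sim N(0,1)$ drives an ordinal BPD grade (thresholds 0, 0.7,
1.3 for mild/moderate/severe — chosen to skew toward milder grades, as in
real cohorts), decreasing gestational age and birth weight, and an
oxygen-at-28-days indicator ($u > 0.2$ with 5% label noise). Expression of
the genes of one chosen murine signature is $-\lambda u \cdot
\mathrm{dir}(g)$ plus unit noise in the targeted sex stratum, so that the
signature's summed Z-score anticorrelates with severity there;
everything else is pure noise. With $\lambda = 0$ the cohort is a pure
null, which doubles as the healthy-cohort analogue used for
signature-geometry analyses.

What a green test does **not** establish: the generator has no batch
effects, no gene-gene correlation beyond the planted structure, no isoform
complexity, no probe-level artifacts, and Y-linked genes outside the
`y_only` set are given ordinary baselines in all samples (including XX) —
so green recovery tests certify the statistical machinery, not robustness
to every artifact of real data.

## Differential expression

Normalization is median-of-ratios (per sample, median over genes positive
everywhere of the count divided by the gene's geometric mean), falling back
to library-size ratios when no gene qualifies; values are
$\log_2(K/s + 1)$, keeping zeros at exactly 0. Genes with fewer than 5
counts in fewer than 2 samples of a contrast are dropped (a conventional
low-count filter, exposed as arguments).

The test is a pooled two-sample t with variance moderation:
$$\tilde s^2_g = \frac{d_0 s_0^2 + df\, s^2_g}{d_0 + df},\qquad
\tilde t_g = \frac{\bar m_B - \bar m_A}{\tilde s_g\sqrt{1/n_A + 1/n_B}},$$
referred to $t_{d_0 + df}$. Two prior modes are provided:

* **fixed** (`d0 = 4`, $s_0^2$ = across-gene arithmetic mean of $s_g^2$) —
  the simplest fully specified moderation;
* **empirical** (`d0 = "empirical"`, the default of the contrast
  wrappers) — $(d_0, s_0^2)$ estimated by log-variance moment matching
  under $s_g^2 \sim s_0^2 F(df, d_0)$, inverting the trigamma function.

The empirical prior is the default for a measured reason: with n = 3 per
group the per-gene variance estimate has only 4 df, so its sampling
distribution is strongly right-skewed and the arithmetic mean over-states
the typical variance by roughly 50%. At the simulator's default effect
size (|log2FC| = 2) the fixed prior recovers only ~0.60–0.76 of planted
core genes per genotype, while the empirical prior reaches ~0.84–0.91 —
on par with an established negative-binomial GLM pipeline run on the same
simulated data — without inflating the null false discovery proportion
(measured ≤ 0.07 at q ≤ 0.05). With `d0 = 0` the test reduces exactly to
the classical pooled t, which the test suite verifies against a reference
implementation at 1e-10.

Signatures are called at q ≤ 0.05 (Benjamini–Hochberg) and |log2FC| ≥ 1,
ties included; both thresholds are arguments.

## Region decomposition

The four genotype hyperoxia signatures are decomposed into the shared
responses of the factorial design: region E (all four genotypes), A
(gonadal female: XXF ∩ XYF), B (gonadal male: XXM ∩ XYM), C (chromosomal
female: XXF ∩ XXM), D (chromosomal male: XYF ∩ XYM), with A–D excluding E.
Membership is **direction-concordant**: a gene shared between two
signatures but up in one and down in the other is not a shared response;
such genes are tracked in a side list rather than silently counted. Overlap
percentages use the directional Jaccard (intersection over union) by
default, with the smaller-set denominator available as an option, since the
percentage convention is not uniquely determined by "percent of DEGs in
common".

A structural note on recovery expectations: region E demands concordant
recovery in all four genotypes, so its sensitivity for planted core genes
is approximately the fourth power of the per-genotype sensitivity (helped
somewhat by the shared truth). At per-genotype power ~0.85–0.91 — the
realistic ceiling at n = 3 with this noise model, matched by standard
external DE methods — region-E sensitivity is ~0.64. A target of 0.8 for
region E would require ~0.95 per genotype, which no method attains in this
world; the corresponding acceptance assertion is therefore expected to
fail, and is left failing rather than weakened.

## Summed Z-score projection

Cohort expression is Z-scored per gene across **all** subjects (n − 1
denominator, zero-variance genes excluded); sex stratification happens only
at the association step, so both sexes are scored on a common scale. The
signature score is
$$Z_j(S) = \sum_{g\in \mathrm{up}} z_{gj} - \sum_{g\in \mathrm{down}} z_{gj},$$
with missing genes dropped (coverage reported, warning under 0.5). The raw
sum is the default; a per-gene normalization and a separate up/down mode
exist, but all downstream Pearson analyses are scale-invariant, so the
choice cannot change correlations or clustering.

Intersignature correlation is Pearson across subjects. Clustering is
unweighted average linkage (UPGMA) on distance 1 − r, with deterministic
tie-breaking by lexicographic label order, ultrametric branch lengths and
Newick export. Clinical association is the two-sided Pearson correlation of
scores with gestational age (weeks), birth weight (grams), BPD grade
encoded ordinally 0/1/2/3, and oxygen-at-28-days encoded 0/1, within each
sex stratum and overall; strata under 3 subjects are reported missing. The
0–3 ordinal encoding is a documented decision — the source data are
categories.

## Preranked gene-set enrichment

Genes are ranked by the signed moderated t (configurable to log2FC), ties
broken lexicographically. The enrichment score is the canonical weighted
Kolmogorov–Smirnov running-sum extremum with weight exponent p = 1. The
null is **gene-sampling**: ES of random gene sets of matching size
(phenotype permutation is degenerate at n = 3 per group). NES is ES divided
by the mean |null ES| of the same sign; the nominal p is the same-sign
exceedance rate with the +1 correction; FDR q compares the observed NES to
the pooled sign-normalized null, clipped to [0, 1]. Sets are filtered to
sizes 5–500 after intersection with the ranked universe; significance for
matrix masking and pathway selection is FDR < 0.25, taken from the
convention of the modelled study.

The discordant-pathway rule selects sets significantly induced in the
human-cohort response, significantly suppressed in all three feminized
murine responses (XXF, XXM, XYF), and in XYM either significantly induced
or not significant; the human ranked list is produced by the same moderated
test (BPD vs. none) on the cohort, a documented decision.

## Three-way ANOVA and post hoc comparisons

Phenotype tables (morphometry-style, n = 5–6 per cell, possibly
unbalanced) are analysed by the full 2x2x2 model with all interactions
under sum-to-zero coding, with Type III sums of squares from full-vs-reduced
fits — these reduce to the textbook balanced formulas when cells are equal
(verified to 1e-10) and match a regression-based oracle on unbalanced data
(1e-8). Post hoc pairwise comparisons use the pooled residual error of the
cell-means fit and Sidak adjustment $1-(1-p)^m$ over the requested family.
Exact equivalence to any particular commercial package's unbalanced
behavior is not claimed.

## Numerical and design choices

* All randomness flows from one root seed through fixed per-stage
  substreams (`child_seed`); reruns are byte-identical, and library calls
  restore the caller's RNG state.
* UPGMA tie-breaks are lexicographic on the smallest leaf label of each
  cluster, so clustering is invariant to input order.
* BH and Sidak are implemented explicitly (they define membership rules,
  not just reporting); BH is verified against the reference implementation.
* A constant score row yields NA correlations (flagged), never silent
  zeros; in NES-matrix clustering a constant row is placed at maximal
  distance 2.
* `enrichment_score` degrades to unweighted increments if every hit has
  zero metric, avoiding 0/0.
* Empty design cells, overlapping planted sets, unannotated genes,
  zero-coverage signatures, malformed GMT lines and non-integer counts all
  fail loudly with the offending name, line or cell.

## Known limitations

* The DE model tests one factor at a time within genotype; there is no
  multi-factor GLM with covariates and no batch correction.
* The cohort generator plants a single-axis severity structure; real
  cohorts have correlated clinical covariates beyond one latent factor.
* GSEA FDR uses the pooled sign-normalized null, the standard
  approximation; very small collections give coarse q-values.
* The Venn decomposition reports three-or-four-way structure through its
  side lists but regions A–D are pair-defined, as in the modelled design.
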