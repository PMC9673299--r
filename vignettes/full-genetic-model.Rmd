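---
title: "The full genetic model: simulation, association and breeding prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The full genetic model: simulation, association and breeding prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namgwas)
```

## The model

`namgwas` analyzes quantitative traits of nested association mapping (NAM)
populations — collections of biparental recombinant-inbred-line (RIL)
families sharing a common parent (B73 in maize) — under a *full genetic
model*.  The phenotype of line $k$ in environment $h$ is

$$
y_{hk} = \mu + c_{hk}
 + \sum_i a_i x_{A_{ik}} + \sum_i d_i x_{D_{ik}}
 + \sum_{i<j} aa_{ij} x_{AA_{ijk}} + ad_{ij} x_{AD_{ijk}}
 + da_{ij} x_{DA_{ijk}} + dd_{ij} x_{DD_{ijk}}
 + e_h
 + \sum_i ae_{ih} u_{AE_{ihk}} + de_{ih} u_{DE_{ihk}}
 + \sum_{i<j} (aae + ade + dae + dde)_{ijh}\, u_{\cdot}
 + \varepsilon_{hk},
$$

with the standard coding: $x_A$ is 1/0/−1 for QQ/Qq/qq (Q the non-B73
allele), $x_D$ is the heterozygote indicator, and each digenic epistasis
contrast is the product of the corresponding single-locus contrasts.  The
$u$ coefficients equal the matching $x$ coefficient inside environment $h$
and 0 elsewhere.  Genetic main effects and epistasis are fixed;
environment and all gene-by-environment (G×E) terms are random, each
interaction family (AE, DE, AAE, ADE, DAE, DDE) carrying one variance
component.  $c_{hk}$ holds optional principal-component cofactors for
population structure; with zero components the *base* model is obtained.

Why a full model?  Additive-only scans leave dominance, epistasis and G×E
variance unexplained ("missing heritability") and cannot say whether a
heterozygous combination would outperform the best homozygote — the
question hybrid breeding actually asks.

## What the simulator emulates — and what it does not

`simulate_nam_genotypes()` generates half-sib RIL families: at each SNP a
family segregates with probability `seg_prob` (founder polymorphic against
B73), homozygotes QQ/qq are equally likely within a segregating family,
non-segregating families are fixed qq, residual heterozygosity is injected
per cell at `het_rate`, and missing calls at `missing_rate`.  The defaults
(25 families, `het_rate = 0.03`) mirror a NAM population that has been
selfed to near-homozygosity; the residual heterozygosity level is not a
published quantity, so 3% is a modeling choice held fixed throughout.

Deliberately **not** emulated: linkage and recombination maps (SNPs are
i.i.d. within family), selection, and multi-allelic sites.  None of the
downstream formulas tested here depend on LD, but this means passing tests
say nothing about LD-induced confounding in real data — only about the
correctness of the estimators on data that satisfy the model.

`make_architecture()` turns target variance shares into effect sizes by
scaling raw Gaussian effects against the realized coefficient variances of
a reference population.  Components are not orthogonalized, so when many
components are requested simultaneously their sample correlations shift
realized shares by a few percent; single-component targets are tight
(±0.02 at 5000 lines).  Interaction deviations are row-centered across
environments, which makes "main effect" and "deviation" identifiable —
the same convention the estimator reports.

## Quality control

QC follows fixed rules with strict boundary semantics (values *strictly*
below a cutoff are removed, values on the boundary kept):

* SNPs: minor allele frequency < 0.05 (heterozygotes contribute one of
  each allele) or call rate < 90%.
* Phenotypes, per trait × environment group: values outside
  $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, with quartiles
  by linear interpolation between order statistics (`quantile()` type 7 —
  the convention is pinned by tests because other quartile rules move the
  fences); then records whose baseline-model residual exceeds 3 standard
  deviations, where the baseline is the trait × environment mean — the
  simplest defensible null when nothing richer has been fitted yet.
  Groups with fewer than 4 values are skipped with a warning, and a
  zero-variance group cannot produce outliers.

## GMDR prescreening

Fitting every SNP pair jointly is infeasible, so candidate loci and pairs
are prescreened by generalized multifactor dimensionality reduction.  The
score statistic is the residual from a mean-plus-environment model;
records are binned by genotype combination (3–27 cells for 1–3 loci), a
training cell is "high-risk" if its mean residual exceeds the training
mean, and the tuple's score is the cross-validated balanced accuracy of
that labeling (5 folds by default).  A tuple unrelated to the trait scores
≈ 0.5; a determining tuple scores 1.  The 1D scan is exhaustive; 2D/3D
scans are restricted to the top 1D survivors (configurable), a deliberate
desk-scale trade against the exhaustive GPU scan the score was designed
for.  Ranking ties break by genome order so results are reproducible.

## Association testing and estimation

* **Henderson method III F-tests.**  Every term is tested by the
  difference of reductions in sums of squares between the model with and
  without the term's columns, over the full model's residual mean square.
  On balanced fixed-only designs this reproduces the classical ANOVA F
  exactly (an oracle test asserts agreement to 1e-10).  One wrinkle of the
  full design: a term's own environment-masked interaction columns span
  the term itself, so they are excluded from both reductions when that
  term is tested — otherwise the F would be identically zero by aliasing.
  Random blocks are tested by the same quadratic form with the block's
  rank as numerator degrees of freedom.
* **Experiment-wise thresholds.**  Phenotypes are permuted within
  environment (preserving $e_h$ while severing the genotype–phenotype
  link; 2000 permutations by default).  The maximum F per term family
  (main, epistasis) yields a critical value, and each term's
  experiment-wise P is $(1 + \#\{\max F \ge F_{\text{obs}}\})/(B+1)$.
  Significance uses the exact rule $P_{EW} \le \alpha$, which controls the
  family-wise error at $\alpha$ for any finite number of permutations;
  the $(1-\alpha)$ type-1 quantile is reported as the critical F (so
  $\alpha = 1$ degenerates to the minimum permuted maximum, a documented
  boundary).  Fewer than 100 permutations are refused unless forced.
* **Variance components** are estimated by REML, profiled over the
  residual variance and optimized on the log variance-ratio scale; the
  Woodbury identity keeps each likelihood evaluation at the cost of the
  (small) number of random-effect columns, independent of record count.
* **Gibbs estimation.**  Effects are estimated by a Gibbs sampler (20000
  iterations, 2000 burn-in, thinning 5 by default): flat priors on fixed
  effects, Normal(0, $\sigma_b^2$) on each random block,
  inverse-gamma(0.001, 0.001) on every variance component.  All location
  parameters are drawn jointly from the mixed-model-equation full
  conditional via one Cholesky per iteration.  Two numerical safeguards:
  each draw is hierarchically recentered (environment mean into the
  intercept, each term's interaction mean into its main effect), which
  fixes the intrinsic confounding of the incidence parameterization and
  reports interactions as pure deviations; and variance draws are capped
  so a one-column block with a vague posterior cannot make the joint
  precision matrix numerically singular.  Chains are initialized at the
  REML solution; a Geweke-style split-mean diagnostic warns when |z| > 4.
  If the model is numerically noiseless the exact solution is returned
  directly with a log message.
* **Heritability.**  Each component's share is the variance, across the
  observed records, of its terms' predicted contribution divided by the
  phenotypic variance, in percent.  Aggregates:
  $h^2_T$ = sum of all components;
  $h^2_{D+}$ = D + AD + DA + DD + DE + ADE + DAE (+ DDE);
  $h^2_{GE}$ = AE + DE + AAE + ADE + DAE (+ DDE).
  The DDE slot is carried even though published component tables often
  omit it; with near-homozygous populations its estimate is ≈ 0.

## Breeding prediction

`genotypic_value()` evaluates the model at any genotype vector
(G relative to the mean; per-environment values add the realized
interaction deviations — the "overall" column deliberately uses main
effects only, mirroring the G vs G+GE presentation).  The breeding table
assembles, per environment and overall: the mean, the all-QQ, all-qq and
all-Qq (F1) combinations, the best existing line (argmax over genotyped
lines, ties by line id), the *superior line* (optimal homozygous
combination) and the *superior hybrid* (optimum over all three codes).

Optimization is exact enumeration up to a configurable search-space bound
(20000 combinations by default, chunked evaluation), otherwise stepwise
tuning: coordinate ascent visiting loci in descending |a|+|d| order, with
deterministic multi-start (main-effect greedy start plus every uniform
vector).  Enumeration is the oracle for tuning in tests: on 8-locus
3-pair random effect sets the tuned optimum equals the exhaustive one in
≥ 95/100 seeded instances and never exceeds it.  The hybrid search is
seeded with the superior-line solution, so superior hybrid ≥ superior
line by construction.  Note one boundary: an *existing* line carrying
heterozygous calls can in principle beat the best homozygous combination
under strong dominance, so "superior line ≥ best line" is guaranteed only
for fully homozygous populations.

## Numerical choices and degenerate inputs

* Missing genotype codes surviving QC are imputed with the locus's mean
  coefficient within the line's family (falling back to the overall
  mean), keeping records usable without discarding lines.
* Collinear fixed columns are pruned by QR before fitting and recorded;
  zero-coefficient terms test as F = 0 with 0 numerator df.
* A locus with no heterozygotes has a degenerate dominance contrast; the
  scan detects this from the design and drops the term's df rather than
  dividing by a near-zero determinant.
* Residual variance of exactly 0 (noiseless fixtures) short-circuits the
  sampler to the exact solution.
* Seeds are explicit everywhere; a run-level seed fans out to stages by
  the fixed rule `stage_seed = (seed * 101 + offset) mod (2^31 - 1)`.

## Problem sizes used in the validation suite

The packaged checks run at desk scale, chosen to keep the full suite
under a couple of minutes while leaving Monte-Carlo tolerances honest:
null type-I-error control uses 200 replicate datasets of 500 lines × 2
environments × 50 SNPs with 200 permutations each; parameter recovery
uses 2000 lines × 4 environments with 6 loci, 2 epistatic pairs and G×E
on 2 loci; optimizer oracles use 100 random 8-locus effect sets; the
Gaussian QC tail check uses 1e5 values.  These sizes are the package's
validation conditions, not limits of the implementation — the pipeline
itself is bounded by the prescreen width and the number of candidate
terms, not by line count.

## Known limitations

* No linkage map: prescreen hit lists on real data will contain LD
  proxies of causal sites; the package ranks and tests terms but does not
  fine-map.
* The marginal scan tests loci one (or one pair) at a time; the joint
  model is refit only on candidates surviving the threshold, so closely
  linked signals can shadow each other.
* GMDR's exact original cross-validation variant is under-specified in
  the literature it comes from; the reconstruction here is pinned by its
  own oracle tests, not by an external implementation.
* Family structure partially confounds per-locus G×E deviations when few
  families segregate a locus; deviations then attenuate toward zero (the
  direction is preserved).
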