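---
title: "Multi-trait genomic selection in a partial-diallel conifer breeding population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genomic selection in a partial-diallel conifer breeding population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spruceGS)
```

spruceGS implements the statistical workflow of a multi-trait genomic
selection (GS) study in a progeny-tested conifer breeding population: a set
of full-sib families from a partial diallel planted on a small number of
sites in randomized complete blocks, phenotyped for growth (height,
diameter, height/diameter ratio), intrinsic wood quality (acoustic velocity
as a stiffness proxy, average wood density, microfibril angle) and an
ordinal insect-resistance score — the cumulative number of weevil attacks
(CWA) in $\{0,1,2,3\}$ — and genotyped on an array of a few thousand gene
SNPs. This vignette explains the models, the choices behind their
implementation, and what the simulation-based tests do and do not establish.

## The single-trait animal model

The central model is the individual-tree ("animal") mixed model

$$ y = \mu + X s + Z_1 b(s) + Z_2 a + Z_3 sa + e $$

with fixed site effects $s$, random blocks within sites
$b(s) \sim N(0, \sigma^2_b I)$, additive genetic effects
$a \sim N(0, \sigma^2_a K)$, a site-by-additive interaction
$sa \sim N(0, \sigma^2_{sa} (I_s \otimes K))$ and homogeneous residuals.
The kernel $K$ is either the pedigree numerator relationship matrix $A$
(ABLUP), built by the recursive tabular method, or the VanRaden genomic
relationship matrix

$$ G = \frac{ZZ'}{2\sum_j p_j(1-p_j)}, \qquad Z = M - 2p, $$

computed from post-QC, imputed dosages with sample allele frequencies
(GBLUP). Derived parameters are the narrow-sense individual heritability
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{sa} + \sigma^2_e)$ and the
type-B genetic correlation $r_B = \sigma^2_a/(\sigma^2_a + \sigma^2_{sa})$,
which measures how stable additive rankings are across sites ($r_B = 1$
means no rank-change GxE). Block variance is deliberately excluded from both
denominators. Standard errors use the first-order delta method with the
asymptotic covariance of the variance components.

### REML implementation

Since every tree sits on exactly one site, the model collapses to an
individual-level covariance
$V = \sigma^2_b Z_bZ_b' + \sigma^2_a K + \sigma^2_{sa}(K \circ S) +
\sigma^2_e I$ with $S$ the same-site indicator, and REML is run directly in
this "V-space". The updates are monotone EM steps
($\theta_i \leftarrow \theta_i + \theta_i^2 (y'PA_iPy -
\mathrm{tr}(PA_i))/n$), accelerated by average-information (AI) Newton
steps under an active-set rule: a component pinned at the zero boundary
with a negative score stays out of the Newton system, and any AI step that
leaves the feasible region or lowers the likelihood falls back to EM. This
keeps the path monotone in practice while converging in around ten
iterations; `algorithm = "em"` forces the provably monotone pure-EM path.
Convergence is declared when the maximum relative component change falls
below $10^{-6}$ or the log-likelihood changes by less than $10^{-8}$.
Variance components are kept non-negative by the EM form itself plus a
small floor; boundary estimates are reported as zero. The asymptotic
covariance of the estimates is the inverse AI matrix at convergence.

Likelihood-ratio tests for variance components use the plain
$\chi^2$ reference with the stated degrees of freedom even when the null
puts the component on the boundary; this is conservative, and negative
statistics are truncated to zero.

## Bivariate and multi-trait models

Trait pairs are analysed per site with a stacked model whose block,
additive and residual effects each carry a 2×2 covariance parameterised as
one variance per trait plus a correlation (the CORGH structure):
$V_B \otimes Z_bZ_b' + V_A \otimes K + V_R \otimes I$. The phenotypic
correlation is derived from the fitted components,

$$ r_p = \frac{r_b \sigma_{b_i}\sigma_{b_j} + r_a \sigma_{a_i}\sigma_{a_j}
 + r_e \sigma_{e_i}\sigma_{e_j}}
 {\sqrt{(\sigma^2_{b_i}+\sigma^2_{a_i}+\sigma^2_{e_i})
        (\sigma^2_{b_j}+\sigma^2_{a_j}+\sigma^2_{e_j})}}, $$

and significance comes from likelihood-ratio tests against the model with
$r_a = 0$ (1 df) and against all three correlations zero (3 df).
Single-site heritabilities are $\sigma^2_{a_i}/(\sigma^2_{a_i} +
\sigma^2_{e_i})$.

These models are maximised by quasi-Newton iteration (L-BFGS-B) on
log-variances and atanh-correlations with an analytic REML gradient;
starting values come from single-trait fits of the same structure with
correlations started at zero, which mirrors how such models are usually
coaxed into convergence. Correlations are bounded at $|r| \le 0.999$;
estimates that reach the bound are reported as boundary-pinned with a
warning rather than silently constrained, since genetic correlations in
40-family designs genuinely pile up at the bounds. For the same reason the
sampling distribution of $\hat r_a$ is skewed whenever the estimate is
large, so interval statements about correlations should be formed on the
Fisher-z (atanh) scale — the package's recovery tests transfer the
delta-method SE with $se_z = se_r/(1-\hat r^2)$ and check coverage there.

Multi-trait prediction uses the two-step form: phenotypes are first
adjusted to $y^*$ (conditional residuals of a fixed-site, random-block
model — by the first Henderson equation these sum to exactly zero), then up
to three traits are fitted jointly with unstructured $V_A$ and $V_R$ and no
GxE term. Missing phenotypes are handled exactly, by building the
mixed-model equations over observed cells only rather than by imputation;
breeding values are returned for every kernel individual and trait,
including trees never phenotyped for the target trait.

## Bayesian whole-genome regressions

`fit_brr()` and `fit_bayescpi()` are Gibbs samplers for
$y = \mu + Xs + Z_1 b(s) + Z_2 a_m + e$ over centred marker dosages, with a
common normal prior on marker effects (BRR) or a spike-slab prior with
inclusion proportion $\pi \sim \mathrm{Beta}(1,1)$ (BayesC$\pi$); no GxE
term is fitted, i.e. marker effects are assumed stable across sites.
Ordinal responses use the probit augmentation: a latent liability with
residual variance fixed at 1, first threshold fixed at 0 and remaining
thresholds sampled uniformly between the neighbouring liability order
statistics. `fit_tgblup()` is the threshold analogue of GBLUP; it samples
the additive effects on the eigenbasis of $K$, where the conditional
posterior is diagonal because the rotation is orthonormal and the liability
residual is 1, making each sweep $O(n^2)$.

Priors are scaled-inverse-$\chi^2$ with 5 degrees of freedom and scales
that split half of the phenotypic variance between the genomic and residual
terms a priori — the conventional weakly-informative defaults for these
samplers; they are implementation choices, stated here because no single
canonical value exists. The default chain runs 50,000 iterations with a
15,000-iteration burn-in and thinning of 20; the package's tests use
shorter chains (3,000-6,000 iterations) because the conjugate-oracle and
correlation checks they perform are insensitive to chain length beyond
mixing. GEBVs are dosage-weighted sums of posterior-mean marker effects,
with the training-set centring reused for new genotypes; for kernel-based
threshold fits, unphenotyped trees receive the projection
$K_{miss,obs} K_{obs,obs}^{-1} \hat a_{obs}$.

All samplers run on R's RNG, so a seed makes chains exactly reproducible.

## Cross-validation, predictive ability and the missing-data experiment

Validation uses family-stratified tenfold cross-validation repeated ten
times (100 fits per trait): within each family, trees are dealt round-robin
into folds from a random starting fold, so every fold holds ~10% of each
family. Validation phenotypes are masked rather than their rows removed, so
design factors remain estimable. Predictive ability (PA) is the
within-fold Pearson correlation between predicted breeding values and
adjusted phenotypes $y^*$, averaged over the 100 cells; predictive
accuracy is $PACC = PA/\sqrt{h^2}$ using the full-data single-trait GBLUP
heritability for every model type, including the ordinal one — with the
consequence, accepted here, that PACC can exceed 1 when $h^2$ is
underestimated.

The missing-data experiment asks whether genetically correlated,
fully-phenotyped indicator traits can rescue the prediction of a target
trait measured on only a subset of trees. The trees are partitioned into
family-stratified validation folds; each replicate withholds one fold for
*all* traits and masks a fraction (0-90%) of the remaining training trees'
target records at random. Two design choices matter here:

* Variance components for every model are estimated per fold on that fold's
  training trees only, warm-started from a full-data fit, and then held
  fixed across masking fractions. Estimating them on the full data would
  let the validation trees' records leak into the genetic-correlation
  estimate and visibly inflate multi-trait accuracy — the effect is large
  enough to manufacture spurious "gains" from an uncorrelated indicator.
  Holding them fixed across masks is justified because masking is
  completely at random.
* Validation trees are withheld for indicator traits too. Keeping their
  indicator records in the model would already lift multi-trait accuracy at
  0% missingness, a pattern the across-model comparisons are designed to
  exclude.

Masks are re-sampled independently per replicate (whether the original
analysis re-used CV folds for its 100 repetitions is not documented; the
independent choice is the more conservative one).

## Selection indices and genetic gains

The ordinal attack phenotype is assembled from survey flags as
$CWA = WA_{prev10} + WA_{cur10} + WA_{11\text{-}14} + WA_{cur15}$, where
the derived flag $WA_{11\text{-}14}$ is set only when an attack before the
age-15 survey cannot be one already counted at or before age 10.

A selection index over four traits scales each trait's breeding values to
unit variance and combines them as
$SI = w_1\,\mathrm{Height} - w_2\,\mathrm{CWA} + w_3\,\mathrm{Velocity} +
w_4\,\mathrm{Density}$, the negative sign encoding that fewer attacks is an
improvement, with $w_i \ge 0$, $\sum w_i = 1$. The weight simplex is
enumerated on a 0.05 lattice — exactly $\binom{23}{3} = 1771$ indices.
Percentage gains divide mean raw-scale breeding values of the selected top
5% by the across-site phenotypic mean (so the index itself is
scale-invariant but the reported gains are on the measurement scale);
"maximise total relative gain" searches are implemented as the arg-max of
the plain sum of the named traits' relative gains over the lattice, the
simplest reading of that objective. Ties in top-k selection break by tree
id, making selections deterministic.

## The synthetic-data generator

Because progeny-trial phenotypes of this kind are not publicly deposited,
every analysis stage is exercised on simulated populations built to have
the structure the models assume:

* a partial diallel (default 35 parents, 40 families × 18 offspring, every
  parent used, ~2.3 crosses per parent), gene-dropped genotypes at
  unlinked loci with founder MAFs uniform on a configured range;
* per-locus additive effects drawn multivariate-normal across traits with a
  configurable genetic correlation matrix (all loci, or `n_qtl` loci for
  oligogenic architectures), rescaled so realised additive variances hit
  the target $h^2$ exactly;
* GxE as independent site-specific marker-effect deviations scaled so
  $\sigma^2_a/(\sigma^2_a+\sigma^2_{sa}) = r_B$, which induces the
  compound-symmetry across-site structure the animal model fits;
* i.i.d. normal block effects, unit $\sigma^2_a+\sigma^2_{sa}+\sigma^2_e$
  per trait, and ordinal traits generated by cutting the gaussian liability
  at configured thresholds (defaults chosen so the four attack categories
  have frequencies near 0.42/0.39/0.15/0.04, matching a moderately attacked
  trial with ~45% of trees never attacked).

The default trait set mirrors the study system: height-like and
height/diameter-ratio-like growth traits ($h^2 \approx 0.2$,
$r_B \approx 0.5$), velocity- and density-like wood traits
($h^2 \approx 0.26\text{-}0.29$, $r_B = 0.76$) and an ordinal attack trait
($h^2 = 0.27$, $r_B = 0.86$), with an additive correlation matrix in which
the attack count is strongly negatively correlated with the
height/diameter ratio (−0.88) and moderately with height (−0.65) and
velocity (−0.55). An optional block-LD mode generates markers in haplotype
blocks of near-copies transmitted without recombination, solely to exercise
the LD-kNN imputation; the analysis models never use linkage information.

What the generator does *not* emulate: linkage maps and recombination,
spatial autocorrelation of residuals, within-block row-plot effects,
mortality-driven imbalance, selection over generations, and genotyping
error beyond missingness. Passing parameter-recovery tests on these
simulations therefore demonstrates that the estimators are correct for the
assumed model, not that the model is adequate for any particular field
dataset. One realistic feature the design does induce is the large
sampling variance of genetic correlations — with ~35 effective parents a
dataset's realised trait-trait BV correlation wanders ±0.15 or so around
its target, which is why correlation-recovery checks average over many
simulated populations and why per-dataset "null indicator" controls are
noisy.

## Numerical details worth knowing

* Relationship kernels are ridged by $10^{-8}$-scale jitter only if a
  Cholesky fails; $A$ is PSD by construction and $G$ is PSD whenever
  markers outnumber trees.
* SNP QC keeps a marker when call rate ≥ 0.90, MAF ≥ 0.005 and
  $|F_{IS}| = |1 - H_{obs}/H_{exp}| < 0.5$ with $H_{exp} = 2p(1-p)$ from
  sample frequencies; monomorphic markers fail the MAF rule (their
  $F_{IS}$ is undefined).
* The LD-kNN imputation is a deliberately simplified restatement of the
  published LD-kNNi idea: plurality vote of the k = 5 nearest neighbours in
  an $r^2$-weighted Manhattan metric over the 20 most-correlated markers,
  with mean-dosage fallback when neighbours are lacking. On block-LD
  simulations it recovers ≥ 75-90% of masked calls; the published tool
  reports ~0.83 on a real array, so this is in a realistic range, but no
  equivalence with that tool is claimed.
* Pedigree verification flags a tree when its mean $|G - A|$ against
  recorded first-degree relatives ($A \ge 0.5$) exceeds 0.35. The threshold
  sits roughly halfway between the Mendelian-sampling noise of true
  relatives (~0.1) and the ~0.5 discordance of a mislabelled tree, and
  yields essentially zero false flags on clean simulations; the original
  analysis does not state its operational rule, so this one is documented
  as the package's own.
* Top-k selection, fold dealing and all simulation steps take explicit
  seeds; nothing reads or leaves behind global RNG state.

## Problem sizes used by the test-suite

The acceptance-style tests run the full design scale (720 offspring, 2,000
markers) where a single fit is checked, 50 simulated populations for the
parameter-recovery coverage checks, four populations × 10 replicates for
the missing-data pattern, and reduced Gibbs chains (3,000-6,000
iterations); these sizes were chosen so the whole suite completes on a
laptop-class single core while leaving the Monte-Carlo error well inside
each check's tolerance.

## Known limitations

Dominance and epistasis are not modelled (the source analyses found no
dominance signal); residual variances are homogeneous across sites;
multi-trait fits are limited to three traits (beyond that, convergence of
unstructured correlation matrices on 40-family data is unrealistic);
threshold-model fits require every ordinal category to be observed;
and the H-matrix (single-step) blending of pedigree and genomic
information is out of scope.
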