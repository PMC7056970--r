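---
title: "Multi-trait genomic prediction for multi-environment barley trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genomic prediction for multi-environment barley trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtgblup)
```

## The problem

Malting barley breeders score two kinds of traits: agronomic traits (grain
yield, grains per square meter, thousand grain weight, plumpness) measured in
every trial, and malting quality traits (beta-glucan, malt extract, soluble
nitrogen, grain protein) that are destructive and expensive, so they are
measured on far fewer samples. The two groups are genetically correlated.
Multi-trait genomic prediction exploits those correlations: a line never
phenotyped for malt extract, but genotyped and phenotyped for the cheap
traits, can borrow information through the genetic covariance.

`mtgblup` implements that workflow end to end for connected biparental
doubled-haploid (DH) populations:

1. `simulate` — a DH study generator with known genetic truth;
2. `pheno` — plot-level mixed models: genotype BLUEs, variance components,
   Cullis heritability, trait correlations and PCA;
3. `gmatrix` — SNP QC and the VanRaden realized additive relationship matrix;
4. `st_model` / `mt_model` — single- and multi-trait Bayesian GBLUP by Gibbs
   sampling;
5. `crossval` — CV1/CV2 comparisons of trait-set strategies, and prediction
   into un-phenotyped environments.

## Models

### Plot-level phenotypic model

For one trait, plot records follow

$$y_{ijkl} = \mu + E_i + B_{j(i)} + G_k + GE_{ik} + e_{ijkl},$$

with environment (location-year) $E$, block nested in environment $B$,
genotype $G$, genotype-by-environment interaction $GE$ and residual $e$.
`fit_blues()` treats genotype as fixed and the rest as random, estimating
variance components by EM-REML on Henderson's mixed-model equations; a
single-environment scope drops the $E$ and $GE$ terms. The EM form was
chosen over average-information REML because its updates keep every
component non-negative and increase the restricted likelihood monotonically
— slow near the optimum but dependable at desk scale (convergence: relative
log-likelihood change below 1e-8, at most 500 iterations; components are
floored at 1e-10 rather than allowed to go negative). `fit_h2()` refits the
same model with genotype random and reports the Cullis heritability

$$H^2 = 1 - \frac{\bar v_{BLUP}}{2\sigma^2_g},$$

where $\bar v_{BLUP}$ is the mean pairwise prediction-error variance of the
genotype BLUPs, read off the inverse coefficient matrix, and the result is
clamped to $[0,1]$. This definition is robust to the unbalanced augmented
designs the package simulates, where line-mean formulas are ill-defined.

### Genomic models

Markers coded $\{-1,0,+1\}$ pass QC (call rate $\ge$ 0.95, MAF $\ge$ 0.05
— a marker at exactly the threshold is kept, the removal rule is strictly
"below" — and a chromosome assignment), are re-oriented so $-1$ is the minor
allele, and yield the VanRaden method-1 kinship
$K = WW'/(2\sum_k p_k(1-p_k))$ with per-marker mean imputation and centering.
For fully inbred DH material the mean diagonal of $K$ sits near
$1+f = 2$. A fixed diagonal jitter of 1e-6 is added only when the smallest
eigenvalue is negative, and is recorded in the object, because the samplers
factorize $K$.

The single-trait model is GBLUP in its kinship parameterization,
$y = 1\mu + u + e$, $u \sim N(0, K\sigma^2_g)$: the equivalent marker-ridge
form is not implemented separately since the multi-trait model requires the
$K$ form anyway. The Gibbs sampler rotates once into the eigenbasis of $K$,
after which every conditional update is diagonal; variances get
scaled-inverse-chi-squared updates (prior df 5, prior scales splitting the
phenotypic variance evenly between genetic and residual, the genetic scale
divided by the mean diagonal of $K$); the intercept is flat-prior. Lines in
$K$ without phenotypes are drawn each iteration from their exact conditional
normal given the phenotyped lines' effects, so their posterior means are
genuine predictions, not plug-ins. Optional per-observation weights
(e.g. $1/\mathrm{se}^2$ of a BLUE) switch the update to a general Cholesky
path.

The multi-trait model stacks $t$ traits with
$\mathrm{vec}(U) \sim MVN(0, \Sigma \otimes K)$ and independent residuals
per trait ($R$ diagonal). Keeping $R$ diagonal means any advantage of the
multi-trait fit is attributable to the genetic covariance $\Sigma$ alone.
Per iteration the sampler (a) imputes every missing phenotype from its
conditional normal, (b) updates all genetic values jointly across traits in
the eigenbasis of $K$ — the $t \times t$ solves for all $n$ eigencomponents
are batched through one simultaneous diagonalization of $\Sigma$ against
$R$, so an iteration is a handful of dense matrix products, (c) draws
$\Sigma$ from its inverse-Wishart conditional (prior df $t+2$, scale half
the phenotypic variances on the diagonal), (d) draws each residual variance,
(e) draws the intercepts. Defaults are 1,500 burn-in iterations of 3,000
total, one chain, no thinning. Imputed phenotypes are accumulated
Rao-Blackwellized (the conditional mean $\mu + U$ of each draw rather than
the noisy draw itself), which cuts Monte Carlo error in the predictions at
no cost.

Missing-data augmentation is what makes the cross-validation schemes pure
masking patterns: CV1 masks every trait of a test line (a new, un-phenotyped
line), CV2 masks only the target trait (a partially phenotyped line whose
correlated records stay in the likelihood). For a single-trait strategy CV1
and CV2 coincide by construction. Predictive ability $r_{PA}$ is the Pearson
correlation between predicted genetic values and the held-out BLUEs of the
test lines. Partitions (60% training by default, 100 repeats by default) are
derived deterministically from one seed, and one partition list can be
shared across strategies and schemes so model comparisons are paired rather
than confounded with partition noise.

Prediction into an un-phenotyped environment stacks each
(trait, source-environment) BLUE as its own variable of the multi-trait
model, with the target trait in the target environment as the scored
variable; leave-one-location-out and leave-one-year-out groupings are
expressed by choosing the source environments.

### Posterior summaries

Genetic covariances are reported as posterior means. Genetic correlations
are summarized by `genetic_correlation()`, a Fisher-z average over the
retained draws: correlation posteriors are skewed near the boundaries, and
the z-scale average (close to the posterior median) drifts less toward zero
than the correlation of the posterior-mean covariance matrix. At moderate
information (300 lines, $h^2$ = 0.5) the residual attenuation of this
summary is about $-0.03$ to $-0.04$ at a true correlation of 0.7; users
comparing correlations across fits should keep that shrinkage in mind.

## The synthetic-data generator

No plot-level data or genotypes from the motivating study are public, so the
package ships a generator whose defaults emulate that study's design: 145 DH
lines in four connected crosses of five parents (33/39/45/28 lines), ~6.5k
uniformly spaced SNPs on seven 150 cM chromosomes, eight traits whose
genetic correlation matrix reproduces the study's structure (a
yield-component block dominating PC1, a malting-quality block on PC2, yield
trading off against protein), nine environments, two blocks, eight
replicated check lines in an augmented design, and strong GEI for agronomic
traits (GEI-to-genotype variance ratio 2) versus weak GEI for quality traits
(ratio 0.5). Every default can be overridden.

Mechanics: parents are independent fully homozygous haplotypes with allele
frequency 0.5 (the real parents' haplotypes are unavailable); families come
from a chain crossing scheme so the population is connected; each DH line is
one recombinant gamete of its family's F1 doubled to homozygosity, with
recombination under the Haldane map function (no interference), which keeps
the recombinant fraction between any two markers in closed form for testing.
Genetic covariance is induced through marker effects — per marker
multivariate normal across traits with covariance $\Sigma_g / m_\mathrm{eff}$,
$m_\mathrm{eff} = \sum_k 4 p_k (1-p_k)$ being the summed genotype variance on
the inbred $\pm1$ scale — so that marker-based kinship estimation is
exercised end to end. GEI deviations are independent normals per line and
environment; no structured GEI is modeled.

What the generator does *not* reproduce: real allele-frequency spectra and
map densities, linkage phase with selection history, epistasis or dominance
(DH lines are homozygous), spatial field trend, and structured GEI. Passing
tests therefore demonstrate correctness of the estimators under the stated
generative model, not performance on any particular real data set.

One property of connected-family simulation deserves emphasis: within
biparental families markers share long-range LD, so the *realized* genetic
covariance of marker-derived breeding values fluctuates with the number of
independent chromosome segments (tens), not the marker count (thousands).
A single simulated data set can realize a genetic correlation 0.2 away from
the requested one. Where a test or benchmark needs the correlation pinned —
parameter recovery, the CV1/CV2 comparisons — breeding values are drawn
directly from $MVN(0, \Sigma \otimes K)$, the exact covariance the samplers
assume; the marker-effect route remains the default for end-to-end runs.

## Benchmark problem sizes

The package's own checks run at desk scale, chosen to finish in minutes on
one core while leaving clear margins on every tolerance: the closed-form
BLUP cross-check at 100 lines; sampler-versus-oracle equivalence at 30 lines
and two traits (long chain, 20k iterations, since the tolerance is 2% of a
standard deviation); correlation recovery at 300 lines in 60 families of 5
(that structure maximizes the number of independent founder contrasts, which
is what pins the realized correlation of a draw); heritability recovery at
120 lines, 3 environments, 20 replicates per target; and the CV1/CV2
comparison at 300 lines in 50 families of 6, with 20 train/test repeats
spread over 10 independently simulated panels — spreading repeats across
panels shrinks the dominant, data-set-level Monte Carlo noise. For the CV
benchmark the panel of many small families was chosen (over the study's four
large families, which at n = 300 make genomic prediction so accurate that a
correlated helper trait has little left to add) to keep baseline accuracy in
the modest range where multi-trait prediction earns its keep; it is the
regime — many small crosses — typical of an early-generation breeding
program.

## Known limitations

- EM-REML converges slowly when a variance component sits near zero; the
  iteration cap (500) is then reached and flagged rather than erroring.
- The multi-trait sampler estimates an unstructured $\Sigma$; with many
  traits and few lines the inverse-Wishart conditional is weakly identified,
  and genetic correlations shrink toward zero at low information.
- No factor-analytic $\Sigma$, no residual covariances between traits, no
  three-way trait-by-environment Kronecker model: environment prediction is
  handled by variable stacking instead.
- $r_{PA}$ is reported as a raw correlation, not divided by $\sqrt{H^2}$.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 11)           # the 145-line, 8-trait default study
study <- simulate_study(cfg)

markers <- qc_filter(study$markers)
K <- additive_relationship(markers)

blues <- do.call(rbind, lapply(DEFAULT_TRAITS, function(tr)
  fit_blues(study$plots, tr)$blues))

sets <- build_trait_sets(blues, target = "GPC")
sch <- cv_scheme("CV2", n_repeats = 20, seed = 7)
res <- run_cv(blues, K, sets$`A+M`, sch, gibbs_config(seed = 3))
res$summary
```
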