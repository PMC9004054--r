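---
title: "Multi-trait Bayesian genomic prediction for augmented wheat trials"
author: "MultiTraitGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait Bayesian genomic prediction for augmented wheat trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MultiTraitGP)
```

## The problem

Complex agronomic traits of wheat — grain yield (GY), harvest index (HI),
grain number (GN), spike partitioning index (SPI), fruiting efficiency (FE) —
are expensive to phenotype and have modest heritability, which caps the
accuracy of genomic selection. Physiological traits such as canopy
temperature (CT) and the normalized difference vegetation index (NDVI) are
cheap to measure at scale, genetically correlated with the yield complex, and
often more heritable. A multi-trait (MT) genomic prediction model can borrow
information from such secondary traits; whether it actually helps depends on
*when* the secondary phenotypes are available:

* **CV1** — test lines have genotypes only. The secondary traits are observed
  on the training lines alone.
* **CV2** — test lines additionally have secondary-trait phenotypes; only the
  primary trait is unobserved on them.

This package implements the full workflow on which such a comparison rests:
plot-level phenotype adjustment for augmented multi-environment trials,
genomic relationship matrices from coded SNPs, single-trait (ST) and
multi-trait Gibbs samplers, the ST-CV1 / MT-CV1 / MT-CV2 cross-validation
comparison, and a synthetic-data generator with known ground truth so every
stage can be tested quantitatively.

## Phenotype adjustment

Trials follow an augmented design: unreplicated test entries plus repeated
check varieties (three by default) in every block. Adjusted genotype means
(BLUEs) are computed per environment from

$$Y_{ijkl} = \mu + \mathrm{Block}_i + \mathrm{IDCheck}_j + \mathrm{Gen}_k +
\mathrm{Check}_l + \beta\,x + \varepsilon_{ijkl}$$

and across environments from the same fixed terms plus environment and all
by-environment interactions, with blocks nested in environments. Genotype,
check, check-group (IDCheck), environment and the days-to-anthesis covariate
$x$ are fixed; blocks and every interaction with environment are random. The
model is deliberately fixed-genotype — a BLUE, not a BLUP — so the adjusted
means carry no genomic shrinkage into the prediction stage. Fitting is REML
via `lme4`; the covariate is centred internally, so adding a constant to all
anthesis dates provably changes nothing. The IDCheck/Check/Gen coding is
structurally rank-deficient (the check group is the complement of the
entries); the fit drops the redundant column, and the package raises an error
only if a *test entry's* effect is aliased.

Broad-sense heritability on an entry-mean basis is

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{G\times E}/n +
\sigma^2_e/(nr)},$$

with $n$ environments and $r$ replications per environment ($r = 1$ for an
augmented design). Variance components for $H^2$ come from an all-random
REML fit; REML on the variance scale keeps them non-negative, so no
truncation rule is needed.

## The prediction models

**Single trait.** $y = \mu + \alpha + \varepsilon$ with
$\alpha \sim N(0, K\sigma^2_g)$ and $\varepsilon \sim N(0, I\sigma^2_e)$,
where $K$ is the VanRaden additive relationship matrix
$K = WW^\top / \sum_j 2f_j(1-f_j)$ built from column-centred $-1/0/+1$ codes.
This is the kinship parameterization of genomic ridge regression: with
$K = WW^\top/c$ the two forms are equivalent, and the kinship form lets the
sampler work in the eigenbasis $K = UDU^\top$ where every update is diagonal.

**Multi trait.** Stacked over $t$ traits,
$\alpha \sim MVN(0, \Sigma \otimes K)$ and
$\varepsilon \sim MVN(0, R \otimes I)$, with $\Sigma$ an unstructured genetic
covariance and $R$ diagonal. In the eigenbasis the genetic-value update
factorizes into one $t \times t$ solve per eigen-coordinate, so a full
iteration costs $O(nt^2 + nt\cdot t)$ after a single eigendecomposition.
$\Sigma$ has an inverse-Wishart full conditional; the diagonal of $R$ has
scaled-inverse-$\chi^2$ conditionals. Missing phenotype cells — arbitrary
patterns, which is what CV2 needs — are data-augmented each iteration from
their conditional normal given the current parameters. Both samplers run
2000 burn-in and 12,000 total iterations by default, without thinning, and
are implemented in C++ driven by R's RNG, so a seed reproduces a chain
bit-for-bit.

### Priors

All scalar variances ($\sigma^2_g$, $\sigma^2_e$, the diagonal of $R$) use
scaled-inverse-$\chi^2$ priors with 5 degrees of freedom and scale chosen so
the prior mode is half the observed trait variance. $\Sigma$ uses an
inverse-Wishart with $t + 3$ degrees of freedom and scale
$(\nu + t + 1)\cdot \tfrac12\,\mathrm{diag}(\widehat{var}(y_j))$, i.e. the
prior *mode* of each diagonal is also half the trait variance. Matching the
modes this way is deliberate: it makes the $t = 1$ multi-trait model
coincide with the single-trait model (we verified the two samplers then agree
to Monte-Carlo error on the same data), so any MT-vs-ST difference in the
cross-validation comparison reflects the traits, not an accidental prior
asymmetry. The degrees of freedom are exposed in `gibbsConfig()`.

### Diagnostics

Each fit computes an effective sample size and a Geweke-style stationarity
z-score per variance component (and for the data log-likelihood chain) and
warns — never fails — on poor mixing. A test hook (`fixSigma2G`,
`fixSigma2E`) freezes the variances so the genetic-value chain can be checked
against the closed-form mixed-model solution
$K(K + \lambda I)^{-1}(y - \hat\mu)$; the test suite does exactly that, with
per-coordinate Monte-Carlo standard errors from batch means.

## Cross-validation

`makeSplits()` draws independent uniform 70/30 partitions (165 training / 71
test lines for a 236-line panel); the same splits are shared across ST-CV1,
MT-CV1 and MT-CV2 so scheme comparisons are paired, which removes most of the
split-to-split noise. Per replicate the held-out cells are masked *before*
fitting — a property the suite audits by corrupting held-out values and
asserting bit-identical predictions — and predictive ability is the Pearson
correlation between held-out BLUEs and predictions on the test lines,
averaged over replicates (replicates with undefined correlations are excluded
and counted, never zero-filled). Replicate chains get seeds derived
deterministically from the global seed and replicate index. The headline
comparison is `percentIncrease()`:
$100(\bar r_{MT\text{-}CV2} - \bar r_{ST\text{-}CV1})/\bar r_{ST\text{-}CV1}$.

## The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture. It
emulates the statistical structure of a 236-line soft-wheat panel:

* markers: per-SNP minor allele frequencies uniform on an interval (default
  $[0.05, 0.5]$), Hardy–Weinberg genotypes coded $-1/0/+1$, optional missing
  calls; 27,466 SNPs at paper scale, 2,000 in the demo profile (the demo
  sizes keep a laptop run in minutes while preserving $p > n$);
* breeding values: $MVN(0, \Sigma_{true} \otimes K_{true})$ on the realized
  kinship of the simulated markers — the infinitesimal model the GS methods
  themselves assume, which makes parameter recovery a fair test;
* plots: overall mean + environment effect + block effect + breeding value +
  an independent per-(genotype, environment) G×E draw + a genotype-level
  anthesis-date covariate effect + residual. Checks receive marker rows and
  breeding values too, so kinship includes them, but only test entries enter
  prediction;
* calibration: residual variances are solved from the requested
  heritabilities through the $H^2$ formula, so the target $h^2$ is exact for
  the design at hand, and `SimTruth` stores every component (the stored
  heritabilities are recomputable from the stored variances — a validity
  check enforces it).

Default trait parameters follow the study panel: seven traits (HI, GY, GN,
SPI, FE, NDVI, CT) with heritabilities 0.38, 0.34, 0.28, 0.26, 0.25, 0.64,
0.37 and a genetic-correlation matrix patterned on the observed
combined-dataset correlations (NDVI positive, CT negative with the yield
complex), projected to the nearest positive-definite correlation matrix.
Replication is $r = 1$ (augmented design); $r$ is exposed as a parameter.

### What the generator does *not* emulate

Simulated lines are unrelated and markers are in linkage equilibrium. Real
GBS panels have family structure and extensive LD, which concentrate $K$'s
spectrum and make the genetic/residual variance partition far better
identified than in this synthetic worst case. Concretely: at $n = 236$,
$p = 2000$ i.i.d. markers, the marginal likelihood of $(\sigma^2_g,
\sigma^2_e)$ is nearly flat along the partition, so *any* correctly computed
posterior mean of $h^2$ — we checked against an exact two-dimensional grid
integration — is pulled toward the middle of $(0,1)$ regardless of prior.
Genetic covariances (off-diagonals of $\Sigma$) remain well identified
because $R$ is diagonal, and *paired* cross-validation comparisons remain
valid because the dataset-level noise cancels. Passing tests on synthetic
data therefore demonstrate correctness of the machinery and of directional
claims, not that $h^2$ point estimates at this panel size are precise — on
real, LD-structured data they are considerably better behaved.

## Numerical choices

* Kinship: monomorphic markers are dropped (they carry no information and a
  monomorphic-only set is an error); if the smallest eigenvalue of $K$ falls
  below $-10^{-8}$, $(|\lambda_{min}| + 10^{-6})I$ is added, the event is
  reported and recorded in the object. The samplers require a
  `KinshipMatrix`, whose validity guarantees PSD.
* Imputation: per-marker mean by default (fractional codes are fine
  downstream); a k-nearest-lines variant (Euclidean distance on shared
  markers, neighbour mean rounded back to a legal code) approximates
  LD-based imputation without external software.
* Eigenvalues below $10^{-10}\lambda_{max}$ are treated as zero; their
  eigen-coordinates carry no genetic value and are excluded from variance
  updates.
* A non-positive-definite $\Sigma$ draw (numerically possible at small $t$
  and extreme scatter) is retried with a jittered scale matrix and the event
  is counted and reported.
* Demo problem sizes: 2,000 markers, 20 CV replicates, 500/3,000 iterations;
  outputs carry the profile label so scaled-down runs are never mistaken for
  protocol-scale ones (100 replicates, 2000/12,000 iterations, 27,466
  markers).

## Design choices that were genuinely open

* *Fixed vs random terms for BLUEs*: genotype must be fixed for a BLUE;
  blocks random is the standard augmented-design treatment. The
  per-environment model could defensibly take blocks fixed — with a single
  environment and few blocks the difference is small — but random blocks
  keep the per-environment and combined models consistent.
* *Checks in kinship and prediction*: checks contribute marker rows (their
  relationships stabilize $K$'s scale) but are excluded from GS panels and
  cross-validation; they are spatial controls, not selection candidates.
* *Which phenotypes anchor predictive ability*: the held-out BLUEs of the
  dataset being cross-validated — the only ground truth available on real
  data; on synthetic data the latent breeding values are also available and
  the unit tests use them where the sharper target is appropriate.
* *Predictions with or without intercept*: predictive ability is a
  correlation, so the intercept is irrelevant to the headline metric;
  `predict()` returns intercept + GEBV so values live on the trait scale.
* *ANOVA layout*: the mean-squares table tests genotype, environment and
  G×E against the residual from a sequential fixed-effects fit in which
  check replication supplies the residual degrees of freedom — the only
  residual an augmented design has.

## Limitations

* The MT sampler scales as $O(n t^2)$ per iteration after one
  eigendecomposition; panels far beyond $10^3$ lines or many traits would
  want a reformulation.
* No spatial field models beyond blocks, no dominance or epistatic kinships,
  no marker-effect (BayesA/B/LASSO) samplers — deliberately out of scope.
* Heritability point estimation on structure-free synthetic panels is
  prior-sensitive (see above); treat synthetic-data $h^2$ posteriors as
  diagnostics, not benchmarks.
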