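---
title: "Reference-free cell-mixture-adjusted EWAS with mixewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free cell-mixture-adjusted EWAS with mixewas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Epigenome-wide association studies (EWAS) regress per-CpG DNA methylation on
a trait of interest. In solid tissues, every specimen is a mixture of cell
types with distinct methylomes, and cell composition typically co-varies
with the traits one cares about (age above all). Composition is therefore a
confounder: a CpG whose methylation differs between cell types will appear
trait-associated whenever composition tracks the trait, even if no cell's
methylome changes. `mixewas` implements the standard reference-free remedy:
estimate latent cell-type methylomes and per-specimen proportions directly
from the methylation matrix, include the estimated proportions as model
covariates, and diagnose residual confounding with the difference between
unadjusted and adjusted effect estimates.

# The deconvolution model

Let $Y$ be the $m \times n$ matrix of beta values (methylation fractions in
$[0,1]$). The model is a convex variant of non-negative matrix
factorization,

$$ Y \approx M \Omega^\top, \qquad
   M \in [0,1]^{m \times K}, \qquad
   \Omega_{i\cdot} \in \Delta^{K-1}, $$

where the columns of $M$ are putative cell-type methylomes and each row of
$\Omega$ lies on the probability simplex (proportions of the $K$ putative
cell types in specimen $i$). `fit_mixture()` alternates two exact
constrained least-squares updates:

* each row of $\Omega$ solves a simplex-constrained quadratic program,
  solved exactly by enumerating support sets (cheap because $K$ is small,
  and vectorised across specimens because the KKT system is shared);
* each row of $M$ is updated by coordinate descent with clipping to
  $[0,1]$, which minimises each coordinate's convex quadratic exactly.

Both updates are monotone, so the recorded residual-sum-of-squares trace
never increases.

## Identifiability and the expansion phase

The factorization has an exactly fit-preserving family of deformations:
expand the methylomes about their centroid while shrinking all proportion
rows toward the uniform vector. When specimens are genuine interior
mixtures (no near-pure specimens), least squares alone cannot resolve where
along this family the truth lies — only the $[0,1]$ box on $M$ pins it
down, because real methylomes saturate near 0 and 1 at many CpGs.
`fit_mixture()` therefore starts with an *exploration phase* whose $M$
update carries a small away-from-centroid repulsion
($-\lambda\,\lVert M_{\cdot k} - \bar M \rVert^2$ with $\lambda$ a fraction,
default 0.1, of the smallest diagonal entry of $\Omega^\top\Omega$). The
repulsion drives the fit along the flat family until the box binds, after
which plain alternating least squares refines the solution; only the
refinement trace is reported as the objective. In simulations with
interior Dirichlet proportions this reduced the matched proportion error
roughly threefold relative to plain alternating least squares.

Components are canonicalised to descending mean proportion, which makes
"the component with the smallest proportion" (dropped from regression
designs to avoid collinearity with the intercept) well defined.

Initialisation is a deterministic farthest-point sweep over specimens
(start from the specimen farthest from the grand mean, greedily add the
specimen farthest from those already chosen), so the fit is invariant to
specimen order up to exact distance ties.

## Choosing the number of cell types

`select_k()` restricts to the most variable CpGs (default 10,000), draws
bootstrap resamples of specimens, fits every candidate $K$, and scores
out-of-bag specimens. Scoring splits the probes in half: out-of-bag
proportions are estimated from one half and the mean squared reconstruction
error is evaluated on the other half. Two biases motivate this definition:

* projecting and scoring on the *same* probes lets every surplus component
  absorb a little of the out-of-bag specimen's own noise, so the deviance
  curve keeps drifting down with $K$ and selection is biased upward;
* scoring fits must include the expansion phase — a shrunken fitted simplex
  stops short of the data extremes, and surplus components then mop up
  genuinely uncovered signal, which again inflates $K$.

With both in place, the mean bootstrap deviance is minimised at the true
$K$ in simulation (and at $K=1$ on structure-free noise); ties go to the
smaller $K$.

# Per-CpG models

Modelling uses M values, $\log_2 \beta/(1-\beta)$, clipped at
$\varepsilon = 10^{-6}$ — this keeps boundary betas finite without moving
interior values. Each CpG gets the same ordinary-least-squares design
(intercept, covariates, and optionally the $K-1$ largest-mean mixture
components); the covariate of interest's coefficient and standard error are
extracted, and residual variances are moderated with the standard
empirical-Bayes shrinkage: a scaled-inverse-chi-square prior whose
parameters $(d_0, s_0^2)$ are estimated by moment matching on the log
residual variances, giving the posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and a $t$-statistic with
$d_0 + d$ degrees of freedom. Setting $d_0 = 0$ recovers the ordinary $t$
exactly (this is tested); $d_0 = \infty$ pools all probes onto a common
variance. False-discovery control is Benjamini–Hochberg per covariate
across probes, with the significance threshold at $Q < 0.01$ by default.

The *delta coefficient* — the unadjusted minus the adjusted coefficient per
CpG — flags loci whose apparent association is carried by composition:
CpGs with cell-type-divergent methylomes acquire large deltas under
composition drift, cell-type-uniform CpGs do not.

# Mixture–covariate association

Whether composition tracks a covariate is tested per putative cell type
with a quasi-binomial (logit link) regression of the proportion on the
covariate, Wald inference with Pearson-residual dispersion (a dispersion
floor keeps perfectly separated fits defined; constant proportions return
$p = 1$ by convention). To avoid conditioning on one choice of $K$, the
minimum $p$ over all components and all $K$ in a grid is compared with its
permutation distribution: the covariate is permuted against the *fixed*
estimated proportions (the deconvolution never sees the covariate, so its
output is permutation-invariant — re-running it per permutation would only
add noise), and
$p_{\mathrm{perm}} = (1 + \#\{\min p_{\mathrm{perm}} \le \min p\})/(B+1)$.
The add-one form avoids zero p-values; $p_{\mathrm{perm}}$ is bounded below
by $1/(B+1)$.

# Region-set enrichment

Significant CpGs are split by coefficient sign (hypermethylating /
hypomethylating with the covariate) and each stratum is tested against
every region set with Fisher's exact test; the background is the full
analysis universe including the query, and q-values are computed across
sets within each direction. Odds ratios are the sample
$(ad)/(bc)$ with a normal-approximation CI on the log scale (0.5 continuity
correction only when a cell is zero). Probe positions are compared
directly against half-open intervals: a probe at position $p$ is inside
$[\mathrm{start}, \mathrm{end})$ iff
$\mathrm{start} \le p < \mathrm{end}$.

For progression contrasts the comparison set is an annotation-matched
background: a random CpG set, disjoint from the query, whose per-stratum
counts of the CpG-island relation equal the query's exactly. Tumor-vs-normal
status coefficients from age-adjusted moderated models at the query are
compared with those at the matched background by a two-sample
Kolmogorov–Smirnov test (exact for small samples). Coefficients, not
p-values, are the compared statistic: effect sizes are comparable across
sets of equal size, and the choice is made once and documented here. A
single matched resample is drawn by default; the sampling seed changes only
the background, never the query's differential table.

# Epigenetic clocks

Clocks are data, not code: a named coefficient vector over CpGs, an
intercept, and an invertible calibration transform (identity, or the
log-linear adult-age breakpoint form
$\mathrm{age} = (1+a)e^{\ell}-1$ for $\ell<0$,
$(1+a)\ell + a$ otherwise, with $a$ the adult-age parameter, default 20).
Published coefficient sets can be dropped in as TSV + JSON via
`read_clock()`; the package bundles none, keeping the repository
download-free, and all tests use synthetic clocks. A mitotic-rate-style
clock is the special case of uniform weights $1/p$ (the score is the mean
beta over the clock's CpG set). Age acceleration is the residual of
DNA-methylation age regressed on chronological age — positive residuals
mean the tissue looks epigenetically older than chronology predicts — and
is associated with risk factors by univariate and joint OLS.

# The synthetic-cohort generator

`simulate_cohort()` generates the structure the analysis assumes, with full
ground truth:

* **Methylomes.** A shared bimodal baseline (Beta(0.4, 0.4)) with a
  fraction of *cell-type-informative* probes (default 0.3) whose levels are
  drawn independently per cell type from Beta(0.3, 0.3). The informative
  probes are what make deconvolution identifiable.
* **Proportions.** Dirichlet draws (concentration 30) whose mean shifts
  linearly with age — component 1 gains, component $K$ loses — at `drift`
  per year (default 0.005, i.e. a shift of about 0.3 across the 18–82-year
  adult range, enough to make composition strongly age-associated).
* **Annotation.** The CpG-island relation is a deterministic function of
  baseline methylation — islands below 0.2, shores in [0.2, 0.5), shelves
  in [0.5, 0.8), open sea above — mirroring the real coupling between
  island context and methylation level. This coupling is load-bearing: it
  is what makes an island-matched background set comparable to an
  intermediate-methylation query in noise scale, exactly the property the
  matched-background resampling relies on in real data.
* **Planted age effects.** `n_age_cpgs` probes receive a linear M-scale
  trend of `slope` M-units/year on the bulk methylome, a fraction
  `hyper_fraction` (default 0.69) with positive sign. Planted probes are
  drawn from the shore/shelf strata: a linear M trend is not representable
  at saturated probes, and real age-drift CpGs concentrate at island
  shores. Effects act on the bulk mixture, consistent with age-related
  change that is largely independent of cell type.
* **Noise.** Gaussian on the beta scale (default sd 0.03), clipped to
  $[0,1]$. This is a deliberate simplification — real array noise is
  closer to Beta-distributed and heteroscedastic — and is adequate for
  recovery and calibration testing, not for emulating probe chemistry.

`simulate_region_sets()` plants one region set covering planted CpGs at a
higher rate (default 0.4) than the genomic background (default 0.1), so the
expected enrichment odds ratio is $(0.4/0.6)/(0.1/0.9) = 6$.
`simulate_tumor_normal()` redraws subjects from the same generative model
and adds, at planted CpGs only, an M-scale offset in the direction of the
probe's age slope, scaled as `(exaggeration - 1) * slope *
progression_years` (default 20 equivalent years): `exaggeration = 1` is an
exact null, larger values emulate tumors in which age-related changes are
further deregulated. `simulate_clock_cohort()` inverts a clock exactly — at
zero noise the predicted ages equal the targets to numerical precision.

What passing tests on these cohorts do **not** show: robustness to probe
chemistry (Infinium I/II) artifacts, batch effects, Beta-distributed noise,
correlated probes within islands, or real cell-type methylome geometry.
They do show that every stage recovers its own generative truth and that
the null calibrations (FDR, permutation, KS) hold.

# Numerical choices and degenerate inputs

* M-value clip $\varepsilon = 10^{-6}$; simplex feasibility tolerance
  $10^{-9}$ with a tiny ridge on the KKT systems; reconstruction entries
  bounded in $[-10^{-6}, 1+10^{-6}]$.
* `fit_mixture` convergence: relative RSS change below `tol` (default
  $10^{-6}$) within `max_iter` (default 300) refinement iterations;
  non-convergence returns the model with `converged = FALSE` and a
  warning rather than an error.
* $K = 1$ degenerates to the probe-mean methylome with all-ones
  proportions; constant proportions or covariates give $p = 1$ by
  convention in the quasi-binomial test; empty enrichment strata emit
  `"skipped"` records rather than disappearing.
* Ties in probe-variance ranking break lexicographically by probe id, so
  probe selection is deterministic and order-invariant.

# Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data at
sizes chosen to exercise the statistics while staying desk-scale: cohorts
of 40–100 specimens over 300–2000 CpGs, $K \le 5$, 50 bootstrap resamples
for model selection, 199 permutations for the min-P test, and 20–100
replicate seeds for the calibration and power properties. Full-fidelity
analyses of array-scale data (hundreds of thousands of probes, 1000
bootstraps/permutations) use the same code paths through the configuration
arguments.

# Known limitations

* Exhaustive support-set enumeration in the proportion solver scales as
  $2^K$; fine for the $K \le 12$ regime this method is used in, wrong tool
  beyond that.
* The method cannot name the cell types its components represent; they are
  putative, and interpretation requires external reference methylomes.
* Reference-based deconvolution, surrogate-variable adjustment,
  normalization from raw intensity files, and missing-beta imputation are
  out of scope; probes with missing values are dropped before modelling.
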