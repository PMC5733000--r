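---
title: "Covariance regression models for differential functional connectivity"
author: "hetconn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance regression models for differential functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetconn)
```

# Overview

`hetconn` compares functional connectivity between subject groups by
modeling the *covariance* of multivariate parcel timeseries as a function
of a design matrix.  Two complementary models are provided.  The
low-dimensional model parameterizes the group difference through a single
p-vector per design column and scales linearly in the number of parcels
p; it answers "which parcels move together differently between groups,
and with which sign pattern?".  The full model places a Wishart likelihood
on per-subject scatter matrices and scales quadratically; it answers
"which individual parcel pairs are differentially correlated?".

This vignette documents the models and their assumptions, the tunable
parameters and defaults, the sampler, the synthetic-data generator, the
numerical choices, and the limitations a user should know about.  It
states no empirical result beyond what the package's tests and
`scripts/acceptance.R` recompute.

# The low-dimensional model

For mean-centered observation vectors $y_i \in \mathbb{R}^p$ with design
rows $x_i \in \mathbb{R}^J$ (first entry 1; second entry 0 for the
reference group, 1 otherwise):

$$y_i = \gamma_i \, B x_i + \varepsilon_i, \qquad
\gamma_i \sim \mathcal{N}(0, 1), \qquad
\varepsilon_i \sim \mathcal{N}(0, \operatorname{diag}(\sigma^2)),$$

independently, giving
$\mathbb{E}(y_i y_i^\top) = (B x_i)(B x_i)^\top +
\operatorname{diag}(\sigma^2) = \Sigma_{x_i}$.

The scalar random effect $\gamma_i$ induces heteroscedasticity: all
parcels share one latent activation whose loading pattern $B x_i$ depends
on the design.  Two parcels with same-sign contrast coefficients are
positively correlated in the group difference, opposite signs negatively;
a zero coefficient means no differential co-activation.  Only moment
conditions are required of $\gamma_i$ and $\varepsilon_i$ for the
covariance identity; full Gaussianity is assumed to obtain a tractable
marginal likelihood, consistent with the covariance-regression lineage
the model descends from.

**Noise structure.** The noise covariance is per-parcel,
$\operatorname{diag}(\sigma_1^2, \dots, \sigma_p^2)$ (p free parameters).
A scalar variant $\sigma^2 I_p$ is available via
`fitLowDim(..., scalarSigma = TRUE)`; the per-parcel version is the
default because parcel signals have no common scale after ICA weighting.

**Priors.** Flat: uniform on $(-\infty, \infty)$ for each entry of $B$
and uniform on $(0, \infty)$ for each $\sigma_j$ (realized through a log
transform whose Jacobian is included in the posterior kernel).  These are
improper; with the informative likelihoods the model targets they pose no
sampling problem.  `prior = "weak"` switches to mildly regularizing
normals for ill-conditioned stress cases.

**Marginalization.** $\gamma_i$ is integrated out analytically rather
than sampled: $y_i \sim \mathcal{N}(0, \Sigma_{x_i})$ with a rank-one
plus diagonal covariance, evaluated with Sherman–Morrison and
determinant-lemma identities at $O(p)$ per observation
(`marginalLogLik()`).  This removes n latent parameters and improves
mixing; a numerical-integration check against the explicit
latent-variable density is part of the test suite.  Internally the
sampler groups observations by unique design rows and works from each
group's scatter matrix, so the per-iteration cost is independent of the
number of observations once the sufficient statistics are formed.

**Sign non-identifiability.** $B$ and $-B$ give the same covariance
function, so chains land on arbitrary column signs.  `alignSigns()`
multiplies each chain's column by the sign of its inner product with the
reference chain's mean column (the Frobenius-optimal choice from the
two-element sign group; a zero inner product keeps $+1$).  Alignment
never changes $|B|$ entries, $\sigma$ draws, or likelihood values, and
summaries refuse unaligned posteriors.

**Summaries.** `summarizeCoefficients()` reports per-parcel posterior
medians and credible intervals with endpoints at the $\alpha/m$ and
$1 - \alpha/m$ quantiles, where the Bonferroni divisor $m$ defaults to p
(for a 15-parcel analysis at $\alpha = 0.05$ the endpoints are the
$0.05/15$ and $1 - 0.05/15$ quantiles).  Intervals entirely below zero
form set 1, entirely above zero set 2, and intervals covering zero are
undecided.  The set labels are arbitrary — only the partition is
meaningful.

# The full Wishart model

Each subject contributes the scatter matrix $S_k = Y_k^\top Y_k$ of its
centered $N \times p$ timeseries (the raw cross-product, not divided by
N), modeled as

$$S_k \sim \text{Wishart}\!\left(x_k^{(1)} \Sigma^{(1)} +
x_k^{(2)} \Sigma^{(2)},\; \nu\right)$$

in the scale parameterization, i.e.
$\mathbb{E}(S_k) = \nu \, \Sigma_{x_k}$.  When the N rows are independent
the scatter of Gaussian rows with covariance $\Sigma$ is exactly
Wishart$(\Sigma, N)$, so $\nu$ concentrates near N; temporal dependence
deflates $\nu$ toward p, which is how this model absorbs autocorrelation
without thinning.  Because $\Sigma^{(m)}$ enters the scale, estimates of
$\Sigma^{(1)}$ correspond to the per-sample covariance times $N/\nu$;
recovery checks therefore compare $\nu \Sigma^{(1)}$ with
$N \Sigma_{\text{true}}$.

**Priors.** Each component is decomposed as
$\Sigma^{(m)} = \operatorname{diag}(\sigma^{(m)}) \, \Omega^{(m)} \,
\operatorname{diag}(\sigma^{(m)})$ with an LKJ$(\eta)$ prior on the
correlation matrix and flat priors on the scales; $\eta = 1$ (the
default) is uniform over valid correlation matrices, larger $\eta$
concentrates correlations near zero.  $\nu$ has a uniform prior on
$(p - 1, N - 1)$, with N taken as the minimum across subjects when they
differ (conservative; overridable via `nTimepoints`).

**Sampling parameterization.** The sampler works on unconstrained
Cholesky factors of $\Sigma^{(1)}$ and $\Sigma^{(2)}$ (log-diagonal, free
off-diagonal) and a logistic transform of $\nu$.  The LKJ-plus-flat-scale
prior is carried to $\Sigma$ coordinates by the exact change of
variables: for $\Sigma = D \Omega D$ the Jacobian is
$2^p \prod_i \sigma_i^p$, giving the kernel
$(\eta - 1)\log|\Omega| - p \sum_i \log \sigma_i$ up to constants, plus
the standard Cholesky Jacobian.  This avoids differentiating the
partial-correlation transform while remaining mathematically identical
to the $(\sigma, \Omega)$ formulation, and every reconstructed draw of
$\Sigma^{(m)}$ is positive definite by construction.  Draws are reported
as $(\sigma^{(m)}, \Omega^{(m)})$.

The design must have an all-ones intercept column and a {0, 1} contrast
column.  If no subject has $x^{(2)} = 1$ the model reduces to the
intercept-only form and $\Sigma^{(2)}$ is dropped (an unconstrained
component with a flat scale prior would have no stationary
distribution); designs with negative entries are rejected because the
scale combination must stay positive definite.

**Differential correlations and FDR.** For every pair,
$P_{ij} = |2 \Pr(\Omega^{(2)}_{ij} > 0) - 1|$, estimated by the fraction
of posterior draws strictly above zero (draws exactly zero count as
not-positive; the diagonal is undefined and stored as NA).  The selection
threshold $\lambda$ is found by grid search (0 to 0.999 in steps of
0.001, resolution chosen so the grid is never the binding constraint):
the smallest $\lambda$ whose posterior expected FDR

$$\text{FDR}_\lambda = \frac{\sum_{i<j} (1 - P_{ij})
\mathbb{1}(P_{ij} > \lambda)}{\sum_{i<j} \mathbb{1}(P_{ij} > \lambda)}$$

is at or below the target with a nonempty selection — smallest because
the selection only shrinks as $\lambda$ grows, so this maximizes
discoveries subject to the bound.  An empty selection is reported as a
distinguished result (`NA`), never as a number.  By construction
$\text{FDR}_\lambda < 1 - \lambda$ whenever the selection is nonempty.

**A calibration caveat.**  For a pair whose true differential correlation
is *exactly* zero, the posterior sign probability behaves like a
posterior p-value: as data accumulate, $P_{ij}$ for such a pair is
approximately uniform on (0, 1) rather than concentrated near 0.
Posterior expected FDR is therefore an honest summary of the posterior
but anti-conservative as a frequentist false-discovery-proportion bound
when most pairs are exact nulls.  In regimes with dense differential
structure — the regime this model targets — the realized FDP stays close
to the nominal level, and the package's tests exercise exactly that
regime (8 of 10 pairs coupled).  Users screening sparse effects should
treat small target FDRs as rankings rather than guarantees.

# Effective sample size and thinning

The low-dimensional model assumes exchangeable observation vectors, but
fMRI timeseries are autocorrelated.  Before fitting, each series is
thinned from N to the effective sample size

$$n = \min_{j = 1, \dots, p} \frac{N}{1 + 2 \sum_{t} \rho_j(t)},$$

the conservative component-wise minimum.  The infinite autocorrelation
sum is truncated by the Geyer initial-positive-sequence rule: consecutive
lag-pair sums $\rho_{2k-1} + \rho_{2k}$ are accumulated while positive
and the first non-positive pair stops the sum.  This is the standard
truncation in the MCMC literature; it avoids accumulating noise from
large lags without a tuning parameter.  A constant component has
undefined autocorrelation and is treated as perfectly dependent
(ESS 1); component ESS above N (negative autocorrelation) is clamped to
N because thinning cannot exceed the available points.  The default lag
cap is $\min(N - 1, 1000)$ — the Geyer rule almost always stops far
earlier, and the cap only bounds the autocovariance work on very long
series.

`thinSeries()` keeps n evenly spaced rows starting at the first time
point (indices $1 + \lfloor (k - 1) N / n \rfloor$), preserving coverage
of the run.  Across subjects, `studyEss()` takes the minimum subject-wise
ESS as the shared thinning count — the most conservative extension of the
component-wise minimum; with one recorded study ESS all subjects
contribute equal-length series.

**Residual correlation after thinning.**  Thinning an AR(1) series with
coefficient $\phi$ to its ESS spaces samples about
$(1 + \phi)/(1 - \phi)$ steps apart, leaving a lag-1 correlation of
roughly $\phi^{(1+\phi)/(1-\phi)}$.  This is below 0.1 only for mild
dependence ($\phi \lesssim 0.15$) and plateaus around 0.12–0.14 as
$\phi$ grows — ESS thinning reduces, but does not eliminate, serial
dependence.  The tests assert the sub-0.1 residual at $\phi = 0.1$ and a
0.2 bound at $\phi = 0.6$.

# The sampler

Both fitters use the package's Hamiltonian Monte Carlo sampler
(`R/hmc.R`) with analytic gradients, verified against finite differences
in the test suite.  Warmup is split into two dual-averaging windows
(target acceptance 0.8); a diagonal mass matrix is estimated from the
later half of the first window.  Sampling runs at the averaged step size
with the leapfrog trajectory length jittered uniformly over 8–16 steps.
A trajectory with a non-finite density/gradient or an energy error above
1000 is rejected and counted as a divergence; a divergence rate above 5%
is recorded as a warning in the fit's diagnostics, alongside split-
$\widehat{R}$ for $\sigma$, $|B|$ (and for aligned $B$ after
`alignSigns()`), or for $\nu$ and $\sigma^{(1)}$ in the full model.

Defaults mirror the reference analysis: 500 warmup steps, 500 retained
draws, 4 chains.  A seed is mandatory; chain and subject seeds are
derived from it with a multiplicative splitting scheme so runs are
reproducible and subjects independently regenerable.

Initial values are data-informed rather than diffuse: the low-dimensional
fitter starts from a crude rank-one decomposition of each group's sample
covariance with random column signs per chain; the full-model fitter
starts from moment estimates ($\hat{\nu}$ from the element-wise
mean–variance relation of the scatters, $\hat{\Sigma} = \bar{S}/\hat{\nu}$
projected to be safely positive definite), jittered per chain.  With flat
priors and informative likelihoods this placement matters mainly for
warmup length.

# The synthetic-data generator

`simulateLowDim()` draws data *exactly* from the low-dimensional model:
per subject, $y_t = \gamma_t B x_g + \varepsilon_t$ with the group's
design row, so with independent time points the per-group covariance is
exactly `expectedCovariance(B, x, sigma)`.  `simulateScatter()` draws
Gaussian rows with covariance $x^{(1)}\Sigma_1 + x^{(2)}\Sigma_2$ and
returns $Y^\top Y$, exactly Wishart with df N in the independent case.
`sampleLKJPrior()` implements the C-vine construction (partial
correlations from scaled Beta distributions), independent of the
sampler's parameterization, so prior behavior (uniformity at $\eta = 1$,
concentration for large $\eta$) can be checked against it.

Temporal dependence is added by AR(1)-filtering the latent $\gamma$
sequence and each noise component with coefficient $\phi$, scaling
innovations by $\sqrt{1 - \phi^2}$ so marginal variances — and hence
every $\Sigma_x$ — are unchanged.  This is a test construction for
exercising the ESS machinery, not a claim about fMRI noise: the generator
has no scanner drift, motion spikes, physiological confounds,
non-Gaussian tails, or spatial structure beyond the modeled covariance.
Passing tests therefore demonstrate correctness of the estimation
machinery under the models' own assumptions, not robustness to real
acquisition artifacts.

# The power analysis

`runPower()` measures the detection performance of the low-dimensional
analysis by repeated stratified subsampling: for each sample size, draw
subjects preserving the population group ratio (non-reference counts
rounded to the nearest integer), thin to the population's study-wide ESS,
fit, align, classify parcels at each significance level, and score
against the true parcel sets.  The ESS is computed once on the full
population rather than per subsample: recomputing the minimum-ESS rule
inside every subsample couples the thinning count to the subsample size
(one low-ESS subject appears in more large subsamples than small ones)
and can make measured power non-monotone for reasons unrelated to the
model.

Because set labels are non-identifiable, true positives take the maximum
over the two label matchings,
$\max(\text{TP}_{1122}, \text{TP}_{1221})$ with
$\text{TP}_{ijkl} = \#(Z_i^{\text{pred}} \cap Z_j^{\text{true}}) +
\#(Z_k^{\text{pred}} \cap Z_l^{\text{true}})$, and false positives the
minimum over matchings of the set differences.  The two optima are taken
independently — deliberately, following the metric's definition — even
though they may correspond to different matchings.  TPR divides by the
total number of true parcels; FDR by predicted positives, defined as 0
when nothing is predicted.

**Ground truth.**  For synthetic populations the truth is the sign
partition of the true contrast column (`signPartition()`).  For real
populations no external truth exists; the documented convention is the
parcel-set assignment of a fit on the entire population.

**Design conditions.**  The packaged power experiment (tests and
acceptance script) uses a 120-subject population (80 reference, 40
non-reference — the two-thirds/one-third ratio), p = 5, 80 time points
per subject with AR(1) coefficient 0.3, and *moderate* contrast effects
(0.4 times the strong-effect pattern used in the recovery checks).  With
fully strong effects the TPR curve saturates at 1 for every sample size
and curve-shape checks degenerate into tie-breaking noise; the moderate
effects place sample sizes 20–80 in the partial-power regime (roughly
50% power around 20–40 subjects), which is the informative operating
range for a power analysis.  Reduced sampler settings (2 chains,
300 + 300) keep the 30-fit experiment to a few minutes; replicate counts
default to 10 here (100 is the reference choice for production use).

# Numerical choices and degenerate inputs

- Symmetry/PSD tolerances: scatter matrices must be symmetric within
  1e-10 and have smallest eigenvalue above $-10^{-8}$ times the largest;
  model code re-symmetrizes matrix products to remove roundoff drift.
- Centering is per subject, per column, before any scatter or model step;
  column means after centering are zero to floating precision.
- `readTimeseries()` distinguishes ragged rows, non-numeric cells, empty
  files and single-row files with separate errors; full double precision
  round trips are exact well below 1e-12.
- Wishart fitting requires full-rank scatters (N ≥ p); a singular scatter
  is a hard error rather than a silent likelihood of $-\infty$.
- Tie-breaks: a zero inner product in sign alignment keeps $+1$; draws
  exactly at zero count as not-positive in $P_{ij}$; the FDR grid search
  returns $\lambda^* = 1$ with an empty report when no grid point
  qualifies.
- Constant timeseries components yield ESS 1 (perfect dependence), never
  a division error.
- All quantities reported by `scripts/acceptance.R` are computed at fixed
  problem sizes stated there (e.g. ESS at N = 20000; recovery at p = 5
  with 800 stacked observations or K = 100 scatters at N = 200; the power
  curve at sizes 20/40/80 with 10 replicates), chosen so the whole script
  runs in minutes on one core while keeping Monte Carlo noise well inside
  the tolerances it checks.

# Limitations

- The sampler is plain HMC with a diagonal mass matrix; for strongly
  correlated posteriors (large p in the full model — parameters grow as
  $p(p+1)$) mixing will degrade before the likelihood cost does.  The
  full model is intended for moderate p with many subjects.
- Flat improper priors assume informative likelihoods; tiny K or N can
  yield effectively improper posteriors.  Use `prior = "weak"` in the
  low-dimensional model for such stress cases.
- ESS thinning leaves residual dependence (see above) and discards data;
  the full model's $\nu$ mechanism is the alternative when that loss
  matters.
- Posterior expected FDR is not a frequentist FDP guarantee under sparse
  exact nulls (see the calibration caveat).
- The package deliberately contains no imaging I/O or preprocessing: it
  starts from delimited parcel timeseries.
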