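---
title: "Multivariate spatio-temporal P-splines for areal counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate spatio-temporal P-splines for areal counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mvpspline)
```

## The model and its assumptions

`mvpspline` estimates relative risks for `J` related outcomes counted on
`I` areas over `T` periods. Conditional on the risks, counts are Poisson,

$$O_{itj} \mid R_{itj} \sim \text{Poisson}(E_{itj} R_{itj}), \qquad
E_{itj} = n_{it} m_j,$$

with expected cases from indirect standardization (`m_j` the overall rate
of outcome `j`, so expected totals match observed totals per outcome by
construction). The log risk decomposes additively:

$$\log R_{itj} = \alpha_j + f_j(x_{1i}, x_{2i}) + f_j(x_{3t}) +
\delta_{itj}.$$

The assumptions worth stating plainly:

* **Poisson sampling given the latent field** — no extra-Poisson noise
  beyond what the interaction term absorbs;
* **complete panel** — a missing (area, period, outcome) cell is treated
  as an error, not as a zero, because the model is defined on the full
  grid;
* **centroids as covariates** — the spatial surface is a smooth function
  of the raw centroid coordinates (planar or geographic); no projection
  handling is attempted;
* **separability** — space and time enter as main effects plus an
  intrinsic interaction; there is no three-dimensional tensor smooth (the
  interaction is deliberately a CAR-type residual, cheaper and usually
  sufficient because it captures a small share of variability).

## Bases and penalties

The spatial basis is the row-wise Kronecker (box) product of marginal
B-spline bases for longitude and latitude, `B_s = B_2 □ B_1`
(`row_wise_kronecker()`), with the longitude index varying fastest. Each
marginal basis (`bspline_basis()`) uses **q equidistant knots spanning the
data range inclusive** plus `degree` extra knots appended on each side at
the same spacing, giving `q - 1 + degree` columns. This convention is
forced by dimension bookkeeping: cubic bases with 10 knots per spatial
margin give 12 columns (surface dimension 144) and 5 temporal knots give
7 columns — the configuration used by default. The equally spaced
exterior extension (never coincident boundary knots) keeps the
equidistant difference penalty meaningful near the boundary, so the
penalty retains its random-walk reading.

Coefficients are penalized by random-walk structure matrices
`P = D'D` (`penalty_matrix()`), order 1 or 2. The surface penalty is the
anisotropic Kronecker sum

$$P_s = \lambda_1 (I_{k_2} \otimes P_1) + \lambda_2 (P_2 \otimes I_{k_1}),$$

with `lambda2 = 1` fixed: once a between-outcome covariance multiplies the
whole penalty, only the ratio `lambda1/lambda2` is identifiable; the same
argument fixes the temporal `lambda3 = 1`. As a consequence the
`sigma_psi_j`, `sigma_gamma_j` "standard deviations" have no absolute
interpretation and are never reported — only the correlations
`rho_psi_jk`, `rho_gamma_jk` and risk functionals are exposed by the
summary API.

## Interactions and identifiability constraints

`interaction_structure()` builds the four intrinsic interaction
structures from `Q_T` (random-walk precision) and `Q_I` (ICAR graph
Laplacian): type I `I_{IT}`, II `Q_T ⊗ I_I`, III `I_T ⊗ Q_I`, IV
`Q_T ⊗ Q_I`, with ranks `IT`, `I(T-r)`, `(I-c)T`, `(I-c)(T-r)` for
random-walk order `r` and `c` graph components. Constraint rows exactly
spanning each structure's null space are generated per type: per-area
time sums (plus linear-in-time contrasts for RW2) for type II; per-period
area sums within each graph component for type III; both sets minus their
per-component overlap for type IV; none for type I. No between-outcome
covariance is placed on the interaction — it is a residual term, enforced
structurally.

Two constraint modes remove the confounding between intercepts and
smooth functions: `"center"` (default) forces `sum_i f_j = 0` and
`sum_t f_j = 0`; `"sumzero"` forces the coefficient sums to zero. Both
identify the same risks (the fitted `R_itj` agree to numerical
precision — an acceptance test verifies `< 1e-6` agreement), but
centering makes the smooth functions orthogonal to the intercept and
yields visibly narrower credible intervals for them, which is why it is
the default. One caveat discovered in testing: with a type II interaction
the temporal main effect and the interaction share the "common temporal
pattern with zero mean" directions, so their individual credible
intervals are wider than the risk intervals; this is a property of the
parameterization, not a defect.

## Hyperpriors, and where the Wishart sits

The between-outcome covariance matrices get Wishart priors with degrees
of freedom `2J + 1` (deliberately informative: some covariance scale
parameters are confounded with the fixed `lambda2`, `lambda3`) and scale
`sigma^2 I`, defaults `(sigma2_psi, sigma2_gamma) = (1, 10)`; larger
`sigma^2` is less informative. `1/sqrt(lambda1)` is uniform on `(0, 100)`
and the interaction standard deviations `1/sqrt(tau_j)` get improper
flat priors. Posterior propriety under these flat priors has, to our
knowledge, no formal proof; the samplers monitor for the symptoms
(unbounded drift, spiky hyperparameter marginals).

A design question with real consequences is whether the Wishart sits on
the **covariance** or the **precision**. The precision placement is
conjugate (Gibbs updates), and was tried first. It fails subtly: the
joint scale of `(lambda1, Sigma_psi)` lies on a near-flat ridge —
multiplying both by `c` changes the likelihood almost not at all — and a
precision-Wishart penalizes large `Sigma` only polynomially, so chains
drift to `lambda1` of order `10^8` while the covariance freezes. The
covariance placement has density `∝ exp(-tr(Sigma)/2sigma^2)`, an
**exponential** tail in large `Sigma` that anchors the ridge. The package
therefore defaults to the literal covariance-Wishart
(`wishart_mode = "covariance"`), updated by Metropolis–Hastings with the
conjugate pseudo-posterior as proposal; the precision mode remains
available for comparison.

## Inference

`fit_mcmc()` is the reference engine. Design choices:

* **Blocking follows the structure.** A single joint Newton proposal for
  the whole latent field is formally correct but its acceptance decays
  exponentially with the number of cells (third-order Poisson error
  accumulates; observed acceptance 0.04 at 600 cells). Instead the smooth
  components `(alpha, Psi, Gamma)` form one moderate block, and the
  interaction is updated in the exact conditional blocks its structure
  allows: per (area, outcome) for types I–II (time-coupled only), per
  (period, outcome) for type III, outcome-wise with Crank–Nicolson
  damping (`beta_typeIV`, default 0.5) for the non-separable type IV.
  Each block uses a one-step-Newton Gaussian proposal with full
  Metropolis–Hastings correction.
* **Constraints by conditioning by kriging** on every proposal; the
  proposal density is the constrained Gaussian (joint density divided by
  the density of the constraint functional), so the correction is exact.
  Retained draws satisfy `|A x| < 1e-8`.
* **Jitter is proposal-only.** A relative diagonal jitter (default
  `1e-8`) stabilizes factorization of the (rank-deficient before
  constraints) proposal precisions. Because the Metropolis ratio uses the
  same jittered proposal density on both sides, the *target* is not
  biased by the jitter.
* **Warm start.** The chain starts at the constrained IWLS mode with one
  conditional mode-update of the hyperparameters. This is not cosmetic:
  one-step-Newton proposals cannot make the long jump from a zero field,
  and a chain left at zero lets the hyperparameters collapse into the
  `lambda1` funnel described above.
* **Hyperparameter sweeps** (conjugate/MH covariance updates, gamma
  updates for `tau_j`, log-scale random walk for `lambda1`) are repeated
  three times per latent update — they are cheap and dominate the mixing
  of the correlation parameters.
* **Interweaving (ASIS).** The centered pair (coefficients given
  covariance, covariance given coefficients) mixes slowly through
  prior-dominated coefficient directions. An interweaved non-centered
  move proposes a new covariance and deterministically rescales the
  coefficient block so the standardized coefficients stay fixed; the
  intrinsic-prior normalizer cancels against the transformation Jacobian
  (exactly for first-order penalties; a known `|Sigma|` power corrects
  higher orders), leaving a likelihood × hyperprior × proposal ratio.
* **Rank-deficient log determinants** use generalized determinants from
  the marginal penalty eigenvalues; for `P_s(lambda1)` the eigenvalues
  are `lambda1 a + b` over marginal pairs, so the `lambda1` conditional
  is evaluated analytically.
* Defaults: 4 chains, 2000 warmup + 2000 retained, mandatory seed; the
  same seed and configuration reproduce a chain bit for bit. Split-R-hat
  and a basic autocorrelation ESS are reported for the hyperparameters
  and correlations; `R-hat > 1.1` triggers a warning.

`fit_gaussian_approx()` is the fast cross-check: constrained penalized
IWLS for the latent mode, alternated with conditional posterior-mean
(mode-plug-in) hyperparameter updates, then Gaussian intervals from the
curvature at the mode. It conditions on point estimates of the
hyperparameters and evaluates coefficient cross-products at the mode, so
it understates uncertainty; in the large-count regime its risk estimates
agree with MCMC medians within 2% (tested).

Posterior summaries use medians and equal-tailed 95% intervals with
linear-interpolation (type 7) sample quantiles — the interior quantile
convention is fixed here because published tables rarely state one.
Exceedance probabilities are fractions of draws above the threshold.

## Model-selection criteria

`dic()` computes `Dbar` (posterior mean deviance) and
`pD = Dbar - D(mu_bar)` with the **posterior mean of the Poisson means**
plugged in (predictor-scale plug-in, the convention of nested-Laplace
software; plugging in mean latent coefficients instead is available via
`plugin = "latent"`). `DIC = Dbar + pD` is an exact identity, verified on
published deviance summaries. `waic()` uses the standard
`lppd - p_waic` decomposition. `log_score()` estimates each cell's CPO by
the harmonic mean of per-draw likelihoods — retained deliberately, with
its known instability, because it is what the common toolchain computes —
stabilized by capping the inverse-likelihood weights at their 99.9th
percentile (capped counts are reported). `LS` is the negative **mean**
log CPO over cells: published magnitudes (≈ 3.9 for a panel of 1768
cells) identify the mean, not the sum. All three match
quadrature/exact-predictive oracles on a conjugate Poisson-gamma toy
model within 1% at 10^4 draws (acceptance criterion).

## The synthetic-data generator

`sample_latent()` draws coefficient blocks from the intrinsic priors by
eigendecomposition — variance `1/eigenvalue` on every non-null
eigendirection, zero on the null space, outcomes mixed by the upper
Cholesky factor of the between-outcome covariance — then projects the
stacked field onto the constraint null space. This gives exact control of
the null space on small bases, which a pseudo-inverse Cholesky would
blur. `sample_counts()` adds Poisson noise around `E * R`.

The registered scenario **S1** is a 5×5 rook grid, `T = 12`, `J = 2`,
spatial coefficient scale 0.5 with correlation 0.8, temporal scale 0.5
with correlation 0.6 (the temporal scale is not dictated by the scenario
definition; 0.5 was fixed once to match the spatial scale), `lambda1 = 1`,
interaction precisions 25, zero intercepts, populations 50 000 and rates
0.001 so `E ≈ 50` per cell — realistic for district-level annual crime
counts. The fitting specification uses 3 spatial knots (5 columns per
margin, a 25-column surface equal to the number of distinct locations)
and 5 temporal knots. The spatial basis size matters more than usual
here: a surface basis with more columns than areas leaves penalized
coefficient directions invisible to the data, and those directions feed a
slow three-way feedback between `lambda1`, `Sigma_psi` and the
uninformed coefficients that degrades both mixing and the
identifiability of `rho_psi`. Matching basis dimension to the number of
distinct locations removes the pathology.

What a green recovery test does establish: the whole pipeline —
generator, constraints, blocked MCMC, covariance updates — concentrates
the posterior of `rho_psi` near the generating value when the data carry
the information. What it does not establish: performance under model
misspecification (real data are not drawn from the model's own priors),
underreporting or reporting bias (deliberately not emulated), irregular
population structures, or scales much larger than the case-study size.
And a hard limit of the scenario itself: with 25 areas, the smooth
spatial fields have only a handful of effective degrees of freedom, so
the *realized* correlation of one draw scatters around the generating 0.8
with a standard deviation near 0.2 — per-replicate point recovery of
`rho_psi` is intrinsically noisy at this problem size, which is why the
credible-interval coverage criterion matters more than the point check.
The default test battery runs 3 replicates with short single chains
(seeds fixed in advance); the full 20-replicate battery is the same code
at nightly scale.

## Numerical choices and degenerate inputs

* Eigenvalue/rank tolerances: `1e-8` relative (structure matrices),
  `1e-9` for generator null spaces.
* A constant covariate is refused (`"degenerate covariate range"`);
  non-positive populations, negative counts, incomplete panels and
  duplicate records are errors at the door.
* Isolated areas are allowed (they add graph components; ICAR rank
  bookkeeping and per-component interaction constraints account for
  them).
* Ties in functional-boxplot depths break by curve order, making central
  region membership deterministic.
* The functional boxplot screens **posterior-median** risk trajectories
  per area (configurable input matrix); screening full posterior draws of
  trajectories would mix estimation noise into the band depth.
* Config hashing uses FNV-1a over the canonical JSON so artifacts are
  stamped reproducibly; manifests carry the only timestamps.

## Known limitations

* Run configurations are JSON only (no TOML parser among the
  dependencies).
* The Gaussian approximation's hyperparameter step is mode-plug-in, not
  a marginal-likelihood optimizer; it is a cross-check, not a substitute
  for MCMC.
* The harmonic-mean CPO estimator is noisy for extreme cells even with
  capping; treat per-cell CPOs qualitatively.
* `lambda1` (spatial anisotropy) is weakly identified on small regions;
  expect heavy-tailed posteriors. The covariance-Wishart default keeps
  this benign, but the parameter's posterior should not be
  over-interpreted.
* Posterior propriety under the flat interaction-scale priors is assumed,
  not proven.
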