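# mvpspline

Joint Bayesian smoothing of relative risks for **several correlated
outcomes** counted on a set of **areas over time** — the setting of
multivariate disease mapping and of district-level crime analysis, where
one wants smooth spatial risk surfaces, smooth temporal trends, area-
specific departures, and, crucially, the **correlations between the
spatial (and temporal) patterns of the different outcomes**.

## The model

Counts are Poisson with an offset of expected cases from indirect
standardization:

    O_itj | R_itj ~ Poisson(E_itj * R_itj),      E_itj = n_it * m_j
    log R_itj = alpha_j + f_j(x1_i, x2_i) + f_j(x3_t) + delta_itj

for area `i = 1..I`, time `t = 1..T`, outcome `j = 1..J`, where

* `f_j(x1, x2)` is a two-dimensional **P-spline surface** on the area
  centroids: the basis is the row-wise Kronecker (box) product
  `B_s = B_2 □ B_1` of marginal B-spline bases, with penalty
  `P_s = lambda1 (I ⊗ P_1) + (P_2 ⊗ I)`, `P_l = D_l' D_l` the structure
  matrix of a first- or second-order random walk;
* `f_j(x3)` is a one-dimensional temporal P-spline with penalty `P_3`;
* `delta_itj` is a space–time interaction with one of the four classical
  intrinsic structures (`I`: iid; `II`: `Q_T ⊗ I`; `III`: `I ⊗ Q_I`;
  `IV`: `Q_T ⊗ Q_I`), `Q_I` the ICAR graph Laplacian of the adjacency;
* stacking coefficients outcome-wise, the joint priors are
  `p(Psi) ∝ exp(-1/2 Psi' (Sigma_psi^{-1} ⊗ P_s) Psi)` and likewise for
  `Gamma` with `P_3`; the off-diagonal elements
  `(Sigma_psi)_jk = rho_jk sigma_j sigma_k` carry the **between-outcome
  correlations**, the identifiable and reportable quantities;
* hyperpriors: Wishart(`2J+1`, `sigma^2 I`) on the between-outcome
  covariance matrices, a uniform prior on `1/sqrt(lambda1)` truncated at
  100, flat priors on the interaction standard deviations.

Identifiability requires linear constraints (centering the smooth
functions, the default, or sum-to-zero coefficients) plus the standard
interaction constraints (e.g. per-area time sums for type II). Inference
is by constrained block MCMC — Gaussian one-step-Newton proposals with
Metropolis–Hastings correction, conditioning-by-kriging for the
constraints, conjugate/MH hyperparameter updates and interweaved
non-centered covariance moves — with a fast Gaussian approximation as a
cross-check. Model choice uses DIC, WAIC and the logarithmic score (CPO).

## Worked example

Simulate the registered scenario S1 (5×5 grid, 12 years, 2 outcomes with
spatial-coefficient correlation 0.8, expected counts ≈ 50 per cell), fit,
and summarize:

```r
library(mvpspline)
scen <- simulate_scenario("S1", seed = 3)
fit  <- fit_mcmc(scen$panel, scen$region, scen$spec,
                 n_chains = 1, n_iter = 500, n_warmup = 300,
                 seed = 3, quiet = TRUE)
summarize_samples(fit, c("rho_psi", "sigma_delta"))
```

```
   functional          name    median     lower     upper exceedance significant
1     rho_psi crimeA:crimeB 0.7626026 0.1651222 0.9498843         NA        TRUE
2 sigma_delta        crimeA 0.1857557 0.1579535 0.2137558         NA          NA
3 sigma_delta        crimeB 0.2010170 0.1733824 0.2351623         NA          NA
```

The posterior median of the spatial-coefficient correlation (0.76) sits
near the generating value 0.8 with a 95% interval excluding zero
(`significant = TRUE`); the interaction standard deviations recover the
generating value `1/sqrt(25) = 0.2`. Model criteria and risk surfaces:

```r
model_criteria(fit)          # Dbar, pD, DIC, WAIC, LS (DIC = Dbar + pD)
risk_surfaces(fit)$spatial   # exp(f_j) per area: median, CI, exceedance
fb <- functional_boxplot(risk_trend_curves(fit, "crimeA"))
fb$outliers                  # areas with outlying risk trajectories
```

A file-based pipeline (JSON configs) is available through
`cmd_simulate()`, `cmd_fit()`, `cmd_compare()` or the CLI entry point
`Rscript -e 'mvpspline::cli_main()' simulate config.json`.

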