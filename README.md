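# momentinfer

Moment-based parameter inference for stochastic chemical kinetics in R.

## The problem

Biochemical reaction networks in single cells are stochastic: molecule
counts `n = (n_1, ..., n_M)` in a reaction volume Ω evolve under the
chemical master equation (CME). Fitting CME models to data by exact
likelihoods is usually intractable, while the deterministic reaction rate
equations (RRE) ignore fluctuations entirely — and for networks with
bimolecular reactions the fluctuations feed back into the means, biasing
RRE-based parameter estimates at finite volume.

`momentinfer` closes this gap for mass-action networks (molecularity ≤ 2).
From a single network description it automatically generates the ODE
systems of six moment approximations —

* **RRE** — macroscopic means `dφ_i/dt = Σ_r ν_ir f_r(φ)`;
* **LNA** — linear-noise covariance `dΣ/dt = JΣ + ΣJᵀ + Ω⁻¹ S diag(f) Sᵀ`;
* **EMRE** — means with the `O(Ω⁻¹)` fluctuation correction;
* **IOS** — corrected means plus a next-order covariance;
* **2MA / 3MA** — moment closures truncating third / fourth cumulants;

— together with exact forward-sensitivity systems, and fits them to
population-average or single-cell snapshot data by multi-start
gradient-based maximum likelihood. The statistical model combines the
finite-sample variance of the snapshot estimators,

```
σ²_μ̂ = Σ̂_ii / N + σ²_T,     σ²_Σ̂ = (Σ̂_iiii − (N−3)/(N−1) Σ̂²_ii) / N,
```

with replicate-level technical noise, in the negative log-likelihood

```
J(θ) = ½ Σ [log 2πσ²_μ̂ + ((μ(t_k,θ) − μ̂)/σ_μ̂)²]  +  ½ Σ [variance block]
```

minimized over `ξ = log θ` with analytic gradients and the Fisher
information as Hessian model. Profile likelihoods and delayed-rejection
adaptive Metropolis MCMC quantify uncertainty; AIC/BIC weights compare
descriptions; a χ² goodness-of-fit test rejects inadequate ones. An exact
Gillespie simulator (compiled core) generates synthetic snapshot data, and
built-in benchmark networks reproduce the in-silico estimation-error study
across volumes and sample sizes — no external data needed.

Intended users: systems biologists and methods developers fitting
mesoscopic stochastic models to flow/mass-cytometry-style snapshot data or
population-average time courses.

## Worked example

Birth–death process `0 →(k) A →(γ) 0` at volume Ω = 4, true rates
k = 10, γ = 2. Simulate 2000 cells at four snapshot times, fit the LNA to
means and variances, and profile `k`:

```r
library(momentinfer)

net <- birth_death_network(volume = 4, k = 10, gamma = 2)
dat <- simulate_snapshot_ensemble(net, mu0 = 0,
                                  timepoints = c(0.25, 0.5, 1, 2),
                                  n_cells = 2000, seed = 7)
summ <- summarize_snapshots(dat)

spec <- objective_spec(net, "LNA", summ, estimate = c("k", "gamma"),
                       lower = c(k = 0.5, gamma = 0.1),
                       upper = c(k = 200, gamma = 40),
                       mu0 = c(A = 0), data_mode = "mean+variance")
est <- fit(spec, n_starts = 10, seed = 3)
est
#> estimation_result [LNA]: J = -19.90145, 10/10 agreeing starts (converged)
#>         k     gamma
#> 10.054419  2.011779

profile_confidence_interval(profile_likelihood(spec, est, "k"), 0.95)
#> [1]  9.899806 10.211789

chi_square_rejection(est)
#> chi-square rejection test: chi2 = 5.46184, dof = 6, p = 0.4861 -> not rejected (alpha = 0.01)
```

The fit recovers the true rates within a percent; the 95% profile interval
for `k` covers the truth; and the χ² test (χ² close to its 6 degrees of
freedom) confirms the LNA describes this unimolecular network exactly, as
it must.

For networks with bimolecular reactions the macroscopic description is
biased at finite volume: on the built-in trimerization benchmark at
intermediate volume, an EMRE fit reduces the squared estimation error by
one to two orders of magnitude relative to the RRE, the EMRE's Akaike
weight is near 1, and the RRE is rejected by the χ² test — see
`estimation_error_sweep()` and the methods vignette.

A thin command-line interface over the same functions lives in
`inst/cli/momentinfer.R` (subcommands `fit`, `select`, `reject`,
`benchmark`) with YAML model documents (`read_network_yaml()`) and summary
CSVs as inputs.

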