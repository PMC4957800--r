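---
title: "Moment-based inference for stochastic chemical kinetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based inference for stochastic chemical kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momentinfer)
```

## The modeling problem

Intracellular reaction networks at low to moderate copy numbers are
stochastic: the state is a vector of molecule counts
$n = (n_1, \dots, n_M)$ in a reaction volume $\Omega$, and its probability
$P(n, t)$ evolves under the chemical master equation (CME) with per-reaction
propensities $a_r(n) = \Omega \hat f_r(n)$. Exact likelihood-based inference
on the CME is rarely tractable. `momentinfer` instead generates, for any
mass-action network with at most bimolecular reactions, closed ODE systems
for the leading statistical moments of the concentration process
$x = n/\Omega$, and fits those to summary statistics of population-average
or single-cell snapshot data by gradient-based maximum likelihood.

Six approximations are generated automatically from the same network
description:

| method | state blocks | content |
|--------|--------------|---------|
| RRE    | $\Phi$ | macroscopic reaction rate equations (infinite-volume mean) |
| LNA    | $\Phi, \Sigma$ | linear noise approximation: Gaussian fluctuations about $\Phi$ |
| EMRE   | $\Phi, \mu, \Sigma$ | $O(\Omega^{-1})$-corrected means about the RRE/LNA pair |
| IOS    | $\Phi, \mu, \Sigma$ | corrected means plus a next-order covariance (below) |
| 2MA    | $\mu, \Sigma$ | second-order moment closure (zero third cumulants) |
| 3MA    | $\mu, \Sigma, T$ | third-order closure (zero fourth cumulants) |

$\Sigma$ is stored as its $M(M+1)/2$ unique entries and the third central
moments $T$ as their $M(M+1)(M+2)/6$ unique entries, so an $M = 8$ network
yields systems of dimension 8 (RRE), 44 (2MA) and 52 (EMRE).

## Generation of the moment equations

Every mass-action rate up to bimolecular is a quadratic polynomial in the
concentrations,
$$\hat f_r(x) = c_r + b_r^\top x + \tfrac12 x^\top H_r x,$$
with at most two nonzero coefficient groups determined by the reaction's
order and reactant indices. The package stores this coefficient structure
(the closed symbolic form of the rate law) and derives all moment equations
from it exactly; no numerical differentiation of rate laws is involved. The
microscopic rate differs from its macroscopic limit only for
homodimerization, where $\hat f = k x (x - 1/\Omega_r)$ versus
$f = k x^2$; this finite-size term is what couples fluctuations back into
the means.

With exact quadratic expectations,
$\langle \hat f_r \rangle = \hat f_r(\mu) + \tfrac12 H_r \!:\! \Sigma$ and
$\mathrm{Cov}(x_j, \hat f_r) = (\Sigma \nabla \hat f_r(\mu))_j +
\tfrac12 H_r \!:\! T_{\cdot \cdot j}$, the mean and covariance equations
follow from the CME jump moments. The 2MA sets $T \equiv 0$ (zero third
cumulants); the 3MA keeps $T$ and closes the fourth central moments by the
zero-fourth-cumulant (Isserlis) combination
$\Sigma_{ij}\Sigma_{kl} + \Sigma_{ik}\Sigma_{jl} + \Sigma_{il}\Sigma_{jk}$.
Note that the $\tfrac12 H\!:\!\Sigma$ correction appears both in the mean
equation and in the $1/\Omega$ diffusion term of the covariance equation:
this is forced by the exact expectation of a quadratic propensity and makes
the closure exact for networks with only zeroth- and first-order reactions.

The system-size expansion family evaluates rates at the macroscopic solution
$\Phi$: the LNA covariance obeys the Lyapunov equation
$\dot\Sigma = J\Sigma + \Sigma J^\top + \Omega^{-1} S\,\mathrm{diag}(f)\,
S^\top$ and the EMRE mean carries the $O(\Omega^{-1})$ correction
$$\dot\mu_i = \dot\Phi_i + \sum_r \nu_{ir} \Big[\nabla f_r^\top (\mu - \Phi)
+ \tfrac12 H_r \!:\! \Sigma - \tfrac{1}{2\Omega_r} \sum_s \Phi_s
\partial^2_{ss} f_r\Big].$$

**IOS construction.** The next-order covariance is implemented, within the
state blocks $\{\Phi, \mu, \Sigma\}$, as the closed covariance equation
evaluated at the corrected mean $\mu$ with the microscopic (finite-size)
rates and the $\tfrac12 H\!:\!\Sigma$ diffusion correction. This carries
every $O(\Omega^{-1})$ covariance term expressible in these blocks, reduces
exactly to the LNA for unimolecular networks, and — like any truncation
beyond the LNA — is not guaranteed positive: at small volumes its variances
can go negative, which the integrator reports as a flag on the trajectory
rather than an error (model selection then naturally favors the LNA there).
It does, however, drop the third-central-moment source term that a full
inverse-omega-squared treatment retains, so its covariance is not uniformly
closer to the CME than the LNA at finite volume; finite-state CME
cross-checks in the test suite document this. Users wanting the full
third-moment feedback should use the 3MA.

**Multiple compartments.** Species live in compartments with volume
fractions relative to the reference volume $\Omega$. A reaction fires in its
reactants' compartment; its rate is evaluated with that compartment's
volume, and the concentration increment of a product in another compartment
is scaled by the source/target volume ratio. This is the unique convention
that conserves molecule counts exactly and keeps rate-constant units
compartment-independent. Bimolecular reactants must share a compartment.
The underlying formula is printed by `describe_system()` as the
volume-rescaled effective stoichiometry. This convention is a
reconstruction: it is stated here as the package's definition rather than a
reproduction of any published formula.

**Time-dependent inputs** are smooth positive functions of time (a cubic
spline helper `input_spline()` is provided) multiplying a reaction's rate,
identically in the microscopic and macroscopic rate; the exact stochastic
simulator handles them by thinning against a gridded upper bound with 5%
headroom (the one approximation in the simulator; exact when the bound
holds).

## Forward sensitivities

Each moment system can be augmented with $\partial(\text{state})/\partial
\theta_l$ blocks and integrated jointly (`augment_with_sensitivities()`).
The sensitivity right-hand sides are the exact directional derivatives of
the moment equations, hand-derived in the same matrix form as the base
equations for RRE, LNA, EMRE, IOS and 2MA; for the 3MA the directional
derivative is evaluated by complex-step differentiation of the polynomial
right-hand side, which is exact to machine precision and free of
subtractive cancellation. Because every rate is linear in its rate
constant, parameter derivatives of the equations are obtained from
per-reaction unit-rate contributions. Sensitivities are propagated on the
natural parameter scale and chain-ruled once to the optimization scale
$\xi = \log\theta$. Central finite differences (step $10^{-4}$ on $\xi$)
are kept as a validation path (`finite_difference_gradient()`,
`gradient_check()`), never as the optimizer's default.

## Statistical model and objective

Snapshot data are summarized per observable $i$ and time $t_k$ by the $1/N$
estimators $\hat\mu_{i,k}$, $\hat\Sigma_{ii,k}$ and the fourth central
moment $\hat\Sigma_{iiii,k}$. Their sampling variances are
$$\sigma^2_{\hat\mu} = \tfrac1N \hat\Sigma_{ii} + \sigma^2_{\hat\mu, T},
\qquad
\sigma^2_{\hat\Sigma} = \tfrac1N\Big(\hat\Sigma_{iiii} -
\tfrac{N-3}{N-1}\hat\Sigma_{ii}^2\Big),$$
with sample-based plug-ins (deliberately, rather than model-implied
higher moments) and replicate-level technical noise
$\sigma^2_{\hat\mu, T}$, either fixed or an estimated positive parameter
optimized on the log scale. Population-average mode drops the statistical
term ($N$ effectively infinite) and carries no variance block. Two
conventions deserve note: the $1/N$ (not $1/(N-1)$) variance estimator is
used together with the $(N-3)/(N-1)$ factor exactly as stated above, and a
non-positive computed $\sigma^2_{\hat\Sigma}$ (possible at tiny $N$) is
floored at $10^{-12}$ with a warning. The correlation between mean and
variance estimators from the same sample is ignored in the likelihood — a
documented limitation of the product-form likelihood.

The objective is the negative log-likelihood
$$J(\theta) = \tfrac12\sum_{k,i}\Big[\log 2\pi\sigma^2_{\hat\mu} +
r_{\mu}^2\Big] + \tfrac12\sum_{k,i}\Big[\log 2\pi\sigma^2_{\hat\Sigma} +
r_{\Sigma}^2\Big],$$
with standardized residuals $r$; the variance block is omitted for
mean-only data. Its gradient combines the residual terms with the
$\tfrac{1}{2\sigma^2}(1 - r^2)\,\partial\sigma^2/\partial\theta_l$
contribution of parameter-dependent noise variances. The Fisher information
matrix (outer products of observable sensitivities weighted by
$1/\sigma^2$, plus the $\tfrac{1}{2\sigma^4}(\partial\sigma^2/\partial\xi)^2$
noise-parameter curvature) serves as the optimizer's Hessian model.

**Optimization.** `fit()` draws latin-hypercube starting points on the
log-parameter box (plain LHS, seeded) and refines each with the PORT
bound-constrained quasi-Newton optimizer (`nlminb`), supplied with the
analytic gradient and the FIM; parameter and objective tolerances default
to $10^{-6}$. Integrator failures at a proposed $\theta$ map to an
effectively infinite objective so multi-starts stay robust. Convergence is
declared when at least 5 starts (configurable) agree with the best
objective within $10^{-3}$ (the agreement tolerance is a package default;
ties are broken by gradient norm, then start index); otherwise the result
recommends doubling the start count.

## Uncertainty, selection, rejection

*Profile likelihoods* re-optimize all remaining parameters along an
adaptive grid in one parameter, stepping to a target objective increase of
about 0.1 per step (initial step calibrated from the FIM curvature,
overshoots retracted), until the $\chi^2_1$ threshold of the highest
requested level is exceeded or a bound is hit; profiles that stay below the
lowest threshold at a bound are flagged flat — the signature of structural
non-identifiability — and the interval endpoint is reported at the bound.
Interval endpoints interpolate the crossing of
$2(J_{\text{profile}} - J(\hat\theta))$ with the $\chi^2_1$ quantile.

*MCMC* uses delayed-rejection adaptive Metropolis on $\xi$ under a
log-uniform prior over the box: covariance adaptation from the chain
history (start iteration $10^3$, interval 100, defaults) plus one
delayed-rejection stage at covariance scale 0.2. Chain and burn-in lengths
default to $10^5$ and $10^4$. Credibility intervals are equal-tailed
marginal percentiles. Running the sampler from a `fit()` result reuses the
inverse FIM as the initial proposal covariance.

*Selection and rejection.* `akaike_weights()` computes
$\mathrm{AIC} = -2\log L(\hat\theta) + 2 n_\theta$ with Akaike weights
relative to the best model, and BIC alongside as a cross-check; $n_\theta$
counts every estimated parameter, nuisance parameters included.
`chi_square_rejection()` refers the sum of squared standardized residuals
at $\hat\theta$ to $\chi^2$ with (data points − parameters) degrees of
freedom; mean and variance entries count separately when both are fitted (a
documented convention, configurable through the data mode), and the default
rejection level is $\alpha = 0.01$.

## Synthetic data and the in-silico benchmark

The Gillespie direct-method simulator (compiled core, R-seeded and
byte-reproducible) generates trajectories and snapshot ensembles; snapshot
sampling simulates fresh, independent cells for every timepoint, matching
snapshot — not time-lapse — semantics. Initial conditions default to
deterministic counts $\mathrm{round}(\Omega_i \mu_0)$ (configurable via a
user-supplied draw function). Technical noise adds one normal draw per
(observable, timepoint, replicate) shared across that replicate's cells.

Two benchmark networks are built in. The *trimerization* fixture (bursty
monomer synthesis realized as a fixed burst $\varnothing \to 2A$ — a
finite mass-action stand-in for a bursty source — reversible dimerization
and trimerization, monomer degradation) has 6 reactions, two of them
bimolecular, and 7 parameters including the volume. The *enzymatic
degradation* fixture (transcription, translation, mRNA turnover, reversible
enzyme-substrate complex formation and catalytic decay) has 6 reactions,
one bimolecular, and 8 parameters including the initial enzyme
concentration and the volume. The canonical fixture rates were chosen once,
by a deterministic calibration (fitting the RRE to third-order-closure
surrogate means and comparing the resulting asymptotic bias against the
Fisher-information sampling floor), so that the fixture operates at low
copy numbers (order 1–100 molecules across the benchmark volumes) where
fluctuation corrections are substantial; they are recorded in
`trimerization_protocol()` and not tuned thereafter.

`estimation_error_sweep()` reproduces the in-silico protocol: for each
volume, sample size and replicate it generates an SSA dataset at the true
parameters, fits each approximation by multi-start maximum likelihood, and
records the squared estimation error
$\mathrm{error}^2 = \lVert\theta_{\text{true}} - \hat\theta\rVert_2^2$,
per-replicate Akaike weights across methods, and rejection outcomes;
aggregates report medians, symmetric 80% percentile intervals, and the
decomposition of the mean squared error into squared bias plus estimator
variance. Mean-only data are fitted with RRE/EMRE/2MA and mean+variance
data with LNA/IOS/3MA. The desk-scale defaults (four volumes spanning the
decade 6.3–63, $N = 1000$ cells, 20 replicates, 8 multi-starts) keep the
full study in the minutes range; they are deliberately smaller than a
full-scale study (hundreds of replicates, $10^5$ cells, 50 starts), which
the same functions run by changing the arguments.

Two regimes are worth knowing about. In the bias-dominated intermediate
regime the median squared error of RRE-based inference falls as
$\Omega^{-2}$ (the squared $O(\Omega^{-1})$ approximation bias); at large
volumes it flattens toward the sampling floor $\propto 1/(N\Omega)$, so
with $N = 10^3$ cells the measured log–log slope over the benchmark decade
is slightly shallower than 2. At the same conditions the EMRE's error is
dominated by sampling noise already, its Akaike weight against the RRE is
near 1, and the RRE is rejected by the goodness-of-fit test — the a
posteriori signatures that a mesoscopic description is needed.

## What the synthetic benchmark does and does not show

The generator emulates well-mixed mass-action kinetics with exchangeable
cells, exact snapshot sampling, and (optionally) replicate-level Gaussian
technical noise. Real single-cell data additionally carry extrinsic
parameter heterogeneity, non-Gaussian measurement noise, cell-cycle and
lineage correlations, and partial observability — none of which the
fixtures contain. Passing tests therefore demonstrate correctness of the
moment machinery, the estimators and the inference pipeline under the
stated model, not robustness to model misspecification on real data.

## Numerical choices

- Integration: `deSolve::lsoda`, relative/absolute tolerances
  $10^{-8}/10^{-10}$ by default; failures carry method and time context.
- Degenerate initial covariances ($\Sigma_0 = 0$, deterministic start) are
  allowed; $\Sigma_0$ must be symmetric PSD.
- Estimation is strictly on $\xi = \log\theta$, so all bounds are positive;
  linear-scale offsets with sign are accommodated by treating the offset as
  a fixed (non-estimated) parameter or shifting the observable.
- Concentrations are molecules/μm³ and volumes μm³; multiply by
  `nM_per_molecule_per_um3` to convert concentrations to nM. No Avogadro
  factors are applied inside the core.
- Seeds: every stochastic entry point takes a seed; sweeps derive
  per-replicate seeds from one master seed, so entire studies are
  reproducible bit for bit.

## Known limitations

- Mass-action only (molecularity ≤ 2); Hill/Michaelis–Menten propensities
  must be mechanistically expanded or are out of scope.
- Diagonal-only likelihood: covariances between different observables are
  not used, and mean/variance estimator correlation is ignored.
- The IOS covariance omits third-moment feedback (see above).
- The SBML importer is deliberately minimal (mass-action kinetic laws,
  global parameters, no rules/events) and rejects everything else.
- Chains and sweep outputs are stored as CSV/JSON, not HDF5.
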