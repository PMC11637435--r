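---
title: "Population dynamics of plasmid fitness-cost compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population dynamics of plasmid fitness-cost compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(plasmidcomp)
library(dplyr)
```

## The problem

Conjugative plasmids are usually costly to their bacterial hosts, yet they
persist. One resolution is compensatory evolution: mutations that reduce
the plasmid's cost. Such a compensatory mutation (CM) can sit on the
chromosome (chrCM) or on the plasmid itself (plaCM), and the two locations
have very different evolutionary consequences — a plaCM travels with the
plasmid into every new transconjugant, while a chrCM stays behind in its
host lineage, which can then use the *uncompensated* plasmid as a weapon
against plasmid-free competitors. This package implements deterministic
population models of that contest, parameterised after the *Pseudomonas
fluorescens* SBW25 / mercury-resistance megaplasmid pQBR57 system, together
with the assay calculations (conjugation-rate and relative-fitness
estimators) and a synthetic-data generator that emulates the corresponding
competition experiments.

## The models

All models track subpopulation densities as fractions of a carrying
capacity $K$, and share the same ingredients: logistic growth on the free
capacity, continuous turnover $\mu$, mass-action conjugation into
plasmid-free cells, and an optional selection pressure $\eta$ acting
against plasmid-free cells. With $f$ plasmid-free, $p$ uncompensated
plasmid bearers and $c$ chrCM bearers ($S$ the total density):

$$
\begin{aligned}
\dot f &= \alpha f (1-S) - \mu f - \gamma_P p f - \gamma_C c f - \eta f,\\
\dot p &= \beta_P p (1-S) - \mu p + \gamma_P p f + \gamma_C c f,\\
\dot c &= \beta_C c (1-S) - \mu c,
\end{aligned}
$$

with $\alpha > \beta_C > \beta_P$ when compensation is imperfect. The
crucial asymmetry is in the conjugation terms: transfer from a chrCM host
moves the *wild-type* plasmid into a wild-type cell, so the $\gamma_C c f$
flux feeds $p$, not $c$. The plaCM variant replaces $c$ by $q$, and there
the CM travels with the plasmid, so $\gamma_Q q f$ feeds $q$ itself. The
four-population `combined` model joins both CM types in one system; its
transfer topology follows the same mechanism (only $f$ can receive, since
resident plasmids exclude superinfection; transfers from $p$ and $c$
create $p$; transfers from $q$ create $q$). Spontaneous plasmid loss by
segregation is deliberately not modelled: on the timescales of interest
population change is driven by competition with existing plasmid-free
cells, and omitting it keeps the fixed-point analysis tractable.

Parameters live in a single validated record:

```{r}
params <- fixture_params("figG")
params
```

Internally everything is dimensionless (densities as fractions of $K$,
conjugation rates $\gamma' = \gamma K$), because the analytic thresholds
are naturally dimensionless, while measured rates are reported in
ml cell$^{-1}$ h$^{-1}$. `nondimensionalize()` / `dimensionalize()`
convert explicitly, and the right-hand sides refuse dimensional parameter
sets rather than guessing.

## Thresholds and phase structure

For the two-member system a costly plasmid invades the plasmid-free
equilibrium only if $\gamma' > \mu(\alpha-\beta)/(\alpha-\mu)$ and
displaces it only if $\gamma' > \mu(\alpha-\beta)/(\beta-\mu)$:

```{r}
gamma_invasion_threshold(0.54, 0.95 * 0.54, 0.04125)
gamma_domination_threshold(0.54, 0.95 * 0.54, 0.04125)
```

With the measured rate $\gamma = 4.6\times10^{-12}$ ml cell$^{-1}$
h$^{-1}$ and $K = 5.7\times10^9$ ml$^{-1}$, both compensated strains sit
comfortably above their domination thresholds:

```{r}
domination_fold_excess(4.6e-12, 0.54, 0.97 * 0.54, 0.04125, 5.7e9) # chrCM
domination_fold_excess(4.6e-12, 0.54, 0.95 * 0.54, 0.04125, 5.7e9) # plaCM
```

`find_fixed_points()` locates every root of a model's right-hand side from
a deterministic seed set — the analytic boundary candidates (extinction,
single-population balances $1-\mu/\text{rate}$, pairwise mixtures) plus
local minima of the squared RHS norm on a 21-points-per-axis grid over the
density simplex — refines them by damped Newton iteration with the
analytic Jacobian, deduplicates at distance $10^{-6}$, and classifies
stability from the eigenvalues of a central finite-difference Jacobian
(relative step $10^{-7}$; the finite-difference Jacobian is validated
against the analytic one in the test suite). Eigenvalues whose real part
is within $10^{-8}$ of zero yield the honest label `nonhyperbolic` rather
than a guess; a complex pair with $|\mathrm{Im}| > 10^{-8}$ marks a
spiral.

```{r}
find_fixed_points("placm", nondimensionalize(fixture_params("figI")))
```

The interior stable spiral above is the rock-paper-scissors regime: $f$
feeds the conjugative spread of $p$; $p$ is outgrown by $q$; $q$, with its
much lower transfer rate, is outgrown by $f$. `rps_scan()` asks how strong
the conjugation trade-off $\gamma_Q = \gamma_P / r$ must be for that
three-population coexistence to exist, combining interior fixed-point
analysis with long-horizon integration:

```{r}
scan <- rps_scan(fixture_params("figI"), reductions = c(1, 3, 10, 30, 100))
select(scan, reduction, has_interior_fp, interior_stability, coexists)
min_rps_reduction(scan)
```

At this parameterisation the interior point first exists within the
scanned grid at a 30-fold reduction — consistent with needing a 10–100
fold trade-off, far larger than any measured difference between the
wild-type and plaCM plasmids.

`classify_region()` names the phase region a parameter set occupies by
combining the stable-attractor set with a confirmation simulation from
the canonical inoculum (total density $0.01K$, half plasmid-bearing, half
of the bearers compensated); disagreement between analysis and simulation
is reported as an explicit `conflict` label, never silently resolved.
plaCM with $\gamma_Q > \gamma_P$ short-circuits to
`wildtype_plasmid_lost`, since the compensated plasmid then beats the
wild type on both growth and transfer. In the bistable regime — chrCM
fixation stable (its conjugation rate above the *compensated* domination
threshold) while the plasmid-free state is also an attractor —
`basin_threshold_chrcm()` locates the separating initial chrCM fraction
by bisection to $10^{-4}$:

```{r}
pink <- nondimensionalize(fixture_params("figA"))
pink$gamma_p <- 0.005   # below the uncompensated invasion threshold
pink$gamma_c <- 0.01    # above the compensated domination threshold
basin_threshold_chrcm(pink)
```

## Simulation regimes

`integrate_continuous()` treats the system as an open, chemostat-like
culture (turnover $\mu$ acts throughout); `run_serial_transfer()` emulates
batch-culture evolution experiments — within each batch $\mu = 0$ (a
closed culture has no washout; any selection $\eta$ is kept) and each
transfer multiplies all densities by the dilution fraction. The default
protocol is 8 daily transfers of 1%, i.e. $8 \log_2 100 \approx 53$
generations. Both use a stiff-capable solver (lsoda) at rtol $10^{-8}$ /
atol $10^{-12}$ with at least 200 output points; round-off negatives above
$-10^{-12}$ are clipped to zero, anything below that triggers a warning.
The divergence between the two regimes is real and intentional: turnover
is a continuous-flow device, so long-run coexistence sets can differ
between regimes for the same parameters.

```{r}
pG <- nondimensionalize(fixture_params("figG"))
tr <- run_serial_transfer("combined", pG, transfer_protocol(),
                          state_vector("combined", f = 0.005, c = 0.0025,
                                       q = 0.0025))
ep <- transfer_endpoints(tr)
round(ep$c / (ep$c + ep$q), 3) # chrCM share of the CM pool rises
autoplot(tr)
```

`long_run_outcome()` declares a subpopulation surviving only if it is
above the extinction tolerance ($10^{-6}$ of $K$ by default) both at the
horizon ($10^4$ h by default, $\gg 1/\mu$) *and* in time-average over the
last 10% of the horizon, so an oscillatory attractor counts as
coexistence rather than extinction. The weaponisation experiment contrasts
the fate of chrCM with and without its ability to conjugate:

```{r}
weaponisation_contrast(pG, state_vector("combined", f = 0.005, c = 0.0025,
                                        q = 0.0025))
```

With conjugation intact, chrCM burdens its plasmid-free competitors with
the costly plasmid and sweeps; with $\gamma_C = 0$ it cannot overcome its
residual growth cost and is lost.

## Assay estimators

`simonsen_gamma()` is the classic end-point estimator
$\gamma = \psi \ln(1 + (T/R)(N/D))/(N_t - N_0)$ with the bulk rate
$\psi = \ln(N_t/N_0)/t$; it assumes equal growth of all populations.
`asm_gamma()` corrects for unequal growth by replacing $\psi$ with
$\psi_D + \psi_R - \psi_T$, the effective accumulation rate of
transconjugants in the per-population exponential model with mass-action
transfer; under equal growth the two coincide exactly. Onward transfer
from transconjugants is neglected, which matches the short (~4 h) assay
window the estimators are designed for. Because the exact correction is
model-based, it is validated against a forward-simulation oracle
(`simulate_assay()`) rather than against any printed constant:

```{r}
assay <- simulate_assay(fixture_params("figG"), gamma_true = 1e-11)
estimate_gamma(assay, method = "asm")$gamma
estimate_gamma(assay, method = "simonsen")$gamma
```

Relative fitness is the Malthusian difference
$r = \ln(\text{test}_\text{end}/\text{test}_\text{start}) -
\ln(\text{ref}_\text{end}/\text{ref}_\text{start})$, invariant to common
count rescaling, with the marker effect (measured in isogenic control
competitions) subtracted via `marker_correct()`.

## Synthetic data

`generate_competition_counts()` emulates flow-cytometry counting of
serial-transfer competitions: at each per-transfer endpoint it draws
labelled-event counts at the trajectory's true frequencies with
beta-binomial noise, parameterised by the intraclass correlation $\rho$
(shape parameters $a = \pi(1-\rho)/\rho$, $b = (1-\pi)(1-\rho)/\rho$, so
the variance is inflated by $1 + (n-1)\rho$ over the binomial; $\rho = 0$
is clean binomial sampling). The study data are overdispersed but the
fitted dispersion is not published, so $\rho$ defaults to a mild 0.05 and
every generator accepts it explicitly. Subpopulations are drawn by
stick-breaking, so counts sum to at most the sample size while each
marginal mean stays exactly $n\pi$. Every count series records its seed
and reproduces byte-for-byte.

What the generator does *not* emulate: gating artefacts (clumped
double-positive events), lag-time differences between fresh
transconjugants and established strains, demographic stochasticity at low
density, and segregational loss. Tests that pass on these synthetic data
therefore validate the estimators and the sampling model, not the full
measurement process of real flow-cytometry data.

## Numerical choices

* Solver: lsoda, rtol $10^{-8}$, atol $10^{-12}$; halving the tolerances
  moves trajectory endpoints by $<10^{-6}$ (asserted in the tests).
* Fixed-point residual bound $10^{-9}$ (Newton typically converges to
  $10^{-12}$); deduplication distance $10^{-6}$; hyperbolicity tolerance
  $10^{-8}$ on eigenvalue real parts.
* Newton seeds: all analytic boundary candidates plus grid local minima of
  the RHS norm (21 points per axis); seeding from every grid point finds
  no additional roots at this resolution and is much slower.
* Extinction tolerance $10^{-6}$ of $K$ and classification horizon
  $10^4$ h, both configurable; near-threshold property tests use
  $10^5$ h because the leading eigenvalue within 20% of a threshold can
  be of order $10^{-4}$ h$^{-1}$.
* Bisection tolerance $10^{-4}$ on the basin-boundary fraction.
* In bistable regions the region label (`cm_fixes_above_saddle`) records
  initial-condition dependence explicitly instead of privileging one
  attractor.
* Test problem sizes (20 parameter draws for threshold bracketing, 50 for
  fixed-point/attractor equivalence, $10^4$ draws for the moment checks)
  were chosen so the whole suite runs in well under a minute while keeping
  Monte-Carlo error far from the asserted bounds.

## Limitations

The models are deterministic and well-mixed: no spatial structure, no
demographic noise, no segregational loss, and at most one plasmid per
cell (entry/surface exclusion is absolute). Selection $\eta$ acts as a
pure death rate on plasmid-free cells, which mirrors the model definition
rather than the full biology of mercury toxicity. The combined
four-population model cannot be solved analytically; all statements about
it are numerical. Parameters are treated as known constants — fitting them
to experimental time series is out of scope.
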