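---
title: "Modelling retinol delivery to and across a BMEC barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling retinol delivery to and across a BMEC barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinolBBB)
```

## The problem

Retinol (ROH, vitamin A alcohol) circulates bound to retinol binding protein 4
(RBP), whose holo form is in turn bound by transthyretin (TTR). An in vitro
blood-brain-barrier model — brain microvascular endothelial-like cell (BMEC)
monolayers on plates or Transwell inserts, fed with defined mixtures of ROH,
RBP and TTR carrying a tritium tracer — yields three kinds of quantitative
data: the equilibrium partitioning of ROH among carrier species, cellular
accumulation time courses, and transfer into the basolateral ("brain")
chamber. `retinolBBB` implements the full analysis chain for such assays, plus
a seeded simulator so every stage is testable without access to raw
scintillation data.

## Carrier speciation

Two coupled mass-action equilibria are assumed:

$$ROH + RBP \rightleftharpoons ROH\!-\!RBP, \qquad
K_D^{(1)} = \frac{[ROH][RBP]}{[ROH\!-\!RBP]} = 0.1\ \mu M$$

$$ROH\!-\!RBP + TTR \rightleftharpoons ROH\!-\!RBP\!-\!TTR, \qquad
K_D^{(2)} = 0.25\ \mu M$$

TTR binds only holo-RBP — never apo-RBP and never free ROH — and is treated as
a single binding entity at its molar concentration (no tetramer-site
multiplicity); both choices reproduce the published carrier-distribution
arithmetic, including the mutant rows where one interaction is abolished
(`variant = "muRBP"` or `"muTTR"`, modelled as an infinite second $K_D$).
Albumin binding of ROH is excluded: albumins are not considered physiologic
ROH carriers.

Given free ROH $r$, the remaining species follow from a closed-form quadratic,
so the full system reduces to one scalar residual
$f(r) = r + [ROH\!-\!RBP] + [ternary] - ROH_{tot}$, strictly increasing on
$(0, ROH_{tot}]$. We solve it by plain bisection driven to machine precision.
An earlier draft used `uniroot` at `tol = 1e-12` on $r$; for tight-binding
systems the residual slope is steep enough that this leaked ~1e-8 into the
relative mass balances, so the bisection runs until the bracket collapses to
adjacent doubles. The solver is deterministic and is cross-checked in the test
suite against an independent nested-bisection oracle on 1000 random systems.

```{r speciation}
solve_ternary(equilibrium_system(2, 2, 4))
fraction_free(solve_ternary(equilibrium_system(2, 2, 0)))
```

Full precision is kept internally; rounding to two decimals happens only at
presentation (`speciation_table()`). At the standard assay condition the free
fraction is 20% with RBP alone and ~7% with RBP and TTR; the full-precision
free ROH with TTR is 0.1348 uM, which rounds to 0.13 (printed tables that
show 0.14 reflect upstream rounding).

## Radiometry

Scintillation counts convert to amounts through fixed constants: 1 Ci =
2.22e12 DPM, a specific activity of 30 Ci/mmol, and the labeled mole fraction
of the analyte pool. The working solutions target 5% tritiated retinol, so
`labeled_fraction` defaults to 0.05; a strict 1:20 tracer:unlabeled mixing
ratio would give 1/21 (~0.0476), and the field is configurable when the
measured ratio is known. Cellular concentrations divide the total amount by
`n_cells` times the single-cell volume (402 um^2 x 3.4 um = 1.37e-12 L for a
BMEC). `n_cells` has no default: published assays report seeding densities
rather than counted cells, so an absolute concentration is only as good as
that assumption and must be stated explicitly. Dual-isotope records carry a
channel tag; no spillover correction is modelled because window crosstalk
coefficients are not available.

## Accumulation kinetics

Accumulation of free ROH into monolayers is modelled as solvent-like
partitioning, not receptor binding — cellular levels reach ~100x the fluid
concentration, far beyond saturable binding:

$$c_{cell}(t) = c_f K_p (1 - e^{-k_1 t})$$

with $c_f$ the (assumed constant) fluid concentration, $K_p$ a partition
coefficient (uM cell / uM fluid) and $k_1$ a first-order rate (1/min). At
higher fluid concentrations a second phase appears; the model assumes a
secondary uptake/storage mechanism (plausibly retinyl-ester synthesis once
CRBP1 is saturated) that triggers when $c_{cell}$ crosses a threshold
$c^*_{cell}$:

$$c_{cell}(t) = c_f K_p (1 - e^{-k_1 t}) +
  c_f K_p^* \left(1 - e^{-k_1^* (t - t_{lag})}\right) 1\{t \ge t_{lag}\},
\qquad t_{lag} = -\frac{\ln(1 - c^*_{cell}/(K_p c_f))}{k_1}$$

When $c^*_{cell} \ge K_p c_f$ the trigger never fires; that branch is a value
(`lag_time()` returns `Inf`, the second term is clamped to zero), not an
error, so the least-squares objective is defined everywhere. The curve is
continuous at $t_{lag}$ with a kink in slope; no smoothing is applied,
matching the stated functional form.

### Fitting and model comparison

`fit_accumulation()` minimises the pooled unweighted SSE across all supplied
curves with one shared parameter set (the $c_f$-dependence of $t_{lag}$ is
what distinguishes concentrations); a `per_curve` option fits each curve
separately, since it is not established whether published parameter values
came from a global or per-concentration fit. Replicates enter as individual
observations. The optimiser is a seeded multistart (one data-driven start
plus log-uniform random starts) of box-constrained L-BFGS-B followed by
Nelder-Mead polish; bounds are $K_p, K_p^* \in [0, 10^4]$,
$k_1, k_1^* \in [10^{-5}, 1]$ /min, $c^*_{cell} \in [0,$ max observed$]$.
On noiseless synthetic data all five parameters are recovered to well below
1%.

`compare_models()` performs the extra-sum-of-squares F test of the nested
monophasic restriction ($K_p^* = 0$; df = 3, $n - 5$) and also reports
$\Delta$AIC; the F test at $\alpha = 0.05$ decides `preferred` because the
claim being tested is significance-based.

A caveat established during development and deliberately left visible in the
test suite: with 5% *multiplicative* noise, pooling curves whose signals span
a 20-fold range makes the unweighted SSE — and hence the F statistic —
dominated by the highest-concentration curve, inflating the type-I rate of
the comparison well above nominal (12–26% across measured replicate batches,
25.5% over the 200-replicate acceptance run, at nominal 5%). On a
single curve the test is near-nominal (~3% measured) — but a single biphasic
curve is also well approximated by a monophasic one (lack-of-fit far below
the noise floor), so single-curve power collapses to ~30%. High power and
nominal type-I are therefore not simultaneously attainable for this design
with an unweighted F test under multiplicative noise; the power/type-I
simulation in the acceptance tests runs the full three-concentration design,
where power is essentially 1 and the type-I expectation fails honestly.
Variance-weighted least squares (weights $1/\mu_i^2$) would be the
principled fix for pooled heteroscedastic fits, but the fitting contract
here is the plain unweighted SSE, matching how such fits are usually
reported.

```{r fit, eval = FALSE}
tcs <- simulate_accumulation(simulation_config(seed = 1,
                                               noise_model = "gaussian_cv"))
fit <- fit_accumulation(tcs, "biphasic")
fit_mono <- fit_accumulation(tcs, "monophasic")
compare_models(fit_mono, fit)
```

### Free-ROH contribution

`free_contribution_fraction()` divides, time point by time point, the
accumulation measured with protein-free ROH (at the free concentration
present in a protein-bound preparation: 0.4 uM for ROH-RBP, 0.1 uM for
ROH-RBP-TTR) by the total accumulation of the protein-bound sample. Curves
are averaged over replicates and interpolated onto the coarser grid of the
overlapping range; the t = 0 ratio is 0/0 and reported as missing; percent
is capped at 100 for reporting while the raw ratio column is left uncapped.

## Transwell permeability

Basolateral samples are replaced with buffer, so the concentration series
undercounts transferred mass. The sampling-corrected cumulative amount is

$$Q(t_k) = C_k V_b + \sum_{j<k} C_j v_s$$

and the apparent permeability of monolayer plus insert combined is the OLS
slope of $Q$ versus $t$ over the regression window divided by membrane area
and donor concentration, converted to cm/s. Numerical policy decisions:

* **C0** is the measured apical concentration at t = 0 when present (the
  apical chamber is sampled at t = 0), with the nominal loading as fallback.
* **Window**: basolateral accumulation shows a short lag before turning
  linear, so the default window starts at the first positive sampling time
  (15 min) and excludes t = 0; it is configurable.
* **Series-resistance correction** (1/Pe_cell = 1/Pe_total − 1/Pe_blank) is
  not applied: no blank-insert data are modelled, and the combined value is
  what is reported.
* Time is minutes internally; Pe is converted to cm/s only at output.

`mass_balance()` checks closure: (apical remaining at actual end volume +
apical withdrawn + sampling-corrected basolateral + lysate) / loaded. On
noiseless simulator output this is exactly 1; the published assays recovered
~97% (ROH) and >=95% (sucrose), which is the scale of agreement to expect on
real data. `normalize_basolateral()` implements the two normalization views:
curves proportional to their apical C0 collapse after apical normalization,
and do not collapse when normalized by (non-proportional) cellular
concentrations — the diagnostic for apical- versus cell-coupled transport.

## The synthetic-data generator

The generator states the world the analysis assumes, with published assay
conditions as defaults:

* accumulation: $c_f \in \{0.1, 0.4, 2\}$ uM sampled every 5 min over 2 h in
  triplicate, biphasic truth $K_p = 90$, $k_1 = 0.02$/min, $K_p^* = 70$,
  $k_1^* = 0.01$/min, $c^*_{cell} = 36$ uM. $K_p$ and $c^*_{cell}$ are the
  published estimates (cell:fluid ratio ~90, threshold ~36 uM); the rates and
  $K_p^*$ are not printed and were chosen once to reproduce the qualitative
  pattern (0.1 uM plateaus at ~9 uM by ~90 min, 2 uM reaches ~320 uM by 2 h,
  ratio curves diverge after the trigger).
* Transwell: 550 uL apical / 1500 uL basolateral, 1.12 cm^2, basolateral
  sampling every 15 min with replacement, apical samples at 0 and 60 min
  without replacement, 30 uL draws (total withdrawn = 10% of bulk), true
  Pe 4.8e-6 cm/s (ROH channel) and 0.6e-6 cm/s (sucrose channel), the
  published point estimates.
* noise: `gaussian_cv` (5% CV default, a typical assay CV) or
  `poisson_counts`, which converts through the inverse radiometry chain and
  draws Poisson counts — physically motivated for scintillation counting; no
  noise model is stated for the original data, so Poisson is the default
  recommendation and Gaussian the simpler alternative.

The Transwell simulator integrates a three-compartment (apical, cell,
basolateral) mass-action system with fixed-step RK4 at 0.1-min steps, with
sampling events applied exactly at scheduled times; mass is conserved to
machine precision before noise. The cell compartment is a *lumped
first-order exchange* (an uptake clearance and a pass-through fraction) — a
documented stand-in sufficient to produce the observed basolateral lag, not
the full biphasic intracellular dynamics. The sucrose channel is direct
apical-to-basolateral paracellular flux. What a green round-trip test
establishes is therefore internal consistency of the estimators under the
stated transfer model — not that real BMEC monolayers follow first-order
lumped kinetics, and not anything about counting efficiency, quench, or
isotope spillover, none of which are modelled.

Because the receiver accumulates and the donor depletes slightly, the
recovered Pe on noiseless data is biased low by the finite-sink effect: <1%
for the sucrose channel (near-constant C0) and ~3% for the faster ROH
channel over 60 min. Tests hold the sucrose channel to 2% and the ROH
channel to 5%.

## Pipeline and CLI

`run_pipeline()` chains speciation, simulation (or CSV loading), kinetic
fitting with model comparison, and permeability/mass-balance into a JSON
report with a manifest (seed, package version, stage list, unit policy:
concentrations uM, time min, volumes L, Pe cm/s). The same stages are
exposed as CLI subcommands (`exec/retinolbbb`): `speciate`, `simulate`,
`fit-accumulation`, `permeability`, `run`. Reports are deterministic for a
fixed seed.

## Known limitations

* Speciation treats TTR as one site; tetramer statistics would matter at
  sub-nM precision but not at the 0.01-uM reporting precision used here.
* The kinetic threshold makes the objective only piecewise smooth;
  multistart handles the resulting local minima, but standard errors from
  the Gauss-Newton approximation are unreliable when a parameter sits at a
  bound (reported as `NA` there).
* Pe estimation assumes constant donor concentration within the window; no
  unstirred-water-layer correction is applied.
* The simulator does not model TEER dynamics, transcriptional regulation, or
  the chemical identity of basolateral tritium signal.
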