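# retinolBBB

Quantitative analysis of retinol (vitamin A) delivery to and across an in
vitro blood-brain-barrier model: brain microvascular endothelial-like cell
(BMEC) monolayers fed with defined mixtures of retinol (ROH), retinol binding
protein 4 (RBP) and transthyretin (TTR), read out by liquid scintillation
counting. The package is for anyone analysing carrier-mediated
retinoid-uptake or Transwell permeability assays who needs the full chain
from raw counts to fitted transport parameters, with a seeded simulator
standing in for unpublished raw data.

Four analysis stages, each usable on its own:

1. **Speciation** — coupled mass-action equilibria
   `ROH + RBP ⇌ ROH-RBP` (K_D = 0.1 uM) and
   `ROH-RBP + TTR ⇌ ROH-RBP-TTR` (K_D = 0.25 uM), solved by bisection on a
   monotone scalar residual in free ROH; binding-dead mutants (muRBP, muTTR)
   via an infinite K_D.
2. **Radiometry** — DPM → mol → uM conversions (1 Ci = 2.22e12 DPM, specific
   activity 30 Ci/mmol, labeled fraction 0.05 by default) and the BMEC
   cell-volume model (402 um² × 3.4 um = 1.37e-12 L/cell); TEER area
   correction.
3. **Accumulation kinetics** — monophasic partitioning
   `c_cell = c_f·Kp·(1 − e^(−k1·t))` and a biphasic extension whose second
   phase triggers when `c_cell` crosses a threshold `c*_cell` (lag time
   `t_lag = −ln(1 − c*_cell/(Kp·c_f))/k1`); global or per-curve nonlinear
   least squares with seeded multistart, extra-sum-of-squares F test and
   ΔAIC for the nested comparison.
4. **Permeability** — sampling-corrected cumulative basolateral amounts
   `Q(t_k) = C_k·V_b + Σ_{j<k} C_j·v_s`, apparent permeability
   `Pe_app = (dQ/dt)/(A·C0)` in cm/s, mass-balance closure, and
   apical-vs-cellular normalization diagnostics.

A three-compartment Transwell simulator (RK4, exact sampling events,
mass-conservative) and a biphasic accumulation simulator generate test data
with Gaussian-CV or Poisson counting noise under a single seed.

## Worked example

```r
library(retinolBBB)

# carrier speciation at the standard assay condition
speciation_table()
#>   total_roh          mode free_roh roh_rbp roh_rbp_ttr
#> 1         2          free     2.00    0.00        0.00
#> 2         2       ROH-RBP     0.40    1.60        0.00
#> 3         2     ROH-muRBP     0.40    1.60        0.00
#> 4         2   ROH-RBP-TTR     0.13    0.18        1.68
#> 5         2 ROH-RBP-muTTR     0.40    1.60        0.00
fraction_free(solve_ternary(equilibrium_system(2, 2, 4)))  # 6.7 (percent)
```

With RBP alone, 20% of ROH is free (0.4 of 2 uM); adding TTR drops the free
fraction to ~7% and moves most ROH into the ternary complex — the difference
that distinguishes free-lipid from carrier-mediated delivery.

```r
# simulate accumulation at 0.1/0.4/2 uM (5-min grid, 2 h, triplicate,
# 5% CV noise), fit both kinetic models, compare
tcs <- simulate_accumulation(simulation_config(seed = 1,
                                               noise_model = "gaussian_cv"))
fit <- fit_accumulation(tcs, "biphasic")
fit
#> biphasic fit: SSE = 6777.7 over 216 observations (5 parameters)
#> Kinetic parameters: Kp=91.38 uM/uM, k1=0.01936 /min, Kp*=65.05,
#>   k1*=0.01149, ccell*=35.53 uM
compare_models(fit_accumulation(tcs, "monophasic"), fit)
#> Extra-sum-of-squares F = 117.6, p = 8.44e-45; dAIC = 206.3; preferred: biphasic
```

The fit recovers the generating parameters (Kp 90, k1 0.02, Kp* 70, k1* 0.01,
c* 36) within noise, and the F test flags the secondary uptake phase as
strongly supported.

```r
# Transwell assay with 2% counting noise: Pe per channel and mass balance
assay <- simulate_transwell(simulation_config(seed = 1,
                                              noise_model = "gaussian_cv",
                                              noise_scale = 0.02))
attr(assay_permeability(assay), "summary")
#>     channel      mean_pe        sd_pe n
#> C14     C14 5.974889e-07 1.142783e-08 3
#> H3       H3 4.522726e-06 1.391315e-07 3
round(mass_balance(assay)$fraction_recovered, 4)
#> [1] 1.0049 1.0250 0.9843 1.0267 1.0217 1.0117
```

Recovered Pe matches the configured truths (ROH 4.8e-6 cm/s, sucrose
0.6e-6 cm/s; the ~3% low bias on the fast channel is the finite-sink effect)
and the tracer mass balance closes to within the noise, as it should for an
intact monolayer.

## Command line

```sh
exec/retinolbbb speciate --config inst/extdata/speciation_assay.json --table
exec/retinolbbb simulate accumulation --seed 3 --out out/
exec/retinolbbb fit-accumulation --data out/accumulation.csv --compare
exec/retinolbbb run --seed 1 --out report/
```

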