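# depclog

Biophysical design tools for **dielectrophoretic (DEP) anti-clogging** in
microfluidic blood plasma separators.

Plasma-skimming chips extract plasma from the cell-free layer of a main
channel through many narrow (15 µm) side branches. Their lifetime is
limited by clogging: van der Waals adhesion sticks a first cell to a
branch wall, aggregation piles further cells onto it, and the branch
closes. Driving a coplanar interdigitated electrode array at a frequency
where blood cells show negative DEP (Re(f_CM) ≈ −0.5 below 10 kHz in
plasma) creates a wall repulsion that blocks the initial attachment
without touching the fluidic design. `depclog` is for lab-on-a-chip
designers who want to reason about that operating window quantitatively.

The package implements:

* **Dielectrics** — complex permittivities ε\* = εε₀ − jσ/ω, the
  Clausius-Mossotti factor f_CM = (ε\*_p − ε\*_m)/(ε\*_p + 2ε\*_m),
  single-shell (core + membrane) effective permittivities, and CM spectra
  with sign-crossover location.
* **Forces** — DLVO adhesion F_adh = A·d/12h² +
  32π ε_m ε₀ κ d γ_p γ_w e^(−κh) (k_BT/e)², with γ = tanh(zeζ/4k_BT),
  against the DEP force F_DEP = 2π r³ ε_m ε₀ Re(f_CM) ∇E²_rms over a
  pluggable electrode field-gradient model; force-balance crossovers and
  the smallest protected cell diameter.
* **Metrics** — cell loss η_L = (1 − (C_o+C_p)/C_i)·100, purity
  efficiency E_p = (1 − C_p/C_i)·100, and plasma yield
  η = 100·(100−H_p)(H_o−H_i) / [(100−H_i)(H_o−H_p)].
* **Transport simulator** — a stochastic Lagrangian model of the
  50-branch network: lumped hydraulic-resistance flow splits, bifurcation-
  law branch entry with margination, nDEP gating, near-wall capture,
  aggregation-accelerated clog growth, voltage-dependent lysis above
  20 V, with exact per-species conservation and bitwise seed
  reproducibility.
* **Synthetic data** — haematocrit-targeted blood populations
  (WBC 10-15 µm, RBC 7-8 µm, PLT 2-3 µm) and lognormal replicate counting
  noise, so everything is testable with no external data.

## Worked example

```r
library(depclog)

# 1. Why 1 kHz works: strongest possible nDEP for blood cells in plasma
cm_spectrum(blood_cell_material(), blood_plasma(), 10^seq(1, 4, by = 1))
#> <cm_spectrum> 4 frequencies, 10 Hz .. 10000 Hz
#>   Re(f_CM) in [-0.5000, -0.5000]; sign crossover: none

# 2. The protection window at the 20 V operating point (7 um RBC)
force_balance(7e-6, field_model(voltage_amplitude = 20))
#> <force_balance> d = 7 um; crossover h = 0.0559 nm; protected (h >= 0.5 nm): TRUE
protected_diameter_threshold(field_model(voltage_amplitude = 20))  # metres
#> [1] 8.04e-07
```

Adhesion wins only below ~0.06 nm — effectively the cell can never reach
sticking range at 20 V — and everything larger than ~0.8 µm is protected,
which is why intact cells are safe but sub-micron debris is not.

```r
# 3. Separation runs with and without the anti-clogging drive
pop <- generate_population(25, volume_ul = 0.02, seed = 1)   # 25% haematocrit
simulate_separation(pop, voltage = 0, duration = 60, seed = 1)
#> <separation_outcome> V = 0 V, 60 s simulated, seed 1
#>        inlet blood_out plasma_out captured lysed
#> RBC    22635     22077        458      100     0
#> PLT     1358      1309         43        6     0
#> WBC       32        32          0        0     0
#> debris     0         0          0        0     0
#> clogged branches: 50/50 (all clogged at t = 56.25 s); plasma share (mean): 0.074

out20 <- simulate_separation(pop, voltage = 20, duration = 60, seed = 1)
out20
#> <separation_outcome> V = 20 V, 60 s simulated, seed 1
#>        inlet blood_out plasma_out captured lysed
#> RBC    22635     22442        193        0     0
#> PLT     1358      1242        116        0     0
#> WBC       32        32          0        0     0
#> debris     0         0          0        0     0
#> clogged branches: 0/50; plasma share (mean): 0.313

performance_report(out20$count_table, flow_weighted = TRUE)
#> <performance_report> (flow-weighted cell loss)
#>  species cell_loss_pct purity_efficiency_pct out_of_range
#>      RBC    -1.998e-13                 97.28        FALSE
#>      PLT    -1.554e-13                 72.74        FALSE
#>      WBC    -2.220e-13                100.00        FALSE
#>      all    -2.220e-13                 95.90        FALSE
#> plasma yield: 41.89%
```

Undriven, every branch clogs within the simulated minute; at 20 V the
network stays fully open, no cell is captured (zero flow-weighted loss),
the skimmed plasma is 95.9% cell-depleted and 41.9% of the inlet plasma
is recovered. Drive the same population at 30 V and lysis reappears as
cell loss — the U-shaped loss-vs-voltage curve with its optimum at 20 V.

A YAML-driven pipeline (generate → simulate → noisy replicate counting →
metrics) is available as `run_pipeline("config.yaml")`, and a thin CLI
wraps the same functions:

```sh
Rscript inst/cli/depclog cm-spectrum --fmin 10 --fmax 1e6 --out spectrum.csv
Rscript inst/cli/depclog simulate --config run.yaml --outdir results/
```

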