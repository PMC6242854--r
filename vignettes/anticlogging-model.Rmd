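---
title: "Modelling DEP anti-clogging in microfluidic blood plasma separators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DEP anti-clogging in microfluidic blood plasma separators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depclog)
```

## The problem

Hydrodynamic blood plasma separators skim plasma from the cell-free layer
of a main channel into many narrow side branches. They fail by clogging: a
cell that wanders into a 15 µm branch can be pulled into adhesive contact
with the wall by van der Waals attraction; the stuck cell narrows the
branch, later cells aggregate onto it, and the branch closes. An
interdigitated electrode array at the branch entrances, driven at a
frequency where blood cells experience negative dielectrophoresis (nDEP),
repels cells from the wall region and blocks the *initial* attachment -
which is the step that seeds the whole cascade.

`depclog` implements the biophysics needed to design and reason about that
operating point: dielectric spectra and the Clausius-Mossotti (CM) factor,
the DLVO adhesion force against the DEP repulsion, the three separation
statistics (cell loss, purity efficiency, plasma yield), and a stochastic
transport/capture simulator of the bifurcating channel network fed by a
synthetic blood population.

## Dielectric model

A phase is described by its relative permittivity and conductivity; its
complex permittivity at drive frequency $f$ (with $\omega = 2\pi f$) is

$$\varepsilon^* = \varepsilon\,\varepsilon_0 - j\,\sigma/\omega .$$

The CM factor
$f_{CM} = (\varepsilon_p^* - \varepsilon_m^*)/(\varepsilon_p^* + 2\varepsilon_m^*)$
sets the sign and scale of the DEP force; its real part is bounded in
$[-0.5, 1]$ for passive materials. With plasma at (78, 60 mS/m) and a
blood cell treated as a homogeneous sphere at (63, 1.0 µS/m), the
conductivity contrast dominates below ~10 kHz and
$\mathrm{Re}(f_{CM}) \approx -0.5$, the strongest possible nDEP:

```{r}
cm_spectrum(blood_cell_material(), blood_plasma(), 10^seq(1, 4, by = 1))$re_fcm
```

The homogeneous cell model is the package default because it is fully
determined by published values. Real cells are better described by a
core-shell (cytoplasm + insulating membrane) model; the single-shell
mixing rule is implemented (`shelled_particle()`,
`effective_shell_permittivity()`) but requires user-supplied membrane
parameters - we deliberately do not invent defaults for them. In the
sub-10-kHz regime used here the two models agree in the quantity that
matters, $\mathrm{Re}(f_{CM}) \approx -0.5$, because any membrane-limited
cell looks like an insulating sphere at low frequency.

## Forces

The adhesive force on a cell of diameter $d$ at separation $h$ from the
wall combines van der Waals attraction and the electrostatic double layer
(EDL) term:

$$F_v = \frac{A d}{12 h^2}, \qquad
F_{EDL} = 32 \pi \varepsilon_m \varepsilon_0 \kappa d \gamma_p \gamma_w
e^{-\kappa h} (k_B T / e)^2 ,$$

with $\gamma = \tanh(z e \zeta / 4 k_B T)$. Defaults: Hamaker constant
5 zJ, Debye parameter 0.159 nm$^{-1}$, $T$ = 296.15 K, $z = 1$
(PBS is dominated by monovalent ions), $\zeta$ = -10.8 mV (RBC) and
-13.825 mV (PDMS). Because both surfaces are like-charged, the EDL term is
physically a repulsion; the literature expression nevertheless *adds* the
two terms. Both conventions are implemented (`adhesive_force()`), and the
literal sum is the default so that results match the printed formulation;
the `"signed"` variant subtracts the EDL term. At the default parameters
the choice is immaterial in practice: $F_v$ exceeds $F_{EDL}$ by more than
an order of magnitude everywhere below a few nanometres.

The time-averaged DEP force on a sphere of radius $r$ is

$$F_{DEP} = 2\pi r^3 \varepsilon_m \varepsilon_0\,
\mathrm{Re}(f_{CM})\, \nabla E_{rms}^2 .$$

### Field-gradient model and its calibration

No closed form exists for an arbitrary electrode layout, so the package
uses the characteristic-scale law for a periodic coplanar IDT array,

$$|\nabla E_{rms}^2|(h) = \left(\frac{V_{rms}}{g}\right)^2 \frac{4\pi}{p}
\, e^{-4\pi h / p},$$

exposed behind `field_gradient()` as one variant of a pluggable interface.
It has the correct $V^2$ scaling and the exponential height decay (decay
length $p/4\pi$) characteristic of periodic coplanar electrodes. Drive
amplitudes are interpreted as sinusoid *peak* values
($V_{rms} = V/\sqrt{2}$); set `voltage_is_rms = TRUE` to override. The
electrode geometry defaults, gap $g$ = 5 µm and pitch $p$ = 10 µm, are a
plausible fine-pitch IDT design chosen once so that the model reproduces
the two published qualitative anchors of the method at the 20 V operating
point: the smallest protected cell diameter falls near 1 µm (the model
gives 0.80 µm), and the separation below which adhesion beats the DEP
force is well under 0.5 nm (the model gives 0.056 nm for a 7 µm RBC).
Both are re-computed and logged by the test suite.

`force_balance()` samples both force magnitudes over a separation grid and
locates their crossing by bisection (tolerance $10^{-12}$ m);
`protected_diameter_threshold()` exploits the linear-vs-cubic diameter
scaling (the threshold is unique) and bisects to $10^{-9}$ m.

## Separation statistics

With $C$ the per-species concentrations and $H$ the haematocrits at inlet
(i), blood outlet (o) and plasma outlet (p):

$$\eta_L = \left(1 - \frac{C_o + C_p}{C_i}\right) \times 100, \qquad
E_p = \left(1 - \frac{C_p}{C_i}\right) \times 100, \qquad
\eta = \frac{(100 - H_p)(H_o - H_i)}{(100 - H_i)(H_o - H_p)} \times 100 .$$

The concentration-based cell loss is the default, exactly as defined.
Note that it ignores the outlet flow split: when plasma is skimmed the
blood-outlet concentration *rises*, so conservative devices can report
negative $\eta_L$. A flow-weighted variant
($C Q$ fluxes instead of $C$) is available behind the `flows` argument /
`flow_weighted` flag and is what the simulator's own direction-of-effect
tests use, since the simulator knows its outlet volumes exactly. Values
outside $[0, 100]$ are reported unchanged with a data-quality flag, never
clipped - noisy replicate counts genuinely produce them.

## The transport and clogging simulator

The supplementary CFD of the original device study is out of scope here;
the simulator replaces it with a desk-scale lumped model in three layers.

**Hydraulic ladder.** Every duct gets the rectangular Hagen-Poiseuille
resistance $R = 12 \mu L / (a^3 b (1 - 0.63 a/b))$ ($a$ the short side).
The 25 junction stations (two branches each) form a resistive ladder
solved by a backward equivalent-resistance pass and a forward
proportional-split pass, so volume conservation is exact by construction.
Branch conductance scales with the cube of the *effective* (fouling-
reduced) width; a clogged branch carries nothing, and flow redistributes
after every capture. Defaults (main 100 µm x 80 µm, branches
15 µm x 80 µm x 5 mm, 200 µm spacing, 2 mm tail, 1.2 mPa s) give a total
branch flow share of 0.31, i.e. plasma-yield headroom in the range
observed for devices of this class.

**Stochastic cell transport.** Cells arrive uniformly over the run,
pre-assigned to a near-wall or core lateral class (near-wall occupancy
0.3) standing in for margination. At each station a cell enters the
branch pair with probability
(local flow fraction) x (class weight) x $e^{-d/d_{ref}}$
($d_{ref}$ = 10 µm), the bifurcation-law baseline damped by
size-dependent margination, and additionally gated by nDEP: the
electrodes sit at the branch mouths, so entry requires beating the DEP
barrier. The gate is $P(\text{deflected}) = r/(1+r)$ with
$r = |F_{DEP}(w_b/2)| / 6\pi\mu a v_b$, DEP against Stokes drag at the
mean branch velocity. This gate is a package design choice beyond the
bare bifurcation law: without it, repelled-but-entering cells would exit
through the plasma port and the plasma would get *dirtier* with voltage,
the opposite of what the device physics does.

Inside a branch the cell draws a near-wall approach distance uniformly on
$(0, 10\,h_{capture}/m_b)$ (no published near-wall approach statistics
exist, so the window is a documented free parameter; $h_{capture}$ =
10 nm) and is captured iff the approach lies below both $h_{capture}$ and
the adhesion-dominance height where $F_{adh} > |F_{DEP}|$. A cell wider
than the current effective width is sieved out deterministically.

**Clog feedback.** A capture narrows the branch by the captured diameter
(`clog_fraction` = 1) and multiplies the branch's capture multiplier
$m_b$ by the aggregation factor (default 3), modelling cell-to-cell
attachment being easier than cell-to-wall. Once a branch holds an
aggregate, passing main-channel cells can also attach at the mouth with
probability `attach_rate` (0.002) times the in-branch capture
probability - the aggregate protrudes into a small fraction of the main
cross-section. This term is what lets a nearly-closed branch finish
clogging even after its through-flow has collapsed (flow $\propto w^3$
self-limits pure entry-driven clogging). nDEP suppresses both channels of
capture through the same force criterion. A branch is clogged when its
effective width falls below the smallest simulated cell diameter.

**Lysis.** Above the 20 V electroporation threshold cells lyse with
probability $1 - e^{-k (V - 20) t_{exp}}$, $k$ = 0.009 V$^{-1}$s$^{-1}$,
$t_{exp}$ the physical residence time over the electrodes (wetted main
volume / flow rate, 3.4 s at 1 µl/min - so halving the flow rate
increases lysis, as observed in practice). A simple hazard with one
parameter was preferred over a two-parameter logistic; the contract
(zero at or below 20 V, increasing in overvoltage and exposure) is
identical. Lysed cells become 0.5 µm debris that re-enters transport;
debris sits below the DEP protection threshold, so it can still foul the
device - this is why performance degrades again above 20 V.

**Time scaling.** Runs use scaled time: the default 60-120 simulated
seconds stand for hours of device time (the `time_compression` factor,
default 60, is bookkeeping recorded in the config). Sample volumes of
0.02-0.12 µl give populations of roughly 25,000-150,000 cells, enough for
stable Poisson statistics of the rare capture events while keeping a full
voltage sweep plus clogging-horizon comparison within a few minutes on
one CPU. The RNG is a single seeded stream with a fixed draw order, so an
identical seed and configuration reproduces an outcome bitwise.

## Synthetic population and counting noise

`generate_population()` draws diameters uniformly within the printed
species ranges (WBC 10-15 µm, RBC 7-8 µm, PLT 2-3 µm), sets the RBC count
so the spherical-equivalent RBC volume fraction matches the target
haematocrit (25% diluted / 45% whole blood), and scales WBC and PLT by
standard physiological ratios (per µl of whole blood: RBC 5x10^6,
PLT 3x10^5, WBC 7x10^3) - none of these ratios are published for the
device study, so textbook values are used and are config-overridable.
`emulate_count_experiment()` applies mean-preserving multiplicative
lognormal noise (default CV 10%, chosen to give replicate SDs of the same
order as bench haemocytometer counts) and reports replicate mean ± SD.
The lognormal form guarantees nonnegative concentrations.

What the generator does *not* emulate: biconcave RBC geometry (spherical
equivalents bias absolute counts at fixed haematocrit), haematocrit-
dependent viscosity and cell-cell hydrodynamic interactions, deformable
squeezing through necks, and specific-receptor adhesion after initial
contact. Passing simulator tests therefore demonstrate that the *model*
reproduces the direction and ordering of the device's behaviour
(clogging without drive, protection at 20 V, degradation above it), not
that it predicts absolute wet-lab percentages.

## Numerical choices

* Bisection tolerances: $10^{-12}$ m (force crossover), $10^{-9}$ m
  (diameter threshold), relative $10^{-6}$ (CM sign crossover); an exact
  zero at a grid point short-circuits to that point.
* All internal quantities are SI; $\omega = 2\pi f$ conversions happen
  inside operations. Unit-carrying config strings ("5 zJ", "15 um") are
  converted on load, and unknown units or keys are hard errors.
* Degenerate inputs fail loudly: zero CM denominator, $h = 0$ in the
  singular van der Waals term, equal outlet haematocrits in the yield,
  updates to already-clogged branches.
* Fixed timestep 0.25 s for branch-state/flow updates; entry draws happen
  per junction passage within a batch against frozen flow fractions, and
  captures re-solve the ladder at batch end.

## Limitations

The electrode field model is a characteristic-scale law, not a field
solution; absolute DEP forces inherit its calibration. The margination,
approach-window, aggregation and attachment parameters are plausible but
unfitted - they are exposed in `sim_control()` precisely because no
quantitative near-wall statistics were available to fit. Whole-blood
rheology, AC electro-osmosis, electrothermal flow and electrode
polarisation are out of scope.
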