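---
title: "Kinetics of glutathione-modulated arsenic methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of glutathione-modulated arsenic methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arsmet)
```

## The model

Ingested inorganic arsenic (iAs, trivalent arsenite in this model) is
detoxified in hepatocytes along the classical alternating
methylation/reduction chain: AS3MT methylates iAs to monomethylarsonic acid
(MMAs^V^), endogenous thiols reduce it to monomethylarsonous acid
(MMAs^III^), AS3MT methylates again to dimethylarsinic acid (DMAs^V^), and a
second reduction yields DMAs^III^. `arsmet` implements a nine-species
kinetic ODE model of this chain in a well-mixed reaction compartment, with
three distinct roles for glutathione (GSH):

1. **Reductant.** The two reductions are first order in the pentavalent
   species with rate constants affine in GSH, `k5 + k6*[GSH]` and
   `k7 + k8*[GSH]`; the intercepts represent thiols other than GSH. At 1 mM
   GSH the first reduction runs exactly twice its GSH-free speed.
2. **Activator of AS3MT.** Both methylation velocities are multiplied by a
   dimensionless activation `U(GSH) = u_basal + k9*GSH^5/(k10^5 + GSH^5)`,
   a Hill function with coefficient 5 over a basal floor. The floor is
   needed because methylation is observed (slowly) in GSH-free assays, which
   a pure Hill term cannot produce.
3. **Sequestering agent.** The three trivalent arsenicals bind GSH
   reversibly by mass action: iAs + 3 GSH <-> arsenic triglutathione (AsTG),
   MMAs^III^ + 2 GSH <-> monomethylarsenic diglutathione (MMAsG),
   DMAs^III^ + GSH <-> dimethylarsenic glutathione (DMAsG). Conjugated
   arsenicals are not methylated further. Free GSH additionally decays with
   a 2.5 h half-life (`k4 = ln 2 / 2.5`), as it does in enzyme-in-solution
   reaction mixtures; this decay is active in every preset experiment.

The methylation velocities are Michaelis–Menten laws with independent
inhibition factors:

$$V_1 = V_{max}\,\frac{[iAs]}{K_m + [iAs]}\cdot
        \frac{1}{1 + [iAs]/K_{iA}}\cdot\frac{1}{1 + [MMAs^V]/K_{iM}},$$

$$V_2 = V_{max}\,\frac{[MMAs^{III}]}{K_m + [MMAs^{III}]}\cdot
        \frac{1}{1 + [iAs]/K_{iA2}}\cdot
        \frac{1}{1 + [MMAs^{III}]^2/K_{iM2}^2},$$

and the fluxes in the equations are $U([GSH])\cdot V_1$ and
$U([GSH])\cdot V_2$. $V_1$ has substrate inhibition by iAs (interior optimum
at $\sqrt{K_m K_{iA}} \approx 2.41$ μM) and product inhibition by MMAs^V^.
$V_2$ carries a *cooperative* (squared) substrate inhibition by MMAs^III^;
the square is what reproduces the sharp rise-then-fall of DMAs yield across
MMAs^III^ doses, with an interior optimum near 3.7 μM. Inhibition terms could in principle
multiply the whole Michaelis–Menten factor or instead modify $K_m$
(competitive placement); we use independent multiplicative factors, the
standard noncompetitive form, throughout.

Two conservation laws are built into the equations and verified by tests at
random states and along trajectories: the eight arsenic-carrying species sum
to a constant (there is no export in this model), and the GSH pool
`GSH + 3 AsTG + 2 MMAsG + DMAsG` changes only through the first-order decay
term. These laws fix every sign and stoichiometric factor in the system: in
particular, MMAs^V^ production is exactly the flux $U\cdot V_1$ that
consumes iAs (no additional rate factor), and the DMAsG dissociation term
enters its own equation negatively, as reversibility requires.

## Units and parameters

All internal concentrations are μM and all times are hours; interface-level
arguments quote GSH doses in mM and assay durations in minutes, converted at
the boundary (×1000, /60). The μM reading of the conjugation and reduction
terms is the only dimensionally consistent one: it makes 1 mM GSH double the
first reduction and makes DMAs^III^ predominantly conjugated at mM GSH, both
features of the data the model was built against; a mM reading would make
conjugation vanish.

The rate constants (`kinetic_parameters()`) fall into two groups:

* **Measured / literature constants** — the conjugation on/off rates, the
  decay and reduction constants, and the kinetic-law constants `Km = 4.6`,
  `KiA = 1.26`, `KiM = 40`, `KiA2 = 40`, `KiM2 = 6` μM. These are fixed
  defaults, shipped verbatim in
  `inst/extdata/default_parameters.conf`.
* **Calibrated constants** — `Vmax`, `k9`, `k10`, `u_basal` are not
  reported by the source experiments. Because every methylation flux
  involves only the product $U \cdot V_{max}$, the activation scale and the
  velocity scale are not separately identifiable; we pin the scale with the
  convention `u_basal + k9 = 1e4` (the reported midrange activation value of
  5000 implies a range of roughly 0–10^4^) and calibrate `Vmax`, `k10`,
  `u_basal`.

## Calibration

`default_problem()` encodes the four semi-quantitative facts the source
experiments pin down, as *interval* constraints with a hinge penalty (zero
inside the interval, squared relative distance outside): the ~4-fold gain of
peak DMAs yield at 1 mM GSH in the substrate sweep (`[3, 5]`); the interior
optimum of 2-hour methylation yield between 5 and 10 mM GSH; the 4–5 h peak
of total methylation flux under decaying 20 mM GSH; and nonzero but
sub-1-mM-GSH methylation in the GSH-free time course. Intervals rather than
point targets are deliberate: the facts are quoted as "about four" and
"range 5–10", so they define a feasibility region, not a point. The region
is genuinely non-degenerate — `analysis/01_calibrate.R` shows a refit from a
naive start converging to a different feasible corner (`k10 ≈ 930`,
`u_basal ≈ 842`) than the shipped values.

`calibrate()` evaluates the starting parameters first and returns them
untouched when they already satisfy every constraint (the shipped defaults
do); otherwise it runs a seeded Latin-hypercube multistart (default 16
starts) of bounded derivative-free searches (Brent in one dimension,
Nelder–Mead on logit/log-transformed coordinates otherwise). Bounds:
`Vmax` ∈ [1e-6, 1e-1] μM/hr per unit activation, `k10` ∈ [0.1, 20] mM,
`u_basal` ∈ [0, 5000]. The shipped values are

```{r}
p <- kinetic_parameters()
unlist(p[c("Vmax", "k9", "k10", "u_basal")])
```

Within the feasible region the experiments behave as follows. Below ~3 mM
GSH the Hill activation is the dominant GSH effect; it saturates by ~5–7 mM
(`k10 = 1.5` mM with coefficient 5). Above ~10 mM, AsTG formation (growing
with the cube of GSH) withholds an increasing share of iAs, so the 2-hour
yield passes through an interior optimum near 8 mM. The small `Vmax` puts
the preset assays in the far-from-saturation regime, where dose–response
*shapes* and yield *ratios* — the only calibration surfaces available — are
invariant to `Vmax`; `Vmax` itself is pinned by the flux-peak timing
constraint (see below). Absolute yields are therefore not comparable to any
particular assay's absolute scale, which would require the unreported
enzyme-specific velocity; this is a known, accepted limitation.

### The flux-peak mechanism and the equilibrated start

In the 8-hour, 20 mM GSH experiment the total methylation flux
$U \cdot (V_1 + V_2)$ peaks at an interior time because two opposing
processes cross: as GSH decays, AsTG dissociates and releases free iAs
(raising $V_1$), while continuing methylation slowly depletes the substrate;
late in the run GSH falls toward `k10` and the activation collapses. The
peak time moves later as `Vmax` decreases (slower depletion), which is what
identifies `Vmax` given the other constraints.

Conjugation at 20 mM GSH equilibrates on a ~10 s timescale
(`1/(k1*GSH^3 + k_1)`), far below the hours-scale observation grid, so
`flux_time_course()` starts from the conjugation equilibrium
(`equilibrate_conjugates()`) rather than a fully unbound state. Starting
unbound would prepend a seconds-long mixing transient whose very first flux
sample (free substrate, full activation) exceeds everything that follows —
an artifact of sampling inside the transient, not a feature of the
dynamics. All other presets start unbound, as their assays do, since at
their GSH levels the transient is negligible.

### Assay horizon of the substrate sweep

The incubation time of the substrate-sweep assay is not reported; the
preset defaults to 1 hour, exposed as `horizon_h`. The calibration stage
reports the sensitivity of the GSH gain ratio to this choice
(`results/fig2_horizon_sensitivity.csv`): roughly 6.1 at 30 min, 4.0 at 1 h,
2.7 at 2 h. The ratio constraint is therefore meaningful only jointly with
the horizon convention, which is why the horizon is a documented preset
default rather than a free knob.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable, adaptive), relative
  tolerance 1e-8, absolute tolerance 1e-10 μM; readout times evaluated on
  the integrator's dense output, never by re-integration. The stiffest rates
  in the presets are ~4000/hr (MMAsG formation at 20 mM GSH).
* Nonnegativity: the right-hand side clamps sub-zero components to zero
  before evaluating rates; after integration, undershoots in (−1e-9, 0) μM
  are clamped to zero and anything below −1e-9 is an error. Halving both
  tolerances moves arsenic-species readouts by < 1e-6 μM (tested).
* Degenerate variants: under `no_conjugation`, conjugates that start at
  zero have no source term, so their columns are set to exactly zero rather
  than integrator noise (~1e-22).
* Argmax extraction on dose grids and flux curves: quadratic interpolation
  through the discrete maximum and its two neighbours; maxima at a grid
  boundary are reported as the boundary point; degenerate (non-concave)
  fits fall back to the grid maximum. Ties in the multistart calibration are
  broken by lowest objective, then lowest start index.
* Problem sizes: presets use a 41-point substrate grid (0–20 μM by 0.5),
  the 6-dose GSH grid {1, 3, 5, 7, 10, 20} mM (the 4-dose alternative
  {1, 5, 10, 20} is available), 17 readout times over 40 minutes, and an
  801-point grid over 8 h for flux-peak extraction; the calibration
  constraints use coarser grids (21-point sweep, 161-point flux grid) since
  hinge constraints need far less resolution than archived tables.

## The synthetic-assay generator

`generate_dataset()` forward-simulates a preset design and applies the
observation model to the *conjugate-blind* readouts — the measured
quantities are sums of an arsenical and its GSH conjugates
(`iAs + AsTG`, total/trivalent MMAs, total/trivalent DMAs), exactly as the
chromatographic assays it emulates cannot distinguish bound from free
arsenicals. Noise is proportional: each readout is multiplied by an
independent Gaussian factor of mean 1 and standard deviation `cv`
(truncated at zero), defaulting to `cv = 0.1`; assay readouts span orders of
magnitude across designs, so proportional error is the standard assumption,
and a unit-mean log-normal alternative is provided. The actual error
magnitude of the emulated assays is unreported; 10% is a placeholder and is
configurable. Datasets regenerate bit-identically from their recorded
(design, true parameters, noise descriptor, seed).

What passing recovery tests show — and what they do not: with this noise
structure, KiM2 is recovered from a 9-dose sweep to ~1% (noise-free) and a
median ~1–2% error across replicates at 10% noise, so the *design*
identifies the cooperative inhibition constant. Real assays add systematic
components the generator deliberately omits (chromatographic recovery,
detection limits, batch effects, model misspecification), so real-data
errors will be larger than the replicate spread seen here.

## Known limitations

* No methylation of GSH-conjugated arsenicals (the alternative pathway in
  which conjugates are the methylation substrates is out of scope), no
  export or bile fluxes, no cellular transport, no explicit SAM state (the
  methyl donor is implicit in `Vmax`), no enzyme-mechanism resolution.
* Absolute yields are in model units of the calibrated `U*Vmax` product;
  only shapes, ratios, optima and timings are calibrated surfaces.
* The activation constants are constrained jointly, not identified
  individually; profile curves on dose–response designs
  (`analysis/07_parameter_recovery.R`) show a shallow `Vmax` direction.
* With 1 mM GSH the substrate sweep's within-grid decline rides on the
  early unbound transient; at full conjugation equilibrium the free
  substrate would sit below the inhibitory range across the 0–20 μM grid.
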