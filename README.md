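# arsmet

Kinetic modeling of glutathione effects on hepatic arsenic methylation.

Inorganic arsenic (iAs) is detoxified in the liver along the classical
alternating methylation/reduction chain catalyzed by AS3MT:
iAs → MMAs^V → MMAs^III → DMAs^V → DMAs^III. Glutathione (GSH) enters this
chain in three mechanistically distinct ways, and disentangling them is what
this package is for. It is aimed at quantitative toxicologists and systems
biologists who want to interpret in-vitro methylation assays — substrate
sweeps, time courses, GSH dose–responses — in which the three effects are
confounded.

`arsmet` implements a nine-species ODE model (the five free arsenicals, GSH,
and the three GSH conjugates AsTG, MMAsG, DMAsG) in which GSH:

1. **speeds the reductions** — first-order rates `k5 + k6·[GSH]` and
   `k7 + k8·[GSH]`;
2. **activates AS3MT** — both methylation velocities are scaled by a Hill
   activation `U(GSH) = u_basal + k9·GSH⁵/(k10⁵ + GSH⁵)`;
3. **sequesters trivalent arsenicals** — reversible mass-action conjugation
   consuming 3, 2, 1 GSH (iAs ⇄ AsTG, MMAs^III ⇄ MMAsG, DMAs^III ⇄ DMAsG),
   with conjugates protected from further methylation.

The methylation velocities are Michaelis–Menten laws with inhibition
factors,

    V₁ = Vmax·[iAs]/(Km+[iAs]) · 1/(1+[iAs]/KiA) · 1/(1+[MMAsV]/KiM)
    V₂ = Vmax·[S]/(Km+[S])     · 1/(1+[iAs]/KiA2) · 1/(1+[S]²/KiM2²),  S = MMAsIII

the fluxes being `U·V₁` and `U·V₂`. The squared (cooperative) substrate
inhibition in V₂ produces the characteristic rise-then-fall of DMAs yield
across MMAs^III doses. Free GSH decays with its 2.5 h in-solution half-life
in every experiment. Arsenic atoms are conserved exactly; the GSH pool
(free + 3·AsTG + 2·MMAsG + DMAsG) changes only by decay — both identities
are enforced by construction and verified by tests.

The interplay of effects 2 and 3 explains the model's headline behavior:
methylation yield is maximal at *intermediate* GSH (the physiological mM
range), because activation saturates by ~5–7 mM while sequestration keeps
growing with the GSH cube. Freezing the activation makes the dose–response
monotone decreasing; removing conjugation makes it monotone increasing; both
effects together give the interior optimum.

## Worked example

```r
library(arsmet)
p <- kinetic_parameters()          # literature constants + calibrated activation

# two-hour GSH dose-response of methylation yield (1 muM iAs)
dr <- gsh_dose_response(params = p)
print(dr$table, digits = 3)
#>   dose_mM total_MMAs total_DMAs total_methylated
#> 1       1   0.000204   8.33e-09         0.000204
#> 2       3   0.003446   3.11e-07         0.003447
#> 3       5   0.003926   1.54e-07         0.003926
#> 4       7   0.003963   8.07e-08         0.003963
#> 5      10   0.003958   3.97e-08         0.003958
#> 6      20   0.003826   9.66e-09         0.003826
sprintf("optimum: %.2f mM", dr$optimum_mM)
#> [1] "optimum: 8.30 mM"
```

The yield columns are *conjugate-blind* (an arsenical plus its GSH
conjugates, μM), matching what chromatographic assays actually measure. The
yield rises steeply from 1 to 5 mM GSH (AS3MT activation), flattens, and
declines by 20 mM (triglutathione sequestration of the substrate); the
quadratic-interpolated optimum of MMAs+DMAs sits at 8.30 mM, inside the
physiological 5–10 mM window.

Two more presets:

```r
# substrate-inhibition sweep: ~4-fold peak-DMAs gain from 1 mM GSH
r0 <- mmas_sweep(0, params = p); r1 <- mmas_sweep(1, params = p)
max(r1$total_DMAs) / max(r0$total_DMAs)
#> [1] 4.044842

# methylation flux under decaying 20 mM GSH: interior peak
flux_time_course(p)$peak_time_h
#> [1] 4.26593
```

## The analysis workflow

The numbered drivers under `analysis/` reproduce the full study and write
their tables (with JSON provenance sidecars) under `results/`:

| script | what it does |
|---|---|
| `01_calibrate.R` | calibrates `Vmax`, `k10`, `u_basal` against the four interval constraints; horizon sensitivity of the 4× ratio |
| `02_substrate_sweep.R` | MMAs^III dose–response of DMAs yield at 0 / 1 mM GSH |
| `03_time_course.R` | 40-minute time courses of 1 μM iAs at 0 / 1 mM GSH |
| `04_gsh_dose_response.R` | 2-hour yield vs GSH dose, interior optimum |
| `05_ablation.R` | frozen-activation and no-conjugation variants |
| `06_flux_dynamics.R` | 8-hour methylation-flux dynamics under GSH decay |
| `07_parameter_recovery.R` | KiM2 recovery from synthetic assays; activation-constant profiles |

The methods vignette
(`vignettes/arsenic-methylation-kinetics.Rmd`) documents the model's
assumptions, units, the calibration conventions (including the
`u_basal + k9 = 10⁴` identifiability convention) and the numerical
contract.

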