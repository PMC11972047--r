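# gadodose

Desk-scale simulation study of gadolinium characteristic x-ray emission as a
surrogate for in-vivo dose in pencil-beam-scanned (PBS) proton therapy.

## The idea

Proton therapy delivers dose with millimetric precision, but verifying *in
vivo* that the planned dose actually reached the target is still an open
problem. When the target is loaded with a gadolinium-based contrast agent
(Dotarem, 0.5 mmol/mL gadoterate), the treatment beam itself makes the target
glow at 43 keV — the Gd Kα1 line — through two channels:

1. **PIXE**: protons ionize the Gd K shell; the vacancy relaxes by emitting
   characteristic x-rays (Kα1 at 43 keV).
2. **Neutron capture**: secondary neutrons thermalize and are captured by
   ¹⁵⁵Gd/¹⁵⁷Gd (a combined thermal cross section of ≈48,900 barns), followed
   by internal conversion and again Kα emission.

Because both channels are driven by the local proton fluence through the
Gd-loaded volume, the detected 43 keV intensity tracks the dose delivered
*to the target*: if the target drifts out of the beam, dose and signal drop
together; if it drifts along the beam axis, signal and dose decouple in a
characteristic, energy-dependent way. This package implements the full
pipeline — materials, phantom, analytic dose engine, treatment planner,
two-channel emission model, displacement scenario engine and tracking
analysis — as a fast, deterministic surrogate for a Monte-Carlo particle
transport study.

## Worked example

The canonical setup is a 10 cm water cube (2 mm voxels) with a 2 cm
Dotarem-filled target at its center, irradiated from the +z face:

```r
library(gadodose)

ph <- phantom_grid()            # defaults = canonical geometry
ph$target
#> <material> dotarem
#>   density: 1.1753 g/cm^3   RSP: 1.1270   mu(43 keV): 0.5276 cm^-1
#>   Gd: 0.5 mmol/mL  (3.011e+20 nuclei/cm^3, Sigma_a = 14.723 cm^-1)

plan <- plan_treatment(ph)      # layers, lattice, NNLS weights (~5 s)
plan
#> <treatment_plan> 588 spots / 12 energy layers (dotarem target)
#>   energies: 69.97 - 89.39 MeV;  lattice 3 mm;  layers 2 mm WE
#>   prescription 4 Gy;  mean target dose 3.997 Gy;  D90 3.829 Gy
#>   total protons 1.586e+10
```

Hold the plan fixed and displace the target (the scenario engine reassigns
the target material; spot positions, energies and weights do not move):

```r
run_scenario(plan, ph, "x", 0)      # baseline
#> <scenario_result> x+0 mm (expected mode)
#>   target dose 3.997 Gy | detected 43 keV 1.851e+06 (PIXE 1.6e+06, capture 2.515e+05)
#>   V95 96.8%  D90 3.829 Gy

run_scenario(plan, ph, "x", 10)     # 10 mm transverse drift
#> <scenario_result> x+10 mm (expected mode)
#>   target dose 3.091 Gy | detected 43 keV 1.453e+06 (PIXE 1.255e+06, capture 1.983e+05)
#>   V95 48.4%  D90 1.280 Gy
```

Transversely, signal is proportional to dose. Over the canonical series
(0–10 mm in 2 mm steps) a single line fits all six scenarios:

```r
sx <- displacement_series(plan, ph, "x")
treatment_tracking(sx)$fits$transverse
#> <dose_signal_fit> [transverse] slope 4.347e+05 +- 5.36e+03 counts/Gy,
#>   intercept 1.078e+05, R^2 0.9994 (n=6)
```

Per spot group, the dose change and the signal change agree within two
percentage points:

```r
pc <- percent_change(sx$results[[1]], sx$results[[6]],
                     group_spots(plan, "corners"))
pc[, c("group", "dose_pct", "signal_pct")]
#>    group dose_pct signal_pct
#>  (-9,-9)    -86.5      -84.8
#>   (-9,9)    -86.5      -84.8
#>   (9,-9)     57.3       55.8
#>    (9,9)     57.3       55.8
```

Longitudinally, the branches split: moving the target downstream (deeper)
loses both dose and signal, while moving it upstream keeps the dose nearly
flat but *raises* the signal, because the protons arrive at the target with
higher kinetic energy where the K-shell ionization cross section is larger.
The per-spot dose-signal slope orders strictly by the protons' target-entry
energy:

```r
sz <- displacement_series(plan, ph, "z")
slope_vs_energy(sz, ph)
#>   mm entry_KE_MeV   slope
#>  -10        36.06  228648
#>   -2        47.65  505257
#>    0        50.22  593205
#>  +10        61.80 1615440    # strictly increasing in entry energy
```

So a single measured quantity (the 43 keV line intensity) distinguishes
"dose fell because the target moved sideways" from "dose is intact but the
target moved along the beam" — the basis for treatment tracking.

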