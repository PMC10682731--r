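# aortaflow

Quantitative hemodynamics of the aortic valve and ascending aorta (AAo) for
R: the analysis chain used to compare prosthetic valve designs — bileaflet
mechanical valved conduits after a Bentall procedure — against healthy
controls with same-day Doppler echocardiography and 4D flow MRI.

**Who it is for.** Cardiovascular imaging researchers who have (a)
time-resolved 3-component velocity fields on a voxel grid (4D flow MRI) with
aorta / AAo segmentation masks, and/or (b) Doppler velocity envelopes, and
want reproducible, unit-checked summary metrics plus the group-comparison
statistics — and verifiable numerics, via analytic flow phantoms with
closed-form ground truth.

## What it computes

**4D flow MRI side** (at peak systole, the frame maximizing mean in-mask
speed):

- velocity gradient tensor `G[i,j] = dv_i/dx_j` by mask-aware finite
  differences;
- voxelwise viscous energy loss rate, `VELR = 2 mu sum_ij S_ij^2` with
  `S = (G + G^T)/2` (W/m^3), and vorticity `omega = curl v` (1/s);
- AAo summaries: total VELR (mW), VELR density (W/m^3), mean vorticity
  magnitude (1/s), ROI volume;
- massless-particle pathlines (RK4, trilinear/linear interpolation, 400
  particles seeded every 40 ms by default);
- NIfTI I/O for fields, masks and maps; venc anti-aliasing (temporal-median
  single-wrap rule).

**Echo side**: ejection-window gating, VTI (cm), transvalvular peak velocity
(m/s), peak/mean pressure gradient by simplified Bernoulli `dP = 4 v^2`
(mmHg), continuity-equation effective orifice area
`EOA = pi (d/2)^2 VTI_LVOT / VTI_AV` (cm^2), EOAi (cm^2/m^2) and discharge
coefficient (EOA / geometric orifice area).

**Statistics**: Lilliefors normality gate (Monte Carlo p), one-way ANOVA or
Kruskal–Wallis omnibus at p < 0.05, pairwise t / Wilcoxon rank-sum at the
Bonferroni-adjusted threshold 0.05/3 (printed 0.017), publication-style
summary tables.

**Synthetic data**: analytic phantoms (Poiseuille, solid-body rotation,
Lamb–Oseen vortex, uniform, shear) with closed-form total VELR and mean
vorticity; Doppler traces with known VTI/TPG; cohort simulator defaulting to
the published three-group summaries (n = 10/6/36).

## Worked example

Poiseuille pipe flow (R = 10 mm, L = 100 mm, U = 1 m/s) has total
dissipation `2 pi mu L U^2 = 2.01 mW` and mean vorticity
`(4/3) U / R = 133.3 1/s`; the pipeline recovers both from the sampled
voxel field:

```r
library(aortaflow)
ph <- make_phantom("poiseuille", params = list(R = 10, L = 100, U = 1),
                   shape = c(18, 18, 82), spacing = c(1.25, 1.25, 1.25),
                   nt = 1, waveform = 1)
q <- quantify_hemodynamics(ph$field, ph$mask)
q$summary
#> <hemodynamic_summary> frame 1
#>   total VELR     2.033 mW
#>   VELR density   62.54 W/m^3
#>   mean vorticity 132.5 1/s
#>   ROI volume     32.5 ml
```

(1.1% off the closed form at 1.25 mm voxels; the error falls at ~2nd order
with resolution — see the acceptance suite.)

Echo metrics from synthetic Doppler traces with known ground truth:

```r
av   <- synthesize_doppler(tpv = 1.9, pulse_width = 0.3, cycle = 0.9,
                           sampling = 500, modality = "CW", site = "aortic-valve")
lvot <- synthesize_doppler(tpv = 1.0, pulse_width = 0.3, cycle = 0.9,
                           sampling = 500, modality = "PW", site = "LVOT")
assess_echo(av$trace, lvot$trace, lvot_diameter_cm = 2.2,
            bsa_m2 = 2.1, goa_cm2 = 3.73)
#> <echo_metrics>
#>   TPV       1.9 m/s   peak TPG 14.4 mmHg   mean TPG 7.71 mmHg
#>   VTI (AV)  36.1 cm    VTI (LVOT) 19 cm
#>   EOA       2 cm^2  EOAi 0.953 cm^2/m^2  discharge coeff 0.536
```

TPV 1.9 m/s gives peak TPG `4 * 1.9^2 = 14.4 mmHg`; the mean TPG of a
half-sine pulse is `2 * tpv^2 = 7.22 mmHg` over the pulse (7.71 over the
10%-gated window, which trims the low-velocity tails).

Three-group comparison on a simulated cohort drawn from the published group
summaries (AAo VELR density, W/m^3: 50.6 ± 20.1 vs 89.8 ± 35.2 vs
21.4 ± 9.2 at n = 10/6/36):

```r
tab <- simulate_cohort(rng_seed = 1)
compare_groups(tab, "velr_density")
#> <comparison_result> velr_density: anova p = 1.2e-14 *
#>   On-X vs SJM/CM: t p = 0.02371
#>   On-X vs healthy: t p = 2.537e-09 *
#>   SJM/CM vs healthy: t p = 3.36e-16 *
```

The omnibus p-value is far below 0.001 — group separation at these published
means/SDs is decisive — and the starred pairs are significant at the 0.017
pairwise threshold.

## Command line

A thin CLI wraps the pipeline (installed at `inst/cli/aortaflow`):

```sh
aortaflow load-check <stem>            # validate a <stem>_vx/_vy/_vz.nii + .json dataset
aortaflow quantify --field <stem> --aorta aorta.nii --roi aao.nii --out summary.json
aortaflow pathlines --field <stem> --aorta aorta.nii --out pathlines.csv
aortaflow echo --av av.csv --lvot lvot.csv --lvot-diameter 2.2 --bsa 2.1 --goa 3.73
aortaflow synth phantom|doppler|cohort --out dir --seed 1
aortaflow stats --cohort cohort.csv --format md
```

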