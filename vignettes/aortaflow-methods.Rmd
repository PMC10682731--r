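---
title: "Methods: quantifying valvular and ascending aortic hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying valvular and ascending aortic hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaflow)
```

## The problem

After aortic valve replacement with a valved conduit (a Bentall procedure),
the prosthesis design shapes the flow entering the ascending aorta (AAo).
Disorganized AAo flow dissipates mechanical energy by viscous friction and
shows up as elevated vorticity; both can be quantified voxel-by-voxel from
4D flow MRI — time-resolved phase-contrast MRI that measures all three
velocity components on a voxel grid across the cardiac cycle.  Valve-level
performance is measured separately by Doppler echocardiography.  This
package implements both quantification chains, the synthetic data needed to
verify them, and the three-group comparison statistics used to contrast
valve designs against healthy controls.

## Voxelwise model

All voxel analysis happens at **peak systole**, defined as the cardiac frame
maximizing the mean velocity magnitude inside the aortic segmentation (ties
break to the earliest frame, making the detector deterministic).

The **velocity gradient tensor** $G_{ij} = \partial v_i / \partial x_j$
(s⁻¹) is estimated by finite differences restricted to the segmentation:
central differences where both axis neighbors are in-mask, one-sided
differences where exactly one is, undefined otherwise.  Central differences
are exact on linear and quadratic velocity profiles, which is what makes the
analytic phantoms below sharp oracles.  The one-sided fallback at mask
boundaries is the dominant numerical error source on real geometries; the
`central_only` policy is available to quantify that bias (it leaves boundary
voxels undefined).

From $G$:

* **Viscous energy loss rate (VELR)**, the rate at which fluid shear
  converts kinetic energy to heat, per voxel:
  $\Phi = 2\mu \sum_{ij} S_{ij}^2$ (W/m³), with strain rate
  $S = (G + G^\top)/2$.  An optional compressibility correction
  $-\tfrac{2}{3}\mu(\nabla\!\cdot v)^2$ can be subtracted; both forms
  coincide on divergence-free flow, which is why every phantom oracle is
  divergence-free and the default is the incompressible form.  Discretized
  values are clamped at 0.
* **Vorticity** $\omega = \nabla \times v$ (s⁻¹), per voxel; its magnitude
  is twice the local angular velocity of a fluid element.

ROI summaries over the AAo mask (sinotubular junction to the
brachiocephalic branch, supplied as an input mask):
total VELR $\sum \Phi\,\Delta V$ (reported in mW), VELR density
(total / ROI volume, W/m³), and mean vorticity (ROI integral of $|\omega|$
divided by ROI volume; on a uniform grid this equals the plain voxel
average — the volume-weighted and plain-average readings coincide, which is
the implemented behavior).  Undefined voxels inside the ROI contribute
nothing to the sums but count toward the volume.

### Parameters that matter

* `mu` — dynamic blood viscosity, default $3.2\times10^{-3}$ Pa·s, the
  standard large-vessel value in the 4D flow literature.  The source study
  never states its value, so it is explicit and configurable here; VELR
  scales linearly with it.
* `boundary_policy` — `one_sided` (default) or `central_only`, see above.
* Grid spacing and frame interval ride along with the data (defaults in the
  generator: 2.5 mm isotropic, 40 ms — inside the clinical acquisition
  ranges of 2.4–4.1 mm and 38.8–40.6 ms).

## Velocity anti-aliasing

Phase-contrast velocities beyond the encoding limit (venc) wrap by
$2\,\mathrm{venc}$.  The correction implemented is deliberately simple and
fully testable: per voxel and component, the temporal median across frames
is the reference, and any frame differing from it by more than venc is
shifted by $\pm 2\,\mathrm{venc}$ toward it (one wrap at most; output lies
in $(\mathrm{med}-\mathrm{venc},\, \mathrm{med}+\mathrm{venc}]$ and the
operation is idempotent).

An honest caveat, derived rather than assumed: a once-wrapped value is
congruent to the true value modulo $2\,\mathrm{venc}$, so the rule restores
it **iff** the true value lies within venc of the voxel's temporal median.
In a diastole-dominated voxel the median sits near zero and systolic wraps
are undetectable by any per-voxel temporal rule.  The wrap-recovery tests
therefore use a sustained-ejection (plateau) waveform, which keeps every
voxel inside the recoverable regime; production aliasing correction on real
data uses spatiotemporal neighborhoods and is out of scope here.

## Pathlines

Massless particles are seeded uniformly at random inside the segmentation at
40 ms intervals (400 particles in total by default, split as evenly as
possible across epochs) and advected with 4th-order Runge–Kutta at a fixed
step of dt/8, using trilinear spatial and linear temporal interpolation.  A
particle terminates when its nearest voxel leaves the mask or the time axis
ends.  Because trilinear interpolation is exact on linear fields, solid-body
rotation provides a strict orbit oracle: radius drift below 1% per
revolution at a 5 ms step.

## Doppler metrics

From a continuous-wave aortic-valve envelope $v(t)$ and a pulsed-wave LVOT
envelope: the ejection window is the longest contiguous run above 10% of the
envelope maximum (a standard gating choice, configurable; edges by linear
interpolation), VTI is the trapezoidal integral over the window (cm), TPV
the window maximum, and the transvalvular gradients follow simplified
Bernoulli: peak $4v_{max}^2$, mean $\overline{4v(t)^2}$ over the window
(mmHg).  Continuity gives
$\mathrm{EOA} = \pi (d/2)^2\, \mathrm{VTI}_{LVOT} / \mathrm{VTI}_{AV}$;
EOAi divides by body surface area and the discharge coefficient divides by
the manufacturer's geometric orifice area.  A subtlety the tests respect:
the 10% gate discards the sub-threshold tails of a half-sine pulse, which is
itself a 0.5% effect ($1 - \cos(\arcsin 0.1) \approx 0.005$), so closed-form
recovery checks integrate over the full pulse support stored by the
generator, while window-detection accuracy is tested against the analytic
crossing times.

## Synthetic data: what it emulates, and what it does not

`make_phantom()` samples analytic flows at voxel centers (grid-centered,
voxel centers at origin + (index + ½)·spacing): Poiseuille pipe flow,
solid-body rotation, a Lamb–Oseen vortex, uniform flow and linear shear,
each with closed-form total VELR and mean vorticity (the Lamb–Oseen
dissipation is obtained by 1-D quadrature of the analytic strain rate — an
independent oracle, not the voxel pipeline).  A per-frame waveform scales
the field (default: half-sine systole over the first half of the cycle,
zero diastole), Gaussian noise and synthetic aliasing are optional, and the
pre-wrap field is retained as ground truth.  The Poiseuille field is
clamped to zero outside the tube (fluid at rest beyond the wall); since
gradients never cross the mask boundary, in-mask results are unaffected.

Numerical choices worth recording:

* **Grid parity.** Quantitative phantom evaluations use even in-plane voxel
  counts so the grid is symmetric about the tube axis and no voxel center
  falls exactly on the wall $r = R$, where the velocity profile has a kink
  and one-sided sampling is degenerate.  With this convention the Poiseuille
  total-VELR error decreases monotonically (58%, 12%, 1.1%, 0.4% at 5, 2.5,
  1.25, 0.625 mm; fitted order ≈ 2.5).  With odd counts the error sequence
  is erratic because on-wall voxel centers enter and leave the mask.
* The staircase approximation of the circular cross-section, not the finite
  differences, dominates the remaining error: central differences are exact
  on the parabolic profile.

What a green phantom test does **not** establish: performance on curved,
subject-specific aortic geometries, partial-volume and noise behavior at
clinical SNR, or anything about MR acquisition physics (k-space, eddy
currents, background phase).  Masks are inputs here; segmentation quality is
out of scope.

`simulate_cohort()` draws each metric independently from a normal
distribution with the published group mean/SD (three groups at n = 10, 6,
36), truncated at zero by resampling — all shipped metrics are physically
nonnegative, and at the published coefficients of variation the truncation
shifts means by well under 1%.  No inter-metric correlation is imposed:
only marginal summaries are published, so any correlation structure would
be invented.  The healthy-control EOA is published as median (IQR) and is
approximated as a normal with mean = median and SD = IQR/1.349.

## Group comparison

Per metric: each group is Lilliefors-tested for normality (Monte Carlo
p-value, ≥10⁴ replicates; the null distribution depends only on n and is
cached, which makes thousand-replicate calibration studies cheap).  If all
groups pass at α = 0.05 the omnibus test is one-way ANOVA, else
Kruskal–Wallis; pairwise contrasts use the pooled-variance t-test when both
groups pass (Welch by flag) and Wilcoxon rank-sum otherwise (exact
enumeration when both n ≤ 20 without ties, normal approximation with
continuity correction otherwise).  Pairwise significance uses the
Bonferroni threshold 0.05/3, printed as 0.017.  Open choices resolved here:

* The gate is per metric per group, and ANOVA requires **all** groups to
  pass — the most conservative reading of "depending on data normality";
  configurable via the gate level.
* Degenerate SD-0 samples raise an explicit error rather than returning a
  p-value: the normal model is meaningless for a constant sample, and a
  silent p ≈ 0 would flip the whole row to nonparametric summaries without
  warning.
* Groups smaller than 4 cannot be Lilliefors-tested and are treated as
  non-normal (conservative).

Simulation checks: under a common-normal null the gated omnibus procedure is
calibrated (false-positive rate ≈ 0.048 at 4,000 replicates, within the
binomial noise of the nominal 0.05 — the normality gate introduces no
material selection distortion at these group sizes), and Lilliefors
p-values are uniform under the null.  Its power against Exp(1) at n = 36 is
≈ 0.87 by an independent 20k-replicate oracle.

## Known limitations

* The anti-aliasing rule is per-voxel temporal only (see above).
* Orientation matrices beyond spacing/origin are ignored; velocity
  component axes are the grid axes.  Reorienting real scanner data is the
  caller's job.
* Turbulent (fluctuating) energy loss is not measured — the underlying
  sequence averages over heartbeats — so VELR captures only the mean-field
  shear dissipation.
* Wall shear stress, helicity and flow displacement are out of scope.
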