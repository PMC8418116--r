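---
title: "SmartFFR: model, numerics and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SmartFFR: model, numerics and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartffr)
```

## The index

Fractional flow reserve (FFR) grades a coronary stenosis by the ratio of
distal to aortic pressure under maximal (adenosine-induced) hyperemia; values
at or below 0.80 mark lesions that cause ischemia. SmartFFR is a
geometry-derived surrogate: instead of a single hyperemic operating point it
summarises the whole pressure-flow relationship of the interrogated segment.
A staged flow protocol imposes increasing flows on the vessel with the
proximal pressure held at 100 mmHg, the distal-to-proximal ratio
$P_d/P_a$ is recorded at each step, the per-step ratios are joined into a
curve over the 0-4 ml/s range, and the index is

$$\mathrm{SmartFFR} = \frac{\int_0^4 \frac{P_d}{P_a}(Q)\, dQ}{4},$$

the area under the patient's curve divided by the area under a drop-free
(healthy) vessel's curve, which is identically 1 and integrates to 4. A
completely healthy idealised vessel scores 1; any epicardial resistance pulls
the curve, and the index, down. Averaging over the flow range rather than
evaluating a single point makes the index insensitive to the exact hyperemic
flow a given patient reaches.

## The reduced-order pressure-drop engine

The package computes segment hemodynamics with the standard quadratic
stenosis pressure-drop law rather than a 3D CFD solve:

$$\Delta P(Q) = fQ + sQ^2.$$

* **Viscous term.** $f = \frac{128\mu}{\pi}\int D(z)^{-4}\,dz$, the
  Poiseuille resistance integrated along the sampled centerline (trapezoidal
  rule). For a straight tube of 3 mm diameter and 30 mm length with blood
  viscosity $\mu = 0.0035$ Pa·s this is 0.396 mmHg/(ml/s).
* **Separation term.** $s = \frac{\rho K_t}{2A_0^2}\left(\frac{A_0}{A_s} -
  1\right)^2$ with $K_t = 1.52$, the Young–Tsai expansion loss between the
  reference area $A_0$ and the minimal lumen area $A_s$; zero for a healthy
  vessel. Blood density $\rho = 1050$ kg/m³. For 70% area stenosis of the
  3 mm tube, $s = 0.652$ mmHg/(ml/s)².

Flow is treated as laminar and Newtonian, and the staged protocol as
quasi-steady: with no inertial or compliance terms each timestep is an
independent steady state, so the nominal 0.25 s step duration is metadata.
This engine is deliberately simple because the index consumes only
$(Q, P_a, P_d)$ triples; when genuine solver output is available the
`read_solver_samples()` adapter feeds it through the identical curve and
area machinery, preserving full fidelity.

All geometry is in millimetres, flow in ml/s and pressure in mmHg; the
single conversion constant 1 mmHg = 133.322 Pa lives inside the coefficient
computations.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `inlet_pressure` | 100 | mmHg | proximal (aortic) boundary condition |
| protocol flows | 1, 2, 3, 4 | ml/s | staged outlet flows, single vessel |
| bifurcation totals | 2, 4, 6, 8 | ml/s | staged total flows, two branches |
| `n_grid` | 100 | – | interpolation points of the ratio curve |
| `pd_floor` | 0 | mmHg | clamp for the computed distal pressure |
| `k_t` | 1.52 | – | empirical separation-loss constant |
| `r_micro` | 25 | mmHg/(ml/s) | hyperemic microvascular resistance (cohort) |

The bifurcation schedule ends at 8 ml/s, the peak hyperemic flow of a
healthy left coronary system (4 ml/s per branch under an even split). We
fixed the four steps at 2, 4, 6, 8 ml/s: a 0-flow step would carry no
information, since the curve is anchored at $(0, 1)$ analytically.

## Bifurcations

Total flow divides between the daughter branches by Murray's law,
$q_2/q_1 = (d_2/d_1)^3$, using each branch's reference diameter (mean lumen
diameter over the proximal and distal 10% of its arc length — the same
convention that defines the healthy caliber for the stenosis measures; where
along the branch to measure the diameter is a modelling choice, and the
10%-ends mean is robust to focal disease at either end). The branch inlet
pressure is the parent's computed distal pressure at the total flow, so
pressure is continuous and flow conserved exactly at the junction.

Because a branch's sampled flows are its Murray fraction of the totals, its
curve must be rebased onto the standard 0-4 ml/s range before the areas are
comparable. Raw spline extrapolation beyond the last sample is numerically
wild, so rebasing fits the origin-forced quadratic $\Delta P = fQ + sQ^2$ to
the branch samples and evaluates $1 - \Delta P(Q)/P_{a,\mathrm{branch}}$ on
the standard grid — an interpolation when the branch flows exceed 4 ml/s and
an extrapolation when they fall short, exact whenever the samples come from
the quadratic model class. When the parent is diseased the branch inlet
pressure varies slightly across steps; the rebased curve uses the mean of
the per-sample inlet pressures (exactly 100 mmHg behind a healthy parent).

## Numerical choices

* **Spline.** The per-step ratios plus the $(0, 1)$ anchor are joined by a
  cubic interpolating spline with Forsythe–Malcolm–Moler end conditions
  (`stats::spline`, `method = "fmm"`), evaluated at 100 points, and the area
  is the composite trapezoidal integral. FMM end conditions fit exact cubics
  through the end points, so quadratic ratio curves are reproduced to
  machine-level accuracy: the worst pipeline-versus-closed-form error over
  the admissible $(f, s)$ region measures $1.7\times 10^{-5}$. Natural end
  conditions were rejected because their zero-second-derivative constraint
  biases the curve near the endpoints (errors up to $1.5\times 10^{-3}$ in
  the high-severity corner).
* **Clipping.** Ratios are clipped to $[0, 1]$: supra-unity values are
  unphysical interpolation artifacts, and the distal pressure itself is
  floored at 0 mmHg for near-occlusive lesions where the quadratic drop
  exceeds the inlet pressure.
* **Ties and orientation in ROC.** Candidate thresholds are the observed
  index values; a case is positive when its value is $\le t$ (low index =
  ischemia). The AUC uses midranks, so it equals the tie-corrected
  Mann–Whitney probability. Among Youden-maximising thresholds the largest
  is reported, favouring sensitivity — the natural choice for a screening
  index.
* **Limits of agreement.** Bland–Altman CIs of the limits use the classical
  $t_{0.975,\,n-1}\, s_d \sqrt{3/n}$ approximation.
* **Degenerate inputs.** Undefined diagnostic metrics (zero denominators)
  are reported as `NA`, never 0; identical score vectors in the DeLong
  comparison return $z = 0$, $p = 1$ by convention.

## The synthetic cohort

No clinical data ship with the package. `generate_cohort()` draws
single-vessel cases: diameter log-normal with median 3 mm (sdlog 0.15, a
realistic proximal-coronary spread), length uniform on 20-60 mm, a
mid-vessel cosine-tapered stenosis with area severity uniform on 30-90% and
lesion length uniform on 10-20 mm. The cosine taper narrows the local radius
so the minimal area is $(1 - \mathrm{sa})$ times the reference area and
blends smoothly into the healthy wall.

The reference ("invasive") FFR couples the vessel's $(f, s)$ model to a
constant hyperemic microvascular resistance $R = 25$ mmHg/(ml/s) — chosen so
a healthy vessel at 100 mmHg reaches exactly 4 ml/s of hyperemic flow. The
operating point solves $P_a = fQ + sQ^2 + QR$, and
$\mathrm{FFR} = Q^{*}R/P_a$. Gaussian noise (SD 0.03, the scale of
pressure-wire repeatability) perturbs only the *measured* FFR; the latent
value and SmartFFR are noise-free. Each case consumes an RNG stream keyed by
(seed, case index), so enlarging a cohort never reshuffles earlier cases.

What the generator does *not* emulate: reconstruction error from imaging,
serial and diffuse disease, vessel taper and curvature, patient-specific
inlet pressure, and microvascular heterogeneity beyond the constant $R$.
Passing the recovery tests therefore shows that the pipeline is internally
consistent and discriminates severity under its own physics — not that it
reproduces clinical diagnostic accuracy, which requires patient data the
package does not ship.

## Problem sizes

The test-suite and acceptance runs use 201-601-point centerlines, 100-point
curves, 1,000 random $(f, s)$ models for the oracle-equivalence sweep,
200-case cohorts, and a 10,000-replicate bootstrap for the DeLong variance
check on a 40-case toy — sizes at which every statistic in play is stable
while a full run completes in well under a minute.

## Known limitations

* The engine is one-dimensional: curvature, eccentric lesions, diffuse
  disease and inter-lesion interaction are folded into the two coefficients.
* Murray's law assumes idealised laminar branching flow; in severe disease
  the true split deviates.
* Only one junction is handled per run (a parent and two leaves); left-main
  common-trunk physiology is out of scope.
* The healthy reference is the idealised drop-free vessel. A real
  disease-free tube retains its Poiseuille resistance, so its index sits
  just below 1 (about 0.992 for a 3 x 30 mm tube) — consistent with the
  index's definition, which normalises by the ideal curve, not by the
  vessel's own healthy twin.
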