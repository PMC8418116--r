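# smartffr

Virtual functional assessment of coronary stenoses from vessel geometry.

Invasive fractional flow reserve (FFR) — the ratio of distal to aortic
pressure under drug-induced maximal hyperemia, with FFR ≤ 0.80 defining an
ischemia-causing lesion — is the reference standard for deciding whether a
coronary stenosis needs revascularisation, but it requires a pressure wire
and adenosine. `smartffr` computes a geometry-derived surrogate for
interventional-cardiology and computational-hemodynamics researchers: from a
centerline-plus-radius description of the vessel it runs a staged flow
protocol (1-4 ml/s against a 100 mmHg inlet), builds the distal-to-proximal
pressure-ratio curve

```
SmartFFR = AUC[ Pd/Pa (Q), 0 ≤ Q ≤ 4 ml/s ] / 4
```

and normalises its area by the drop-free healthy curve (area 4). Averaging
over the flow range, instead of evaluating one hyperemic point, makes the
index robust to how much flow a particular patient actually reaches.

The per-segment hemodynamics use the standard reduced-order stenosis law
`ΔP(Q) = fQ + sQ²`: a Poiseuille viscous integral along the centerline plus
a Young–Tsai separation loss at the throat (blood: 0.0035 Pa·s, 1050 kg/m³,
laminar, Newtonian). Bifurcations split flow by Murray's cubic-diameter law
with exact flow conservation and pressure continuity at the junction, and
branch curves are rebased onto the standard flow range through an
origin-forced quadratic fit. Externally computed pressure–flow samples (from
any CFD solver) enter through `read_solver_samples()` and flow through the
identical index machinery.

The package also ships the diagnostic-validation layer used to assess such
indices — confusion-matrix metrics, Pearson correlation, Bland–Altman
agreement with CIs of the limits, ROC with the Youden-optimal cutoff, DeLong
comparison of correlated ROC curves — and a seeded synthetic-cohort
generator that pairs SmartFFR with a microvascular-resistance reference FFR
so the whole evaluation pipeline runs without any clinical data.

## Worked example

```r
library(smartffr)

# 3 mm x 30 mm vessel with a 10 mm, 70% area stenosis at mid-vessel
vessel <- make_straight_vessel(3, 30, 601) |>
  apply_stenosis(stenosis_spec(center = 15, length = 10, area_stenosis = 0.7))

res <- smartffr(vessel)
res
#> <smartffr_result> vessel: SmartFFR = 0.9486 (AUC = 3.7943 over 0-4 ml/s)

model <- segment_pressure_drop_model(vessel)
c(f = model$f, s = model$s)
#>      f      s
#> 0.8318 0.6522          # mmHg/(ml/s) and mmHg/(ml/s)^2
round(100 * percent_diameter_stenosis(vessel), 1)
#> 45.2                   # % diameter stenosis (= 1 - sqrt(0.3))
simulate_reference_ffr(model)
#> 0.8881                 # wire-style FFR at the hyperemic operating point
```

The index 0.9486 is the curve area 3.7943 divided by the healthy area 4: the
lesion's viscous (f) and separation (s) losses bend the Pd/Pa curve away
from 1 as flow rises. `autoplot(res)` draws the curve with its protocol
samples.

A full in-silico validation run:

```r
cohort <- generate_cohort(cohort_spec(n_vessels = 200, seed = 1))
ev <- evaluate_index(cohort)   # SmartFFR vs noisy "measured" FFR, cutoff 0.80
ev
#> <diagnostic_evaluation> n = 200 | r = 0.944 | AUC = 0.998 | cutoff <= 0.896166
#>   accuracy 98.0% | sens 97.5% | spec 98.1% | PPV 92.9% | NPV 99.4%
glance(ev)         # one-row tibble of the same numbers
autoplot(ev$roc)   # ROC curve; autoplot(ev$bland_altman) for agreement
```

Command-line use mirrors the R API (`exec/smartffr`):

```sh
smartffr compute --centerline vessel.csv --out report.json
smartffr bifurcation --tree tree.json --out report.json
smartffr evaluate --pairs pairs.csv --index-cutoff 0.83 --ffr-cutoff 0.80
smartffr simulate-cohort --spec cohort.yaml --out cohort.csv
```

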