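# baods

Beam-angle optimization for three-port double-scattering (DS) proton
therapy, from CT anatomy alone.

Choosing the three gantry angles of a DS liver plan is normally a manual,
planner-dependent step: good ports reach the tumor through little tissue,
avoid parking organs at risk just beyond the target's distal edge (where
range uncertainty bites), and stay spread out. `baods` scores **all 360
integer gantry angles at once** with a convolutional network that sees only
geometry — no candidate-beam dose calculations — and then picks the three
treatment angles with a separation-constrained greedy rule.

The pieces, end to end:

* **Collector** — per gantry angle, 25 parallel beam's-eye-view rays
  (1 central + 12 + 12 on two ellipses over the target cross-section), each
  1000 mm long, 4000 bins at 0.25 mm; every bin records 9 features:
  Z-score-normalized Hounsfield units plus 8 binary structure channels
  (body, liver, tumor, duodenum, stomach, esophagus, heart, spleen). At
  2-degree steps the assembled input is a 40500 x 4000 array.
* **Targets** — a 360-element ranking score `s` over gantry angles:
  clinically planned angles get 1.0, spread by a peak-normalized circular
  Gaussian (sigma 5 degrees), so `s[θ] ∈ [0, 1]` with unit peaks at the
  planned angles; training augments targets by random circular shifts of
  -2..2 degrees each epoch.
* **Network** — 8 convolutions (a 9x1/stride-9 feature-merging layer, a
  25x1/stride-25 ray-merging layer, six 3x3 layers with max-pooling) and 4
  fully connected layers (1220 → 560 → 560 → 560 → 360), batch-norm and
  leaky-ReLU throughout; L1 / L2 / smooth-L1 (β = 0.5) losses; Adam
  (lr 0.001, weight decay 2e-4, β₁ 0.9, β₂ 0.999); patient-wise K-fold
  cross-validation. Layers, backprop and the optimizer are implemented in
  base R; `shape_inference()` reproduces every tabulated intermediate
  shape.
* **Selection** — greedy over descending scores, accepting an angle only if
  it is ≥ 30 degrees (circular) from every accepted one.
* **Evaluation** — conformity index CI = (TV·PIV)/(TV∩PIV)² (Paddick
  variant available), V_x volume percentages and min/mean/max dose
  statistics.
* **Phantoms & I/O** — a synthetic abdominal phantom generator with
  geometry-derived "clinical" angles (so learning is testable without
  patient data), a toy unit-weight dose model, an internal array container,
  and a minimal DICOM-RT reader/writer (CT series, RTSTRUCT, RTPLAN,
  RTDOSE; exact mask round-trips).

## Worked example

```r
library(baods)

case <- generate_case(phantom_config(seed = 42))
print(case)
#> <patient_case> phantom-seed42-rot0
#> <volume_grid> 96 x 96 x 48 voxels, spacing 4 x 4 x 4 mm
#>   origin (-192, -192,  -96) mm, HU range [-1000, 99]
#>   body         7084.5 cm^3
#>   TLV           623.3 cm^3
#>   PGTV           21.8 cm^3
#>   ...
#>   isocenter (-36.99,  -6.99,   9.01) mm; clinical angles: 340, 309, 10

sb <- make_sbeam(case$clinical_angles, sigma = 5)   # unit peaks at 340/309/10
beams <- select_angles(sb)
beams
#> [1]  10 309 340

dose <- toy_dose(case, beams)
pm <- plan_metrics(case, dose)
round(pm$conformity_index, 3)
#> [1] 2.211
round(pm$dose_stats["PGTV", ], 1)
#>  min mean  max
#>  100  100  100
```

The phantom's "clinical" angles come from a water-equivalent-path-length
score over the anatomy, so the selected beams enter through the short,
OAR-free corridors (here from the patient's right-anterior side, where the
liver sits). The toy dose covers the tumor uniformly (PGTV min = mean =
max = 100% of prescription); its conformity index of 2.21 reflects the
deliberately boxy unit-weight fields, not a clinical plan. Training the
network end-to-end on phantoms is shown in the test suite and the
vignette; `baods_fit()` returns a fitted model with `print`, `summary`,
`coef`, `predict`, `plot` and `residuals` methods.

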