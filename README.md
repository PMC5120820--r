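# pulse4d

Quantification of intracranial aneurysm pulsation from ECG-gated 4D CT
angiography (4D-CTA).

Unruptured cerebral aneurysms pulse with the cardiac cycle, and the
character of that pulsation may carry information about wall stability and
rupture risk. The wall excursions involved are at or below the CT voxel
size, so the measurement hinges on sub-voxel surface modelling and on a
statistical argument that the measured volume fluctuations are pulse-like
rather than image noise. `pulse4d` implements the full computer-aided
post-processing chain for neuroradiology researchers working with gated
CTA: HU-threshold lumen segmentation, per-phase sub-voxel isosurface models
(the "3D+t model"), iterative-closest-point transfer of neck delineation
points across phases, cut-surface separation of the aneurysm dome from its
parent vessel, per-phase volume curves, and the associated statistics.

The core quantities, for a volume curve V(p) over cardiac phases p:

* **Pulsation amplitude** A = Vmax / Vmin.
* **Pulsation plausibility**: with Vn the min-max-normalized curve and w an
  arterial pulse-wave template, curves are embedded as point sets
  {(t_i, v_i)}, t_i = i/(n−1), and compared by the symmetric Hausdorff
  distance d_H(Vn, w) = max( h(A,B), h(B,A) ), h(A,B) = max_a min_b ||a−b||.
  The measured distances are tested (Welch two-sided t) against distances
  of random noise curves with the images' noise characteristics
  (Gaussian, mean 0.5, SD 0.2, clipped to [0,1]).
* **Agreement**: Bland–Altman bias ± 1.96 SD of paired differences,
  two-way ICC (ICC(2,1) by default, "good" above 0.75), Spearman
  correlation.

Because no physical calibration object exists for sub-voxel vessel
pulsation, the package ships a synthetic 4D-CTA phantom generator
(`phantom_spec()` / `generate_phantom_4d()`): a spherical aneurysm on a
straight parent vessel at the clinical acquisition geometry
(0.39 × 0.39 × 0.5 mm, 10 cardiac phases, 18% intraluminal noise), whose
dome volume is driven linearly by the pulse template so that the
ground-truth amplitude is exact by construction. Every pipeline stage is
validated against this phantom and against analytic/brute-force oracles.

## Worked example

Generate a noisy pulsating phantom (amplitude 1.06, 18% noise) and run the
full pipeline on it:

```r
library(pulse4d)

spec  <- phantom_spec(pulsation_amplitude = 1.06, noise_fraction = 0.18,
                      seed = 42)
truth <- generate_phantom_4d(spec)$truth

cfg <- pipeline_config(
  phantom     = spec,
  neck_points = truth$neck_rings[[1]][seq(1, 24, by = 2), ],  # 12 neck points
  dome_seed   = c(3.5, 0, 0),
  iso         = 220)            # half-maximum for the 400/40 HU phantom
report <- run_pipeline(cfg)
report
#> <pulsation_report> amplitude 1.0728, Hausdorff to pulse 0.1679 (null mean 0.5051), p = 4.2e-09, class = pulsatile
report$curve
#> <volume_curve> 10 phases, state=raw
#>  [1] 100.0964 102.3401 105.7752 101.4238 100.1547 100.6614  98.5970  99.5944
#>  [9]  99.4823  99.8025
```

The report says: the measured aneurysm volume swings by a factor 1.0728
over the cycle (true value 1.06; the excess is measurement noise on the
extremes), its normalized curve lies much closer to the arterial pulse
wave (Hausdorff 0.17) than random noise curves do (mean 0.51), the Welch
test rejects the noise explanation (p = 4×10⁻⁹), and the profile is
classified as pulsation-like. Per-phase volumes are in mm³; the systolic
peak at phase 2 mirrors the template.

Real 4D-CTA data enter the same way via `read_volume_4d("scan.nii.gz")`
and a neck-point CSV; a command-line front end with subcommands
(`phantom`, `segment`, `mesh`, `separate`, `pulsation`, `agreement`,
`run`) is installed at `inst/cli/pulse4d.R`.

The methods vignette (`vignettes/pulsation-quantification.Rmd`) documents
the model, every tunable parameter, the cut-surface construction, the
phantom's scope and the package's numerical choices.

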