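---
title: "Quantifying aneurysm pulsation from 4D CTA: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aneurysm pulsation from 4D CTA: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulse4d)
```

## The measurement problem

ECG-gated 4D CT angiography reconstructs the contrast-filled cerebral
vasculature at several phases of the cardiac (R-R) cycle — here ten phases,
on a 0.39 x 0.39 mm in-plane / 0.5 mm slice grid. Over the cycle an
intracranial aneurysm inflates and deflates with the arterial pulse wave,
but the wall excursion of a 5 mm aneurysm is of the order of, or below, one
voxel. Any volumetry based on counting voxels is therefore blind to the
effect; the signal lives entirely in sub-voxel displacements of the
partial-volume interface, and image noise of comparable magnitude threatens
to swamp it.

`pulse4d` implements a computer-aided post-processing chain for this
measurement and, because no physical micro-pulsation calibration object
exists, validates it end to end on a synthetic pulsating-aneurysm phantom
with exact analytic ground truth:

1. **Lumen segmentation** — inclusive HU thresholding (default 160–890 HU,
   separating contrast-filled lumen from CSF/brain while excluding bone),
   per phase, with optional VOI cropping and 26-connected component
   filtering from a seed voxel.
2. **3D+t surface model** — one triangulated isosurface of the grayscale HU
   field per phase (marching tetrahedra; vertices placed by linear
   interpolation along grid edges, i.e. at sub-voxel positions).
3. **Neck transfer** — neck delineation points placed at phase 0 are
   carried to every other phase by rigid iterative-closest-point (ICP)
   registration focused on the neck, then snapped onto that phase's surface.
4. **Dome separation** — a cut surface spanned over the neck points
   separates the aneurysm dome from the parent vessel; the dome plus a cap
   over the cut is a closed mesh whose enclosed volume (divergence theorem)
   is the per-phase aneurysm volume.
5. **Pulsation statistics** — the 10-point volume curve is min-max
   normalized and compared with an arterial pulse-wave template by the
   symmetric Hausdorff distance, against a null distribution of random
   noise curves; amplitude is Vmax/Vmin.
6. **Agreement statistics** — Bland–Altman bias and limits of agreement,
   two-way ICC (good agreement above 0.75), Spearman correlation and the
   Welch two-sided t-test for paired/grouped comparisons.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `low`, `high` | 160, 890 | HU | inclusive lumen threshold window |
| `iso` | 160 | HU | isosurface value; see below |
| `smooth_sigma` | 0.4 (pipeline) | mm | Gaussian denoising before isosurfacing |
| ICP focus radius | 1.5 x neck ring radius | mm | restricts registration to the neck |
| ICP stopping | RMS change < 1e-6, max 50 iterations | mm | closed-form (Kabsch) updates |
| `fan_extend` | 1 | – | radial extension of the cut fan |
| `flat_threshold` | 1.02 | – | amplitude below which a profile is "flat" |
| null moments | mean 0.5, SD 0.2 | – | Gaussian noise curves, clipped to [0,1] |

**Iso-value.** The pipeline default equals the lower threshold (160 HU),
the only value available on clinical data where true lumen attenuation is
unknown. When lumen and background attenuations *are* known — as for the
phantom (400/40 HU) — the half-maximum value (220 HU) is used instead: for
a symmetric point-spread function the half-maximum level set is the
unbiased estimate of the true interface, while any other level shifts the
surface by a noise- and blur-dependent offset. Absolute volumes measured at
160 HU on the phantom would be biased outward by roughly the PSF width;
amplitude (a ratio) is nearly immune to the choice.

**Denoising.** At realistic noise (18% of lumen attenuation) the
half-maximum surface of the raw field develops spurious tunnels through
the partial-volume shell, because single-voxel excursions below the
iso-value suffice to pierce it. The pipeline therefore smooths the HU field
with a small Gaussian (0.4 mm, about one voxel) before isosurfacing —
the same role iterative-reconstruction denoising plays on the scanner.
Smoothing is off by default at the `extract_isosurface()` level so the
operation remains a pure isosurfacer.

## The cut surface

The neck points are ordered canonically by angle about the best-fit plane
normal through their centroid (anchored at the point farthest from the
centroid, so the ordering is reproducible even for rotationally symmetric
rings) and connected into a centroid triangle fan. The fan — not a plane —
is the cut, because a real ostium is not planar: for a spherical dome on a
cylindrical vessel the junction curve is a saddle elongated along the
vessel by a factor sqrt(1 + R/r) relative to its width, and a bounded
planar cut provably fails to separate the two sides of the lumen surface
(paths around the saddle tips avoid it). A `planar = TRUE` option projects
the points onto their least-squares plane first.

Separation proceeds by region-growing triangle faces from the face nearest
the dome seed, never crossing an edge that intersects the cut. Three
robustness measures matter in practice:

* **Curtain.** Neck points land on the surface within about one voxel
  diagonal of the true ostium (ICP residual plus vertex snapping), and the
  cut meets the vessel wall at a grazing angle, so the fan alone leaves
  leak paths under mesh jitter. The blocking surface is therefore extended
  by a "curtain" of quads leaving the neck polygon along locally averaged
  outward surface normals — 1.2 mm outward and 0.6 mm into the lumen —
  which crosses the wall transversally.
* **On-cut vertices.** Snapped neck points are mesh vertices, and the
  membrane can additionally pass exactly through lattice-aligned non-neck
  vertices; all edges incident to such vertices are treated as cut
  (symbolic perturbation would otherwise be needed).
* **Exact clipping.** Triangles straddling the fan are split exactly at
  the recorded edge–fan intersection points (a fixpoint rule suppresses
  splits next to degenerate crossings so no T-vertices arise). The dome
  keeps the quad side, the vessel keeps the corner, and both sides are
  closed by the identical (reversed) cone cap from the cut centroid over
  the boundary loop. Consequently the dome and vessel meshes are closed by
  construction and their volumes add up to the whole-lumen volume exactly.

Closedness is verified as directed-edge balance (every directed edge
matched by its reverse), which tolerates pinched boundary vertices where
the divergence theorem still applies; strict edge-manifoldness is reported
as a diagnostic.

## The phantom

`phantom_spec()` describes a straight parent vessel (tube, radius 1.5 mm)
carrying a spherical aneurysm (base diameter 6 mm, centre 3.5 mm off the
vessel axis — a narrow-necked saccular geometry), rasterized at the
acquisition grid (0.39/0.39/0.5 mm, 10 phases) by supersampled occupancy
(3 per axis), mapped to 400 HU lumen on 40 HU background, blurred with a
0.4 mm Gaussian PSF (partial-volume surrogate for the scanner), and
degraded with i.i.d. Gaussian noise of SD 18% of lumen attenuation — the
deviation measured in a homogeneous aneurysm ROI in the reference
protocol. Diameters and pulsation amplitudes (1.02–1.2) follow the
clinical range.

The *dome volume is driven linearly* by the pulse template:
V(p) = Vmin (1 + (A−1) w(p)) with w the min-max-normalized template and A
the amplitude; the per-phase sphere radius is recovered by root-finding
from the analytic plane-dome volume, so the ground-truth amplitude equals
A to machine precision and the normalized ground-truth curve *is* the
template. Radius-driving would make amplitude recovery approximate.

The ground-truth neck ring is the sphere–tube junction curve (the ostium a
rater traces on the 3D model). The circle in which the neck plane cuts the
sphere is analytically simpler but partly lies *inside* the lumen at the
saddle tips and cannot anchor a separating cut. Because the method's cut is
the ostium membrane rather than the neck plane, the validation oracle for
absolute dome volume is a seeded Monte-Carlo integral of the
membrane-bounded region (inside the sphere, and outside the tube or above
the centroid cone over the junction); on the default geometry this region
is about 2% smaller than the plane-dome, a definitional — not numerical —
difference.

The built-in pulse template (`generate_pulse_template()`) emulates a
middle-cerebral-artery Doppler waveform: a systolic peak within the first
40% of the cycle, a dicrotic shoulder near mid-cycle and a smooth diastolic
decay, min-max normalized. Any measured template (e.g. from ultrasound) can
be supplied as CSV and is normalized the same way.

What the phantom does **not** emulate: correlated CT noise textures and
streaks (noise is white by design; the reference protocol characterizes
noise only by an ROI standard deviation), beam hardening, contrast-bolus
dynamics, ECG misgating, non-spherical domes and curved parent vessels.
Passing the phantom validation therefore demonstrates that the *pipeline*
resolves sub-voxel volume pulsation under realistic white noise on ideal
geometry — not that any particular clinical acquisition does.

## The plausibility statistic

Measured curves are min-max normalized to [0,1]; curves and the template
are embedded as point sets {(i/(n−1), v_i)} and compared by the symmetric
Hausdorff distance (a `value_only` mode drops the time coordinate for
sensitivity analysis). The null consists of i.i.d. Gaussian(0.5, 0.2)
curves, clipped to [0,1]; by default they are *not* re-normalized, which
reproduces the published protocol. For phantom calibration the null is
min-max re-normalized (`renorm = TRUE`): a min-max-normalized measurement
curve always spans [0,1] while a raw clipped-Gaussian curve does not, so
comparing normalized curves against an unnormalized null is biased against
the null by construction and would declare even pure measurement noise
"significantly different". Group comparison uses the two-sided Welch
t-test; the null size is 14 (cohort size) for reproduction work and 1000
for calibration.

Amplitude is defined as Vmax/Vmin (the values reported clinically, all
at least 1, are consistent with this ratio) and is invariant under
mean-one normalization. The three-way profile classification
(flat / pulsatile / random) uses an amplitude floor of 1.02 and the 5th
percentile of null distances; both thresholds are package conveniences,
not validated clinical cut-offs.

## Numerical choices and degenerate inputs

* Marching tetrahedra (6 tetrahedra per cube around a fixed diagonal)
  rather than a cube case table: translation-consistent, ambiguity-free,
  watertight by construction. Its piecewise-linear surface underestimates
  convex volumes by O(h^2 x curvature) — about 1% at 0.4 mm spacing for a
  5 mm sphere, shrinking with grid refinement; ratios across phases are
  nearly unaffected. Grid values equal to the iso-value are nudged by
  1e-9 to avoid degenerate vertices.
* Nearest-neighbour queries use a uniform spatial hash with ties broken by
  lowest vertex index (determinism); ICP subsamples at most 600 focus
  vertices deterministically.
* ICP is initialized at the identity and solved in closed form per
  iteration; between cardiac phases the motions are well below 0.1 mm, far
  inside its convergence basin. Transform-recovery experiments focus on
  the aneurysm dome, since a cylindrical neighbourhood cannot identify a
  translation along its own axis.
* Degenerate inputs raise classed conditions rather than messages only:
  constant curves (`p4d_degenerate_curve`), collinear neck points
  (`p4d_invalid_geometry`), empty masks (`p4d_empty_mesh`), open meshes
  (`p4d_open_mesh`, with the boundary edge count), failed separations
  (`p4d_leak_error`), identical-sample t-tests fall back to p = 1.
* The whole pipeline is deterministic given its configuration; every
  random draw (phantom noise, null curves) flows from an explicit seed.

## Validation problem sizes

The shipped test-suite conditions, chosen to exercise the method at the
study's acquisition geometry while keeping a laptop-scale runtime: phantom
grids of 34 x 26 x 26 voxels at 0.39/0.39/0.5 mm with 10 phases; analytic
sphere oracles at 0.25 mm spacing; 50 noise seeds for amplitude recovery
and pulsation-vs-null power; 50 zero-amplitude replicates (3 noise
realizations each) for null calibration. Translation-cancellation
experiments rasterize at supersampling 5 instead of the default 3 because
the rasterizer's own occupancy quantization under sub-voxel shifts (~0.7%
at 3, ~0.2% at 5) would otherwise be attributed to the pipeline against a
1% bound.

## Worked example

```{r example, eval = FALSE}
spec <- phantom_spec(pulsation_amplitude = 1.06, noise_fraction = 0.18,
                     seed = 42)
truth <- generate_phantom_4d(spec)$truth

cfg <- pipeline_config(
  phantom     = spec,
  neck_points = truth$neck_rings[[1]][seq(1, 24, by = 2), ],
  dome_seed   = c(3.5, 0, 0),
  iso         = 220,           # half-maximum for the 400/40 HU phantom
  out_dir     = "pulse4d_out")
report <- run_pipeline(cfg)
report
```

## Limitations

* The cut surface is only as good as the neck points; with three or four
  points a coarse fan under- or over-shoots a saddle-shaped ostium.
  Measurement noise in the volume curve is dominated by the phase-to-phase
  jitter of the transferred, vertex-snapped cut — the same sensitivity
  that limits the interactive workflow this package emulates.
* Absolute volumes carry the marching-tetrahedra secant bias and, at
  clinical iso-values, a threshold-placement offset; comparisons across
  phases (amplitudes, curve shapes) are the reliable outputs.
* The phantom's white-noise model makes its noise the *hardest* case at a
  given SD for tunnel artifacts but does not capture structured clinical
  artifacts; observer variability is emulated, not reproduced.
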