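---
title: "Methods: Otsu thresholding for ICG angiography, phantom verification, and outcome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Otsu thresholding for ICG angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icgaOtsu)
```

## The segmentation model

Intraoperative indocyanine-green (ICG) fluorescence angiography images
the cerebral vasculature under a near-infrared microscope: perfused
vessels fluoresce brightly against a dark surgical field. The resulting
gray-level histogram is approximately bimodal, which is exactly the
regime the Otsu method addresses. The method assumes nothing about the
image beyond its histogram: it picks the threshold `t*` that maximizes
the between-class variance of the two resulting intensity classes,
equivalently the separability criterion `eta(t) = sigma_C^2(t) / sigma_E^2`.

Gray levels are indexed `1..K` throughout the computational core, and an
adapter maps stored 8-bit intensities `v` to levels `i = v + 1`
(`K = 256`; 16-bit images use `K = 65536`). Keeping the core 1-based
means every formula in the README can be transcribed literally; the
adapter isolates the indexing convention in one place
(`image_histogram()`).

Thresholds that would leave one class empty are excluded from the search
rather than scored zero: the closed-form criterion
`(mu_E omega - mu)^2 / (omega (1 - omega))` is undefined there, and since
such splits separate nothing, excluding them cannot change the argmax. A
histogram with a single occupied level has no admissible split at all and
raises a dedicated constant-image error (carrying the occupied level)
instead of returning a silent default; on the command line this is exit
status 2.

### Ties and the fractional threshold

When several thresholds attain the maximal between-class variance — as
happens whenever the histogram has an empty gap between its modes — their
arithmetic mean is returned, so `t*` can be fractional. Ties are detected
at a relative tolerance of `1e-12`, tight enough that only exact
arithmetic ties (empty bins between modes) qualify in practice. For
pixel classification the fractional `t*` is rounded half-up to a cut
level; this single documented rule keeps masks bit-reproducible.

The class polarity is a genuine decision point: the algorithm's "low"
class B0 is conventionally called the target, but ICG fluorescence makes
vessels the *bright* class. The pipeline therefore defaults to
`bright_foreground` and exposes `dark_foreground` (CLI flag
`--dark-foreground`) for the literal low-class-as-target labeling.

### Numerical choices

All accumulations are single forward passes over the histogram in double
precision (`K <= 65536` makes `O(K)` exact passes trivially cheap; no
incremental update recurrences are used, so there is no drift to
control). The within/between/total decomposition is validated against
the conservation identity `sigma_V^2 + sigma_C^2 = sigma_E^2` at `1e-9`
relative tolerance, and the closed first-order form of `sigma_C^2`
against the two-term definition at the same tolerance. When the
within-class variance is exactly zero (two point masses), the `lambda`
and `kappa` criteria are reported as `Inf` rather than `NaN`; `eta` is
still defined whenever the total variance is positive.

## Preprocessing

None by default. The segmentation result is a pure function of the
histogram, and silent smoothing would change thresholds; an optional
Gaussian filter (`preprocess()`, `--smooth SIGMA`, sigma in pixels) is
available for noisy inputs and is always explicit. Color inputs are
reduced by the fixed Rec. 601 luma weights so RGB-encoded grayscale
exports segment bit-identically to their single-channel originals.

## Quality metrics

* **MSE** — mean squared intensity difference; on masks it is computed on
  the 0/1 labels.
* **SSIM** — structural similarity with the conventional stabilizers
  `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. The default is the *global*
  (single-window) form using whole-image population moments: it is
  deterministic and parameter-free, which matters more here than local
  sensitivity. A sliding-window mean (uniform windows) is available via
  `window =`. The implementation is pinned in the tests to an
  independent reference implementation's value on a fixed fixture at
  `1e-6`.
* **Shape error (SE)** — defined in this package as the symmetric
  difference between predicted and true masks normalized by the true
  area, `|pred XOR truth| / |truth|`. This is a *definition choice*, not
  an inherited formula: the quantity is named in the angiography
  literature without a formula. It is zero iff the masks agree, 1 when
  the prediction is empty, 2 for disjoint equal-area masks, and
  deliberately asymmetric (errors are scored relative to the anatomy to
  be recovered).
* **Dice** — `2|A∩B|/(|A|+|B|)`, the standard overlap oracle used by the
  phantom acceptance checks.

## The synthetic phantom

Real intraoperative angiograms of this kind are not publicly deposited,
so verification uses a seeded generator
(`generate_phantom()` / `icga-otsu simulate`) that emulates the
*statistics* the algorithm consumes — not the optics. A scene is:

1. a smooth random-walk centerline crossing the field left to right
   (fixed-length steps, AR(1)-damped heading jitter clipped to ±45°),
   dilated to a tube of the specified caliber (default 2.5 mm — a typical
   proximal cerebral artery);
2. one circular saccular bulge whose disc is tangent to the centerline
   (so it always overlaps the vessel), with diameter drawn uniformly
   within the requested clinical size class: small `[1.5, 5)` mm, medium
   `[5, 10]`, large `(10, 25]`, giant `(25, 35]` (the giant class is
   capped at 35 mm and the small class floored at 1.5 mm so every draw is
   renderable);
3. intensities `fg_mean = 180` on the geometry and `bg_mean = 40`
   elsewhere, Gaussian PSF blur (`blur_sigma = 1` px), additive Gaussian
   noise (`noise_sigma = 10`), clipping and rounding to 8 bits.

Default scale is 512×512 at 10 px/mm, so a 5 mm aneurysm spans 50 px and
the size classes stay visually and metrically distinct. The ground truth
is the **pre-blur** geometry: blur models optics, not anatomy, so metrics
score anatomy recovery. Additive Gaussian noise was chosen over Poisson
as the simplest model giving direct control over histogram overlap.

What the phantom does *not* emulate: fluorescence wash-in/wash-out
kinetics, depth-dependent attenuation, specular highlights from surgical
instruments, vessel trees with perforators, and non-uniform illumination.
Passing the phantom tests therefore shows the algorithm is implemented
correctly and behaves as theory predicts on bimodal imagery; it does not
certify clinical performance on patient angiograms.

Empirically (recomputed by `scripts/acceptance.R`): at the default noisy
conditions the Otsu mask holds Dice above 0.95 over 20 seeds, the
threshold always falls strictly between the two mean intensities, and
with noise and blur removed the segmentation reproduces the truth mask
exactly.

## Outcome statistics

The two-arm study component reproduces printed clinical tables (shipped
as transcribed JSON in `inst/extdata/study_tables.json`, 43 patients per
arm):

* **Rates** are percentages rounded *half-up* to two decimals — the
  convention under which 39/43 prints as 90.70 — implemented explicitly
  because base R rounds half to even.
* **Chi-square** is uncorrected Pearson on the 2×2 table. The Yates
  correction was deliberately not applied: for a good-outcome table of
  this size the corrected statistic crosses the 0.05 boundary, whereas
  the uncorrected statistic reproduces the reported significance, and
  uncorrected Pearson is the SPSS line such studies report.
* **The t-test** is the pooled-variance (Student) independent-samples
  test computed directly from each arm's mean/SD/n. Pooled rather than
  Welch: with equal n and similar SDs the choice is immaterial, and
  pooled is the literal "independent samples t-test" default. A raw-data
  round-trip test confirms equality with `t.test(var.equal = TRUE)`.

The **synthetic cohort** generator emulates the study design for
end-to-end testing: Hunt–Hess grade, aneurysm location and size class
reproduce the printed per-arm compositions exactly (permuted multisets),
while outcome category, complication flag and the continuous measures
are independent seeded draws with the printed rates and mean±SD values
as defaults. WHOQOL-BREF dimension scores are bounded numeric fields in
[0, 100]; the source reports their means only graphically, so the
defaults (pre 58±9 both arms; post 78±8 experimental, 70±8 control) are
plausible choices consistent with the reported direction of effect, and
no instrument scoring logic is implemented (the source's description of
the outcome scale conflates it with the coma scale, so scale arithmetic
would be guesswork). Setting the two arms' parameters equal yields a
null configuration used for calibration.

## Problem sizes used in verification

The shipped checks run at sizes chosen to make failures legible rather
than to stress hardware: oracle comparisons use 1000 random histograms
with `K` up to 16 plus an exhaustive sweep of all histograms with
`K = 4, 5` and counts in {0, 1, 2}; phantom quality uses 20 seeds at the
default 512×512 conditions (smaller rasters for geometry unit tests);
test calibration uses 2000 null-cohort replicates, under which the
chi-square's *exact* size at n = 43 and a 0.3 event rate is 0.052, so the
[0.04, 0.06] band is an honest two-sided check with Monte-Carlo SD
≈ 0.005.

## Known limitations

* Single global threshold only: no multi-level Otsu, no local/adaptive
  windows, no entropy criteria.
* The published image-quality values for this method on patient data
  (MSE 3.71, SSIM 0.84, SE 0.47) are not recomputable — the images are
  unavailable and the comparison reference unspecified — and are not
  claimed or targeted by any test here.
* DICOM, video streams and multi-frame ICG kinetics are out of scope;
  inputs are single PNG/TIFF frames.
* The shape-error definition is this package's own (documented above);
  comparisons against other reported "shape error" numbers require
  checking the definition first.
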