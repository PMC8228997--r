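---
title: "Methods: corneal flat-mount vessel quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corneal flat-mount vessel quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

The package quantifies vessel ingrowth into the cornea from whole-mount
RGB fluorescence images. The readout is an *area density*: the number of
pixels in a binary vessel segmentation divided by the number of pixels
in a user-defined corneal region, expressed in percent. Lymphatic
vessels are read from the red channel (LYVE-1/Cy3), blood vessels from
the green channel (CD31/FITC); the blue channel is ignored.

The region of interest is a pair of polygons: the outer limbal edge,
which defines the total cornea area, and an optional inner exclusion
border around the central cornea. We exclude the inner region from
**both** the segmentation and the area denominator — the central
exclusion exists because of staining artifacts, and tissue that cannot
contribute vessel pixels should not contribute denominator pixels
either. A user who wants the inner region counted in the denominator
can simply rasterize the outer polygon alone via `rasterize_roi()` on
an ROI without an inner border.

# The segmentation chain

Each stage is a separate tested function; `segment_vessels()` composes
them in fixed order. All filters use reflected borders, and the chain
contains no randomness: identical inputs give bit-identical masks.

**Anisotropic diffusion** (`enhance_contrast_diffusion()`). The
workflow this package follows names only a generic diffusion filter; we
use Perona–Malik diffusion with exponential conductance, the canonical
edge-preserving choice. Defaults: 10 iterations, κ = 20 on a 0–255
intensity scale, λ = 0.2 (explicit scheme, stable below 0.25). κ sits
well below typical vessel-to-background contrast (≈ 150 intensity
units on rendered synthetic data), so vessel edges conduct essentially
nothing and are preserved while speckle inside regions is smoothed.

**Median filter** (`median_filter()`). 15 × 15 at acquisition scale.
Implemented in C++ as an exact neighborhood median with reflected
borders; the test suite checks it against a brute-force per-pixel
oracle for exact equality.

**White top-hat** (`tophat_subtract()`). The workflow specifies the
top-hat by a single size parameter, 45, written as if it were a
Gaussian σ. Morphological top-hat has no Gaussian scale, so we read it
as the structuring-element size: a flat disc of radius 45 px at
acquisition scale. The open design question (σ vs element size) is
resolved this way because the neighboring stages
(median kernel in pixels, Frangi scales in pixels) are all specified as
pixel sizes. Grayscale opening is delegated to EBImage; since that
implementation operates on [0, 1] intensities, the input is affinely
mapped into [0, 1] and back — opening with a flat element commutes with
positive affine maps, so the result is exact. Note that a top-hat
cannot remove a background gradient right at the image border (the
residual there is slope × radius, which the tests account for).

**Frangi vesselness** (`frangi_vesselness()`). The two filter sizes of
20 and 25 pixels are read as Gaussian scales σ ∈ {20, 25} px, combined
by the per-pixel maximum. β = 0.5 (the standard blob-suppression constant) and γ set
per scale to half the maximum Frobenius norm of the scale-normalized
Hessian, the standard adaptive choice. Bright-vessel polarity: the
response is zeroed where λ₂ ≥ 0. Hessians are computed by
Gaussian-derivative convolution (FFT-based, reflect-padded); the
discrete second-derivative kernel is mean-centered so that a constant
image has exactly zero response despite support truncation, and a
vanishing Hessian norm (γ below 10⁻⁸) short-circuits to a zero
response.

**Otsu threshold** (`otsu_threshold()`). 256-bin histogram of min–max
normalized response values, *restricted to the cornea mask* by default,
so that the large dark area outside the limbus cannot drag the
threshold down. A `"frame"` scope is available since the original
workflow may have thresholded frame-wide. A constant response within
the region is a degenerate histogram: the stage itself raises an
error, but the composed pipeline treats it as "no tubular structure"
and returns an empty mask (this is exactly the situation of an image
whose only structures lie outside the ROI). Ties in the between-class
variance take the first (lowest) split.

**Cleanup** (`clean_segmentation()`). Pixels outside the annulus are
zeroed first, then connected components of fewer than 50 pixels are
removed (strict "less than": a 49-pixel object goes, a 50-pixel object
stays). Connectivity is 8 by default, the common 2-D convention; the
labeling is C++ with a flood-fill oracle in the tests.

**Manual corrections** (`apply_corrections()`). The original
workflow's hand edits in an image editor are replayed from add/remove
masks; the two must be disjoint, and the segmentation records a
`corrected` flag only when pixels actually changed.

## Parameter presets

The `"fullsize"` preset carries the acquisition-scale parameters above
for 2048 × 2048 images at 1.3 µm/px. The `"test"` preset targets the
512 × 512 synthetic canvas; its length parameters were calibrated once,
jointly with the synthetic generator defaults, before being frozen:
median 5, top-hat radius 30, Frangi scales {3, 5, 7}, minimum object
30 px. The top-hat radius is deliberately larger than a pure ¼
rescale of 45: on the synthetic images the relevant requirement is
that the disc be much wider than a vessel profile (diameter ≈ 9 px)
while narrower than the background vignette, and radius 30 sits safely
in that window.

# The synthetic generators

**Flat mounts.** Vessel trees are biased random walks: `n_seeds` entry
points drawn uniformly on the limbal polygon's perimeter, per-step
drift toward the cornea center (`inward_bias` = 0.5), Gaussian heading
noise (`wiggle_sd` = 0.15 rad), per-step bifurcation with probability
0.06 up to depth 3, and tube radius 3.5 px decaying ×0.85 per level
(values for the 512 preset; lengths scale ×4 at full size). Tubes are
rasterized as stamped discs and clipped to the annulus; the clipped
mask *is* the ground truth, so the stored true density is exactly
recomputable from it. Rendering adds a Gaussian cross-section profile
(blur σ = 2 px), a vignetted background, bright blob artifacts placed
uniformly over the frame (inside and outside the ROI, to exercise the
cleanup stage), Gaussian noise, and 8-bit quantization. Every
generator output is a pure function of its parameters and seed.

What this emulates: limbus-anchored dendritic ingrowth, uneven
illumination, speckle, staining artifacts, channel bleed-free two-class
staining. What it does not: optics (PSF, z-structure), tile stitching,
real staining chemistry, vessel caliber/branching statistics of real
corneas (no published morphometry constrains them — the defaults are
stated choices, not literature values). Passing recovery tests on
these images therefore demonstrates the pipeline's internal
correctness and its behavior under the modeled nuisances, not clinical
accuracy on real flat mounts, which retain a manual-correction step.

**Cohorts.** `generate_cohort()` draws per-eye outcomes (systemic GVHD
score 0–10, blepharitis 0–4, fluorescein grade 0–5, tear mm, lymphatic
and blood density %) from latent normals per group × timepoint cell;
scores are rounded and clamped to their declared ranges, densities
clamped to [0, 100]. With no effect specification all groups are
exchangeable — the basis of the type-I-error calibration. The default
of 10 eyes per group per timepoint corresponds to five mice with both
eyes scored, the upper end of the cohort sizes typical for this model
(3–5 mice, 6–10 eyes); it was fixed as the design default before any
power property was evaluated. `ogvhd_effects()` encodes a stylized
allogeneic disease course whose lymphatic-density shift is confined to
days 21/28, the window where lymphangiogenesis separates allogeneic
from syngeneic recipients.

# Statistical workflow

All group comparisons are nonparametric, matching the field's practice
for small ordinal-heavy samples. Choices worth recording:

- **Mann–Whitney U**: exact p by enumeration when combined n ≤ 12 and
  there are no ties (group sizes of 6–10 eyes make exact inference
  feasible), otherwise a tie-corrected normal approximation with
  continuity correction. The U statistic uses midranks.
- **Friedman post hoc**: the workflow specifies Bonferroni correction
  without naming the post hoc test family; we use pairwise Wilcoxon signed-rank tests with
  p multiplied by the number of comparisons (clipped at 1). Fully tied
  blocks yield statistic 0 and p = 1 rather than NaN. Incomplete
  blocks are rejected rather than silently dropped.
- **Pearson correlation**: effect-size categories at the conventional
  |r| ≥ 0.1/0.3/0.5 cut-offs, so r in the 0.3–0.5 band reports
  "medium".
- **KS normality screen**: parameters are estimated from the sample
  (the Lilliefors situation), making the asymptotic p conservative;
  it is advisory only — the pipeline proceeds nonparametrically
  regardless of its outcome.
- **Survival**: Kaplan–Meier and log-rank via the survival package; a
  dataset with no events at all is an explicit error, not a silent
  zero.

# Problem sizes used in the test suite

The shipped tests run the imaging pipeline on the 512 × 512 preset
(10 clean + 5 noisy recovery images, a 10 × 3 density sweep), the
calibration properties on 1000 null and 500 shifted synthetic cohorts,
and the stage oracles on ≥ 50 randomized ≤ 64 × 64 instances each —
sizes chosen so the full suite and the acceptance script each complete
in a few minutes on one CPU while keeping every property
well-resolved.

# Known limitations

- The Otsu scope and the σ = 45 / "20 and 25 pixels" interpretations
  are documented choices; a workflow replicating a specific historical
  analysis should verify them against that analysis's code.
- Density is a pure pixel ratio; no attempt is made to measure vessel
  length, caliber or branching topology.
- The generator's morphology parameters are plausible but
  unconstrained by published morphometry (see above).
- 16-bit output is supported for TIFF only; PNG round-trips at 8 bit.
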