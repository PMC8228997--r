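# corneaquant

Quantification of corneal lymphangiogenesis and hemangiogenesis from
whole-mount fluorescence images, for researchers studying ocular surface
disease in mouse models (e.g. ocular graft-versus-host disease after
bone marrow transplantation). The cornea is normally avascular; disease
drives lymphatic (LYVE-1⁺, red/Cy3) and blood (CD31⁺, green/FITC)
vessels to grow inward from the limbus. This package turns flat-mount
RGB images of such corneas into per-eye vessel *area densities* and
provides the clinical scoring aggregations and nonparametric statistics
used alongside them — plus synthetic data generators with known ground
truth so the whole pipeline is testable without any animal data.

## The method

**Segmentation.** For each vessel class, the assigned channel is
isolated and passed through a deterministic operator chain:

1. Perona–Malik anisotropic diffusion (edge-preserving contrast
   enhancement), conductance g(∇I) = exp(−(∇I/κ)²);
2. median filtering (15 × 15 kernel at acquisition scale);
3. white top-hat background subtraction, I − (I ∘ B) with a disc
   structuring element B (radius 45 px at acquisition scale);
4. multiscale Frangi vesselness: with scale-normalized Hessian
   eigenvalues |λ₁| ≤ |λ₂| at Gaussian scale σ,

   V(σ) = exp(−R_B²/2β²) · (1 − exp(−S²/2γ²)),  λ₂ < 0,

   where R_B = λ₁/λ₂, S = √(λ₁²+λ₂²), combined by the per-pixel
   maximum over σ ∈ {20, 25} px at acquisition scale;
5. Otsu thresholding on the histogram restricted to the user-drawn
   cornea region (so background outside the limbus cannot bias the
   threshold);
6. cleanup: pixels outside the limbal-edge/inner-border annulus are
   zeroed and connected components of fewer than 50 pixels removed;
   optional manual correction masks are applied with
   `apply_corrections()`.

**Quantification.** Density = 100 × (vessel pixels) / (cornea-mask
pixels), the percent of total cornea area covered by vessels; cornea
area is also reported in mm² at the configured pixel size (default
1.3 µm/px).

**Statistics.** Mann–Whitney U (exact by enumeration for combined
n ≤ 12 without ties), Friedman with Bonferroni-corrected pairwise post
hoc, Pearson correlation with effect-size categories
(small/medium/large at |r| ≥ 0.1/0.3/0.5), a Kolmogorov–Smirnov
normality screen (advisory), and Kaplan–Meier/log-rank survival.
Clinical scores: systemic GVHD score (five 0–2 sub-scores summed to
0–10, stop criterion at ≥ 6), blepharitis score (two 0–2 sub-scores
summed to 0–4), and 2^(−ΔΔCt) relative qPCR expression.

## Worked example

```r
library(corneaquant)

# a synthetic flat mount with known ground truth (512 x 512 preset)
sim <- simulate_flat_mount(seed = 11, noise_sd = 0, artifact_count = 0)
sim$gt$true_density_pct
#> lymphatic     blood
#> 10.626180  9.454759

seg <- segment_vessels(sim$image, sim$roi,
                       pipeline_params("lymphatic", preset = "test"))
seg
#> vessel_segmentation (lymphatic): 13895 px in mask (8.98% of cornea)

vessel_density(seg)          # percent of cornea area
#> [1] 8.98283
dice(seg$mask, sim$gt$lymphatic_mask)
#> [1] 0.8623236
```

The segmentation recovers the planted 10.6% lymphatic density as 9.0%
with a Dice overlap of 0.86 against the known mask. A cohort-level
analysis works from long-format tables:

```r
co <- generate_cohort(cohort_design(effect_spec = ogvhd_effects(),
                                    seed = 1))
compare_groups(co, "lymphatic_density_pct",
               c("syngeneic", "allogeneic"))
# Mann-Whitney U and p per timepoint; the planted allogeneic shift
# becomes significant at days 21/28 only
```

End-to-end runs (`run_full()`, or `inst/cli/corneaquant.R` from a
shell) write images, masks, `densities.csv`, `cohort.csv` and a JSON
statistics report, all reproducible from the seed.

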