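---
title: "Quantifying tri-lineage differentiation by colour deconvolution: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tri-lineage differentiation by colour deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainquant)
```

## The measurement problem

Tri-lineage differentiation assays stain the differentiated product (lipid
droplets, glycosaminoglycan matrix, calcium deposits) with one dye and the
cellular context (nuclei or cell-culture area) with a second. The readout
this package computes, the differentiation ratio

\[
\mathrm{DR} = \frac{\text{area\% of the differentiation dye}}
                   {\text{area\% of the counterpart}},
\]

is a per-image quantity; its donor-level normalized form
\(\mathrm{DR^N} = \overline{\mathrm{DR}}_{\text{diff}} /
\overline{\mathrm{DR}}_{\text{ctrl}}\) compares a donor's induced wells to
its own non-induced controls, cancelling donor-specific staining intensity
and cell density. \(\mathrm{DR^N} < 1\) reads as less differentiation
signal than spontaneously present in controls; \(> 1\) as more.

## Image model and assumptions

**Flat-field correction.** Brightfield intensities are modelled as
\(O = D + (L - D)\,T\): a sensor offset plus an illumination profile scaled
by specimen transmittance \(T\). The correction is the per-pixel,
per-plane quotient \(T = (O - D)/(L - D)\), clipped to \([0, 1]\). This is
the only reading under which a vignette cancels; the fraction of values
clipped at 1 (specimen brighter than the empty well) is logged per image.
Correction is done per colour plane, not on luminance, because the stain
vectors downstream are defined per plane.

**Hot pixels.** Sites where \(L \le D\) in any plane carry no usable
dynamic range. `repair_calibration()` replaces them — in both calibration
frames, all planes — by the median of their valid 8-neighbours, iterating
up to 10 sweeps; more than 1% defective sites is reported as a failed
calibration rather than silently patched. The same sites are interpolated
in the specimen image inside `correct_illumination()`: a saturated sensor
site holds no specimen signal, and carrying its raw value through the
quotient would leave a fixed-pattern artifact the darkfield capture exists
to remove.

**Beer–Lambert deconvolution.** Absorbance \(\mathrm{OD} = -\log_{10}
\max(T, 1/255)\) is additive across co-localized dyes, each contributing
along its unit stain vector \(v_s \in \mathbb{R}^3_{\ge 0}\). With the
residual vector \(v_3 = (v_1 \times v_2)/\lVert v_1 \times v_2 \rVert\)
(sign-flipped if its component sum is negative), concentrations solve the
3×3 system exactly: \(c = \mathrm{OD} \cdot M^{-1}\), \(M\) the row-stacked
basis. Assumptions worth stating: dyes absorb rather than scatter light
(dyes that scatter, or are neutral grey, cannot be unmixed this way), and
staining is stoichiometric enough that "more dye" means "more product".
Neither holds perfectly for real histology; the area-fraction readout is
deliberately robust to both because it thresholds rather than integrates
concentration.

**Thresholding.** Channels are re-coded to 8-bit transmittance
(\(255 \cdot 10^{-c}\), half-away-from-zero rounding, so stained = dark)
and binarized at a histogram threshold computed per channel per image.
Otsu's between-class-variance maximizer is the default; mean, isodata and
triangle are available, and a study-wide fixed threshold can be forced via
config when a lab prefers a frozen cut-off. Positivity is `value <=
threshold`, fixed globally — one convention, no silent sign errors.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| stain vectors | six named presets | unit OD triple | starting points only; real studies should calibrate with `estimate_stain_vector()` on a stained ROI (≥ 10 px, mean OD norm ≥ 0.05) |
| threshold method | `otsu` | – | most reproducible default; the method used is echoed into every output record |
| OD floor | 1/255 | transmittance | one grey level; caps OD at \(\log_{10} 255 \approx 2.41\) and keeps the transform finite at black pixels |
| repair cap | 1% of sites | – | beyond this the calibration, not the image, is the problem |
| `pixel_size_um` | user-supplied | µm/px | magnification alone does not determine µm/px, so the config must state it; conflicting image metadata only warns |

## Aggregation and statistics

Image DRs are averaged within well, then wells within donor (sections
averaged directly for chondrogenic studies, which have no well level).
Nested means equal grand means for balanced designs and stay well-defined
under dropouts; undefined DRs (counterpart area 0) are excluded with a
logged count. A donor with no usable controls falls back to the mean of
the other donors' control means, and the summary records
`control_source = "pooled-fallback"`.

The condition effect is tested by a univariate repeated-measures
decomposition on donor × condition means: \(SS_{\text{cond}}\) on 1 df
against the donor × condition interaction on \(n - 1\) df. One value per
cell is the only structure this design supports without modelling the
replicate covariance; with two conditions the resulting \(F\) equals the
squared paired \(t\) statistic (verified to 1e-8 in the tests, and
cross-checked against `stats::aov` with a donor error stratum). Degenerate
inputs are given defined behaviour rather than errors: identical
conditions give \(F = 0, p = 1\); a zero interaction SS with a non-zero
condition SS is reported as \(F = \infty, p = 0\) with a warning.

Pellet area supports both modes: manual ellipse axes
(\(\pi a b / 4\), from a sidecar CSV) and an automatic mask (union of both
stain masks, largest 8-connected component, pixel count × (µm/px / 1000)²).
Per-donor mean areas feed the same repeated-measures ANOVA.

## The synthetic-data generator

`render_stained_image()` is the exact forward model of the analysis:
regions of known stain concentration, transmittance
\(10^{-\sum_s c_s v_s}\) per plane, a radial multiplicative vignette
(corner gain in (0, 1]), a constant sensor offset, additive Gaussian noise
on the 8-bit scale (default σ = 2, a typical camera read-noise magnitude),
and saturated hot-pixel sites shared across a series like real
fixed-pattern noise. Ground truth (concentration maps, masks, area
fractions, DR) is emitted alongside every render.
`generate_synthetic_study()` writes a full donor/condition/well/image tree
(three wells × four images per donor and condition by default, the
replicate structure of the assay) in which differentiated images carry a
stained-area fraction equal to a per-donor effect multiplier times the
control fraction (defaults: control 5%, counterstain 20%).

What the generator does **not** emulate: stain co-localization, scattering
or grey dyes, focus variation, uneven section thickness, chromatic
aberration, and the texture of real tissue. Passing tests therefore
demonstrate that the pipeline inverts its own physics correctly and ranks
known effects reliably — not that any particular preset vector matches a
given lab's staining, which always needs per-study calibration.

## Problem sizes and numerical choices

Tests and the acceptance script run at sizes chosen to exercise every code
path at desk scale: 256×256 canvases for round-trip and flat-field
accuracy, 128×128 for the DR-recovery grid
(\(p_1, p_2 \in \{0.05, 0.1, 0.2, 0.4\}\)), 64×64 canvases and 96-image
studies for the 20-replicate end-to-end smoke. The type-I-error
calibration of the ANOVA (500 null studies of 6 donors) simulates at the
measurement level — per-image DRs with lognormal donor and replicate
variation via `simulate_dr_study()` — because the property under test
concerns the donor-level F statistic given replicate noise; rendering
micrographs for it would only add runtime. Image-level null behaviour is
covered separately by null `generate_synthetic_study()` runs.

Other numerical conventions, stated so results are bit-reproducible:
8-bit conversion rounds half away from zero; Otsu ties break to the
smallest qualifying threshold; negative unmixed concentrations (OD outside
the stain cone) are floored to zero after counting, and the count is
logged; all randomness in the generator flows from a single integer seed.

## Known limitations

- Two-stain unmixing only; the residual channel is computed but never
  thresholded, and three-stain quantification is out of scope.
- No retrospective shading correction: a calibration pair is required.
- No local/adaptive thresholding and no morphological cleanup of masks.
- Preset stain vectors are starting points, not reference values; studies
  that skip ROI calibration inherit whatever bias the presets carry.
- The ANOVA is the univariate donor-level decomposition; designs needing
  replicate-level covariance modelling should export `records.csv` and fit
  a mixed model directly.
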