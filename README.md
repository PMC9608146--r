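# stainquant

Quantifying mesenchymal stem cell (MSC) tri-lineage differentiation from
stained brightfield micrographs is usually done by eye, which makes
comparisons between donors, species and labs unreliable. `stainquant`
turns a batch of two-dye histology images — Oil Red O / hematoxylin for
adipogenic, Alcian Blue / Nuclear Fast Red for chondrogenic, Alizarin Red S
against the purple undifferentiated signal for osteogenic — into a single
per-donor number, the normalized differentiation ratio, plus the study-level
statistics to compare conditions.

## The method

For each micrograph:

1. **Flat-field correction.** With a darkfield frame *D* (closed
   illumination path) and a brightfield frame *L* (empty well) from the same
   acquisition series, each pixel and colour plane becomes the
   transmittance `T = (O − D) / (L − D)`, clipped to [0, 1]. Hot pixels
   found in the calibration pair (sites with `L ≤ D`) are repaired by the
   median of their 8-neighbours.
2. **Colour deconvolution.** Optical density `OD = −log₁₀ T` is linear in
   stain amount (Beer–Lambert), so with unit stain vectors `v₁` (the
   differentiation dye) and `v₂` (the counterstain), completed by their
   normalized cross product `v₃`, the per-pixel stain concentrations are
   `(c₁, c₂, c₃) = OD · M⁻¹` where `M` has rows `v₁, v₂, v₃`. Presets for
   the six dyes above ship with the package; `estimate_stain_vector()`
   calibrates a vector from a stained region of interest.
3. **Binarization and DR.** Each concentration map is re-coded as an 8-bit
   transmittance channel (`255·10^(−c)`), auto-thresholded (Otsu by
   default; mean, isodata and triangle also available), and the
   differentiation ratio is the ratio of positive-area percentages:
   `DR = area%₁ / area%₂`.

At the study level, image DRs are averaged within well and wells within
donor, and each donor's **normalized DR** is

```
DR^N = mean DR (differentiated wells) / mean DR (non-induced controls)
```

`DR^N > 1` means more differentiation signal than the donor's own controls;
`< 1` means less. A donor without usable controls (e.g. a control pellet
that never formed) falls back to the mean control DR of the other donors.
The condition effect is tested with a univariate repeated-measures ANOVA
(condition fixed, donor random; with two conditions, `F` equals the squared
paired *t* statistic). For chondrogenic studies, pellet cross-section area
(mm²) is an auxiliary readout, either from manually fitted ellipse axes
(`π·a·b/4`) or automatically from the largest connected stained component.

A forward renderer (`synthetic_scene()`, `render_stained_image()`,
`generate_synthetic_study()`) produces ground-truth micrographs through the
same Beer–Lambert model — with vignetting, sensor offset, hot pixels and
noise — so the entire pipeline is testable without real data.

## Worked example

```r
library(stainquant)

# a synthetic 4-donor study: donor effects 4x, 3x, 2x, 1x over control
g <- generate_synthetic_study("demo_study", n_donors = 4,
                              effect_multipliers = c(4, 3, 2, 1), seed = 11)

layout <- discover_study("demo_study", "adipogenic")
calib  <- calibration_pair(read_rgb_image(g$calibration$dark),
                           read_rgb_image(g$calibration$light))
res <- process_study(layout, calib, g$basis, out_dir = "demo_out")
res$summary[, c("donor", "dr_normalized", "classification")]
#>           donor dr_normalized classification
#> donor01 donor01      3.811307  above-control
#> donor02 donor02      2.855482  above-control
#> donor03 donor03      1.910700  above-control
#> donor04 donor04      1.006041  above-control
res$anova
#> rm-ANOVA (condition fixed, donor random): F(1,3) = 5.355, p = 0.1036
```

The recovered `dr_normalized` values sit within 0.2% of the generator's
expected DR^N (3.81, 2.85, 1.91, 1.01): donors are ranked exactly by their
true effect. The ANOVA *p* is large here because the donor effects are
deliberately heterogeneous (a large condition-by-donor interaction is the
error term of this design).

The same run from a shell:

```sh
Rscript inst/cli/stainquant.R synth    --config synth.yaml --out demo_study --seed 11
Rscript inst/cli/stainquant.R quantify --config run.yaml   --out demo_out
```

writing `records.csv` (per image, with thresholds used), `summary.csv`
(per donor), `anova.csv` and a run log.

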