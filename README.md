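# memcurve

Quantitative image analysis relating **membrane geometry to fluorescent-protein
recruitment** in time-lapse microscopy, built for the kind of question posed by
curvature-sensing actin regulators: does a probe enrich where the membrane is
highly curved, where it is flattening, or where the edge moves fastest?

The package covers four linked analyses:

- **Ring morphometry.** Nanoscale protein rings are segmented (rolling-ball
  background subtraction, thresholding, area filtering) and each particle's
  sub-pixel perimeter *C* is converted to the diameter of the perfect circle
  with the same perimeter, *d = C/π*.
- **Boundary geometry.** Segmented cell boundaries are traced as 1000-point
  sub-pixel splines. Signed curvature at point *P* comes from the osculating
  circle through *P* and the two points *S* indices away (*κ = 1/r*, positive
  when the circle's center lies on the non-cell side, so a closing
  transendothelial macroaperture — a TEM — has *κ* > 0). Edge velocity at *P*
  is the central difference of inside-positive signed Euclidean distance
  transforms of the masks at *t−1* and *t+1*, interpolated at *P* (positive =
  edge advancing).
- **Enrichment scoring.** Doughnut masks from successive dilations of the TEM
  mask give the enrichment factor *E* = (signal band intensity per area) /
  (background band intensity per area) — *E* = 1 means no enrichment — and the
  background-corrected intensity per unit perimeter followed across closure
  (Spearman ρ per TEM). Angularly binned normalized probe profiles
  (probe/membrane, 7.2° bins) are classified into **flattening** (*κ* > 0,
  d*κ*/d*t* < 0) and **lagging** (*κ* > 0, d*κ*/d*t* > 0) bins; the pooled
  fold enrichment (flattening over lagging; 1 = no preference) is tested
  against a **rotation null** that circularly shifts the fluorescence while
  the geometry stays put. Manders M1 colocalization, compartment ratios,
  scrambled-image controls, and protrusion length/width/speed morphometrics
  round out the toolbox.
- **Synthetic microscopy.** Every estimator is validated against a seeded
  generator with analytic ground truth: a closing TEM with a decaying mode-*m*
  lag perturbation and curvature/flattening-coupled probe deposition, an
  advancing leading edge with velocity-coupled probe, and fields of annular
  nanorings — all blurred by a unit-sum Gaussian PSF and corrupted by
  Poisson + read noise over a constant background.

## Worked example

```r
library(memcurve)

# a synthetic closing TEM whose probe couples to boundary curvature
sim <- make_closing_tem(seed = 42, b0 = 20, b1 = 600)
sim$stack
#> ImageStack: 8 frame(s) x 2 channel(s) x 128 x 128 px
#>   channels: membrane, probe
#>   pixel size 110 nm/px, frame interval 5 s

prof <- classify_regions(tem_edge_profile(sim$stack))
head(prof[prof$frame == 2, c("bin", "kappa", "velocity", "normalized", "label")], 3)
#>    bin      kappa velocity normalized   label
#> 51   1 0.07799246 1.951371  0.2611476 lagging
#> 52   2 0.07184921 1.824167  0.3769609 lagging
#> 53   3 0.06156260 1.614747  0.2817016 lagging

ser <- tem_series(sim$stack)
perimeter_trend(ser[ser$channel == "probe", ])      # 0.9285714
perimeter_trend(ser[ser$channel == "membrane", ])   # -0.524
```

The hole at frame 2 has curvature ≈ 0.05–0.08 /px (its radius is ≈ 15–20 px)
and closes at ≈ 1.4–2 px/frame. The curvature-coupled probe's intensity per
unit perimeter rises monotonically as the TEM shrinks (Spearman ρ = 0.93)
while the membrane dye's does not (ρ = −0.52) — the signature of progressive
enrichment at smaller, more curved apertures.

```r
rings <- run_ring_analysis(run_config("rings", seed = 1))
rings$summary
#>    n median_nm mode_nm hist_binwidth_nm
#> 1 25  243.3733     230               20
```

Twenty-five generated nanorings (diameters drawn around 230 nm) are recovered
with a histogram mode of 230 nm at the stated 20-nm bin width.

A thin CLI over the same functions lives at `inst/cli/memcurve`
(`synth-tem`, `analyze-tem`, `analyze-rings`, ... driven by YAML configs).

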