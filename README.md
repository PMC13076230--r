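# pillarwrap

Quantification of oligodendrocyte (OL) myelin wrapping on hydrogel
micropillar arrays.

In vitro myelination assays grow OLs on regular grids of vertical
polyacrylamide pillars that stand in for axons: cells wrap the pillar
shafts in myelin basic protein (MBP)–positive membrane, and the degree of
wrapping read from confocal z-stacks is the assay readout. `pillarwrap`
implements the complete measurement chain for such assays:

- **Array geometry and swelling.** Hydrogel features swell on immersion,
  so a pillar molded at diameter *D* realizes *D*(1 + *s*); the package
  detects the pillar grid in the FITC channel, measures realized
  diameters, and reports the swelling factor (*measured* − *D*)/*D*
  against the mold specification.
- **Wrapping score.** On the base-excluded maximum-intensity projection
  of the MBP channel, the annulus around each pillar is sampled in equal
  angular sectors; the covered fraction *c* and the largest angular gap
  grade each pillar on the ordinal 0–3 wrapping score (0 = no wrapping,
  3 = closed ring; the ring-closure rule demotes near-complete arcs with
  a gap wider than the tolerance).
- **g-ratio.** From the myelin ring thickness *t* (radial FWHM of the
  MBP signal outward from the pillar edge) and the measured pillar
  diameter *D*: *g* = *D*/(*D* + 2*t*).
- **Per-cell statistics.** Hoechst nuclei counted on the full-height
  projection (watershed-split), score distributions per field, fully
  wrapped pillars per cell, pillar:cell ratios, fold changes, and
  one-way ANOVA + Tukey HSD across conditions.
- **AFM stiffness.** The force-curve chain — smoothing, baseline
  subtraction, contact-point estimation, cantilever-bending correction —
  followed by the spherical Hertz fit
  *F* = (4/3)(*E*/(1 − ν²))√*R* δ^{3/2} for the Young's modulus, with
  per-gel aggregation of the 3 × 3 indentation grid.
- **TEM ultrastructure.** Lamella counting by prominence-filtered peaks
  on radial transects, band thickness between outer half-maximum
  crossings, per-lamella thickness, multilayer prevalence per field, and
  the thickness-versus-layers regression.
- **Synthetic data.** A seeded generator renders three-channel pillar
  fields (PILLAR/MBP/NUCLEI), Hertzian force curves and lamellar
  profiles with ground truth, so every stage is testable without
  microscope data.

All measurement functions take tabular inputs (tibbles or data frames)
where possible and return tibbles, so results flow through dplyr/ggplot2
pipelines; fitted objects have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate a 5 × 5 field of 5-µm pillars (10 µm spacing, 26% swelling),
then run the full quantification chain:

```r
library(pillarwrap)

spec  <- array_spec(mold_diameter_um = 5, interpillar_um = 10,
                    height_um = 22, rows = 5, cols = 5)
truth <- simulate_field_truth(spec, coverage = c(0, 0.25, 0.5, 0.75, 1),
                              sample_coverage = TRUE, n_nuclei = 6, seed = 42)
field <- render_field(spec, truth, noise_model(), seed = 42)

pillars <- detect_pillars(
  max_project(field$stack, "PILLAR", 0, Inf),
  expected_pitch_um = spec$pitch_um,
  expected_diameter_um = spec$realized_diameter_um
)
swelling_factor(pillars$diameter_um[pillars$present & !pillars$border], 5)
#>    mean      sd     n
#> 1 0.263 0.00452    25
```

The rendered field was built at 26% swelling, and the detected pillar
footprints report 26.3% ± 0.5% — the mold-versus-realized comparison a
new array design needs. Wrapping is then measured on the base-excluded
MBP projection (the gel base, below 4 µm here, carries no myelin):

```r
wraps <- measure_wrapping(max_project(field$stack, "MBP", 4, Inf), pillars)
head(wraps, 2)
#>   pillar_id coverage max_gap_deg score thickness_um g_ratio ...
#> 1         1        0         360     0        NA      NA
#> 2         2        1           0     3         1.15   0.731

nuc <- count_nuclei(max_project(field$stack, "NUCLEI", 0, Inf))
summarize_field(wraps, nuc$n_cells)[, c("n_cells", "n_pillars",
                                        "pct_score3", "score3_per_cell")]
#>   n_cells n_pillars pct_score3 score3_per_cell
#> 1       6        25         20           0.833
```

Pillar 1 carries no myelin (score 0); pillar 2 is a closed ring (score
3, coverage 1, gap 0°) with an apparent ring thickness of 1.15 µm — the
0.66-µm rendered ring widened by the 0.4-µm optical blur — giving
g = 0.73 on the 6.3-µm swollen shaft. Field-level: 20% of the 25
pillars are fully wrapped, 0.83 per cell.

AFM and TEM arms work the same way:

```r
fit <- fit_force_curve(simulate_force_curve(E = 5100, k = 0.1,
                                            noise_sd = 2e-10, seed = 1))
fit
#> <hertz_fit> E = 5.11 kPa (contact z0 = 2 um, rms 0.069 nN, 435 pts)

lam <- measure_lamellae(lapply(2:6, function(n)
  simulate_lamella_profile(n, 13, noise_sd = 0.03, seed = n)))
glance(thickness_layer_regression(lam))
#>   slope_nm_per_layer intercept_nm r_squared n
#> 1               13.0        0.104     1.000 5
```

A 5.1-kPa gel fits back at 5.11 kPa, and lamellar transects built at a
13-nm spacing regress to 13.0 nm per layer with R² ≈ 1.

Config-driven batch runs (`run_simulate()` / `run_quantify()`) write
stacks, per-pillar tables, field summaries and provenance records to
disk; see the methods vignette (`vignettes/pillarwrap-methods.Rmd`) for
the model, parameter defaults and design choices.

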