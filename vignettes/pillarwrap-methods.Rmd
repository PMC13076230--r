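---
title: "Methods: quantifying myelin wrapping on micropillar arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying myelin wrapping on micropillar arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillarwrap)
```

## The assay and its model

Oligodendrocytes cultured on arrays of vertical polyacrylamide pillars
wrap the pillar shafts in MBP-positive membrane, much as they wrap axons
in vivo. The pillars are a known, regular geometry: circles of mold
diameter $D$ at edge-to-edge spacing $d$, which swell on immersion to a
realized diameter $D(1+s)$ with center-to-center pitch $D(1+s)+d$. The
default swelling fraction is $s = 0.26$, the typical diameter increase
of polyacrylamide features in PBS relative to their mold. Because every
downstream quantity (annulus placement, g-ratio) keys off the realized
diameter, the package measures it from the image rather than trusting
the design value: Otsu threshold on the pillar (FITC) channel,
connected components, centroid and equivalent-disc diameter
$\sqrt{4A/\pi}$, then an axis-aligned lattice fit that also flags absent
sites and border-clipped discs.

Two maximum-intensity projections drive the measurements, both with
slice inclusion by slice-center in a half-open interval $[z_{lo},
z_{hi})$ (so adjacent ranges partition without double counting):

* full height — cell bodies and nuclei;
* base-excluded — myelin. The cut height is not a measured property of
  the assay but an acquisition convention; we default to $z_{lo} = 4$ µm
  and expose it as a parameter.

## Wrapping score

Per pillar, the annulus $[r, r + w]$ (inner radius $r$ = measured pillar
radius, width $w = 2$ µm by default) is sampled in $n = 72$ equal
angular sectors (5° each). Each radial ray is reduced to its maximum
intensity across the annulus — a ring much thinner than the annulus
would otherwise be averaged below threshold — and a sector counts as
covered when the mean over its rays exceeds the field threshold (Otsu on
the base-excluded MBP projection, computed once per field;
overridable). Coverage $c$ is the covered fraction; the maximum gap is
the longest circular run of uncovered sectors.

The ordinal score is defined at its endpoints by the assay itself
(0 = no wrapping, 3 = closed ring). The intermediate edges are not
physical constants, so we fix symmetric defaults and report them with
every summary: score 0 for $c < 0.05$, 1 for $c < 0.45$, 2 for
$c < 0.95$, and 3 for $c \ge 0.95$ **and** maximum gap $\le 18°$ (a
"full ring" must close; near-complete arcs with a wider gap demote
to 2). All edges and the gap tolerance live in `score_bins()`.

Ring thickness is the median, over covered sectors, of the
full-width-at-half-maximum of the radial MBP profile outward from the
pillar edge; values under one pixel floor at the pixel size and carry a
resolution flag. The g-ratio uses the measured (swollen) diameter,
$g = D/(D + 2t)$, because the formula's $D$ is the diameter of the
wrapped structure, not of the mold.

### What blur does to thickness

Optical blur widens the apparent ring: a rendered 0.66-µm ring under
the default 0.4-µm Gaussian blur measures ≈1.15 µm FWHM
($\sqrt{0.66^2 + (2.355\cdot 0.4)^2}$), and the g-ratio drops
accordingly. This is a property of the imaging, not a defect of the
estimator — noiseless tests recover thickness within one pixel — but it
means absolute g-ratios from diffraction-limited light microscopy are
systematically low for thin rings, on real data as much as on synthetic
renders.

## Per-cell statistics

Nuclei are counted on the full-height Hoechst projection: Otsu
threshold, distance transform, watershed split (tolerance 1 px), and a
minimum area of 12 µm² to reject debris — enough to separate touching
somata without fragmenting single nuclei. Field summaries report score
counts and percentages, fully wrapped (score 3) pillars per cell, and
the pillar:cell ratio; pillars flagged during measurement (annulus off
the image) are excluded from every denominator and their count is
reported, so nothing is dropped silently. Fold changes divide a
condition's values by the **mean** of the reference fields (a ratio of
means, not a mean of ratios); the choice is recorded in output
provenance. Cross-condition testing is standard one-way ANOVA with
Tukey HSD via `stats::aov()`/`TukeyHSD()`.

## AFM force curves

The processing chain mirrors standard instrument software, made
explicit and reproducible: moving-average smoothing (11 samples);
straight-line baseline fitted on the pre-contact segment and
subtracted; contact point $z_0$ by a two-segment piecewise fit (flat
baseline plus Hertz-shaped rise) minimizing total squared residual over
a coarse candidate grid, then refined continuously by Brent
optimization **against the raw curve** — refining on the smoothed curve
would bias $z_0$ early by about half the smoothing window; cantilever
bending removed via the vertical tip position $\delta = (z - z_0) -
F/k$. The spherical Hertz model
$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}$ is linear
in $E$ given $\delta$, so the modulus is a closed-form least-squares
estimate over indentations up to 10% of the bead radius (the
shallow-indentation regime where Hertz contact holds). Poisson ratio
defaults to 0.5 (incompressible gel); bead radius is half the stated
bead diameter (12.5 or 25 µm). Gel stiffness is the arithmetic mean of
the nine measurements of the 3 × 3 indentation grid.

The synthetic generator solves the same relation self-consistently
(Newton iteration on $\delta + A\delta^{3/2}/k = z - z_0$), so
generator and fitter share only the physics, not the code path. A curve
whose post-contact force never rises five baseline-noise standard
deviations is rejected as "no contact". When pairing cantilevers with
gels, the spring constant should roughly match the expected contact
stiffness — fitting a 55-kPa gel with a 0.01 N/m lever leaves almost no
true indentation signal — which is why the stiffness-ladder simulations
pair 0.01/0.1/0.3/0.6 N/m with 0.5/5/20/55 kPa.

## TEM lamellae

Transects across compact myelin show one intensity peak per lamella.
Layers are counted as local maxima whose topographic prominence exceeds
20% of the profile's dynamic range, at least 5 nm apart (individual
lamellae below ~4 nm spacing are not resolvable, so closer peaks are
merged). Total thickness is the width of the lamellar band between its
outer half-maximum crossings after demodulation by a moving average
over one lamellar period — a symmetric boxcar preserves a band's
half-maximum width exactly, whereas a moving maximum would dilate it by
about half a period per side. Per-lamella thickness is
thickness/layers by definition, and the thickness-versus-layers
relation is ordinary least squares (`stats::lm()`), checked in the
tests against hand-rolled normal equations.

## The synthetic generator

The generator exists so that every stage has ground truth. It emulates:

* pillar fields: binary cylinders over the full height; myelin as
  annular arcs of configured coverage and thickness at the pillar
  surface, present only above the base-exclusion height (default 4 µm),
  one contiguous arc per pillar at a seeded random start angle
  (optionally split into two opposite arcs to exercise gap logic);
  nuclei as ellipsoidal blobs (3.5 µm lateral, 2.5 µm axial semi-axes)
  near the gel base with a 9-µm minimum separation;
* optics and noise: Gaussian blur (0.4 µm), flat background (5% of
  peak), Gaussian read noise (2% of peak), optional Poisson shot noise.
  These are engineering choices for a plausible confocal
  signal-to-noise ratio, not measured acquisition parameters;
* force curves: 1,024 evenly spaced piezo samples spanning a ~50%
  baseline plus 2 µm of travel beyond contact, with the
  self-consistent bending relation above;
* lamellar transects: $n$ evenly spaced peaks under a smooth band
  envelope whose half-maximum width equals $n \times$ period, sampled
  at 0.25 nm.

What it does **not** emulate: a real point-spread function (only
Gaussian blur), cell morphology beyond arcs and blobs, myelin
z-structure (arcs are uniform above the exclusion height),
TEM imaging physics, or instrument drift in force curves. Passing
recovery tests therefore demonstrates the estimators are correct on
data obeying the stated model — sub-pixel centroids, one-bin coverage,
1%-level moduli — not that segmentation is robust to arbitrary real
microscopy; thresholds are exposed precisely so real data can be tuned.

Determinism is strict: every generator takes an integer seed, restores
the caller's RNG state, and identical inputs give bit-identical
outputs. Batch runs (`run_simulate()`/`run_quantify()`) are fully
determined by their configuration — output tables, logs and provenance
files are byte-identical across re-runs, with stage timings kept out of
the persisted log for that reason.

## Problem sizes and numerical choices

Tests and the acceptance script run on deliberately small instances
chosen to exercise every code path at desk scale: 3×3 to 5×5 pillar
fields at 0.25–0.3 µm/px (one 15 × 15 field for the end-to-end
summary), 24-transect TEM cohorts, 9-curve gels, and 1,000-replicate
null simulations for the ANOVA type-I check. Other numerical defaults:
bilinear interpolation for all sub-pixel sampling; annulus sampling at
half-pixel radial steps; contact-point refinement tolerance 0.01 nm;
Hertz fit restricted to ≥20 post-contact samples; lattice fit by
iterated least squares with nearest-node assignment. Degenerate inputs
(blank fields, baseline-only curves, flat transects, zero-variance
groups, zero-cell fields) raise classed errors or flagged NA rather
than silent zeros.

## Known limitations

* Scoring is 2-D, from the projection, as in the assay convention; no
  3-D surface reconstruction of the wrap.
* The score bin edges between the defined endpoints are conventions;
  comparisons across laboratories must state them (summaries carry
  them in provenance).
* Thin-ring thickness, and hence the g-ratio, inherits the optical
  resolution bias discussed above.
* The Hertz fit assumes a thick, flat, elastic substrate: no
  bottom-effect correction, no viscoelasticity, no conical-tip
  geometry.
* Pillars are not assigned to individual cells; per-cell metrics are
  field-level ratios.
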