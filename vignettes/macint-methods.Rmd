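---
title: "Measuring macular integrity in geographic atrophy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring macular integrity in geographic atrophy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macint)
```

## The measurement problem

Geographic atrophy is tracked in trials by total lesion area on fundus
autofluorescence, yet a lesion can add square millimetres far from the fovea
without touching vision. `macint` quantifies what actually remains of the
central macula: the Macular Tissue Integrity Index (MTII) is the percentage
of non-atrophic retina within fovea-centered circles on FAF, and the
Ellipsoid Zone Integrity Index (EZII) is the percentage of intact ellipsoid
zone — the OCT band that tracks photoreceptor inner-segment health — within
the same circles. Two zone sizes are used because their physiology differs:
the 1-mm zone is cone-dominated and couples to best-corrected acuity, the
3-mm parafovea carries most rods and couples to low-luminance acuity.

Both indices are ratios of areas, so everything reduces to one geometric
primitive: the area of a region (a pixel mask, or a stack of per-scan
intervals) intersected with a disc, in physical units.

## Raster geometry

A mask pixel with zero-based indices $(i, j)$ occupies the half-open
rectangle $[i s_x, (i+1) s_x) \times [j s_y, (j+1) s_y)$ in millimetres,
origin at the image's top-left corner, y downward. A fovea given in pixel
coordinates is taken at its pixel center, $((i + 0.5) s_x, (j + 0.5) s_y)$ —
a fixed convention so that files round-trip without half-pixel ambiguity.

`mask_area_in_circle()` classifies each pixel rectangle against the disc by
its nearest and farthest corner distance: wholly-inside and wholly-outside
pixels are resolved exactly; only the $O(\text{perimeter}/s)$ pixels cut by
the disc boundary are subdivided into `supersample` × `supersample` subcells
whose centers are tested. With the default `supersample = 8` the residual
error is far below the Monte-Carlo noise of a $10^6$-point estimate (the
test suite checks 50 random mask/circle pairs against exactly that oracle,
and that refining 4 → 16 changes results by well under 0.5% of the circle
area). Portions of a disc outside the image count as non-atrophic, mirroring
graders who can only mark visible lesion; exact polygon clipping is
deliberately avoided — the subcell scheme has bounded error and no geometry
dependencies.

The clinically reported quantity is `intact_area_in_circle()` = circle area minus
GA-in-circle, clamped to $[0, A_{circle}]$, and
$\mathrm{MTII}_d = 100 \cdot \mathrm{intact}_d / A_{circle}(d)$. The FAF
denominators are the *annotated* grid circles — 1.2 mm and 3.6 mm diameter
(1.13, 10.18 mm²) — because those are the circles the reading-center
software actually draws; the OCT grid uses nominal 1 mm and 3 mm circles
(0.79, 7.07 mm²).

## Lesion quality control

Lesions are 8-connected components (diagonal contact joins; blob-like
lesions fragment unnaturally under 4-connectivity). The minimum-size rule
keeps a component if its minimum Feret diameter is at least 250 µm **or**
its area at least 0.05 mm², both boundaries inclusive; the disjunction reads
the grading protocol literally, and a conjunctive variant is available for
sensitivity analysis (`lesion_filter_rule: "and"`). "Smallest diameter" is
operationalized as the minimum Feret diameter of the union of pixel
rectangles, computed exactly on the convex hull via the rotating-calipers
identity (the minimum width of a convex polygon is attained perpendicular to
one of its edges); tests compare against a brute-force 3600-rotation
projection oracle. Eyes with less than 0.05 mm² of intact tissue in the
small circle are flagged ineligible — the same floor the atrophy
classification consensus uses as a minimum lesion size.

## EZ strip integration

Graders annotate intact-EZ runs per B-scan; en face this yields, per scan, a
set of disjoint half-open intervals at a known y. Each scan represents a
strip whose thickness is half the distance to each neighboring scan (edge
scans extended symmetrically, so uniform spacing gives every scan the
spacing as thickness). `ez_area_in_circle()` clips the strip's band to the
disc's vertical extent, takes the chord at the clipped band's midpoint, and
sums interval–chord overlap times band height. The single representative
chord per strip matches the per-B-scan nature of the data; its error is
bounded by the strip thickness and is checked against a 5-µm rasterization
oracle (within 1% of the circle area on random maps at the default 0.06 mm
spacing). Clipping the band matters: without it, strips straddling the disc
edge are either dropped or counted at full thickness, and the cap error
alone can reach several percent of a 1-mm disc. Intervals are binary — any
EZ presence counts as intact, with no thickness weighting. A scan with no
intact EZ is still a scan: it occupies its strip with zero contribution
rather than widening its neighbors.

## Longitudinal change and stratification

`compute_change()` annualizes paired visits with the clinical sign
convention (positive growth = enlargement, positive loss = tissue decline);
it is antisymmetric under visit exchange, and per-eye rates average to the
difference of cohort means under complete pairing. The Slow/Rapid **Loser**
split uses fixed per-zone thresholds — FAF 0.10 (1 mm) and 0.75 (3 mm)
mm²/yr, OCT 0.04 and 0.49 mm²/yr — with the boundary belonging to the slow
stratum. No published cutoff exists for Slow/Rapid **Grower**, so the
cohort-median split is used (ties go slow; scale-free and matching the
descriptive usage), with an absolute `grower_cutoff` override.

## Structure–function regression

Acuity is converted by the standard chart identity
$\mathrm{logMAR} = -0.02 \cdot \mathrm{letters} + 1.7$ (85 letters ≡ 0.0).
Regressions are ordinary least squares of logMAR on an index (percent) or an
area (mm²), reported as slope, $R^2$, and the two-sided slope t-test with
$n-2$ df. Whether published fits used letters or logMAR is ambiguous; logMAR
is the default here since that is the plotted axis, and letters remain one
conversion away. Following the single-threshold convention (p < 0.05), no
multiplicity correction is applied, but `regression_panel()` carries a
Holm-adjusted column for readers who want it. A constant outcome is a
legitimate degenerate case and returns slope 0, $R^2$ 0, p 1 rather than an
error.

Grader agreement is the signed paired difference in intact area (mean ±
sample SD) — signed, because a mean near zero with a larger SD is exactly
the signature of unbiased graders, which absolute differences would hide.
Bland–Altman limits are available but off by default.

## The synthetic cohort

No images from the underlying trial are public, so the generator is a
first-class module: it produces cohorts with the statistical structure the
analysis assumes, and every pipeline stage is validated against its ground
truth. What it emulates, with defaults:

| parameter | default | rationale |
|---|---|---|
| `n_eyes` | 43 | analyzed cohort size |
| `image_px`, `scale` | 384 px, 0.025 mm/px | 9.6 mm field covering the 3.6 mm circle plus lesion growth |
| `multifocal_prob` | 0.74 | reported multifocal share |
| `subfoveal_prob` | 0.42 | reported subfoveal share (pre-eligibility) |
| `baseline_ga_mean/sd` | 8.87 / 5.34 mm² | reported baseline GA, truncated to the 1.9–17 mm² inclusion window |
| `growth_mean/sd` | 1.90 / 1.39 mm²/yr | reported annual growth, truncated at 0 |
| `central_budget_mm2` | 0.4 | scale of the independent centripetal advance (below) |
| `ez_margin_mean` | 0.15 mm | EZ loss extends a halo beyond the GA margin |
| `va_slope`, `va_noise_sd` | 0.43, 0.27 logMAR | decompose a 15-letter BCVA spread into a structural part explaining $R^2 = 0.20$ (given a 31-point MTII spread) plus residual noise |
| `scan_spacing` | 0.06 mm | dense macular OCT volume |
| `grader_jitter_sd` | 0.4 mm² | regrade area perturbation (≈ reported between-grader SDs / √2) |

Truncated-normal draws are *moment-matched*: the normal location is solved
(by `uniroot` on the closed-form truncated mean) so the post-truncation mean
equals the configured cohort mean — naive truncation of N(1.90, 1.39) at
zero would inflate mean growth to ≈ 2.15 mm²/yr.

Baseline lesions grow by stochastic boundary dilation from seed points.
Placement is calibrated to the published baseline composition: a subfoveal
largest focus is seeded at 0.6–0.9 of its eventual radius from the fovea
(fovea involved, central disc only partly covered — as the eligibility floor
demands of analyzed eyes), a sparing focus puts its margin 0.05–0.9 mm from
the fovea, satellites sit at 0.6–2.0 mm. This reproduces baseline
MTII-1mm ≈ 55 ± 33 (published 51 ± 31) and keeps the realized multifocal
share near 74%. The realized subfoveal share (~35%) sits below the
configured 42% because eligibility regeneration preferentially rejects
deeply involved eyes — the trial itself excluded 20 of 63 eyes at the same
floor.

Year-1 growth is directional. A per-eye centripetal share (U-shaped Beta
around `centripetal_fraction`, so most eyes are predominantly
macula-sparing or macula-centric) scales a small *independent* centripetal
budget (`share × central_budget_mm2`, capped by the eye's growth draw, a cap
that rarely binds) which advances a narrow front at the fovea-nearest
boundary; the rest of the growth spreads over the fovea-far half. The
budget is independent of the growth magnitude by construction because that
is the empirical phenomenon under test: central progression does not track
overall enlargement. We first implemented the more obvious design — growth
allocated by a directional probability weight alone — and found it cannot
decouple the two (central loss stays proportional to total growth,
r ≈ 0.4 at n = 300); the independent-budget design yields r ≈ 0.03–0.10
with central-disc loss 0.11–0.14 ± 0.12 mm²/yr against the reported
0.12 ± 0.09. A known limitation: 3-mm-circle intact loss comes out around
0.3 mm²/yr versus the reported 0.83, a side effect of keeping the
fovea-near boundary quiescent outside the tongue.

Acuity is linear in central integrity:
$\mathrm{BCVA}_{logMAR} = 0 + s(1 - \mathrm{MTII}_1/100) + \varepsilon$,
$\mathrm{LLVA}_{logMAR} = 0.3 + s(1 - \mathrm{EZII}_3/100) + \varepsilon$.
The 0.0/0.3 anchors are generator conventions, not cohort estimates. Letter
scores are kept fractional (clipped to [0, 100]) so the coupling survives
the letters round trip exactly; whole-letter quantization would add ~0.006
logMAR of noise for no modeling gain. Ceiling clipping at 100 letters
slightly attenuates slope recovery in cohorts with many near-intact maculae;
with the calibrated lesion placement the 95% CI coverage of the recovered
slope is ≈ 94%.

What the generator does **not** emulate: FAF/OCT intensity texture,
reticular pseudodrusen, junctional-zone phenotypes, eccentric fixation,
measurement error in the fovea location, or inter-visit registration error.
Passing tests therefore validate the *analysis machinery* under the assumed
statistical structure — they say nothing about segmentation quality on real
images, which is upstream of this package's scope.

## Determinism and problem sizes

Every stochastic operation draws from R's RNG; `generate_cohort()` seeds it
from `config$seed`, so a bundle is byte-identical across reruns. The test
suite exercises cohorts of 8–200 eyes plus one 500-eye run for the
growth/loss decoupling, a $10^6$-point Monte-Carlo oracle on 50 geometry
cases, a 5-µm raster oracle on 25 EZ maps, 1000 coverage replicates and 400
type-I replicates on a fixed 200-eye design — sizes chosen so each property
is measured with its sampling error well inside the asserted margin. The
coverage check uses 1000 replicates against the 93% pass threshold because
at 100 replicates the binomial noise (±2.3 points) is as large as the margin
between nominal 95% and the threshold.

## Degenerate inputs and tie-breaks

Empty masks and empty EZ maps are valid (indices 100 and 0 respectively);
a GA mask covering both discs gives index 0 and ineligibility. Loss rates
exactly at a Loser threshold go slow; growth exactly at the cohort median
goes slow; a lesion exactly at 0.05 mm² or 250 µm is retained; an intact
area exactly at 0.05 mm² is eligible. Single-scan EZ maps parse but refuse
area computation until a strip thickness is supplied
(`single_scan_thickness`), since spacing cannot be inferred from one scan.
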