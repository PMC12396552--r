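# macint

Integrity indices for the central macula in geographic atrophy (GA).

Total GA area growth on fundus autofluorescence (FAF) is the standard
clinical-trial endpoint for atrophic age-related macular degeneration, but it
barely correlates with visual function: lesions can enlarge peripherally while
the fovea is spared, or creep centrally while total growth is slow. `macint`
implements two zone-restricted alternatives and the analysis pipeline around
them:

- **MTII** (Macular Tissue Integrity Index) — the percentage of non-GA retina
  within fovea-centered circles on FAF:
  `MTII_d = 100 · (A_circle(d) − A_GA∩circle(d)) / A_circle(d)`,
  with the annotated ETDRS-grid circles of diameter 1.2 mm and 3.6 mm
  (areas 1.13 and 10.18 mm²).
- **EZII** (Ellipsoid Zone Integrity Index) — the percentage of intact
  ellipsoid zone within the same zones on OCT, integrated en face from
  per-B-scan intact-EZ intervals, with nominal 1 mm and 3 mm circles
  (areas 0.79 and 7.07 mm²).

Around the two indices the package provides:

- calibrated raster geometry with sub-pixel handling of the circle boundary
  (`mask_area_in_circle`, `intact_area_in_circle`);
- GA lesion extraction with reading-center minimum-size quality control
  (8-connected components, minimum Feret diameter ≥ 250 µm **or** area
  ≥ 0.05 mm²) and the central-tissue eligibility floor (intact area
  ≥ 0.05 mm² in the small circle);
- per-B-scan intact-EZ interval validation and strip integration
  (`ez_map`, `ez_area_in_circle`, `compute_ezii`);
- paired baseline → year-1 change rates, Slow/Rapid **Loser** stratification
  at the per-zone thresholds (FAF: 0.10 / 0.75, OCT: 0.04 / 0.49 mm²/yr) and
  Grower × Loser quadrant labels (`compute_change`, `classify_loser`,
  `classify_quadrant`);
- ETDRS-letter ↔ logMAR conversion and univariate structure–function
  regression panels (`letters_to_logmar`, `fit_univariate`,
  `regression_panel`);
- inter-grader agreement as signed paired differences
  (`paired_difference_stats`);
- a seeded synthetic-cohort generator — multifocal lesions grown by
  stochastic dilation, directional year-1 growth with an independent
  centripetal budget, EZ-loss halos beyond GA margins, acuity linearly
  coupled to central integrity — for validating every stage
  (`sim_config`, `generate_cohort`).

File formats: single-channel PNG/TIFF masks with JSON sidecars (pixel scale,
fovea), CSV intact-EZ interval tables, CSV cohort tables, YAML configuration.

## Worked example

```r
library(macint)

cfg <- sim_config(n_eyes = 6, seed = 42)       # defaults emulate a GA trial cohort
coh <- generate_cohort(cfg)                    # masks, EZ maps, acuity, ground truth
eye <- coh$eyes[[1]]

compute_mtii(eye$mask_baseline, eye$meta_baseline, size_filter = FALSE)
#> MTII: 9.0% (1 mm, 0.102 mm^2 intact), 38.9% (3 mm, 3.962 mm^2 intact)
#> GA area: 15.62 mm^2; eligible: TRUE

compute_ezii(eye$ez_baseline, fovea_point(eye$meta_baseline))
#> EZII: 0.0% (1 mm, 0.000 mm^2), 13.1% (3 mm, 0.923 mm^2); total intact EZ 72.18 mm^2

ch <- compute_change(as_visit_result(eye$mtii_baseline, "P001"),
                     as_visit_result(eye$mtii_year1, "P001"))
#> GA growth 2.29 mm2/yr, central intact loss 0.000 mm2/yr
classify_loser(ch$intact_loss_1, "z1mm", "FAF")$label
#> "SlowLoser"
```

This eye grew by 2.29 mm²/yr overall yet lost nothing inside the central
1-mm zone — a "Rapid Grower, Slow Loser" pattern; its 9% baseline MTII and 0%
EZII in the 1-mm circle show a heavily involved but still eligible macula
(EZ loss extends beyond the GA margin, so EZII sits below MTII). A
structure–function panel over the cohort regresses acuity on the indices:

```r
tab <- coh$truth
tab$bcva_logmar <- letters_to_logmar(tab$bcva_letters)
regression_panel(tab, c("mtii_1", "ezii_1"), "bcva_logmar")
```

At n = 6 nothing is significant (p ≈ 0.4–0.6); the acceptance script below
runs the same machinery at n = 200 where the configured coupling is
recovered.

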