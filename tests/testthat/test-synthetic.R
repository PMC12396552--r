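test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_eyes = 2, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$eyes[[1]]$mask_baseline$pixels,
                   b$eyes[[1]]$mask_baseline$pixels)

  set.seed(5); m1 <- simulate_baseline_mask(cfg)
  set.seed(5); m2 <- simulate_baseline_mask(cfg)
  expect_identical(m1$mask$pixels, m2$mask$pixels)
})

test_that("baseline masks respect focality, involvement and area settings", {
  cfg_uni <- sim_config(multifocal_prob = 0, subfoveal_prob = 1, seed = 1)
  set.seed(21)
  for (k in 1:5) {
    e <- simulate_baseline_mask(cfg_uni)
    expect_equal(e$focality, "unifocal")
    expect_equal(e$foveal_involvement, "subfoveal")
    expect_length(extract_lesions(e$mask), 1)
    # area lands within the inclusion window (pixel rounding tolerance)
    expect_gte(mask_area(e$mask), 1.9 - 0.01)
    expect_lte(mask_area(e$mask), 17 + 0.01)
  }
  # subfoveal seeding puts GA on the fovea pixel
  set.seed(22)
  e <- simulate_baseline_mask(cfg_uni)
  fpx <- cfg_uni$image_px %/% 2L + 1L
  expect_true(e$mask$pixels[fpx, fpx])
})

test_that("every generated focus clears the minimum-size criteria", {
  cfg <- sim_config(seed = 1)
  set.seed(23)
  for (k in 1:4) {
    e <- simulate_baseline_mask(cfg)
    les <- extract_lesions(e$mask)
    kept <- apply_lesion_size_filter(les)
    expect_equal(length(kept), length(les))
  }
})

test_that("year-1 masks contain their baselines and zero growth is identity", {
  cfg <- sim_config(seed = 1)
  set.seed(24)
  bl <- simulate_baseline_mask(cfg)
  fov <- fovea_point(bl$meta)
  for (k in 1:5) {
    y1 <- grow_mask(bl$mask, fov, cfg)
    expect_true(all(y1$pixels[bl$mask$pixels]))
  }
  frozen <- sim_config(growth_mean = 0, growth_sd = 0, seed = 1)
  y0 <- grow_mask(bl$mask, fov, frozen)
  expect_identical(y0$pixels, bl$mask$pixels)
})

test_that("EZ maps shadow the GA mask: zero halo matches MTII, halos lower EZII", {
  set.seed(25)
  cfg0 <- sim_config(ez_margin_mean = 0, scan_spacing = 0.025, seed = 1)
  bl <- simulate_baseline_mask(cfg0)
  fov <- fovea_point(bl$meta)
  mt <- compute_mtii(bl$mask, bl$meta, c(1.0, 3.0), 16, size_filter = FALSE)
  ez <- compute_ezii(derive_ez_map(bl$mask, cfg0), fov, c(1.0, 3.0))
  expect_lt(abs(ez$ezii_1 - mt$mtii_1), 2)
  expect_lt(abs(ez$ezii_3 - mt$mtii_3), 2)

  cfg_halo <- sim_config(ez_margin_mean = 0.2, scan_spacing = 0.025, seed = 1)
  ezh <- compute_ezii(derive_ez_map(bl$mask, cfg_halo), fov, c(1.0, 3.0))
  expect_lte(ezh$ezii_1, mt$mtii_1 + 2)
  expect_lte(ezh$ezii_3, mt$mtii_3 + 2)
  expect_lt(ezh$ezii_3, ez$ezii_3)    # the halo strictly erodes coverage

  # GA covering the whole image leaves no intact EZ
  cov <- full_mask(64, 0.05)
  ez_none <- derive_ez_map(cov, cfg0)
  expect_equal(ez_area_total(ez_none), 0)
})

test_that("acuity model anchors and noiseless slope recovery hold", {
  cfg0 <- sim_config(va_noise_sd = 0, seed = 1)
  va <- simulate_va(100, 100, cfg0)
  expect_equal(va$bcva_letters, 85)
  expect_equal(va$llva_letters, 70)    # +0.3 logMAR anchor

  set.seed(26)
  mtii <- runif(100, 5, 95)
  va2 <- simulate_va(mtii, mtii, cfg0)
  fit <- fit_univariate(1 - mtii / 100, letters_to_logmar(va2$bcva_letters))
  expect_equal(fit$slope, cfg0$va_slope, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("regrade perturbation is identity at zero jitter and unbiased otherwise", {
  set.seed(27)
  mask <- digital_disc_mask(25, 0.02)
  expect_identical(perturb_grading(mask, 0)$pixels, mask$pixels)
  areas <- replicate(50, mask_area(perturb_grading(mask, 0.3)))
  expect_gt(sd(areas), 0)
  expect_lt(abs(mean(areas) - mask_area(mask)), 3 * sd(areas) / sqrt(50))
})

test_that("cohort bundles round-trip through the file formats", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_eyes = 3, seed = 13)
  coh <- generate_cohort(cfg, dir = dir)
  d <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(nrow(d), 6)
  expect_equal(attr(d, "complete_pairs"), 3)
  # mask + sidecar reread reproduces the in-memory lattice
  got <- read_mask(file.path(dir, "P001_baseline_ga.png"),
                   file.path(dir, "P001_baseline_ga.json"))
  expect_identical(got$mask$pixels, coh$eyes[[1]]$mask_baseline$pixels)
  # EZ intervals reread match
  ez <- read_ez_intervals(file.path(dir, "P001_baseline_ez.csv"),
                          x_extent = cfg$image_px * cfg$scale)
  expect_equal(length(ez$scans), length(coh$eyes[[1]]$ez_baseline$scans))
  # same seed regenerates an identical ground-truth table
  dir2 <- withr::local_tempdir()
  generate_cohort(cfg, dir = dir2)
  expect_identical(readLines(file.path(dir, "ground_truth.csv")),
                   readLines(file.path(dir2, "ground_truth.csv")))
})

test_that("generated eyes are eligible and self-consistent with the pipeline", {
  coh <- cached_cohort(8, seed = 31)
  for (x in coh$eyes) {
    expect_true(x$mtii_baseline$eligible)
    # pipeline MTII at default supersampling vs ground truth at 16x
    mt8 <- compute_mtii(x$mask_baseline, x$meta_baseline,
                        supersample = 8, size_filter = FALSE)
    expect_lt(abs(mt8$mtii_1 - x$mtii_baseline$mtii_1), 1)
    expect_lt(abs(mt8$mtii_3 - x$mtii_baseline$mtii_3), 1)
    # intact EZ in the 1-mm disc cannot exceed intact tissue in the larger
    # 1.2-mm disc (the EZ-absent halo only removes coverage)
    expect_lte(x$ezii_baseline$ez_area_1, x$mtii_baseline$intact_1 + 0.05)
  }
})
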