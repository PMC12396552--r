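test_that("lesion extraction uses 8-connectivity", {
  m <- block_mask(50, 0.01, 5:14, 5:14)
  m$pixels[30:39, 30:39] <- TRUE
  expect_length(extract_lesions(m), 2)

  expect_length(extract_lesions(full_mask(20, 0.01, FALSE)), 0)

  # two blocks touching only at a corner join into one lesion
  diag_m <- block_mask(20, 0.01, 2:5, 2:5)
  diag_m$pixels[6:9, 6:9] <- TRUE
  expect_length(extract_lesions(diag_m), 1)
})

test_that("lesion areas and pixel sets are consistent", {
  m <- block_mask(40, 0.01, 3:12, 3:22)    # 10 x 20 block
  les <- extract_lesions(m)
  expect_length(les, 1)
  expect_equal(les[[1]]$area, 200 * 1e-4)
  expect_equal(nrow(les[[1]]$pixels), 200)
})

test_that("minimum Feret diameter matches known shapes and the brute-force oracle", {
  g <- make_grid(60, 0.001)    # 1 um/px would be odd; use 1 px = 1 um x1000
  # single pixel at 10 um/px
  m1 <- block_mask(10, 0.01, 5, 5)
  l1 <- extract_lesions(m1)[[1]]
  expect_equal(l1$min_feret, 10, tolerance = 1e-9)

  # axis-aligned 5 x 20 block at 10 um/px: short side 50 um
  m2 <- block_mask(40, 0.01, 10:14, 10:29)
  l2 <- extract_lesions(m2)[[1]]
  expect_equal(l2$min_feret, 50, tolerance = 1e-9)

  # digital disc of radius 20 px at 10 um/px: about 400 um across
  md <- digital_disc_mask(20, 0.01)
  ld <- extract_lesions(md)[[1]]
  expect_equal(ld$min_feret, 400, tolerance = 0.05)
  oracle <- brute_force_min_feret(ld$pixels, md$grid)
  expect_equal(ld$min_feret, oracle, tolerance = 1e-3)

  # random blobs against the rotating oracle: the sampled oracle can only
  # overestimate the true minimum, and only by its angular resolution
  set.seed(81)
  for (k in 1:5) {
    m <- random_mask(40, 0.01)
    for (l in extract_lesions(m)) {
      oracle <- brute_force_min_feret(l$pixels, m$grid, n_angles = 3600)
      expect_lte(l$min_feret, oracle + 1e-6)
      expect_equal(l$min_feret, oracle, tolerance = 0.02)
    }
  }
})

test_that("empty lesions are rejected by min_feret_diameter", {
  fake <- structure(list(pixels = matrix(integer(), ncol = 2),
                         area = 0, min_feret = NA_real_), class = "lesion")
  expect_error(min_feret_diameter(fake, make_grid(10)), "empty")
})

test_that("minimum-size filter applies the inclusive OR criteria", {
  mk <- function(area, feret) structure(
    list(pixels = matrix(c(1L, 1L), ncol = 2), area = area, min_feret = feret),
    class = "lesion")
  small_wide <- mk(0.05, 200)    # area boundary inclusive -> retained
  thin_long <- mk(0.03, 260)     # feret passes alone -> retained (OR)
  tiny <- mk(0.03, 200)          # fails both -> removed
  feret_boundary <- mk(0.01, 250)
  kept <- apply_lesion_size_filter(list(small_wide, thin_long, tiny,
                                        feret_boundary))
  expect_length(kept, 3)
  expect_identical(apply_lesion_size_filter(kept), kept)   # idempotent
  # conjunctive variant keeps only lesions passing both
  kept_and <- apply_lesion_size_filter(list(small_wide, thin_long, tiny),
                                       rule = "and")
  expect_length(kept_and, 0)
})

test_that("filtering never increases GA area", {
  set.seed(82)
  for (k in 1:5) {
    m <- random_mask(60, 0.01)
    les <- extract_lesions(m)
    kept <- apply_lesion_size_filter(les)
    expect_lte(sum(vapply(kept, function(l) l$area, numeric(1))),
               sum(vapply(les, function(l) l$area, numeric(1))) + 1e-12)
  }
})

test_that("MTII saturates at 100 for no GA and 0 for full GA", {
  meta <- sidecar_meta(0.01, 0.01, 249, 249)   # fovea centered in 5 mm field
  none <- full_mask(500, 0.01, FALSE)
  r0 <- compute_mtii(none, meta)
  expect_equal(r0$mtii_1, 100)
  expect_equal(r0$mtii_3, 100)
  expect_true(r0$eligible)

  all_ga <- full_mask(500, 0.01, TRUE)
  r1 <- compute_mtii(all_ga, meta, size_filter = FALSE)
  expect_lt(r1$mtii_1, 0.5)
  expect_lt(r1$mtii_3, 0.5)
  expect_false(r1$eligible)
  expect_equal(r1$ga_total, 25)    # whole 5 x 5 mm image
})

test_that("half-plane GA through the fovea halves both indices", {
  px <- 1200; s <- 0.005           # 6 mm field at 5 um/px
  meta <- sidecar_meta(s, s, px / 2, px / 2)
  fov <- fovea_point(meta)
  hp <- half_plane_mask(px, s, split_mm = fov$x)
  r <- compute_mtii(hp, meta, size_filter = FALSE)
  expect_equal(r$mtii_1, 50, tolerance = 0.01)   # relative tolerance: 0.5%
  expect_equal(r$mtii_3, 50, tolerance = 0.01)
})

test_that("MTII equals 100 minus the in-circle GA percentage", {
  set.seed(83)
  meta <- sidecar_meta(0.01, 0.01, 60, 60)
  fov <- fovea_point(meta)
  m <- random_mask(120, 0.01)
  r <- compute_mtii(m, meta, size_filter = FALSE)
  for (zone in 1:2) {
    d <- c(1.2, 3.6)[zone]
    ga_in <- mask_area_in_circle(m, circle_spec(fov, d), 8)
    expect_equal(c(r$mtii_1, r$mtii_3)[zone],
                 100 * (1 - ga_in / circle_area(d)), tolerance = 1e-9)
  }
})

test_that("MTII is monotone under mask nesting", {
  set.seed(84)
  meta <- sidecar_meta(0.01, 0.01, 60, 60)
  a <- random_mask(120, 0.01)
  bpix <- a$pixels
  bpix[matrix(runif(length(bpix)) < 0.15, nrow(bpix))] <- TRUE
  b <- binary_mask(bpix, a$grid)
  ra <- compute_mtii(a, meta, size_filter = FALSE)
  rb <- compute_mtii(b, meta, size_filter = FALSE)
  expect_gte(ra$mtii_1 + 1e-9, rb$mtii_1)
  expect_gte(ra$mtii_3 + 1e-9, rb$mtii_3)
})

test_that("eligibility is inclusive at the 0.05 mm^2 floor", {
  expect_true(check_eligibility(0.05))
  expect_false(check_eligibility(0.049))
  expect_true(check_eligibility(1.13))
})
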