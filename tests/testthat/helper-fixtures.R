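# Shared fixtures and independent oracles. Everything is built in code at
# test time; the oracles never call the code paths they check.

# --- mask builders -----------------------------------------------------------

make_grid <- function(px = 100L, scale = 0.01) grid_spec(px, px, scale, scale)

full_mask <- function(px = 100L, scale = 0.01, value = TRUE) {
  binary_mask(matrix(value, px, px), make_grid(px, scale))
}

# half-plane mask: true where the pixel center x is >= split_mm
half_plane_mask <- function(px, scale, split_mm) {
  centers <- (seq_len(px) - 0.5) * scale
  m <- matrix(rep(centers >= split_mm, each = px), px, px)
  binary_mask(m, make_grid(px, scale))
}

block_mask <- function(px, scale, rows, cols) {
  m <- matrix(FALSE, px, px)
  m[rows, cols] <- TRUE
  binary_mask(m, make_grid(px, scale))
}

# random blobby mask: a few rectangles plus salt noise
random_mask <- function(px = 100L, scale = 0.01) {
  m <- matrix(FALSE, px, px)
  for (b in seq_len(sample(1:4, 1))) {
    r <- sort(sample.int(px, 2)); c <- sort(sample.int(px, 2))
    m[r[1]:r[2], c[1]:c[2]] <- TRUE
  }
  m[matrix(runif(px * px) < 0.02, px, px)] <- TRUE
  binary_mask(m, make_grid(px, scale))
}

# --- independent oracles -----------------------------------------------------

# Monte-Carlo estimate of area(mask true pixels  intersect disc), sampling
# uniformly over the disc's bounding square. Returns estimate and its SE.
mc_mask_circle_area <- function(mask, circle, n = 1e6) {
  g <- mask$grid
  r <- circle$diameter / 2
  cx <- circle$center$x; cy <- circle$center$y
  xs <- runif(n, cx - r, cx + r)
  ys <- runif(n, cy - r, cy + r)
  in_disc <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  i <- floor(xs / g$scale_x); j <- floor(ys / g$scale_y)
  in_img <- i >= 0 & i < g$width_px & j >= 0 & j < g$height_px
  hit <- logical(n)
  sel <- in_disc & in_img
  hit[sel] <- mask$pixels[cbind(j[sel] + 1, i[sel] + 1)]
  p <- mean(hit)
  box <- (2 * r)^2
  list(area = box * p, se = box * sqrt(p * (1 - p) / n))
}

# Fine y-rasterization of an EZ map's disc intersection: strips of `step`
# height, each using the exact chord at its own midline y, intervals taken
# from the scan whose band covers that y.
raster_ez_circle_area <- function(map, circle, step = 0.005) {
  r <- circle$diameter / 2
  cx <- circle$center$x; cy <- circle$center$y
  ys <- vapply(map$scans, function(s) s$y, numeric(1))
  th <- vapply(map$scans, function(s) s$thickness, numeric(1))
  lo <- ys - th / 2; hi <- ys + th / 2
  yy <- seq(cy - r + step / 2, cy + r - step / 2, by = step)
  area <- 0
  for (y in yy) {
    k <- which(lo <= y & y < hi)
    if (length(k) == 0L) next
    iv <- map$scans[[k[1]]]$intervals
    if (nrow(iv) == 0L) next
    h <- sqrt(max(r^2 - (y - cy)^2, 0))
    ov <- pmin(iv[, 2], cx + h) - pmax(iv[, 1], cx - h)
    area <- area + sum(pmax(ov, 0)) * step
  }
  area
}

# Closed-form normal equations for simple OLS, independent of lm()
normal_equations_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  res <- y - a - b * x
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / sst
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  t <- b / se
  list(slope = b, intercept = a, r_squared = r2,
       p_value = 2 * pt(-abs(t), n - 2))
}

# Brute-force minimum Feret diameter: minimum over many rotations of the
# projected width of all pixel-rectangle corners.
brute_force_min_feret <- function(pixels, grid, n_angles = 360) {
  i <- pixels[, 2] - 1; j <- pixels[, 1] - 1
  sx <- grid$scale_x; sy <- grid$scale_y
  cx <- c(i * sx, (i + 1) * sx, i * sx, (i + 1) * sx)
  cy <- c(j * sy, j * sy, (j + 1) * sy, (j + 1) * sy)
  widths <- vapply(seq_len(n_angles), function(k) {
    a <- pi * (k - 1) / n_angles
    p <- cx * cos(a) + cy * sin(a)
    max(p) - min(p)
  }, numeric(1))
  min(widths) * 1000
}

# digital disc lesion mask (pixel centers within radius_px of the center)
digital_disc_mask <- function(radius_px, scale) {
  px <- as.integer(2 * radius_px + 9)
  ctr <- (px + 1) / 2
  idx <- expand.grid(r = seq_len(px), c = seq_len(px))
  m <- matrix((idx$r - ctr)^2 + (idx$c - ctr)^2 <= radius_px^2, px, px)
  binary_mask(m, make_grid(px, scale))
}

# --- cached synthetic cohorts (generated once per test run) ------------------

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n_eyes, seed, with_ez = TRUE) {
  key <- paste0("n", n_eyes, "_s", seed, "_ez", with_ez)
  if (is.null(.cohort_cache[[key]])) {
    cfg <- sim_config(n_eyes = n_eyes, seed = seed)
    .cohort_cache[[key]] <- generate_cohort(cfg, with_ez = with_ez)
  }
  .cohort_cache[[key]]
}
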