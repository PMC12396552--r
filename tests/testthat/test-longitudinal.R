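faf_visit <- function(id, ga, i1, i3, x1 = 50, x3 = 50, mod = "FAF") {
  visit_result(id, mod, ga = ga, intact_1 = i1, intact_3 = i3,
               index_1 = x1, index_3 = x3)
}

test_that("change arithmetic reproduces the published cohort means", {
  # FAF block: GA 8.87 -> 10.77, intact 1 mm 0.57 -> 0.45
  bl <- faf_visit("P1", ga = 8.87, i1 = 0.57, i3 = 4.86)
  y1 <- faf_visit("P1", ga = 10.77, i1 = 0.45, i3 = 4.03)
  ch <- compute_change(bl, y1)
  expect_equal(ch$ga_growth, 1.90, tolerance = 1e-9)
  expect_equal(ch$intact_loss_1, 0.12, tolerance = 1e-9)
  expect_equal(ch$intact_loss_3, 0.83, tolerance = 1e-9)

  # OCT block: GA 9.40 -> 11.02, intact EZ 3 mm 2.68 -> 2.08
  blo <- faf_visit("P1", ga = 9.40, i1 = 0.33, i3 = 2.68, mod = "OCT")
  y1o <- faf_visit("P1", ga = 11.02, i1 = 0.27, i3 = 2.08, mod = "OCT")
  cho <- compute_change(blo, y1o)
  expect_equal(cho$ga_growth, 1.62, tolerance = 1e-9)
  expect_equal(cho$intact_loss_3, 0.60, tolerance = 1e-9)
})

test_that("identical visits give zero change; swapping visits negates rates", {
  v <- faf_visit("P2", ga = 5, i1 = 0.4, i3 = 3)
  z <- compute_change(v, v)
  expect_equal(z$ga_growth, 0)
  expect_equal(z$intact_loss_1, 0)

  a <- faf_visit("P3", ga = 4, i1 = 0.5, i3 = 3.5, x1 = 60, x3 = 55)
  b <- faf_visit("P3", ga = 6, i1 = 0.3, i3 = 2.9, x1 = 40, x3 = 45)
  fw <- compute_change(a, b)
  bw <- compute_change(b, a)
  for (f in c("ga_growth", "intact_loss_1", "intact_loss_3",
              "index_change_1", "index_change_3"))
    expect_equal(fw[[f]], -bw[[f]])
})

test_that("interval scaling and input validation work", {
  a <- faf_visit("P4", ga = 4, i1 = 0.5, i3 = 3.5)
  b <- faf_visit("P4", ga = 5, i1 = 0.4, i3 = 3.0)
  expect_equal(compute_change(a, b, interval_years = 2)$ga_growth, 0.5)
  expect_error(compute_change(a, b, interval_years = 0), "interval_years")
  other <- faf_visit("P5", ga = 5, i1 = 0.4, i3 = 3.0)
  expect_error(compute_change(a, other), "participant mismatch")
})

test_that("Loser stratification is a step function with the boundary going slow", {
  expect_equal(classify_loser(0.10, "z1mm", "FAF")$label, "SlowLoser")
  expect_equal(classify_loser(0.11, "z1mm", "FAF")$label, "RapidLoser")
  expect_equal(classify_loser(0.75, "z3mm", "FAF")$label, "SlowLoser")
  expect_equal(classify_loser(0.76, "z3mm", "FAF")$label, "RapidLoser")
  expect_equal(classify_loser(0.04, "z1mm", "OCT")$label, "SlowLoser")
  expect_equal(classify_loser(0.49, "z3mm", "OCT")$label, "SlowLoser")
  expect_equal(classify_loser(0.50, "z3mm", "OCT")$label, "RapidLoser")
  expect_error(classify_loser(0.1, "z2mm", "FAF"))

  # monotone step: sweeping the rate crosses the label exactly once
  rates <- seq(0, 0.3, by = 0.005)
  labels <- vapply(rates, function(r) classify_loser(r, "z1mm", "FAF")$label,
                   character(1))
  expect_equal(sum(labels[-1] != labels[-length(labels)]), 1)
  expect_equal(labels[rates <= 0.1][1], "SlowLoser")
})

test_that("quadrant labels cover each eye exactly once", {
  growth <- c(0.5, 1.2, 2.5, 3.1, 1.9)
  loss <- c(0.05, 0.2, 0.08, 0.3, 0.1)
  labs <- mapply(function(g, l)
    classify_quadrant(g, l, growth, zone = "z1mm", modality = "FAF")$label,
    growth, loss)
  expect_true(all(labs %in% c("RapidGrowerSlowLoser", "RapidGrowerRapidLoser",
                              "SlowGrowerSlowLoser", "SlowGrowerRapidLoser")))
  counts <- table(factor(labs, levels = c("RapidGrowerSlowLoser",
                                          "RapidGrowerRapidLoser",
                                          "SlowGrowerSlowLoser",
                                          "SlowGrowerRapidLoser")))
  expect_equal(sum(counts), length(growth))

  # definition checks around the cohort median (1.9)
  expect_equal(classify_quadrant(3.0, 0.05, growth)$label,
               "RapidGrowerSlowLoser")
  expect_equal(classify_quadrant(1.0, 0.30, growth)$label,
               "SlowGrowerRapidLoser")
  # an eye at the median is a Slow Grower (tie goes slow)
  expect_equal(classify_quadrant(1.9, 0.05, growth)$label,
               "SlowGrowerSlowLoser")
  # identical cohort: everyone sits at the median, all Slow Growers
  same <- rep(2.0, 6)
  labs2 <- vapply(same, function(g)
    classify_quadrant(g, 0.05, same)$label, character(1))
  expect_true(all(grepl("^SlowGrower", labs2)))
  expect_error(classify_quadrant(1, 0.1, numeric(0)), "non-empty")
})

test_that("change_table produces one consistent row per eye", {
  bl <- list(faf_visit("A", 5, 0.5, 3.5), faf_visit("B", 8, 0.3, 2.5))
  y1 <- list(faf_visit("A", 6, 0.4, 3.0), faf_visit("B", 10.5, 0.1, 1.5))
  tab <- change_table(bl, y1)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$ga_growth, c(1, 2.5))
  expect_equal(tab$intact_loss_1, c(0.1, 0.2), tolerance = 1e-9)
})
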