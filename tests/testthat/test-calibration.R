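lh_grid <- c(0, 5, 10, 20, 30, 40, 50)
pdg_grid <- c(0, 2.5, 5, 7.5, 10, 15)

test_that("noise-free curve fits recover planted parameters exactly", {
  sc <- fit_standard_curve(lh_grid, 0.005 * lh_grid + 0.05, form = "linear",
                           hormone = "LH")
  expect_equal(unname(coef(sc)["m"]), 0.005, tolerance = 1e-12)
  expect_equal(unname(coef(sc)["b"]), 0.05, tolerance = 1e-12)
  expect_equal(sc$r_value, 1.0, tolerance = 1e-12)

  conc <- c(0, 2.5, 5, 7.5, 10, 15)
  sce <- fit_standard_curve(conc, 0.4 * exp(-0.2 * conc),
                            form = "exponential", hormone = "PdG")
  expect_equal(unname(coef(sce)["A"]), 0.4, tolerance = 1e-10)
  expect_equal(unname(coef(sce)["k"]), 0.2, tolerance = 1e-10)
  expect_equal(abs(sce$r_value), 1.0, tolerance = 1e-12)
  expect_lt(sce$r_value, 0)  # competitive format: signed r is negative
})

test_that("fit r_value matches an independently coded Pearson correlation", {
  set.seed(301)
  pearson <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  conc <- rep(lh_grid, each = 3)
  int_lin <- (0.005 * conc + 0.05) * exp(rnorm(length(conc), 0, 0.05))
  sc <- fit_standard_curve(conc, int_lin, form = "linear")
  expect_equal(sc$r_value, pearson(conc, int_lin), tolerance = 1e-12)

  conc2 <- rep(pdg_grid, each = 3)
  int_exp <- 0.4 * exp(-0.2 * conc2) * exp(rnorm(length(conc2), 0, 0.05))
  sce <- fit_standard_curve(conc2, int_exp, form = "exponential")
  expect_equal(sce$r_value, pearson(conc2, log(int_exp)), tolerance = 1e-12)
})

test_that("fit rejects degenerate panels and non-positive intensities", {
  expect_error(fit_standard_curve(c(0, 0, 5, 5), c(1, 1, 2, 2)),
               "degenerate panel")
  expect_error(fit_standard_curve(c(0, 5, 10), c(0.4, 0, 0.1),
                                  form = "exponential"),
               "non-positive intensity")
})

test_that("invert_curve is exact arithmetic and the inverse of predict", {
  lin <- fit_standard_curve(lh_grid, 0.005 * lh_grid + 0.05, form = "linear")
  expect_equal(invert_curve(lin, 0.175), 25, tolerance = 1e-9)

  conc <- c(0, 2.5, 5, 7.5, 10, 15)
  ex <- fit_standard_curve(conc, 0.4 * exp(-0.2 * conc),
                           form = "exponential")
  expect_equal(invert_curve(ex, 0.4), 0, tolerance = 1e-9)
  expect_equal(invert_curve(ex, predict(ex, 7.5)), 7.5, tolerance = 1e-9)
  # round trip across whole grids, both forms
  expect_equal(invert_curve(lin, predict(lin, lh_grid)), lh_grid,
               tolerance = 1e-9)
  expect_equal(invert_curve(ex, predict(ex, conc)), conc, tolerance = 1e-9)
  # clamped at zero, never negative
  expect_identical(invert_curve(ex, 0.5), 0)
  expect_error(invert_curve(ex, 0), "undefined inverse")
})

test_that("exponential curves decrease and sandwich curves increase", {
  conc <- seq(0, 15, by = 0.5)
  ex <- fit_standard_curve(pdg_grid, 0.4 * exp(-0.2 * pdg_grid),
                           form = "exponential")
  expect_true(all(diff(predict(ex, conc)) < 0))
  lin <- fit_standard_curve(lh_grid, 0.005 * lh_grid + 0.05, form = "linear")
  expect_true(all(diff(predict(lin, conc)) > 0))
})

test_that("percent CV matches the hand formula and is scale invariant", {
  expect_identical(percent_cv(c(0.2, 0.2, 0.2)), 0)
  expect_equal(percent_cv(c(9, 10, 11)), 10, tolerance = 1e-12)
  set.seed(17)
  for (i in 1:20) {
    x <- runif(sample(2:12, 1), 0.5, 2)
    a <- runif(1, 0.1, 50)
    expect_equal(percent_cv(a * x), percent_cv(x), tolerance = 1e-9)
  }
  expect_error(percent_cv(c(1, -3)), "mean must be positive")
  expect_error(percent_cv(0.2), "at least 2")
})

test_that("3-SD acceptance bounds and pass rates behave as specified", {
  # mean 0.10, SD 0.01 by construction
  x <- c(0.09, 0.10, 0.11)
  expect_equal(acceptance_bound(x, "at_most")$bound, 0.13, tolerance = 1e-12)
  expect_equal(acceptance_bound(x, "at_least")$bound, 0.07, tolerance = 1e-12)
  # constant data: bound equals the constant either direction, and only
  # exactly that constant passes
  const <- rep(0.2, 5)
  for (dir in c("at_least", "at_most")) {
    b <- acceptance_bound(const, dir)
    expect_equal(b$bound, 0.2)
    expect_true(pass_rate(const, b)$pass)
  }

  b <- acceptance_bound(x, "at_most")
  vals98 <- c(rep(0.10, 98), 0.20, 0.20)
  pr <- pass_rate(vals98, b)
  expect_equal(pr$proportion, 0.98)
  expect_true(pr$pass)
  vals89 <- c(rep(0.10, 89), rep(0.20, 11))
  pr <- pass_rate(vals89, b)
  expect_equal(pr$proportion, 0.89)
  expect_false(pr$pass)
  # inclusive on the bound itself
  pr <- pass_rate(rep(b$bound, 10), b)
  expect_equal(pr$proportion, 1)
  expect_true(pr$pass)
  # permutation invariance
  set.seed(5)
  v <- runif(50, 0.05, 0.2)
  expect_equal(pass_rate(v, b)$proportion,
               pass_rate(sample(v), b)$proportion)
})

test_that("QC gate report passes clean panels and flags a noisy day", {
  clean <- simulate_qc_panels(noise_cv = 0, seed = 1)
  rep0 <- qc_gate_report(clean)
  expect_true(all(rep0$cv_by_day$cv == 0))
  expect_true(all(rep0$cv_pooled$cv == 0))
  expect_true(all(rep0$r_fraction == 1))
  expect_true(rep0$pass)
  # gate thresholds echoed in the report
  expect_equal(rep0$cv_limit, 10)
  expect_equal(rep0$r_limit, 0.9)
  expect_equal(rep0$r_fraction_required, 0.90)

  low <- simulate_qc_panels(noise_cv = 0.03, seed = 2)
  repl <- qc_gate_report(low)
  expect_true(repl$cv_gate)
  expect_true(repl$pass)

  # inject 20% noise into day 2 of the LH panels only
  noisy <- low
  sel <- noisy$hormone == "LH" & noisy$day == 2
  set.seed(3)
  mu <- 0.005 * noisy$concentration[sel] + 0.05
  noisy$intensity[sel] <- mu * exp(rnorm(sum(sel), 0, sqrt(log(1 + 0.2^2))))
  repn <- qc_gate_report(noisy)
  flagged <- repn$cv_by_day[repn$cv_by_day$hormone == "LH" &
                              repn$cv_by_day$day == 2, ]
  expect_gt(max(flagged$cv), 10)
  expect_false(repn$cv_gate)
  expect_false(repn$pass)

  expect_error(qc_gate_report(low[, setdiff(names(low), "lot")]),
               "missing columns")
})
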