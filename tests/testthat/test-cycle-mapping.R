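th <- cycle_thresholds()

test_that("E1G rise needs both the absolute level and the baseline ratio", {
  r <- rec(days = c(5, 10, 11), e1g = c(50, 120, 190))
  expect_equal(detect_e1g_rise(r, th), 11)
  # flat E1G: no rise is a valid outcome
  expect_true(is.na(detect_e1g_rise(rec(1:10, e1g = rep(60, 10)), th)))
  # 180 clears 175 but not 1.5 x baseline 150; 240 clears both
  r2 <- rec(days = c(5, 9, 10), e1g = c(150, 180, 240))
  expect_equal(detect_e1g_rise(r2, th), 10)
})

test_that("LH surge episodes are maximal runs strictly above threshold", {
  r <- rec(days = 10:14, lh = c(5, 8, 30, 40, 12))
  s <- detect_lh_surges(r, th)
  expect_equal(s$peak_day, 12)
  expect_equal(s$episode_count, 1L)
  expect_equal(s$episodes[[1]], c(12L, 13L))
  # exactly 25 is not a surge
  expect_true(is.na(detect_lh_surges(rec(10, lh = 25), th)$peak_day))
  expect_equal(detect_lh_surges(rec(10, lh = 25.01), th)$peak_day, 10)
  # three separated super-threshold runs
  r3 <- rec(days = 10:18, lh = c(30, 5, 28, 26, 6, 7, 40, 5, 5))
  s3 <- detect_lh_surges(r3, th)
  expect_equal(s3$episode_count, 3L)
  expect_equal(s3$peak_day, 10)
  # an unmeasured day does not split an episode
  r4 <- rec(days = c(10, 12), lh = c(30, 28))
  expect_equal(detect_lh_surges(r4, th)$episode_count, 1L)
})

test_that("PdG rise is inclusive at the confirmation threshold", {
  r <- rec(days = 14:17, pdg = c(0.8, 0.9, 2.6, 6.1))
  expect_equal(detect_pdg_rise(r, th, after = 14), 16)
  expect_equal(detect_pdg_rise(rec(10, pdg = 2.5), th), 10)
  expect_true(is.na(detect_pdg_rise(rec(10, pdg = 2.49), th)))
  # never confirmed across a long tracked series
  long <- rec(days = 1:51, pdg = runif(51, 0.3, 1.2))
  expect_true(is.na(detect_pdg_rise(long, th)))
  # `after` anchors the search
  r2 <- rec(days = 10:14, pdg = c(2.6, 0.9, 0.8, 2.7, 5))
  expect_equal(detect_pdg_rise(r2, th, after = 12), 13)
})

test_that("worked-example cycles map to 1-, 11- and surge-opened 1-day windows", {
  m1 <- map_cycle(fixture_same_day_rise(), th)
  expect_equal(m1$e1g_rise_day, 12)
  expect_equal(m1$lh_peak_day, 12)
  expect_equal(m1$pdg_rise_day, 13)
  expect_equal(m1$fertile_window_days, 1L)
  expect_equal(m1$e1g_to_lh_days, 0L)
  expect_equal(m1$lh_to_pdg_days, 1L)

  m2 <- map_cycle(fixture_11_day_window(), th)
  expect_equal(m2$fertile_window_days, 11L)
  expect_equal(m2$e1g_to_lh_days, 7L)
  expect_equal(m2$lh_to_pdg_days, 4L)

  m3 <- map_cycle(fixture_no_e1g_rise(), th)
  expect_true(is.na(m3$e1g_rise_day))
  expect_equal(m3$lh_peak_day, 14)
  expect_equal(m3$fertile_window_days, 1L)  # window opens at the LH peak
  expect_true(is.na(m3$e1g_to_lh_days))
})

test_that("map_cycle fills implantation window, pre-ovulatory PdG and FSH", {
  m <- map_cycle(fixture_full_cycle(), th)
  expect_equal(m$lh_peak_day, 13)
  expect_equal(unname(m$implantation_pdg), c(8.0, 7.5, 7.0, 6.5))
  expect_equal(names(m$implantation_pdg), c("7", "8", "9", "10"))
  expect_equal(m$high_pdg_day_count, 4L)
  expect_equal(m$classification, "successful_ovulation")
  expect_equal(m$ovulation_score, 100L)
  # measured PdG strictly before the peak day: days 9..12
  expect_equal(m$pre_ovulatory_pdg_mean, mean(c(0.7, 0.8, 0.8, 0.9)))
  expect_equal(m$fsh_status, "normal")
  expect_equal(m$fsh_max, 8)
  expect_equal(m$fsh_max_day, 7)
})

test_that("classification follows the implantation-window rules", {
  base <- map_cycle(fixture_full_cycle(), th)
  with_impl <- function(v) {
    m <- base
    m$implantation_pdg[] <- v
    m
  }
  expect_equal(classify_ovulatory_function(with_impl(c(8, 9, 7, 6)), th),
               "successful_ovulation")
  expect_equal(classify_ovulatory_function(with_impl(c(6, 6, 3, 2)), th),
               "ovulatory_dysfunction")
  # fewer than 3 observed offsets -> indeterminate, never imputed
  expect_equal(classify_ovulatory_function(with_impl(c(8, 9, NA, NA)), th),
               "indeterminate")
  # 3 observed with 2 high / 1 low satisfies neither rule
  expect_equal(classify_ovulatory_function(with_impl(c(8, 9, 3, NA)), th),
               "indeterminate")
  # no PdG rise anywhere -> anovulatory regardless of the window
  anov <- base
  anov$pdg_rise_day <- NA_integer_
  expect_equal(classify_ovulatory_function(anov, th), "anovulatory")
})

test_that("ovulation score endpoints and intermediate bands", {
  expect_equal(ovulation_score(c(8, 9, 7, 6), th), 100L)
  expect_equal(ovulation_score(c(1, 2, 1, 1), th), 10L)
  expect_equal(ovulation_score(c(6, 6, 6, 3), th), 80L)  # 70 + 10 (mean 5.25)
  expect_equal(ovulation_score(c(6, 1, 1, 1), th), 20L)  # 30 - 10 (mean 2.25)
  expect_equal(ovulation_score(c(6, 6, 1, 1), th), 50L)  # base 50, mean 3.5
  # exactly 5 counts as sustained (inclusive), but the mean 4.975 < 5
  # earns no bonus: base 70
  expect_equal(ovulation_score(c(5, 5, 5, 4.9), th), 70L)
  expect_true(is.na(ovulation_score(c(8, 9, NA, NA), th)))
  expect_equal(ovulation_score(c(8, 9, 7, NA), th), 80L)  # 3 of 4 observed
})

test_that("raising PdG never decreases the score; raising LH never delays the peak", {
  set.seed(99)
  for (i in 1:60) {
    v <- runif(4, 0.5, 9)
    s0 <- ovulation_score(v, th)
    j <- sample(4, 1)
    v[j] <- v[j] + runif(1, 0, 6)
    expect_gte(ovulation_score(v, th), s0)
  }
  for (i in 1:40) {
    lh <- runif(8, 5, 40)
    r0 <- rec(10:17, lh = lh)
    p0 <- detect_lh_surges(r0, th)$peak_day
    j <- sample(8, 1)
    lh[j] <- lh[j] + runif(1, 0, 30)
    p1 <- detect_lh_surges(rec(10:17, lh = lh), th)$peak_day
    if (!is.na(p0)) expect_lte(p1, p0)
  }
})

test_that("detectors agree with a brute-force day scan on simulated cycles", {
  kinds <- c("normal", "luteal_deficient", "anovulatory_with_surge",
             "multi_surge", "no_e1g_rise")
  for (i in seq_along(kinds)) {
    for (seed in c(11, 23, 47)) {
      spec <- phenotype_spec(kinds[i], gap_e1g_to_lh = (seed + i) %% 8,
                             gap_lh_to_pdg = (seed + 2 * i) %% 8)
      r <- simulate_cycle(spec, seed = seed)$record
      expect_equal(detect_e1g_rise(r, th), oracle_e1g_rise(r, th))
      s <- detect_lh_surges(r, th)
      eps <- oracle_lh_episodes(r, th)
      expect_equal(s$episodes, eps)
      peak <- if (length(eps)) eps[[1]][1] else NA_integer_
      expect_equal(s$peak_day, peak)
      expect_equal(detect_pdg_rise(r, th, after = peak),
                   oracle_pdg_rise(r, th, after = peak))
    }
  }
})

test_that("window additivity holds whenever all three events exist", {
  set.seed(8)
  for (i in 1:50) {
    spec <- phenotype_spec(sample(c("normal", "luteal_deficient"), 1),
                           gap_e1g_to_lh = sample(0:7, 1),
                           gap_lh_to_pdg = sample(0:7, 1))
    m <- map_cycle(simulate_cycle(spec, seed = i)$record, th)
    if (!is.na(m$e1g_rise_day) && !is.na(m$lh_peak_day) &&
        !is.na(m$pdg_rise_day))
      expect_equal(m$fertile_window_days,
                   m$e1g_to_lh_days + m$lh_to_pdg_days)
    # every cycle gets exactly one classification
    expect_true(m$classification %in%
                  c("successful_ovulation", "ovulatory_dysfunction",
                    "anovulatory", "indeterminate"))
    expect_equal(is.na(m$pdg_rise_day), m$classification == "anovulatory")
  }
})

test_that("FSH screen is strict at the threshold and reports the max day", {
  r <- rec(days = c(5, 7, 9), fsh = c(6, 8, 7))
  f <- fsh_screen(r, th)
  expect_equal(f$status, "normal")
  expect_equal(f$fsh_max, 8)
  expect_equal(f$max_day, 7)
  expect_equal(fsh_screen(rec(c(5, 7, 9), fsh = c(6, 12, 9)), th)$status,
               "elevated")
  expect_equal(fsh_screen(rec(c(5, 7, 9), fsh = c(6, 12, 9)), th)$max_day, 7)
  expect_equal(fsh_screen(rec(5, fsh = 10), th)$status, "normal")
  expect_equal(fsh_screen(rec(5, e1g = 50), th)$status, "not_tested")
})

test_that("the directed testing schedule follows cycle length and peak day", {
  s <- testing_schedule(28)
  expect_equal(s$baseline_day, 5L)
  expect_equal(s$fsh_days, c(5L, 7L, 9L))
  expect_equal(s$predicted_ovulation_day, 14L)
  expect_equal(s$mh_start_day, 9L)
  expect_equal(s$implantation_days(17), c(24L, 25L, 26L, 27L))
  expect_equal(testing_schedule(35)$fsh_days, c(5L, 7L, 9L))
  expect_error(testing_schedule(20), "below 21")
})

test_that("grid search recovers each classifier threshold", {
  grid <- (1:4000) / 100  # 0.01-step grid with exactly representable 2.5/5/10/25
  lh_surge <- vapply(grid, function(v)
    !is.na(detect_lh_surges(rec(10, lh = v), th)$peak_day), logical(1))
  expect_equal(max(grid[!lh_surge]), 25, tolerance = 1e-9)

  pdg_conf <- vapply(grid, function(v)
    !is.na(detect_pdg_rise(rec(10, pdg = v), th)), logical(1))
  expect_equal(min(grid[pdg_conf]), 2.5, tolerance = 1e-9)

  sustain <- vapply(grid, function(v)
    ovulation_score(c(v, 1, 1, 1), th) > 10L, logical(1))
  expect_equal(min(grid[sustain]), 5, tolerance = 1e-9)

  fsh_elev <- vapply(grid, function(v)
    fsh_screen(rec(5, fsh = v), th)$status == "elevated", logical(1))
  expect_equal(max(grid[!fsh_elev]), 10, tolerance = 1e-9)
})

test_that("record validation rejects malformed input", {
  expect_error(cycle_record("s", c(3, 3), e1g = c(1, 2)), "duplicated")
  expect_error(cycle_record("s", 0, e1g = 1), ">= 1")
  expect_error(cycle_record("s", 3, e1g = -1), "negative")
  expect_error(cycle_record("s", 1:2), "no hormone measured")
  expect_error(map_cycle(data.frame(x = 1)), "cycle_record")
})
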