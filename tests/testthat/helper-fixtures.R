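# in-code fixtures shared across test files

# single-subject record builder with positional hormone vectors
rec <- function(days, e1g = NA_real_, lh = NA_real_, pdg = NA_real_,
                fsh = NA_real_, id = "t") {
  cycle_record(id, days, e1g = e1g, lh = lh, pdg = pdg, fsh = fsh)
}

# the two shortest-window archetypes and the longest-window archetype
fixture_same_day_rise <- function() {
  # E1G rise and LH surge both on day 12, PdG rise on day 13
  rec(days = c(5, 10, 11, 12, 13),
      e1g = c(50, 120, 150, 230, 210),
      lh  = c(4, 6, 9, 30, 12),
      pdg = c(0.7, 0.8, 0.9, 1.0, 2.6))
}

fixture_11_day_window <- function() {
  # E1G rise day 8, LH surge day 15 (gap 7), PdG rise day 19 (gap 4)
  days <- c(5, 6:19)
  e1g <- c(50, 80, 90, 200, 230, 240, 230, 220, 210, 200, 250, 200, 150,
           120, 100)
  lh <- c(4, 5, 5, 6, 6, 7, 8, 9, 10, 12, 40, 15, 9, 7, 6)
  pdg <- c(0.7, 0.8, 0.8, 0.7, 0.9, 0.8, 0.8, 0.9, 1.0, 1.1, 1.2, 1.4, 1.8,
           2.2, 2.8)
  rec(days, e1g, lh, pdg)
}

fixture_no_e1g_rise <- function() {
  # E1G flat below threshold; LH surge day 14; PdG rise day 15
  rec(days = c(5, 11, 12, 13, 14, 15),
      e1g = c(55, 60, 62, 58, 61, 60),
      lh  = c(4, 6, 8, 10, 30, 11),
      pdg = c(0.7, 0.8, 0.8, 0.9, 1.0, 3.0))
}

# a fully-observed successful cycle incl. implantation window, for reports
fixture_full_cycle <- function() {
  days <- c(5, 7, 9, 9:17, 20, 21, 22, 23)
  days <- sort(unique(days))
  n <- length(days)
  e1g <- lh <- pdg <- fsh <- rep(NA_real_, n)
  fsh[match(c(5, 7, 9), days)] <- c(6, 8, 7)
  mh <- days >= 9 & days <= 17 | days >= 20
  e1g[match(5, days)] <- 50
  e1g[mh] <- c(100, 120, 140, 230, 250, 240, 200, 160, 140, 120, 110, 100, 90)
  lh[mh] <- c(5, 6, 8, 10, 35, 30, 12, 9, 7, 6, 5, 5, 5)
  pdg[mh] <- c(0.7, 0.8, 0.8, 0.9, 1.0, 1.2, 2.8, 4.5, 6.0, 8.0, 7.5, 7.0,
               6.5)
  cycle_record("full", days, e1g = e1g, lh = lh, pdg = pdg, fsh = fsh)
}

# independent brute-force event scans (kept deliberately naive; they re-read
# the rules from scratch rather than reusing any detector code)
oracle_e1g_rise <- function(r, th = cycle_thresholds()) {
  base <- NA_real_
  for (i in seq_len(nrow(r))) {
    v <- r$e1g[i]
    if (is.na(v)) next
    if (is.na(base)) base <- v
    if (v >= th$e1g_abs && v >= th$e1g_baseline_ratio * base)
      return(r$cycle_day[i])
  }
  NA_integer_
}

oracle_lh_episodes <- function(r, th = cycle_thresholds()) {
  eps <- list()
  cur <- integer()
  for (i in seq_len(nrow(r))) {
    v <- r$lh[i]
    if (is.na(v)) next
    if (v > th$lh_surge) cur <- c(cur, r$cycle_day[i])
    else if (length(cur)) { eps[[length(eps) + 1L]] <- cur; cur <- integer() }
  }
  if (length(cur)) eps[[length(eps) + 1L]] <- cur
  eps
}

oracle_pdg_rise <- function(r, th = cycle_thresholds(), after = NA) {
  for (i in seq_len(nrow(r))) {
    v <- r$pdg[i]
    if (is.na(v)) next
    if (!is.na(after) && r$cycle_day[i] < after) next
    if (v >= th$pdg_confirm) return(r$cycle_day[i])
  }
  NA_integer_
}

# a minimal stand-in cycle_map for statistics tests that only need the
# summarised scalar fields
fake_map <- function(window, classification = "successful_ovulation",
                     score = NA_integer_, gap1 = NA_integer_,
                     gap2 = NA_integer_, high = NA_integer_,
                     fsh_status = "normal") {
  structure(list(subject_id = "fake", e1g_rise_day = NA_integer_,
                 lh_peak_day = NA_integer_, surge_episode_count = 1L,
                 surge_episodes = list(), pdg_rise_day = 1L,
                 fertile_window_days = window, e1g_to_lh_days = gap1,
                 lh_to_pdg_days = gap2,
                 implantation_pdg = rep(NA_real_, 4),
                 high_pdg_day_count = high,
                 classification = classification,
                 ovulation_score = score, fsh_status = fsh_status,
                 fsh_max = NA_real_, fsh_max_day = NA_integer_,
                 pre_ovulatory_pdg_mean = NA_real_,
                 treatment = NA_character_, diagnosis = NA_character_),
            class = "cycle_map")
}
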