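#' Run code under a private, restorable RNG state
#'
#' All simulator entry points take an explicit seed and leave the caller's
#' RNG stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# multiplicative log-normal noise with E[out] = mu and CV = cv
lnoise <- function(mu, cv) {
  if (cv <= 0) return(mu)
  sdlog <- sqrt(log(1 + cv^2))
  mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Phenotype specification for the cycle simulator
#'
#' Describes one synthetic cycle archetype.  Supported kinds:
#' \describe{
#'   \item{`"normal"`}{E1G rise, single 2-day LH surge, PdG confirmation and
#'     a sustained luteal plateau (successful ovulation).}
#'   \item{`"luteal_deficient"`}{ovulation confirmed (PdG reaches the
#'     2.5 ug/mL confirmation level) but the luteal plateau stays below the
#'     5 ug/mL sustain level (ovulatory dysfunction).}
#'   \item{`"anovulatory_with_surge"`}{an LH surge occurs but PdG never
#'     reaches the confirmation level.}
#'   \item{`"multi_surge"`}{three separated LH surge episodes with no PdG
#'     rise (the PCOS-like pattern).}
#'   \item{`"no_e1g_rise"`}{ovulatory, but E1G never reaches the rise
#'     criterion; the fertile window opens at the LH peak.}
#' }
#'
#' The planted LH peak falls on the schedule's predicted ovulation day
#' (cycle length - 14); the E1G rise precedes it by `gap_e1g_to_lh` days and
#' the PdG rise follows it by `gap_lh_to_pdg` days.  Hormone trajectories are
#' piecewise phase templates with multiplicative log-normal noise at
#' `noise_cv`; template margins around every decision threshold are wide
#' enough that, at the default 5% assay CV, the rule engine recovers the
#' planted event days in essentially every simulated cycle.
#'
#' @param kind phenotype, see above.
#' @param cycle_length cycle length in days (default 28; must leave the
#'   planted E1G rise after the day-5 baseline test).
#' @param e1g_baseline early-cycle E1G, ng/mL (default 50; must stay clear of
#'   the rise criterion).
#' @param e1g_peakmult peak E1G as a multiple of baseline (default 5).
#' @param lh_base non-surge LH, mIU/mL (default 5).
#' @param lh_surge_height surge-day LH, mIU/mL (default 45; must clear the
#'   25 mIU/mL surge threshold with noise margin).
#' @param pdg_base pre-ovulatory PdG, ug/mL (default 0.81, the cohort mean).
#' @param pdg_plateau luteal PdG plateau, ug/mL; default 8 for `"normal"`,
#'   4 for `"luteal_deficient"`, ignored for anovulatory kinds.
#' @param fsh_levels FSH on days 5/7/9, mIU/mL (default `c(6, 8, 7)`).
#' @param gap_e1g_to_lh days from E1G rise to LH peak, 0-7 (default 3).
#' @param gap_lh_to_pdg days from LH peak to PdG rise, 0-7 (default 3).
#' @param noise_cv assay coefficient of variation as a proportion
#'   (default 0.05).
#' @return An object of class `phenotype_spec` (named list).
#' @export
phenotype_spec <- function(kind = c("normal", "luteal_deficient",
                                    "anovulatory_with_surge", "multi_surge",
                                    "no_e1g_rise"),
                           cycle_length = 28,
                           e1g_baseline = 50,
                           e1g_peakmult = 5,
                           lh_base = 5,
                           lh_surge_height = 45,
                           pdg_base = 0.81,
                           pdg_plateau = NULL,
                           fsh_levels = c(6, 8, 7),
                           gap_e1g_to_lh = 3,
                           gap_lh_to_pdg = 3,
                           noise_cv = 0.05) {
  kind <- match.arg(kind)
  ovulatory <- kind %in% c("normal", "luteal_deficient", "no_e1g_rise")
  if (is.null(pdg_plateau))
    pdg_plateau <- switch(kind, normal = 8, no_e1g_rise = 8,
                          luteal_deficient = 4, pdg_base)
  if (gap_e1g_to_lh < 0 || gap_e1g_to_lh > 7 ||
      gap_lh_to_pdg < 0 || gap_lh_to_pdg > 7)
    stop("config error: gaps must lie in 0-7 days", call. = FALSE)
  if (lh_surge_height <= 25)
    stop("config error: lh_surge_height must exceed the 25 mIU/mL surge threshold",
         call. = FALSE)
  if (kind %in% c("normal", "no_e1g_rise") && pdg_plateau < 5)
    stop("config error: ", kind,
         " phenotype needs pdg_plateau at or above the 5 ug/mL sustain level",
         call. = FALSE)
  if (kind == "luteal_deficient" && (pdg_plateau < 2.5 || pdg_plateau >= 5))
    stop("config error: luteal_deficient needs pdg_plateau in [2.5, 5)",
         call. = FALSE)
  if (pdg_base >= 2.5)
    stop("config error: pdg_base must sit below the 2.5 ug/mL confirmation level",
         call. = FALSE)
  peak_day <- as.integer(round(cycle_length)) - 14L
  e1g_rise_day <- if (kind == "no_e1g_rise") NA_integer_
                  else peak_day - as.integer(gap_e1g_to_lh)
  if (ovulatory && !is.na(e1g_rise_day) && e1g_rise_day < 6L)
    stop("config error: cycle too short for the requested E1G-to-LH gap ",
         "(planted rise would precede the day-5 baseline)", call. = FALSE)
  if (1.5 * e1g_baseline >= 175 || e1g_baseline * e1g_peakmult < 1.3 * 175)
    stop("config error: e1g_baseline/e1g_peakmult incompatible with the ",
         "rise criterion", call. = FALSE)
  structure(list(kind = kind, cycle_length = as.integer(round(cycle_length)),
                 e1g_baseline = e1g_baseline, e1g_peakmult = e1g_peakmult,
                 lh_base = lh_base, lh_surge_height = lh_surge_height,
                 pdg_base = pdg_base, pdg_plateau = pdg_plateau,
                 fsh_levels = rep_len(fsh_levels, 3L),
                 gap_e1g_to_lh = as.integer(gap_e1g_to_lh),
                 gap_lh_to_pdg = as.integer(gap_lh_to_pdg),
                 noise_cv = noise_cv),
            class = "phenotype_spec")
}

#' Simulate one tracked cycle
#'
#' Builds the daily testing calendar the app would direct (day-5 baseline,
#' FSH on days 5/7/9, daily multi-hormone testing from 5 days before
#' predicted ovulation -- extended earlier when the planted E1G rise precedes
#' that -- until the PdG rise or, for anovulatory kinds, 14 days past the
#' planted peak, plus the four implantation-window days) and fills it with
#' noisy piecewise-template hormone values.
#'
#' @param spec a [phenotype_spec()].
#' @param seed integer seed; the same seed always yields the same record.
#' @param subject_id identifier for the record.
#' @return A list with `record` (a [cycle_record()]) and `truth`, the planted
#'   ground truth: `kind`, `e1g_rise_day`, `lh_peak_day`, `pdg_rise_day`,
#'   `gap_e1g_to_lh`, `gap_lh_to_pdg`, `fertile_window_days`,
#'   `fsh_elevated`, `surge_episodes`.
#' @examples
#' sim <- simulate_cycle(phenotype_spec("normal"), seed = 42)
#' map_cycle(sim$record)$fertile_window_days == sim$truth$fertile_window_days
#' @export
simulate_cycle <- function(spec, seed = NULL, subject_id = "sim") {
  if (!inherits(spec, "phenotype_spec"))
    stop("simulate_cycle() expects a phenotype_spec", call. = FALSE)
  with_seed(seed, {
    ovulatory <- spec$kind %in% c("normal", "luteal_deficient", "no_e1g_rise")
    peak <- spec$cycle_length - 14L
    rise <- if (spec$kind == "no_e1g_rise") NA_integer_
            else peak - spec$gap_e1g_to_lh
    pdg_rise <- if (ovulatory) peak + spec$gap_lh_to_pdg else NA_integer_

    mh_start <- max(6L, min(peak - 5L, if (is.na(rise)) peak - 5L else rise))
    mh_end <- if (ovulatory) pdg_rise else peak + 14L
    mh_days <- mh_start:mh_end
    impl_days <- peak + 7:10
    fsh_days <- c(5L, 7L, 9L)
    all_days <- sort(unique(c(5L, fsh_days, mh_days, impl_days)))
    is_mh <- all_days %in% c(5L, mh_days, impl_days)
    is_fsh <- all_days %in% fsh_days

    thr <- 175
    e1g_peak_val <- spec$e1g_baseline * spec$e1g_peakmult
    e1g_mean <- vapply(all_days, function(d) {
      if (!is.na(rise) && d >= rise && d <= peak) {
        if (peak == rise) e1g_peak_val
        else 1.25 * thr + (e1g_peak_val - 1.25 * thr) *
          (d - rise) / (peak - rise)
      } else if (!is.na(rise) && d > peak) {
        max(spec$e1g_baseline, 1.1 * thr * exp(-0.3 * (d - peak)))
      } else {
        # pre-rise ramp (or the whole cycle when no rise is planted),
        # capped at 78% of the absolute threshold to keep clear of it
        lo <- spec$e1g_baseline
        hi <- 0.78 * thr
        anchor <- if (is.na(rise)) peak else rise
        frac <- min(1, max(0, (d - 5) / max(1, anchor - 1 - 5)))
        lo + (hi - lo) * frac * 0.95
      }
    }, numeric(1))

    surge_days <- if (spec$kind == "multi_surge")
      list(c(peak, peak + 1L), peak + 3L, peak + 5L)
    else list(c(peak, peak + 1L))
    lh_mean <- rep(spec$lh_base, length(all_days))
    lh_mean[all_days %in% unlist(surge_days)] <- spec$lh_surge_height

    pdg_mean <- rep(spec$pdg_base, length(all_days))
    if (ovulatory) {
      post <- all_days >= pdg_rise
      conf_val <- 1.32 * 2.5   # confirmation-day template value, 3.3 ug/mL
      pdg_mean[post] <- spec$pdg_plateau +
        (conf_val - spec$pdg_plateau) * exp(-(all_days[post] - pdg_rise))
    }

    cv <- spec$noise_cv
    e1g <- ifelse(is_mh, lnoise(e1g_mean, cv), NA_real_)
    lh  <- ifelse(is_mh, lnoise(lh_mean, cv), NA_real_)
    pdg <- ifelse(is_mh, lnoise(pdg_mean, cv), NA_real_)
    fsh <- rep(NA_real_, length(all_days))
    fsh[is_fsh] <- lnoise(spec$fsh_levels[match(all_days[is_fsh], fsh_days)],
                          cv)

    rec <- cycle_record(subject_id, all_days,
                        e1g = e1g, lh = lh, pdg = pdg, fsh = fsh)
    truth <- list(kind = spec$kind,
                  e1g_rise_day = rise,
                  lh_peak_day = peak,
                  pdg_rise_day = pdg_rise,
                  gap_e1g_to_lh = if (is.na(rise)) NA_integer_
                                  else spec$gap_e1g_to_lh,
                  gap_lh_to_pdg = if (ovulatory) spec$gap_lh_to_pdg
                                  else NA_integer_,
                  fertile_window_days = if (!ovulatory) NA_integer_
                    else if (is.na(rise)) spec$gap_lh_to_pdg
                    else spec$gap_e1g_to_lh + spec$gap_lh_to_pdg,
                  fsh_elevated = max(spec$fsh_levels) > 10,
                  surge_episodes = length(surge_days))
    list(record = rec, truth = truth)
  })
}

# mean of a Poisson truncated to support {0..kmax}
trunc_pois_mean <- function(lambda, kmax = 7L) {
  k <- 0:kmax
  p <- stats::dpois(k, lambda)
  sum(k * p) / sum(p)
}

# moment-match the truncation-adjusted rate to a target mean on {0..kmax}
trunc_pois_lambda <- function(target, kmax = 7L) {
  if (target <= 0 || target >= kmax)
    stop("config error: infeasible gap mean ", target,
         " for support {0..", kmax, "}", call. = FALSE)
  stats::uniroot(function(l) trunc_pois_mean(l, kmax) - target,
                 interval = c(1e-6, 100), tol = 1e-10)$root
}

sample_trunc_pois <- function(n, target_mean, kmax = 7L) {
  lambda <- trunc_pois_lambda(target_mean, kmax)
  k <- 0:kmax
  p <- stats::dpois(k, lambda)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

#' Cohort preset for the simulator
#'
#' Defaults emulate the pilot-study cohort: 40 tracked cycles of which 38
#' were ovulatory and 2 anovulatory; E1G-rise-to-LH-peak gaps with mean 2.68
#' days and LH-peak-to-PdG-rise gaps with mean 2.64 days, both on support
#' 0-7; 16 of the 38 ovulatory cycles luteal-deficient; and elevated
#' early-cycle FSH in 43% of cycles.  Gaps are drawn from discretised
#' truncated Poisson distributions moment-matched to the preset means.
#'
#' @param n_ovulatory ovulatory cycles (default 38).
#' @param n_anovulatory anovulatory cycles (default 2; the first of them is
#'   the multi-surge pattern when `n_anovulatory >= 1`).
#' @param gap1_mean mean E1G-rise-to-LH-peak gap, days (default 2.68).
#' @param gap2_mean mean LH-peak-to-PdG-rise gap, days (default 2.64).
#' @param dysfunction_fraction fraction of ovulatory cycles that are
#'   luteal-deficient (default 16/38).
#' @param elevated_fsh_fraction probability a cycle carries elevated FSH
#'   (default 0.43).
#' @param noise_cv assay CV for every cycle (default 0.05).
#' @param seed default seed used by [simulate_cohort()] when none is given.
#' @return An object of class `cohort_preset`.
#' @export
cohort_preset <- function(n_ovulatory = 38, n_anovulatory = 2,
                          gap1_mean = 2.68, gap2_mean = 2.64,
                          dysfunction_fraction = 16 / 38,
                          elevated_fsh_fraction = 0.43,
                          noise_cv = 0.05, seed = 1L) {
  if (dysfunction_fraction < 0 || dysfunction_fraction > 1 ||
      elevated_fsh_fraction < 0 || elevated_fsh_fraction > 1)
    stop("config error: fractions must lie in [0, 1]", call. = FALSE)
  trunc_pois_lambda(gap1_mean)  # validates feasibility
  trunc_pois_lambda(gap2_mean)
  structure(list(n_ovulatory = as.integer(n_ovulatory),
                 n_anovulatory = as.integer(n_anovulatory),
                 gap1_mean = gap1_mean, gap2_mean = gap2_mean,
                 dysfunction_fraction = dysfunction_fraction,
                 elevated_fsh_fraction = elevated_fsh_fraction,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "cohort_preset")
}

#' @rdname cohort_preset
#' @export
table3_preset <- function(seed = 1L) cohort_preset(seed = seed)

#' Simulate a cohort of tracked cycles
#'
#' Draws one cycle per subject under a [cohort_preset()].  One root seed
#' drives everything; each cycle gets a deterministic substream seed drawn up
#' front, so enlarging the cohort never reshuffles earlier cycles.  Each
#' cycle's gaps and FSH status are drawn inside its own substream.
#'
#' @param preset a [cohort_preset()].
#' @param seed root seed; defaults to `preset$seed`.
#' @return A list with `records` (list of [cycle_record()]) and `truth` (a
#'   data frame of planted ground truth, one row per cycle: `subject_id`,
#'   `kind`, `e1g_rise_day`, `lh_peak_day`, `pdg_rise_day`, gaps,
#'   `fertile_window_days`, `fsh_elevated`).
#' @examples
#' coh <- simulate_cohort(table3_preset(), seed = 7)
#' length(coh$records)
#' mean(coh$truth$fertile_window_days, na.rm = TRUE)
#' @export
simulate_cohort <- function(preset = table3_preset(), seed = NULL) {
  if (!inherits(preset, "cohort_preset"))
    stop("simulate_cohort() expects a cohort_preset", call. = FALSE)
  if (is.null(seed)) seed <- preset$seed
  n_ov <- preset$n_ovulatory
  n_an <- preset$n_anovulatory
  n <- n_ov + n_an
  n_dys <- as.integer(round(preset$dysfunction_fraction * n_ov))
  kinds <- c(rep("normal", n_ov - n_dys), rep("luteal_deficient", n_dys),
             if (n_an >= 1L) "multi_surge",
             rep("anovulatory_with_surge", max(0L, n_an - 1L)))

  sub_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n, replace = TRUE))

  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- with_seed(sub_seeds[i], {
      g1 <- sample_trunc_pois(1L, preset$gap1_mean)
      g2 <- sample_trunc_pois(1L, preset$gap2_mean)
      elev <- stats::runif(1) < preset$elevated_fsh_fraction
      fsh_levels <- if (elev) c(7, 13, 8) else c(6, 8, 7)
      spec <- phenotype_spec(kinds[i],
                             gap_e1g_to_lh = g1, gap_lh_to_pdg = g2,
                             fsh_levels = fsh_levels,
                             noise_cv = preset$noise_cv)
      simulate_cycle(spec,
                     seed = sample.int(.Machine$integer.max - 1L, 1L),
                     subject_id = sprintf("sim%04d", i))
    })
  }
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- out[[i]]$truth
    data.frame(subject_id = sprintf("sim%04d", i), kind = t$kind,
               e1g_rise_day = t$e1g_rise_day, lh_peak_day = t$lh_peak_day,
               pdg_rise_day = t$pdg_rise_day,
               gap_e1g_to_lh = t$gap_e1g_to_lh,
               gap_lh_to_pdg = t$gap_lh_to_pdg,
               fertile_window_days = t$fertile_window_days,
               fsh_elevated = t$fsh_elevated,
               surge_episodes = t$surge_episodes,
               stringsAsFactors = FALSE)
  }))
  list(records = lapply(out, `[[`, "record"), truth = truth)
}

#' Simulate spiked lateral-flow QC panels
#'
#' Emulates the strip-validation design: for each requested hormone, every
#' lot x technician x day cell tests the hormone's spiked concentration grid
#' with replicate strips, and line intensities are the hormone's true
#' dose-response curve (linear sandwich for LH, exponential competitive for
#' E1G and PdG) under multiplicative log-normal noise.
#'
#' Grids: LH 0/5/10/20/30/40/50 mIU/mL; E1G 0/25/50/75/100/150/200 ng/mL;
#' PdG 0/2.5/5/7.5/10/15 ug/mL.
#'
#' @param hormones subset of `c("LH", "E1G", "PdG")`.
#' @param lots,technicians,days design size (defaults 3 x 3 x 3).
#' @param replicates strips per technician per concentration per day
#'   (default 2).
#' @param noise_cv assay CV as a proportion (default 0.03).
#' @param seed integer seed.
#' @return A data frame with columns `lot`, `technician`, `day`, `hormone`,
#'   `concentration`, `intensity`, ready for [qc_gate_report()].
#' @export
simulate_qc_panels <- function(hormones = c("LH", "E1G", "PdG"),
                               lots = 3L, technicians = 3L, days = 3L,
                               replicates = 2L, noise_cv = 0.03,
                               seed = NULL) {
  grids <- list(LH = c(0, 5, 10, 20, 30, 40, 50),
                E1G = c(0, 25, 50, 75, 100, 150, 200),
                PdG = c(0, 2.5, 5, 7.5, 10, 15))
  true_curve <- list(
    LH  = function(c) 0.005 * c + 0.05,
    E1G = function(c) 0.40 * exp(-0.02 * c),
    PdG = function(c) 0.40 * exp(-0.20 * c))
  hormones <- match.arg(hormones, names(grids), several.ok = TRUE)
  with_seed(seed, {
    rows <- expand.grid(lot = paste0("lot", seq_len(lots)),
                        technician = paste0("tech", seq_len(technicians)),
                        day = seq_len(days),
                        hormone = hormones,
                        rep = seq_len(replicates),
                        stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      h <- rows$hormone[i]
      conc <- grids[[h]]
      data.frame(lot = rows$lot[i], technician = rows$technician[i],
                 day = rows$day[i], hormone = h,
                 concentration = conc,
                 intensity = lnoise(true_curve[[h]](conc), noise_cv),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
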