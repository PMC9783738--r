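#' Map a tracked cycle: events, fertile window, classification, score
#'
#' The central rule engine.  Runs the three hormone-event detectors
#' ([detect_e1g_rise()], [detect_lh_surges()], [detect_pdg_rise()]) on a
#' daily urinary hormone series and derives:
#' \itemize{
#'   \item the fertile window, opening on the E1G-rise day (or, when no E1G
#'     rise exists, on the peak-fertility day) and closing on the PdG-rise
#'     day;
#'   \item its decomposition into the E1G-rise-to-LH-peak and
#'     LH-peak-to-PdG-rise gaps (day-index differences, so same-day events
#'     give a gap of 0);
#'   \item the implantation-window PdG readings (days peak+7 .. peak+10);
#'   \item the ovulatory-function classification
#'     (see [classify_ovulatory_function()]);
#'   \item the Ovulation Score (see [ovulation_score()]);
#'   \item the early-cycle FSH ovarian-reserve screen (see [fsh_screen()]);
#'   \item the mean pre-ovulatory PdG (over measured days strictly before the
#'     LH peak).
#' }
#'
#' The PdG-rise search is anchored at the peak-fertility day when one exists
#' (a same-day rise gives an LH-to-PdG gap of 0); with no LH peak the whole
#' record is searched.
#'
#' @param cycle a [cycle_record()].
#' @param th a [cycle_thresholds()] object.
#' @return An object of class `cycle_map`: a list with fields
#'   `subject_id`, `e1g_rise_day`, `lh_peak_day`, `surge_episode_count`,
#'   `surge_episodes`, `pdg_rise_day`, `fertile_window_days`,
#'   `e1g_to_lh_days`, `lh_to_pdg_days`, `implantation_pdg` (named numeric,
#'   names are offsets "7".."10", `NA` where untested),
#'   `high_pdg_day_count`, `classification`, `ovulation_score`,
#'   `fsh_status`, `fsh_max`, `fsh_max_day`, `pre_ovulatory_pdg_mean`,
#'   `treatment`, `diagnosis`.
#' @examples
#' rec <- cycle_record("s1", cycle_day = 5:18,
#'   e1g = c(50, 60, 70, 80, 90, 110, 150, 180, 230, 200, 150, 120, 100, 90),
#'   lh  = c(4, 4, 5, 5, 6, 7, 9, 12, 35, 18, 9, 7, 6, 5),
#'   pdg = c(0.7, 0.8, 0.8, 0.7, 0.9, 0.8, 0.8, 0.9, 1.0, 1.4, 2.7,
#'           4.5, 6.2, 7.5))
#' map_cycle(rec)
#' @export
map_cycle <- function(cycle, th = cycle_thresholds()) {
  if (!inherits(cycle, "cycle_record"))
    stop("map_cycle() expects a cycle_record", call. = FALSE)

  e1g_rise <- detect_e1g_rise(cycle, th)
  surges <- detect_lh_surges(cycle, th)
  peak <- surges$peak_day
  pdg_rise <- detect_pdg_rise(cycle, th, after = peak)

  open_day <- if (!is.na(e1g_rise)) e1g_rise else peak
  window <- if (!is.na(open_day) && !is.na(pdg_rise))
    as.integer(pdg_rise - open_day) else NA_integer_
  gap1 <- if (!is.na(e1g_rise) && !is.na(peak))
    as.integer(peak - e1g_rise) else NA_integer_
  gap2 <- if (!is.na(peak) && !is.na(pdg_rise))
    as.integer(pdg_rise - peak) else NA_integer_

  offs <- th$implantation_offsets
  impl <- rep(NA_real_, length(offs))
  names(impl) <- as.character(offs)
  if (!is.na(peak)) {
    idx <- match(peak + offs, cycle$cycle_day)
    impl[!is.na(idx)] <- cycle$pdg[idx[!is.na(idx)]]
  }
  n_obs <- sum(!is.na(impl))
  high_count <- if (n_obs == length(offs))
    sum(impl >= th$pdg_sustain) else NA_integer_

  pre_pdg <- NA_real_
  if (!is.na(peak)) {
    m <- measured(cycle, "pdg")
    before <- m$value[m$day < peak]
    if (length(before)) pre_pdg <- mean(before)
  }

  fsh <- fsh_screen(cycle, th)

  map <- structure(list(
    subject_id = attr(cycle, "subject_id"),
    e1g_rise_day = e1g_rise,
    lh_peak_day = peak,
    surge_episode_count = surges$episode_count,
    surge_episodes = surges$episodes,
    pdg_rise_day = pdg_rise,
    fertile_window_days = window,
    e1g_to_lh_days = gap1,
    lh_to_pdg_days = gap2,
    implantation_pdg = impl,
    high_pdg_day_count = high_count,
    classification = NA_character_,
    ovulation_score = NA_integer_,
    fsh_status = fsh$status,
    fsh_max = fsh$fsh_max,
    fsh_max_day = fsh$max_day,
    pre_ovulatory_pdg_mean = pre_pdg,
    treatment = attr(cycle, "treatment"),
    diagnosis = attr(cycle, "diagnosis")
  ), class = "cycle_map")

  map$classification <- classify_ovulatory_function(map, th)
  # no confirmed ovulation, no score: an anovulatory cycle is reported as
  # unconfirmed rather than as a 10
  map$ovulation_score <- if (is.na(pdg_rise)) NA_integer_
                         else ovulation_score(impl, th)
  map
}

#' Classify ovulatory function from a mapped cycle
#'
#' Rules, applied in order over the four implantation-window offsets
#' (days peak+7 .. peak+10):
#' \enumerate{
#'   \item no PdG rise anywhere in the cycle: `"anovulatory"`;
#'   \item fewer than 3 of the 4 offsets tested: `"indeterminate"` (missing
#'     days are never imputed);
#'   \item at least `success_min_high_days` (default 3) tested days with PdG
#'     at or above the sustain threshold: `"successful_ovulation"`;
#'   \item at least `dysfunction_min_low_days` (default 2) tested days below
#'     it: `"ovulatory_dysfunction"`;
#'   \item otherwise (only possible with exactly 3 tested days, 2 high and
#'     1 low): `"indeterminate"`.
#' }
#'
#' @param map a `cycle_map` (from [map_cycle()]).
#' @param th a [cycle_thresholds()] object.
#' @return One of `"successful_ovulation"`, `"ovulatory_dysfunction"`,
#'   `"anovulatory"`, `"indeterminate"`.
#' @export
classify_ovulatory_function <- function(map, th = cycle_thresholds()) {
  if (is.na(map$pdg_rise_day)) return("anovulatory")
  impl <- map$implantation_pdg
  obs <- impl[!is.na(impl)]
  if (length(obs) < 3L) return("indeterminate")
  n_high <- sum(obs >= th$pdg_sustain)
  n_low <- sum(obs < th$pdg_sustain)
  if (n_high >= th$success_min_high_days) return("successful_ovulation")
  if (n_low >= th$dysfunction_min_low_days) return("ovulatory_dysfunction")
  "indeterminate"
}

#' Ovulation Score: luteal PdG production on a 10-100 scale
#'
#' Summarises PdG production over the four implantation-window testing days
#' (peak+7 .. peak+10):
#' \itemize{
#'   \item 100 when all four days reach the sustain threshold (default
#'     5 ug/mL, inclusive);
#'   \item 10 when no day reaches it;
#'   \item otherwise a band score: base 30/50/70 for 1/2/3 sustained days,
#'     +10 when the mean implantation-window PdG is at or above the sustain
#'     threshold, -10 when the mean is below half of it (below the
#'     confirmation threshold), clamped to [20, 90].
#' }
#' The intermediate banding is this package's documented convention; the
#' endpoints (100 and 10) are the validated definitions.
#'
#' @param implantation_pdg numeric vector of PdG values (ug/mL) on the four
#'   offsets, `NA` where untested.  Named or unnamed; order is irrelevant.
#' @param th a [cycle_thresholds()] object.
#' @return Integer score in `{10, 20..90, 100}`, or `NA` when fewer than 3 of
#'   the 4 offsets were tested.
#' @examples
#' ovulation_score(c(8, 9, 7, 6))   # 100
#' ovulation_score(c(1, 2, 1, 1))   # 10
#' ovulation_score(c(6, 6, 6, 3))   # 80
#' @export
ovulation_score <- function(implantation_pdg, th = cycle_thresholds()) {
  obs <- implantation_pdg[!is.na(implantation_pdg)]
  n_offsets <- length(th$implantation_offsets)
  if (length(obs) < 3L) return(NA_integer_)
  n_high <- sum(obs >= th$pdg_sustain)
  if (n_high == n_offsets) return(100L)
  if (n_high == 0L) return(10L)
  base <- c(30L, 50L, 70L)[min(n_high, 3L)]
  score <- base
  m <- mean(obs)
  if (m >= th$pdg_sustain) score <- score + 10L
  if (m < th$pdg_confirm) score <- score - 10L
  as.integer(min(90L, max(20L, score)))
}

#' Screen early-cycle FSH for diminished ovarian reserve
#'
#' FSH testing is directed on cycle days 5, 7 and 9.  The screen flags the
#' cycle as `"elevated"` when any measured FSH value is strictly above the
#' threshold (default 10 mIU/mL), a pattern typically used to indicate low
#' ovarian reserve.
#'
#' @inheritParams detect_e1g_rise
#' @return A list with `status` (`"normal"`, `"elevated"`, `"not_tested"`),
#'   `fsh_max` and `max_day` (both `NA` when not tested).
#' @export
fsh_screen <- function(cycle, th = cycle_thresholds()) {
  m <- measured(cycle, "fsh")
  if (length(m$day) == 0L)
    return(list(status = "not_tested", fsh_max = NA_real_,
                max_day = NA_integer_))
  i <- which.max(m$value)
  list(status = if (m$value[i] > th$fsh_elevated) "elevated" else "normal",
       fsh_max = m$value[i], max_day = m$day[i])
}

#' Directed testing schedule for a cycle
#'
#' Reproduces the testing plan the app directs from a subject's average cycle
#' length: an all-hormone baseline test on day 5; FSH on days 5, 7 and 9
#' regardless of cycle length; daily multi-hormone testing starting 5 days
#' before predicted ovulation (predicted as average cycle length minus a
#' 14-day default luteal phase) and continuing until the PdG rise; and four
#' implantation-window tests on days peak+7 .. peak+10 once peak fertility is
#' known.
#'
#' @param avg_cycle_length average cycle length in days (>= 21).
#' @param th a [cycle_thresholds()] object (supplies the implantation
#'   offsets).
#' @return A list with `baseline_day` (5), `fsh_days` (5, 7, 9),
#'   `predicted_ovulation_day`, `mh_start_day`, and a function
#'   `implantation_days(peak_day)` returning the four post-peak test days.
#' @examples
#' sched <- testing_schedule(28)
#' sched$mh_start_day            # 9
#' sched$implantation_days(17)   # 24 25 26 27
#' @export
testing_schedule <- function(avg_cycle_length, th = cycle_thresholds()) {
  if (!is.numeric(avg_cycle_length) || length(avg_cycle_length) != 1L ||
      avg_cycle_length < 21)
    stop("average cycle length below 21 days is not supported",
         call. = FALSE)
  pred <- as.integer(round(avg_cycle_length)) - 14L
  offs <- th$implantation_offsets
  list(baseline_day = 5L,
       fsh_days = c(5L, 7L, 9L),
       predicted_ovulation_day = pred,
       mh_start_day = pred - 5L,
       implantation_days = function(peak_day) as.integer(peak_day) + offs)
}

#' @export
print.cycle_map <- function(x, ...) {
  fmt_day <- function(d) if (is.na(d)) "-" else sprintf("day %d", d)
  cat(sprintf("Cycle map: subject %s\n", x$subject_id))
  cat(sprintf("  E1G rise: %s | LH peak: %s (%d surge episode%s) | PdG rise: %s\n",
              fmt_day(x$e1g_rise_day), fmt_day(x$lh_peak_day),
              x$surge_episode_count,
              if (x$surge_episode_count == 1L) "" else "s",
              fmt_day(x$pdg_rise_day)))
  if (!is.na(x$fertile_window_days))
    cat(sprintf("  Fertile window: %d day%s (E1G->LH %s, LH->PdG %s)\n",
                x$fertile_window_days,
                if (x$fertile_window_days == 1L) "" else "s",
                if (is.na(x$e1g_to_lh_days)) "-" else x$e1g_to_lh_days,
                if (is.na(x$lh_to_pdg_days)) "-" else x$lh_to_pdg_days))
  else cat("  Fertile window: not determined\n")
  cat(sprintf("  Classification: %s | Ovulation Score: %s\n",
              x$classification,
              if (is.na(x$ovulation_score)) "-" else x$ovulation_score))
  cat(sprintf("  FSH: %s%s\n", x$fsh_status,
              if (is.na(x$fsh_max)) ""
              else sprintf(" (max %g mIU/mL on day %d)",
                           x$fsh_max, x$fsh_max_day)))
  invisible(x)
}

#' @export
summary.cycle_map <- function(object, ...) {
  impl <- object$implantation_pdg
  cat(sprintf("Subject %s: %s\n", object$subject_id, object$classification))
  print(object)
  cat("  Implantation-window PdG (ug/mL):\n")
  for (i in seq_along(impl))
    cat(sprintf("    peak+%s: %s\n", names(impl)[i],
                if (is.na(impl[i])) "not tested" else sprintf("%.2f", impl[i])))
  if (!is.na(object$pre_ovulatory_pdg_mean))
    cat(sprintf("  Pre-ovulatory PdG mean: %.2f ug/mL\n",
                object$pre_ovulatory_pdg_mean))
  invisible(object)
}

#' Flatten cycle maps to a data frame
#'
#' One row per map, scalar fields only (surge episode day lists are dropped;
#' implantation readings become columns `impl_pdg_<offset>`).
#'
#' @param maps a `cycle_map` or a list of them.
#' @return A data frame.
#' @export
as.data.frame.cycle_map <- function(x, ...) {
  cycle_maps_table(list(x))
}

#' @rdname as.data.frame.cycle_map
#' @export
cycle_maps_table <- function(maps) {
  if (inherits(maps, "cycle_map")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    impl <- as.list(m$implantation_pdg)
    names(impl) <- paste0("impl_pdg_", names(m$implantation_pdg))
    as.data.frame(c(list(
      subject_id = m$subject_id,
      e1g_rise_day = m$e1g_rise_day,
      lh_peak_day = m$lh_peak_day,
      surge_episode_count = m$surge_episode_count,
      pdg_rise_day = m$pdg_rise_day,
      fertile_window_days = m$fertile_window_days,
      e1g_to_lh_days = m$e1g_to_lh_days,
      lh_to_pdg_days = m$lh_to_pdg_days,
      high_pdg_day_count = m$high_pdg_day_count,
      classification = m$classification,
      ovulation_score = m$ovulation_score,
      fsh_status = m$fsh_status,
      fsh_max = m$fsh_max,
      pre_ovulatory_pdg_mean = m$pre_ovulatory_pdg_mean,
      treatment = m$treatment,
      diagnosis = m$diagnosis
    ), impl))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
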