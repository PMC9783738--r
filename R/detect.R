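#' Detect the E1G rise
#'
#' The fertile window opens on the first day the urinary E1G concentration
#' reaches both an absolute physiological threshold (default 175 ng/mL) and a
#' multiple of the subject's own early-cycle baseline (default 1.5x the E1G
#' value on the earliest measured day, i.e. the directed day-5 baseline
#' test).  The AND rule keeps a chronically high baseline from triggering a
#' spurious rise while still using a meaningful absolute concentration.
#'
#' @param cycle a [cycle_record()].
#' @param th a [cycle_thresholds()] object.
#' @return The cycle day of the rise, or `NA` if the criterion is never met
#'   (a valid outcome: some ovulatory cycles show no E1G rise).
#' @seealso [map_cycle()] which runs all three detectors.
#' @export
detect_e1g_rise <- function(cycle, th = cycle_thresholds()) {
  m <- measured(cycle, "e1g")
  if (length(m$day) == 0L) return(NA_integer_)
  baseline <- m$value[1L]
  cut <- max(th$e1g_abs, th$e1g_baseline_ratio * baseline)
  hit <- which(m$value >= cut)
  if (length(hit) == 0L) NA_integer_ else m$day[hit[1L]]
}

#' Detect LH surge episodes and the peak-fertility day
#'
#' A surge episode is a maximal run of consecutive \emph{measured} days with
#' LH strictly above the surge threshold (default 25 mIU/mL); episodes are
#' separated by at least one measured sub-threshold day.  Peak fertility is
#' the first day of the first episode.  Multiple episodes in one cycle are a
#' recognised pattern (e.g. in PCOS) and are reported, not collapsed.
#'
#' @inheritParams detect_e1g_rise
#' @return A list with `peak_day` (cycle day or `NA`), `episode_count`, and
#'   `episodes` (a list of integer vectors of cycle days, one per episode).
#' @export
detect_lh_surges <- function(cycle, th = cycle_thresholds()) {
  m <- measured(cycle, "lh")
  if (length(m$day) == 0L)
    return(list(peak_day = NA_integer_, episode_count = 0L,
                episodes = list()))
  above <- m$value > th$lh_surge
  if (!any(above))
    return(list(peak_day = NA_integer_, episode_count = 0L,
                episodes = list()))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  episodes <- lapply(keep, function(i) m$day[starts[i]:ends[i]])
  list(peak_day = episodes[[1L]][1L],
       episode_count = length(episodes),
       episodes = episodes)
}

#' Detect the PdG rise that confirms ovulation
#'
#' Ovulation is confirmed on the first measured day, at or after `after` when
#' given, whose PdG value reaches the confirmation threshold (default
#' 2.5 ug/mL, inclusive).
#'
#' @inheritParams detect_e1g_rise
#' @param after restrict the search to cycle days `>= after` (typically the
#'   peak-fertility day); `NA` searches the whole record.
#' @return The cycle day of the rise, or `NA` if PdG never reaches the
#'   threshold (an anovulatory pattern).
#' @export
detect_pdg_rise <- function(cycle, th = cycle_thresholds(), after = NA) {
  m <- measured(cycle, "pdg")
  if (length(m$day) == 0L) return(NA_integer_)
  if (!is.na(after)) {
    keep <- m$day >= after
    m$day <- m$day[keep]; m$value <- m$value[keep]
  }
  hit <- which(m$value >= th$pdg_confirm)
  if (length(hit) == 0L) NA_integer_ else m$day[hit[1L]]
}
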