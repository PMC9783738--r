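#' Decision thresholds for cycle mapping
#'
#' Bundles every tunable threshold used by the detectors, the classifier and
#' the Ovulation Score into one auditable object.  Defaults are the clinical
#' cut-offs the system was validated with; any of them can be overridden per
#' call or loaded from a JSON config (see [read_thresholds()]).
#'
#' Comparison conventions (fixed, not configurable):
#' \itemize{
#'   \item LH surge and FSH elevation are \emph{strict} (`> lh_surge`,
#'     `> fsh_elevated`): a reading exactly at 25 mIU/mL is not a surge and
#'     10 mIU/mL FSH is still normal.
#'   \item PdG confirmation and PdG sustain are \emph{inclusive}
#'     (`>= pdg_confirm`, `>= pdg_sustain`): ovulation may be confirmed with
#'     a value as low as 2.5 ug/mL exactly.
#'   \item The E1G rise requires both parts of an AND rule:
#'     `e1g >= max(e1g_abs, e1g_baseline_ratio * baseline)`, where the
#'     baseline is the E1G value on the earliest measured day (the directed
#'     day-5 baseline test).
#' }
#'
#' @param lh_surge LH surge threshold, mIU/mL (strict). Default 25.
#' @param e1g_abs absolute E1G rise threshold, ng/mL. Default 175.
#' @param e1g_baseline_ratio multiplier on the baseline E1G that the rise
#'   must also exceed; guards against chronically high baselines. Default 1.5.
#' @param pdg_confirm PdG level confirming ovulation, ug/mL (inclusive).
#'   Default 2.5.
#' @param pdg_sustain PdG level counted as "sustained" during the
#'   implantation window, ug/mL (inclusive). Default 5.
#' @param fsh_elevated FSH level flagging possible diminished ovarian
#'   reserve, mIU/mL (strict). Default 10.
#' @param implantation_offsets day offsets after peak fertility over which
#'   luteal PdG production is judged. Default `7:10`.
#' @param dysfunction_min_low_days minimum number of implantation-window days
#'   below `pdg_sustain` that defines ovulatory dysfunction. Default 2.
#' @param success_min_high_days minimum number of implantation-window days at
#'   or above `pdg_sustain` that defines successful ovulation. Default 3.
#'
#' @return An object of class `cycle_thresholds` (a named list).
#' @examples
#' th <- cycle_thresholds()
#' th$lh_surge
#' cycle_thresholds(lh_surge = 20)$lh_surge
#' @export
cycle_thresholds <- function(lh_surge = 25,
                             e1g_abs = 175,
                             e1g_baseline_ratio = 1.5,
                             pdg_confirm = 2.5,
                             pdg_sustain = 5,
                             fsh_elevated = 10,
                             implantation_offsets = 7:10,
                             dysfunction_min_low_days = 2,
                             success_min_high_days = 3) {
  th <- list(
    lh_surge = lh_surge,
    e1g_abs = e1g_abs,
    e1g_baseline_ratio = e1g_baseline_ratio,
    pdg_confirm = pdg_confirm,
    pdg_sustain = pdg_sustain,
    fsh_elevated = fsh_elevated,
    implantation_offsets = as.integer(sort(implantation_offsets)),
    dysfunction_min_low_days = as.integer(dysfunction_min_low_days),
    success_min_high_days = as.integer(success_min_high_days)
  )
  num <- c("lh_surge", "e1g_abs", "e1g_baseline_ratio", "pdg_confirm",
           "pdg_sustain", "fsh_elevated")
  for (f in num) {
    v <- th[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("threshold '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (length(th$implantation_offsets) < 1L || any(th$implantation_offsets < 1L))
    stop("implantation_offsets must be positive day offsets", call. = FALSE)
  structure(th, class = "cycle_thresholds")
}

#' @export
print.cycle_thresholds <- function(x, ...) {
  cat("Cycle-mapping thresholds\n")
  cat(sprintf("  LH surge        > %g mIU/mL (strict)\n", x$lh_surge))
  cat(sprintf("  E1G rise        >= max(%g ng/mL, %g x baseline)\n",
              x$e1g_abs, x$e1g_baseline_ratio))
  cat(sprintf("  PdG confirm     >= %g ug/mL\n", x$pdg_confirm))
  cat(sprintf("  PdG sustain     >= %g ug/mL\n", x$pdg_sustain))
  cat(sprintf("  FSH elevated    > %g mIU/mL (strict)\n", x$fsh_elevated))
  cat(sprintf("  implantation window: peak + {%s}\n",
              paste(x$implantation_offsets, collapse = ", ")))
  cat(sprintf("  success rule: >= %d of %d days sustained; dysfunction: >= %d low\n",
              x$success_min_high_days, length(x$implantation_offsets),
              x$dysfunction_min_low_days))
  invisible(x)
}

#' Read thresholds from a JSON config file
#'
#' The JSON object may set any subset of the [cycle_thresholds()] arguments;
#' unset fields keep their defaults.  Unknown keys are an error so that typos
#' in a config never silently fall back to defaults.
#'
#' @param path path to a JSON file.
#' @return A `cycle_thresholds` object.
#' @export
read_thresholds <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(cycle_thresholds))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown threshold config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(cycle_thresholds, cfg)
}
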