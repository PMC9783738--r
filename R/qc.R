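#' Percent coefficient of variation of replicate intensities
#'
#' 100 * sample SD / mean (n-1 denominator).  The replicate-precision gate
#' for strip manufacturing requires every per-day and pooled %CV below 10.
#'
#' @param replicates numeric vector, length >= 2, positive mean.
#' @return %CV as a percentage.
#' @examples
#' percent_cv(c(9, 10, 11))   # 10
#' @export
percent_cv <- function(replicates) {
  if (length(replicates) < 2L)
    stop("need at least 2 replicates", call. = FALSE)
  m <- mean(replicates)
  if (!is.finite(m) || m <= 0)
    stop("replicate mean must be positive", call. = FALSE)
  100 * stats::sd(replicates) / m
}

#' 3-SD acceptance bound for specificity/sensitivity gating
#'
#' The bound a strip population must read beyond to pass: mean - 3 SD when
#' passing means reading at or above the bound (`direction = "at_least"`,
#' sensitivity of sandwich lines / specificity of competitive lines), or
#' mean + 3 SD when passing means reading at or below it (`"at_most"`).
#' Sample SD (n-1) throughout.
#'
#' @param intensities numeric vector, length >= 2, from the validation lots.
#' @param direction `"at_least"` or `"at_most"`.
#' @param pass_fraction_required fraction of strips that must satisfy the
#'   bound for the lot to pass (default 0.90).
#' @param hormone,sample_label optional labels carried on the object.
#' @return An object of class `acceptance_bound` with fields `bound`,
#'   `direction`, `pass_fraction_required`, `mean`, `sd`, plus labels.
#' @export
acceptance_bound <- function(intensities,
                             direction = c("at_least", "at_most"),
                             pass_fraction_required = 0.90,
                             hormone = NA_character_,
                             sample_label = NA_character_) {
  direction <- match.arg(direction)
  if (length(intensities) < 2L)
    stop("need at least 2 intensities", call. = FALSE)
  if (pass_fraction_required <= 0 || pass_fraction_required > 1)
    stop("pass_fraction_required must be in (0, 1]", call. = FALSE)
  m <- mean(intensities); s <- stats::sd(intensities)
  b <- if (direction == "at_least") m - 3 * s else m + 3 * s
  structure(list(bound = b, direction = direction,
                 pass_fraction_required = pass_fraction_required,
                 mean = m, sd = s,
                 hormone = hormone, sample_label = sample_label),
            class = "acceptance_bound")
}

#' @export
print.acceptance_bound <- function(x, ...) {
  cat(sprintf("Acceptance bound%s: read %s %.6g (mean %.6g, SD %.6g); >= %g%% must pass\n",
              if (is.na(x$hormone)) "" else paste0(" [", x$hormone, "]"),
              if (x$direction == "at_least") "at or above" else "at or below",
              x$bound, x$mean, x$sd, 100 * x$pass_fraction_required))
  invisible(x)
}

#' Fraction of strips satisfying an acceptance bound
#'
#' Comparison is inclusive: a strip reading exactly on the bound passes.
#'
#' @param intensities numeric vector of strip readings (non-empty).
#' @param bound an [acceptance_bound()].
#' @return A list with `proportion` and `pass` (`proportion >=
#'   pass_fraction_required`).
#' @export
pass_rate <- function(intensities, bound) {
  if (!inherits(bound, "acceptance_bound"))
    stop("pass_rate() expects an acceptance_bound", call. = FALSE)
  if (length(intensities) == 0L)
    stop("no intensities supplied", call. = FALSE)
  ok <- if (bound$direction == "at_least") intensities >= bound$bound
        else intensities <= bound$bound
  p <- mean(ok)
  list(proportion = p, pass = p >= bound$pass_fraction_required)
}

curve_form_for <- function(hormone) {
  switch(toupper(hormone),
         LH = "linear", FSH = "linear",
         E1G = "exponential", PDG = "exponential",
         stop("unknown hormone: ", hormone, call. = FALSE))
}

#' Reproducibility gate report over spiked QC panels
#'
#' Runs the full manufacturing reproducibility check over a set of spiked
#' quality-control panels (the validation design is 3 lots x 3 technicians x
#' 3 days with replicate strips per concentration):
#' \itemize{
#'   \item a standard curve is fitted per hormone x lot x technician x day
#'     (linear for sandwich-format LH, exponential on log intensity for
#'     competitive-format E1G and PdG), and the fraction of fits with
#'     |r| > 0.9 must be at least 0.90 per hormone;
#'   \item %CV across replicates is computed per hormone x day x
#'     concentration and pooled over the three days per hormone x
#'     concentration; every %CV must be below 10.
#' }
#'
#' @param panels a data frame with columns `lot`, `technician`, `day`,
#'   `hormone`, `concentration`, `intensity` (one row per strip), e.g. from
#'   [read_qc_panels()] or [simulate_qc_panels()].
#' @param cv_limit %CV gate (default 10).
#' @param r_limit correlation gate on |r| (default 0.9).
#' @param r_fraction_required fraction of fits that must exceed `r_limit`
#'   (default 0.90).
#' @return An object of class `qc_report`: a list with `curves` (per-group
#'   fit table), `cv_by_day`, `cv_pooled`, per-hormone `r_fraction`, the gate
#'   thresholds, and booleans `cv_gate`, `r_gate`, `pass`.
#' @export
qc_gate_report <- function(panels, cv_limit = 10, r_limit = 0.9,
                           r_fraction_required = 0.90) {
  need <- c("lot", "technician", "day", "hormone", "concentration",
            "intensity")
  miss <- setdiff(need, names(panels))
  if (length(miss))
    stop("QC panel table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)

  key <- interaction(panels$hormone, panels$lot, panels$technician,
                     panels$day, drop = TRUE)
  fits <- lapply(split(panels, key), function(g) {
    form <- curve_form_for(g$hormone[1L])
    conc <- g$concentration; int <- g$intensity
    if (form == "exponential") {
      keep <- int > 0
      conc <- conc[keep]; int <- int[keep]
    }
    sc <- fit_standard_curve(conc, int, form = form,
                             hormone = g$hormone[1L])
    data.frame(hormone = g$hormone[1L], lot = g$lot[1L],
               technician = g$technician[1L], day = g$day[1L],
               form = form, r_value = sc$r_value,
               stringsAsFactors = FALSE)
  })
  curves <- do.call(rbind, fits)
  rownames(curves) <- NULL

  cv_by_day <- stats::aggregate(
    intensity ~ hormone + day + concentration, data = panels,
    FUN = percent_cv)
  names(cv_by_day)[names(cv_by_day) == "intensity"] <- "cv"
  cv_pooled <- stats::aggregate(
    intensity ~ hormone + concentration, data = panels, FUN = percent_cv)
  names(cv_pooled)[names(cv_pooled) == "intensity"] <- "cv"

  r_fraction <- vapply(split(curves$r_value, curves$hormone),
                       function(r) mean(abs(r) > r_limit), numeric(1))

  cv_gate <- all(cv_by_day$cv < cv_limit) && all(cv_pooled$cv < cv_limit)
  r_gate <- all(r_fraction >= r_fraction_required)

  structure(list(curves = curves, cv_by_day = cv_by_day,
                 cv_pooled = cv_pooled, r_fraction = r_fraction,
                 cv_limit = cv_limit, r_limit = r_limit,
                 r_fraction_required = r_fraction_required,
                 cv_gate = cv_gate, r_gate = r_gate,
                 pass = cv_gate && r_gate),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Lateral-flow QC gate report\n")
  cat(sprintf("  %d standard-curve fits over %d hormone(s)\n",
              nrow(x$curves), length(x$r_fraction)))
  for (h in names(x$r_fraction))
    cat(sprintf("  %s: fraction |r| > %g = %.3f (gate >= %g)\n",
                h, x$r_limit, x$r_fraction[h], x$r_fraction_required))
  cat(sprintf("  max per-day %%CV = %.2f, max pooled %%CV = %.2f (gate < %g)\n",
              max(x$cv_by_day$cv), max(x$cv_pooled$cv), x$cv_limit))
  cat(sprintf("  CV gate: %s | R gate: %s | overall: %s\n",
              if (x$cv_gate) "PASS" else "FAIL",
              if (x$r_gate) "PASS" else "FAIL",
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Read spiked QC panels from CSV
#'
#' Expected header: `lot,technician,day,hormone,concentration,intensity`.
#'
#' @param path CSV path.
#' @return A data frame suitable for [qc_gate_report()].
#' @export
read_qc_panels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lot", "technician", "day", "hormone", "concentration",
            "intensity")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("QC panel CSV is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(d$concentration) || !is.numeric(d$intensity))
    stop("concentration and intensity must be numeric", call. = FALSE)
  d
}
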