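params_summarized <- c("fertile_window_days", "e1g_to_lh_days",
                       "lh_to_pdg_days", "high_pdg_day_count",
                       "ovulation_score")

ci_t <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- if (n) mean(x) else NA_real_
  if (n < 2L)
    return(list(n = n, mean = m, min = if (n) min(x) else NA_real_,
                max = if (n) max(x) else NA_real_,
                ci95_low = NA_real_, ci95_high = NA_real_))
  if (stats::sd(x) == 0) {
    ci <- c(m, m)
  } else {
    ci <- stats::t.test(x, conf.level = 0.95)$conf.int
  }
  list(n = n, mean = m, min = min(x), max = max(x),
       ci95_low = ci[1], ci95_high = ci[2])
}

#' Cohort-level summary of mapped cycles
#'
#' Aggregates a set of [map_cycle()] results into the cohort table reported
#' for the pilot study: per-parameter n, mean, range and t-based 95%
#' confidence interval (mean +/- t(0.975, n-1) * s / sqrt(n), sample SD) for
#' the fertile window, its two component gaps, the count of sustained-PdG
#' implantation days and the Ovulation Score, plus cohort counts.
#' Anovulatory cycles are counted but excluded from all day-parameter
#' statistics; cycles missing a parameter contribute nothing to that
#' parameter.
#'
#' @param maps a list of `cycle_map` objects.
#' @return An object of class `cohort_summary`: a list with `parameters` (a
#'   data frame, one row per parameter) and `counts` (named integer vector:
#'   `total`, `ovulatory`, `anovulatory`, `successful`, `dysfunction`,
#'   `indeterminate`, `elevated_fsh`).
#' @export
summarize_cohort <- function(maps) {
  if (inherits(maps, "cycle_map")) maps <- list(maps)
  if (!length(maps)) stop("no cycle maps supplied", call. = FALSE)
  cls <- vapply(maps, `[[`, character(1), "classification")
  ov <- maps[cls != "anovulatory"]

  rows <- lapply(params_summarized, function(p) {
    x <- vapply(ov, function(m) as.numeric(m[[p]]), numeric(1))
    c(list(parameter = p), ci_t(x))
  })
  parameters <- do.call(rbind, lapply(rows, as.data.frame))

  counts <- c(total = length(maps),
              ovulatory = sum(cls != "anovulatory"),
              anovulatory = sum(cls == "anovulatory"),
              successful = sum(cls == "successful_ovulation"),
              dysfunction = sum(cls == "ovulatory_dysfunction"),
              indeterminate = sum(cls == "indeterminate"),
              elevated_fsh = sum(vapply(maps, `[[`, character(1),
                                        "fsh_status") == "elevated"))
  structure(list(parameters = parameters, counts = counts),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  cycles: %d total, %d ovulatory, %d anovulatory\n",
              x$counts["total"], x$counts["ovulatory"],
              x$counts["anovulatory"]))
  cat(sprintf("  function: %d successful, %d dysfunction, %d indeterminate; elevated FSH in %d\n",
              x$counts["successful"], x$counts["dysfunction"],
              x$counts["indeterminate"], x$counts["elevated_fsh"]))
  p <- x$parameters
  for (i in seq_len(nrow(p))) {
    ci <- if (is.na(p$ci95_low[i])) "" else
      sprintf("  CI95 [%.*f, %.*f]", digits, p$ci95_low[i], digits,
              p$ci95_high[i])
    cat(sprintf("  %-22s n=%-4d mean %.*f  range [%g, %g]%s\n",
                p$parameter[i], p$n[i], digits, p$mean[i], p$min[i],
                p$max[i], ci))
  }
  invisible(x)
}

map_param <- function(maps, parameter) {
  vapply(maps, function(m) as.numeric(m[[parameter]]), numeric(1))
}

#' Compare a cycle parameter between two groups
#'
#' Two-sided two-sample comparison of a mapped-cycle parameter (e.g. fertile
#' window length) between two groups of cycles, as used to compare treated
#' vs untreated cycles.  The default is Welch's unequal-variance t-test; a
#' Monte-Carlo permutation test on the difference in means is available as a
#' distribution-free alternative.
#'
#' When both groups are constant, the p-value is 1 for equal means and 0
#' otherwise (the degenerate-variance convention).
#'
#' @param maps_a,maps_b lists of `cycle_map` objects (or bare numeric vectors
#'   of the parameter values).
#' @param parameter one of `"fertile_window_days"`, `"e1g_to_lh_days"`,
#'   `"lh_to_pdg_days"`, `"high_pdg_day_count"`, `"ovulation_score"`.
#'   Ignored when numeric vectors are given.
#' @param method `"welch"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed seed for the permutation draw.
#' @return The two-sided p-value.
#' @export
compare_groups <- function(maps_a, maps_b,
                           parameter = "fertile_window_days",
                           method = c("welch", "permutation"),
                           n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  a <- if (is.numeric(maps_a)) maps_a else map_param(maps_a, parameter)
  b <- if (is.numeric(maps_b)) maps_b else map_param(maps_b, parameter)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  if (method == "welch")
    return(stats::t.test(a, b, var.equal = FALSE)$p.value)
  with_seed(seed, {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    na <- length(a)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      d <- abs(mean(pool[idx]) - mean(pool[-idx]))
      if (d >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1L) / (n_perm + 1L)
  })
}
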