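#' One tracked cycle of daily urinary hormone measurements
#'
#' A `cycle_record` holds one subject's daily quantified hormone values for a
#' single tracked cycle.  Cycle day 1 is the first day of red menstrual
#' bleeding flow; days need not be contiguous (untested days are simply
#' absent) but must be strictly increasing and unique.  A hormone that was
#' not measured on a tested day is `NA`.
#'
#' @param subject_id subject identifier (coerced to character).
#' @param cycle_day integer vector of tested cycle days (>= 1, unique).
#' @param e1g estrone-3-glucuronide, ng/mL (`NA` = not measured).
#' @param lh luteinizing hormone, mIU/mL.
#' @param pdg pregnanediol-3-glucuronide, ug/mL.
#' @param fsh follicle-stimulating hormone, mIU/mL.
#' @param age subject age in years, optional.
#' @param treatment one of `"none"`, `"ovulation_induction"`,
#'   `"progesterone"`, `"other"`, or `NA`.
#' @param diagnosis free-text diagnosis, optional.
#'
#' @return An object of class `cycle_record`: a data frame with columns
#'   `cycle_day`, `e1g`, `lh`, `pdg`, `fsh`, plus attributes `subject_id`,
#'   `age`, `treatment`, `diagnosis`.
#' @examples
#' rec <- cycle_record("s1", cycle_day = c(5, 12, 13, 14),
#'                     e1g = c(50, 180, 220, NA),
#'                     lh  = c(4, 8, 32, 12),
#'                     pdg = c(0.7, 0.8, 0.9, 2.8))
#' rec
#' @export
cycle_record <- function(subject_id, cycle_day,
                         e1g = NA_real_, lh = NA_real_, pdg = NA_real_,
                         fsh = NA_real_,
                         age = NA_real_, treatment = NA_character_,
                         diagnosis = NA_character_) {
  n <- length(cycle_day)
  if (n < 1L) stop("a cycle_record needs at least one tested day",
                   call. = FALSE)
  cycle_day <- as.integer(cycle_day)
  if (anyNA(cycle_day) || any(cycle_day < 1L))
    stop("cycle_day must be integers >= 1", call. = FALSE)
  if (anyDuplicated(cycle_day))
    stop("duplicated cycle_day: ",
         paste(unique(cycle_day[duplicated(cycle_day)]), collapse = ", "),
         call. = FALSE)
  rec <- data.frame(
    cycle_day = cycle_day,
    e1g = rep_len(as.numeric(e1g), n),
    lh  = rep_len(as.numeric(lh), n),
    pdg = rep_len(as.numeric(pdg), n),
    fsh = rep_len(as.numeric(fsh), n)
  )
  rec <- rec[order(rec$cycle_day), , drop = FALSE]
  rownames(rec) <- NULL
  for (h in c("e1g", "lh", "pdg", "fsh")) {
    v <- rec[[h]]
    if (any(!is.na(v) & (v < 0 | !is.finite(v))))
      stop("negative or non-finite ", h, " value", call. = FALSE)
  }
  if (all(is.na(rec$e1g) & is.na(rec$lh) & is.na(rec$pdg) & is.na(rec$fsh)))
    stop("no hormone measured on any day", call. = FALSE)
  structure(rec,
            subject_id = as.character(subject_id),
            age = age, treatment = treatment, diagnosis = diagnosis,
            class = c("cycle_record", "data.frame"))
}

#' @export
print.cycle_record <- function(x, ...) {
  cat(sprintf("Cycle record: subject %s, %d tested days (cycle days %d-%d)\n",
              attr(x, "subject_id"), nrow(x),
              min(x$cycle_day), max(x$cycle_day)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

measured <- function(rec, hormone) {
  ok <- !is.na(rec[[hormone]])
  list(day = rec$cycle_day[ok], value = rec[[hormone]][ok])
}
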