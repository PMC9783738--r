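score_band <- function(score) {
  if (is.na(score)) return(NA_character_)
  if (score >= 100) "excellent luteal PdG production: sustained on all four implantation-window days"
  else if (score >= 70) "good luteal PdG production: sustained on most implantation-window days"
  else if (score >= 40) "moderate luteal PdG production: consider discussing luteal support with a clinician"
  else if (score >= 20) "low luteal PdG production: a pattern consistent with ovulatory dysfunction"
  else "no implantation-window day reached the sustain level"
}

classification_text <- c(
  successful_ovulation = "Ovulation confirmed with sustained luteal PdG (successful ovulation).",
  ovulatory_dysfunction = "Ovulation confirmed, but PdG was not sustained through the implantation window (ovulatory dysfunction).",
  anovulatory = "No PdG rise was detected: ovulation was not confirmed this cycle.",
  indeterminate = "Insufficient implantation-window data to judge ovulatory function.")

report_payload <- function(map) {
  flags <- character()
  if (map$surge_episode_count > 1L)
    flags <- c(flags, sprintf("multiple LH surge episodes (%d), a pattern seen in PCOS",
                              map$surge_episode_count))
  if (is.na(map$e1g_rise_day) && !is.na(map$lh_peak_day))
    flags <- c(flags, "no E1G rise detected; fertile window opened at the LH peak")
  if (map$classification == "indeterminate")
    flags <- c(flags, "insufficient implantation-window data")
  list(
    schema = "cyclemap/cycle_report",
    schema_version = map_schema_version,
    subject_id = map$subject_id,
    events = list(e1g_rise_day = map$e1g_rise_day,
                  lh_peak_day = map$lh_peak_day,
                  surge_episode_count = map$surge_episode_count,
                  pdg_rise_day = map$pdg_rise_day),
    fertile_window = list(days = map$fertile_window_days,
                          e1g_to_lh_days = map$e1g_to_lh_days,
                          lh_to_pdg_days = map$lh_to_pdg_days),
    implantation_pdg = as.list(map$implantation_pdg),
    classification = map$classification,
    classification_text = unname(classification_text[map$classification]),
    ovulation_score = map$ovulation_score,
    ovulation_score_text = score_band(map$ovulation_score),
    fsh = list(status = map$fsh_status, max = map$fsh_max,
               max_day = map$fsh_max_day),
    pre_ovulatory_pdg_mean = map$pre_ovulatory_pdg_mean,
    flags = as.list(flags))
}

render_markdown <- function(p) {
  fmt_day <- function(d) if (is.na(d)) "not detected" else sprintf("cycle day %d", d)
  fmt_num <- function(v, unit) if (is.na(v)) "-" else sprintf("%.2f %s", v, unit)
  lines <- c(
    sprintf("# Cycle report: subject %s", p$subject_id),
    "",
    "## Event timeline",
    "",
    sprintf("- E1G rise: %s", fmt_day(p$events$e1g_rise_day)),
    sprintf("- LH peak (peak fertility): %s (%d surge episode%s)",
            fmt_day(p$events$lh_peak_day), p$events$surge_episode_count,
            if (p$events$surge_episode_count == 1L) "" else "s"),
    sprintf("- PdG rise (ovulation confirmed): %s",
            fmt_day(p$events$pdg_rise_day)),
    "",
    "## Fertile window",
    "",
    if (is.na(p$fertile_window$days))
      "No fertile window could be determined this cycle."
    else sprintf("%d fertile day%s detected (%s days from E1G rise to LH peak, %s from LH peak to PdG rise).",
                 p$fertile_window$days,
                 if (p$fertile_window$days == 1L) "" else "s",
                 if (is.na(p$fertile_window$e1g_to_lh_days)) "-"
                 else p$fertile_window$e1g_to_lh_days,
                 if (is.na(p$fertile_window$lh_to_pdg_days)) "-"
                 else p$fertile_window$lh_to_pdg_days),
    "",
    "## Ovulatory function",
    "",
    p$classification_text,
    "",
    if (p$classification == "indeterminate")
      c("### Insufficient implantation-window data",
        "",
        "Fewer than 3 of the 4 directed implantation-window tests (days 7-10 after peak fertility) were taken; ovulatory function cannot be judged.",
        ""),
    if (!is.na(p$ovulation_score))
      c(sprintf("Ovulation Score: **%d** / 100", p$ovulation_score),
        "",
        sprintf("Interpretation (package bands): %s.", p$ovulation_score_text))
    else "No Ovulation Score: ovulation was not confirmed or the window was insufficiently tested.",
    "",
    "Implantation-window PdG (ug/mL):",
    "",
    vapply(names(p$implantation_pdg), function(o)
      sprintf("- peak+%s: %s", o,
              if (is.na(p$implantation_pdg[[o]])) "not tested"
              else sprintf("%.2f", p$implantation_pdg[[o]])),
      character(1)),
    "",
    "## Ovarian reserve (FSH)",
    "",
    switch(p$fsh$status,
      not_tested = "FSH was not tested this cycle.",
      elevated = sprintf("Elevated FSH detected: maximum %.1f mIU/mL on cycle day %d (above 10 mIU/mL, a pattern typically used to indicate low ovarian reserve).",
                         p$fsh$max, p$fsh$max_day),
      normal = sprintf("FSH normal: maximum %.1f mIU/mL on cycle day %d (at or below 10 mIU/mL).",
                       p$fsh$max, p$fsh$max_day)),
    "",
    if (!is.na(p$pre_ovulatory_pdg_mean))
      c(sprintf("Pre-ovulatory PdG mean: %s.",
                fmt_num(p$pre_ovulatory_pdg_mean, "ug/mL")), ""),
    if (length(p$flags))
      c("## Flags", "", paste0("- ", unlist(p$flags)), ""))
  paste(unlist(lines), collapse = "\n")
}

#' Render a per-cycle report
#'
#' Turns one [map_cycle()] result into a human-readable cycle report:
#' detected event timeline, fertile-window statement, ovulatory-function
#' classification with the Ovulation Score and plain-language interpretation
#' bands (the bands are this package's own), implantation-window PdG values,
#' the FSH ovarian-reserve section, and flags (multiple surge episodes, no
#' E1G rise, insufficient implantation-window data).  Every number in the
#' report is a field of the cycle map.  Rendering is deterministic: the same
#' map always yields byte-identical output.
#'
#' @param map a `cycle_map`.
#' @param format `"json"`, `"markdown"`, or `"html"`.
#' @return A single string in the requested format.
#' @export
render_report <- function(map, format = c("json", "markdown", "html")) {
  format <- match.arg(format)
  if (!inherits(map, "cycle_map"))
    stop("render_report() expects a cycle_map", call. = FALSE)
  p <- report_payload(map)
  if (format == "json")
    return(as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA,
                                         na = "null", pretty = TRUE)))
  md <- render_markdown(p)
  if (format == "markdown") return(md)
  html_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  body <- html_escape(md)
  body <- gsub("(?m)^# (.*)$", "<h1>\\1</h1>", body, perl = TRUE)
  body <- gsub("(?m)^## (.*)$", "<h2>\\1</h2>", body, perl = TRUE)
  body <- gsub("(?m)^### (.*)$", "<h3>\\1</h3>", body, perl = TRUE)
  body <- gsub("(?m)^- (.*)$", "<li>\\1</li>", body, perl = TRUE)
  body <- gsub("\\*\\*([^*]+)\\*\\*", "<strong>\\1</strong>", body)
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>",
         "Cycle report: ", html_escape(p$subject_id),
         "</title></head><body>\n",
         gsub("\n\n", "\n<p>\n", body, fixed = TRUE),
         "\n</body></html>\n")
}
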