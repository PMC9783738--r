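cycle_csv_cols <- c("subject_id", "cycle_day", "e1g_ng_ml", "lh_miu_ml",
                    "pdg_ug_ml", "fsh_miu_ml")

#' Read tracked cycles from CSV
#'
#' Expected header: `subject_id,cycle_day,e1g_ng_ml,lh_miu_ml,pdg_ug_ml,
#' fsh_miu_ml`, one row per subject per tested day.  An empty hormone cell
#' means "not measured that day".  Malformed rows (non-numeric hormone
#' values, duplicated cycle days within a subject, cycle day < 1) are
#' collected into an error report attached as `attr(, "errors")` -- they are
#' reported with their line numbers, never silently dropped; the offending
#' subject's record is excluded.
#'
#' @param path CSV path.
#' @return A list of [cycle_record()] objects, with attribute `errors` (a
#'   data frame with columns `line`, `subject_id`, `problem`; zero rows when
#'   the file is clean).
#' @seealso [write_cycles()] for the inverse.
#' @export
read_cycles <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  miss <- setdiff(cycle_csv_cols, names(d))
  if (length(miss))
    stop("cycle CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  errors <- data.frame(line = integer(), subject_id = character(),
                       problem = character(), stringsAsFactors = FALSE)
  note <- function(line, sid, problem) {
    errors[nrow(errors) + 1L, ] <<- list(line, sid, problem)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  d$.line <- seq_len(nrow(d)) + 1L   # header is line 1

  bad_subjects <- character()
  for (i in seq_len(nrow(d))) {
    sid <- d$subject_id[i]
    day <- num(d$cycle_day[i])
    if (is.na(day) || day < 1 || day != round(day)) {
      note(d$.line[i], sid, paste0("invalid cycle_day '", d$cycle_day[i], "'"))
      bad_subjects <- c(bad_subjects, sid)
      next
    }
    for (col in cycle_csv_cols[3:6]) {
      v <- d[[col]][i]
      if (nzchar(trimws(v)) && is.na(num(v))) {
        note(d$.line[i], sid, paste0("non-numeric ", col, " value '", v, "'"))
        bad_subjects <- c(bad_subjects, sid)
      }
    }
  }
  for (sid in unique(d$subject_id)) {
    days <- num(d$cycle_day[d$subject_id == sid])
    dup <- unique(days[duplicated(days)])
    dup <- dup[!is.na(dup)]
    if (length(dup)) {
      note(min(d$.line[d$subject_id == sid]), sid,
           paste0("duplicated cycle_day ", paste(dup, collapse = ", ")))
      bad_subjects <- c(bad_subjects, sid)
    }
  }

  keep <- setdiff(unique(d$subject_id), bad_subjects)
  records <- lapply(keep, function(sid) {
    g <- d[d$subject_id == sid, , drop = FALSE]
    cycle_record(sid, num(g$cycle_day),
                 e1g = num(g$e1g_ng_ml), lh = num(g$lh_miu_ml),
                 pdg = num(g$pdg_ug_ml), fsh = num(g$fsh_miu_ml))
  })
  names(records) <- keep
  attr(records, "errors") <- errors
  records
}

#' Write tracked cycles to CSV
#'
#' Writes the dialect read by [read_cycles()]; `NA` hormone values become
#' empty cells.  `write_cycles()` then `read_cycles()` reproduces the input
#' records exactly.
#'
#' @param records a list of [cycle_record()] objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cycles <- function(records, path) {
  if (inherits(records, "cycle_record")) records <- list(records)
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(subject_id = attr(r, "subject_id"),
               cycle_day = r$cycle_day,
               e1g_ng_ml = r$e1g, lh_miu_ml = r$lh,
               pdg_ug_ml = r$pdg, fsh_miu_ml = r$fsh,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

map_schema_version <- "1.0"

#' Write cycle maps to schema-versioned JSON
#'
#' @param maps a `cycle_map` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cycle_maps <- function(maps, path) {
  if (inherits(maps, "cycle_map")) maps <- list(maps)
  payload <- list(schema = "cyclemap/cycle_map",
                  schema_version = map_schema_version,
                  maps = lapply(maps, unclass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
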