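parse_timestamp <- function(x, field) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  blank <- is.na(x) | !nzchar(trimws(x))
  out <- rep(as.POSIXct(NA), length(x))
  todo <- which(!blank)
  if (length(todo)) {
    v <- trimws(x[todo])
    parsed <- as.POSIXct(v, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    sp <- is.na(parsed)
    parsed[sp] <- as.POSIXct(v[sp], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
    # bare clock times are pinned to one calendar day (no midnight wrap)
    bare <- is.na(parsed) & grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", v)
    parsed[bare] <- as.POSIXct(
      paste("1970-01-01", ifelse(grepl("^\\d{1,2}:\\d{2}$", v[bare]),
                                 paste0(v[bare], ":00"), v[bare])),
      format = "%Y-%m-%d %H:%M:%S", tz = "UTC"
    )
    if (anyNA(parsed)) {
      bad <- v[is.na(parsed)]
      stop_data(paste0(
        "Unparseable ", field, " value(s): ",
        paste(utils::head(unique(bad), 5), collapse = ", ")
      ))
    }
    out[todo] <- parsed
  }
  out
}

#' Filter corrupted visit records and report the exclusions
#'
#' Applies the standard paradata exclusion filters, in order and mutually
#' exclusively, so that the report's counts partition the input exactly:
#' records without a start time, then records without an end time, then
#' records with illogical times (non-positive duration, or duration above
#' `max_duration` seconds). Timestamps may be POSIXct or ISO 8601 character
#' (empty string = missing); bare clock times like `"21:00"` are interpreted
#' on a single calendar day, so a 9 pm start with a 10 am end is illogical
#' rather than an overnight interview.
#'
#' @param visits Tibble of visit records with columns `participant_id`,
#'   `visit`, `start_time`, `end_time`, `word_count` (extra columns pass
#'   through).
#' @param max_duration Duration cap in seconds (default 24 hours).
#' @return A list of class `clean_result`: `kept` (tibble of retained
#'   records, timestamps as POSIXct) and `report` (tibble with `n_input`,
#'   `n_missing_start`, `n_missing_end`, `n_illogical`, `n_kept`).
#' @examples
#' v <- tibble::tibble(
#'   participant_id = c("A", "A"), visit = c(50L, 51L),
#'   start_time = c("2008-10-01T09:00:00", "2009-04-01T21:00:00"),
#'   end_time = c("2008-10-01T09:12:30", "2009-04-01T10:00:00"),
#'   word_count = c(3000L, 1500L)
#' )
#' clean_visits(v)$report
#' @export
clean_visits <- function(visits, max_duration = 24 * 3600) {
  visits <- tibble::as_tibble(visits)
  dup <- visits |>
    dplyr::count(.data$participant_id, .data$visit) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_data(paste0(
      "Duplicate (participant_id, visit) pairs: ",
      paste(utils::head(paste0(dup$participant_id, "/", dup$visit), 5),
            collapse = ", ")
    ))
  }
  start <- parse_timestamp(visits$start_time, "start_time")
  end <- parse_timestamp(visits$end_time, "end_time")
  missing_start <- is.na(start)
  missing_end <- !missing_start & is.na(end)
  duration <- as.numeric(difftime(end, start, units = "secs"))
  illogical <- !missing_start & !missing_end &
    (duration <= 0 | duration > max_duration)
  keep <- !missing_start & !missing_end & !illogical

  kept <- visits[keep, , drop = FALSE]
  kept$start_time <- start[keep]
  kept$end_time <- end[keep]
  report <- tibble::tibble(
    n_input = nrow(visits),
    n_missing_start = sum(missing_start),
    n_missing_end = sum(missing_end),
    n_illogical = sum(illogical),
    n_kept = sum(keep)
  )
  structure(list(kept = kept, report = report), class = "clean_result")
}

#' @export
print.clean_result <- function(x, ...) {
  r <- x$report
  cat("<clean_result> ", r$n_kept, "/", r$n_input, " records kept (",
      r$n_missing_start, " missing start, ", r$n_missing_end,
      " missing end, ", r$n_illogical, " illogical)\n", sep = "")
  invisible(x)
}

#' Compute per-visit response speed
#'
#' Response speed is the total responded word count N divided by the total
#' survey time T in seconds (words per second), with T taken from the
#' start/end timestamp difference. Records must already have passed
#' [clean_visits()], so T > 0.
#'
#' @param kept Tibble of cleaned visit records (or a `clean_result`).
#' @param visit_zero Visit number mapped to coded time 0 (default 50).
#' @return Tibble with `participant_id`, `visit`, `t` (coded time),
#'   `word_count`, `duration` (seconds) and `speed` (words/second), plus any
#'   visit-level covariate columns.
#' @examples
#' v <- tibble::tibble(
#'   participant_id = "A", visit = 50L,
#'   start_time = "2008-10-01T09:00:00", end_time = "2008-10-01T09:10:00",
#'   word_count = 1200L
#' )
#' compute_speed(clean_visits(v))$speed # 2 words/s
#' @export
compute_speed <- function(kept, visit_zero = 50) {
  if (inherits(kept, "clean_result")) kept <- kept$kept
  duration <- as.numeric(difftime(kept$end_time, kept$start_time, units = "secs"))
  if (any(is.na(duration)) || any(duration <= 0)) {
    stop_data("Non-positive or missing durations: records must pass clean_visits() first.")
  }
  kept |>
    dplyr::mutate(
      t = as.integer(.data$visit - visit_zero),
      duration = duration,
      speed = .data$word_count / duration,
      .after = "visit"
    ) |>
    dplyr::select(-"start_time", -"end_time")
}

#' Assemble per-participant speed series
#'
#' Orders speed observations into one series per participant by coded time.
#' Participants are retained however few visits they have; panels may be
#' unbalanced.
#'
#' @param speeds Output of [compute_speed()].
#' @return A tibble of class `speed_series` with `participant_id`, `t`,
#'   `speed` (plus covariates), sorted by participant and coded time.
#' @export
build_series <- function(speeds) {
  out <- speeds |>
    dplyr::arrange(.data$participant_id, .data$t)
  if (anyDuplicated(out[c("participant_id", "t")]) > 0) {
    stop_data("Duplicate (participant_id, t) observations in speed data.")
  }
  class(out) <- c("speed_series", class(out))
  out
}
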