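# Smartwatch stream processing: hourly step totals, motion-context
# inference for unlabeled HR records, wear time, person-day validity
# filters, and participant-level summaries.

#' Per-participant, per-clock-hour step totals
#'
#' Sums step-interval records into clock-hour bins. Intervals that cross
#' hour boundaries are apportioned proportionally to the time overlapped
#' with each hour; the split is rounded so each record's total is
#' conserved exactly (cumulative rounding, ties half to even). Every
#' clock hour between a participant's first and last observed hour gets
#' a row, zero where no records fall.
#'
#' @param step_records Tibble with `participant_id`, `start`, `end`
#'   (POSIXct) and `steps` (non-negative counts). Intervals for one
#'   participant must not overlap.
#' @param complete_span If `TRUE` (default), fill the full hour span per
#'   participant with zeros.
#' @return Tibble `participant_id`, `hour` (POSIXct, floored), `steps`.
#' @export
hourly_steps <- function(step_records, complete_span = TRUE) {
  req <- c("participant_id", "start", "end", "steps")
  stopifnot(all(req %in% names(step_records)))
  if (nrow(step_records) == 0) {
    return(tibble::tibble(participant_id = character(),
                          hour = as.POSIXct(character()),
                          steps = numeric()))
  }
  stopifnot(all(step_records$end > step_records$start),
            all(step_records$steps >= 0))
  x <- dplyr::arrange(step_records, .data$participant_id, .data$start)
  overlap <- dplyr::mutate(
    x, prev_end = dplyr::lag(.data$end), .by = "participant_id")
  bad <- !is.na(overlap$prev_end) & overlap$start < overlap$prev_end
  if (any(bad)) {
    who <- unique(overlap$participant_id[bad])
    stop(sprintf("overlapping step intervals for participant(s): %s",
                 paste(who, collapse = ", ")), call. = FALSE)
  }

  tz <- attr(x$start, "tzone") %||% ""
  s <- as.numeric(x$start)
  e <- as.numeric(x$end)
  h0 <- floor(s / 3600)
  h1 <- ceiling(e / 3600) - 1  # last hour index touched
  n_hours <- pmax(1, h1 - h0 + 1)

  # expand each record to the hours it touches, apportion by overlap
  rec_id <- rep(seq_len(nrow(x)), n_hours)
  hour_idx <- h0[rec_id] + sequence(n_hours) - 1
  ov_start <- pmax(s[rec_id], hour_idx * 3600)
  ov_end <- pmin(e[rec_id], (hour_idx + 1) * 3600)
  w <- ov_end - ov_start

  parts <- numeric(length(rec_id))
  single <- n_hours[rec_id] == 1
  parts[single] <- x$steps[rec_id[single]]
  if (any(!single)) {
    multi_ids <- which(n_hours > 1)
    idx_by_rec <- split(which(!single), rec_id[!single])
    for (r in multi_ids) {
      ix <- idx_by_rec[[as.character(r)]]
      parts[ix] <- apportion_count(x$steps[r], w[ix])
    }
  }

  out <- tibble::tibble(
    participant_id = x$participant_id[rec_id],
    hour_num = hour_idx * 3600,
    steps = parts)
  out <- dplyr::summarise(out, steps = sum(.data$steps),
                          .by = c("participant_id", "hour_num"))
  if (complete_span) {
    out <- dplyr::reframe(
      out,
      {
        full <- seq(min(.data$hour_num), max(.data$hour_num), by = 3600)
        v <- numeric(length(full))
        v[match(.data$hour_num, full)] <- .data$steps
        tibble::tibble(hour_num = full, steps = v)
      },
      .by = "participant_id")
  }
  out$hour <- as.POSIXct(out$hour_num, origin = "1970-01-01", tz = tz)
  dplyr::arrange(out[c("participant_id", "hour", "steps")],
                 .data$participant_id, .data$hour)
}

#' Infer motion context for unlabeled HR records
#'
#' Device-supplied context labels are authoritative: `active` stays
#' `active` and `sedentary` becomes `nonactive`. A record with unknown
#' context is labeled `nonactive` if and only if both conditions hold:
#' (1) the recording interval to the adjacent HR record exceeds
#' `gap_threshold_s` (60 s), and (2) the step total of the clock hour
#' containing the record is below `step_threshold` (30 steps). Otherwise
#' it is labeled `active`. The interval is the gap to the immediately
#' preceding record of the same participant-day; the first record of a
#' participant-day uses the gap to the following record instead (for a
#' day with a single record the interval is treated as long).
#'
#' @param hr_records Tibble with `participant_id`, `timestamp`
#'   (POSIXct), `hr_bpm` and `context` in
#'   `{"active","sedentary","unknown"}`.
#' @param hourly Output of [hourly_steps()]; hours absent from it count
#'   as zero steps.
#' @param gap_threshold_s Interval cut, seconds; strictly greater than
#'   the cut qualifies as sparse.
#' @param step_threshold Hourly step cut; strictly below qualifies.
#' @param tz Timezone defining the calendar day used for the
#'   first-record fallback.
#' @return `hr_records` with columns `gap_s`, `hour_steps` and
#'   `context_resolved` in `{"active","nonactive"}` appended.
#' @export
infer_motion_context <- function(hr_records, hourly = NULL,
                                 gap_threshold_s = 60, step_threshold = 30,
                                 tz = "UTC") {
  if (nrow(hr_records) == 0) {
    out <- hr_records
    out$gap_s <- numeric(0)
    out$hour_steps <- numeric(0)
    out$context_resolved <- character(0)
    return(out)
  }
  x <- dplyr::arrange(hr_records, .data$participant_id, .data$timestamp)
  x$date <- as.Date(x$timestamp, tz = tz)
  x <- dplyr::mutate(
    x,
    gap_prev = as.numeric(.data$timestamp) -
      dplyr::lag(as.numeric(.data$timestamp)),
    gap_next = dplyr::lead(as.numeric(.data$timestamp)) -
      as.numeric(.data$timestamp),
    .by = c("participant_id", "date"))
  x$gap_s <- ifelse(is.na(x$gap_prev), x$gap_next, x$gap_prev)
  x$gap_s[is.na(x$gap_s)] <- Inf  # single record in a day: sparse

  x$hour_num <- floor(as.numeric(x$timestamp) / 3600) * 3600
  if (is.null(hourly) || nrow(hourly) == 0) {
    x$hour_steps <- 0
  } else {
    hk <- paste(hourly$participant_id, floor(as.numeric(hourly$hour) / 3600) *
                  3600)
    m <- match(paste(x$participant_id, x$hour_num), hk)
    x$hour_steps <- ifelse(is.na(m), 0, hourly$steps[m])
  }

  inferred <- ifelse(x$gap_s > gap_threshold_s &
                       x$hour_steps < step_threshold, "nonactive", "active")
  x$context_resolved <- dplyr::case_when(
    x$context == "active" ~ "active",
    x$context == "sedentary" ~ "nonactive",
    .default = inferred)
  x[setdiff(names(x), c("date", "gap_prev", "gap_next", "hour_num"))]
}

#' Daily wear time from record coverage
#'
#' Wear time for a participant-day is the number of distinct clock hours
#' of that day containing at least one HR record or overlapped by at
#' least one step interval.
#'
#' @param hr_records,step_records Raw stream tibbles (either may be
#'   empty).
#' @param tz Timezone defining calendar days.
#' @return Tibble `participant_id`, `date`, `wear_hours`.
#' @export
wear_time <- function(hr_records, step_records, tz = "UTC") {
  hr_hours <- if (nrow(hr_records) > 0) {
    tibble::tibble(
      participant_id = hr_records$participant_id,
      hour_num = floor(as.numeric(hr_records$timestamp) / 3600) * 3600)
  } else {
    tibble::tibble(participant_id = character(), hour_num = numeric())
  }
  step_hours <- if (nrow(step_records) > 0) {
    s <- as.numeric(step_records$start)
    e <- as.numeric(step_records$end)
    h0 <- floor(s / 3600)
    n_h <- pmax(1, ceiling(e / 3600) - h0)
    tibble::tibble(
      participant_id = rep(step_records$participant_id, n_h),
      hour_num = (rep(h0, n_h) + sequence(n_h) - 1) * 3600)
  } else {
    tibble::tibble(participant_id = character(), hour_num = numeric())
  }
  all_hours <- dplyr::distinct(rbind(hr_hours, step_hours))
  if (nrow(all_hours) == 0) {
    return(tibble::tibble(participant_id = character(),
                          date = as.Date(character()),
                          wear_hours = integer()))
  }
  all_hours$date <- as.Date(
    as.POSIXct(all_hours$hour_num, origin = "1970-01-01", tz = tz), tz = tz)
  out <- dplyr::summarise(all_hours, wear_hours = dplyr::n(),
                          .by = c("participant_id", "date"))
  dplyr::arrange(out, .data$participant_id, .data$date)
}

#' Person-day summaries with validity flags
#'
#' One row per participant-day with any record: wear hours, total daily
#' steps (from hour-apportioned totals), HR record count, and the
#' step-day validity flag. A day is a valid step day unless wear time is
#' less than `min_wear_hours` (5 h) or daily steps are less than
#' `min_daily_steps` (1000); both cuts are strict, so a day at exactly
#' the threshold passes.
#'
#' @param hr_records HR stream (context need not be resolved).
#' @param step_records Step stream.
#' @param min_wear_hours,min_daily_steps Validity cuts.
#' @param tz Timezone defining calendar days.
#' @return Tibble `participant_id`, `date`, `wear_hours`, `daily_steps`,
#'   `n_hr_records`, `valid_step_day`.
#' @export
summarize_days <- function(hr_records, step_records, min_wear_hours = 5,
                           min_daily_steps = 1000, tz = "UTC") {
  wear <- wear_time(hr_records, step_records, tz = tz)
  hs <- hourly_steps(step_records, complete_span = FALSE)
  daily <- if (nrow(hs) > 0) {
    hs$date <- as.Date(hs$hour, tz = tz)
    dplyr::summarise(hs, daily_steps = sum(.data$steps),
                     .by = c("participant_id", "date"))
  } else {
    tibble::tibble(participant_id = character(), date = as.Date(character()),
                   daily_steps = numeric())
  }
  nhr <- if (nrow(hr_records) > 0) {
    h <- tibble::tibble(participant_id = hr_records$participant_id,
                        date = as.Date(hr_records$timestamp, tz = tz))
    dplyr::summarise(h, n_hr_records = dplyr::n(),
                     .by = c("participant_id", "date"))
  } else {
    tibble::tibble(participant_id = character(), date = as.Date(character()),
                   n_hr_records = integer())
  }
  out <- dplyr::full_join(wear, daily, by = c("participant_id", "date"))
  out <- dplyr::full_join(out, nhr, by = c("participant_id", "date"))
  out$daily_steps[is.na(out$daily_steps)] <- 0
  out$n_hr_records[is.na(out$n_hr_records)] <- 0L
  out$wear_hours[is.na(out$wear_hours)] <- 0L
  out$valid_step_day <- !(out$wear_hours < min_wear_hours |
                            out$daily_steps < min_daily_steps)
  dplyr::arrange(out, .data$participant_id, .data$date)
}

#' Participant-level watch summaries and inclusion flags
#'
#' The participant's nonactive HR is the unweighted mean over all
#' HR records resolved as nonactive (by default including records on
#' invalid step days, since the day-validity filter belongs to the step
#' analysis; set `hr_valid_days_only = TRUE` to restrict). Mean daily
#' steps averages `daily_steps` over valid step days only. Inclusion
#' requires at least `min_days` (30) contributing days — days with HR
#' data for the HR analysis, valid step days for the step analysis, and
#' both for the joint primary sample; the cut is inclusive ("30 or more
#' days").
#'
#' @param day_summaries Output of [summarize_days()].
#' @param labeled_hr Output of [infer_motion_context()].
#' @param min_days Inclusion cut in days.
#' @param hr_valid_days_only Restrict nonactive-HR averaging to valid
#'   step days.
#' @param tz Timezone defining calendar days.
#' @return Tibble: one row per participant with `nonactive_hr_mean`,
#'   `n_nonactive_records`, `mean_daily_steps`, `n_hr_days`,
#'   `n_step_days`, `median_wear_hours` and inclusion flags
#'   `include_hr`, `include_steps`, `include_primary`. Participants with
#'   zero nonactive records get `NA` HR mean and `zero_nonactive = TRUE`.
#' @export
summarize_participants <- function(day_summaries, labeled_hr, min_days = 30,
                                   hr_valid_days_only = FALSE, tz = "UTC") {
  stopifnot(nrow(day_summaries) > 0)
  stopifnot("context_resolved" %in% names(labeled_hr))
  hr <- labeled_hr
  hr$date <- as.Date(hr$timestamp, tz = tz)
  if (hr_valid_days_only) {
    valid <- day_summaries[day_summaries$valid_step_day,
                           c("participant_id", "date")]
    hr <- dplyr::semi_join(hr, valid, by = c("participant_id", "date"))
  }
  na_hr <- dplyr::summarise(
    hr[hr$context_resolved == "nonactive", ],
    nonactive_hr_mean = mean(.data$hr_bpm),
    n_nonactive_records = dplyr::n(),
    .by = "participant_id")

  per <- dplyr::summarise(
    day_summaries,
    n_hr_days = sum(.data$n_hr_records > 0),
    n_step_days = sum(.data$valid_step_day),
    mean_daily_steps = ifelse(any(.data$valid_step_day),
                              mean(.data$daily_steps[.data$valid_step_day]),
                              NA_real_),
    median_wear_hours = median(.data$wear_hours),
    .by = "participant_id")
  out <- dplyr::left_join(per, na_hr, by = "participant_id")
  out$n_nonactive_records[is.na(out$n_nonactive_records)] <- 0L
  out$zero_nonactive <- out$n_nonactive_records == 0L
  out$include_hr <- out$n_hr_days >= min_days & !out$zero_nonactive
  out$include_steps <- out$n_step_days >= min_days
  out$include_primary <- out$include_hr & out$include_steps
  cols <- c("participant_id", "nonactive_hr_mean", "n_nonactive_records",
            "mean_daily_steps", "n_hr_days", "n_step_days",
            "median_wear_hours", "zero_nonactive", "include_hr",
            "include_steps", "include_primary")
  dplyr::arrange(out[cols], .data$participant_id)
}

#' Full watch-stream processing stage
#'
#' Chains [hourly_steps()], [infer_motion_context()],
#' [summarize_days()] and [summarize_participants()].
#'
#' @inheritParams infer_motion_context
#' @inheritParams summarize_days
#' @inheritParams summarize_participants
#' @param step_records Step stream tibble.
#' @return List with `labeled_hr`, `day_summaries` and
#'   `participant_summaries`.
#' @export
process_watch <- function(hr_records, step_records, gap_threshold_s = 60,
                          step_threshold = 30, min_wear_hours = 5,
                          min_daily_steps = 1000, min_days = 30,
                          hr_valid_days_only = FALSE, tz = "UTC") {
  hs <- hourly_steps(step_records, complete_span = FALSE)
  labeled <- infer_motion_context(hr_records, hs,
                                  gap_threshold_s = gap_threshold_s,
                                  step_threshold = step_threshold, tz = tz)
  day_sum <- summarize_days(hr_records, step_records,
                            min_wear_hours = min_wear_hours,
                            min_daily_steps = min_daily_steps, tz = tz)
  part <- summarize_participants(day_sum, labeled, min_days = min_days,
                                 hr_valid_days_only = hr_valid_days_only,
                                 tz = tz)
  list(labeled_hr = labeled, day_summaries = day_sum,
       participant_summaries = part)
}
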