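# Per-worker stream orchestration: ingestion, abnormal-duration tracking,
# risk evaluation with alert episodes, and the graded-exercise-test error
# report used for indoor validation.

#' Ingest a raw device stream against a worker roster
#'
#' Sorts records per worker, rejects rows referencing unknown worker ids,
#' and counts (without failing on) malformed rows.
#'
#' @param stream data frame of device samples (or a path readable by
#'   [read_device_stream()]); must contain `timestamp` and `worker_id`.
#' @param roster data frame with at least `worker_id` (or a path readable
#'   by [read_roster_csv()]).
#' @return List with `workers` (named list of per-worker data frames,
#'   time-sorted), `rejected` (rows with unknown ids) and `n_malformed`.
#' @export
ingest_stream <- function(stream, roster) {
  if (is.character(stream)) stream <- read_device_stream(stream)
  if (is.character(roster)) roster <- read_roster_csv(roster)
  if (nrow(stream) == 0) {
    warning("empty device stream")
    return(list(workers = list(), rejected = stream, n_malformed = 0L))
  }
  if (!all(c("timestamp", "worker_id") %in% names(stream)))
    stop("stream must have timestamp and worker_id columns", call. = FALSE)
  ts <- stream$timestamp
  if (!inherits(ts, "POSIXct")) ts <- .parse_ts(ts)
  bad <- is.na(ts) | is.na(stream$worker_id)
  n_malformed <- sum(bad)
  if (n_malformed > 0) warning(n_malformed, " malformed row(s) dropped")
  stream <- stream[!bad, , drop = FALSE]
  stream$timestamp <- ts[!bad]
  known <- stream$worker_id %in% roster$worker_id
  rejected <- stream[!known, , drop = FALSE]
  accepted <- stream[known, , drop = FALSE]
  workers <- split(accepted, accepted$worker_id)
  workers <- lapply(workers, function(d) d[order(d$timestamp), , drop = FALSE])
  list(workers = workers, rejected = rejected, n_malformed = n_malformed)
}

#' Minutes of persisting abnormal status
#'
#' The fuzzy time-interval input T: elapsed minutes since the current
#' abnormal episode began. T is 0 whenever the status is normal (both the
#' heartbeat and core-temperature dominant sets are Normal) and resets on
#' every return to normal.
#'
#' @param timestamps POSIXct vector, non-decreasing.
#' @param abnormal logical vector, TRUE where the status is abnormal.
#' @return Numeric vector of minutes, same length.
#' @examples
#' ts <- as.POSIXct("2020-08-01", tz = "UTC") + 60 * (0:25)
#' track_abnormal_duration(ts, rep(c(TRUE, FALSE), c(21, 5)))
#' @export
track_abnormal_duration <- function(timestamps, abnormal) {
  stopifnot(length(timestamps) == length(abnormal))
  n <- length(abnormal)
  if (n == 0) return(numeric(0))
  if (is.unsorted(timestamps)) stop("timestamps must be sorted", call. = FALSE)
  tmin <- as.numeric(timestamps) / 60
  T <- numeric(n)
  start <- NA_real_
  for (i in seq_len(n)) {
    if (!abnormal[i]) {
      start <- NA_real_
      T[i] <- 0
    } else {
      if (is.na(start)) start <- tmin[i]
      T[i] <- tmin[i] - start
    }
  }
  T
}

.dominant_set <- function(mu) names(mu)[which.max(mu)]

#' Evaluate one worker's stream: risk series and alert episodes
#'
#' The per-sample pipeline: Hampel-filter the skin temperature, match each
#' sample to the nearest weather observation (within 90 minutes) for the
#' ambient temperature, estimate the core temperature, update the
#' abnormal-duration clock from the dominant heartbeat/core-temperature
#' fuzzy sets, and run Mamdani inference. One alert is opened per
#' contiguous Attention/Danger episode and closed when the category falls
#' back to Concern or below.
#'
#' @param samples data frame with `timestamp`, `hr_bpm`, `skin_temp_c`
#'   (a per-minute cadence is assumed downstream of PPG processing).
#' @param worker a [worker_profile()], or a one-row roster data frame with
#'   `age`, `resting_hr`, `work_intensity` (and optionally
#'   `sensor_body_part`).
#' @param weather data frame with `timestamp`, `ta_c` (and `rh_pct`).
#' @param sys optional prebuilt [fuzzy_risk_system()]; built from the
#'   worker profile when NULL.
#' @param body_part sensor body part for core-temperature estimation.
#' @param hampel_half_window,hampel_k skin-temperature filter parameters.
#' @return List of class `worker_evaluation`: `assessments` (data frame
#'   with `timestamp`, `hr`, `skin_temp`, `ambient`, `core_temp`, `T_min`,
#'   `rl`, `category`, `alert`) and `alerts` (one row per episode).
#' @export
evaluate_worker <- function(samples, worker, weather, sys = NULL,
                            body_part = "hand", hampel_half_window = 5,
                            hampel_k = 3) {
  req <- c("timestamp", "hr_bpm", "skin_temp_c")
  if (!all(req %in% names(samples)))
    stop("samples must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (is.data.frame(worker)) {
    prof <- worker_profile(worker$age[1],
                           resting_hr = if ("resting_hr" %in% names(worker))
                             worker$resting_hr[1] else 60,
                           work_intensity = as.character(
                             worker$work_intensity[1]))
    if ("sensor_body_part" %in% names(worker) &&
        missing(body_part))
      body_part <- as.character(worker$sensor_body_part[1])
  } else prof <- worker
  stopifnot(inherits(prof, "worker_profile"))
  if (is.null(sys)) sys <- fuzzy_risk_system(prof)
  ts <- samples$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  o <- order(ts)
  ts <- ts[o]
  hr <- samples$hr_bpm[o]
  skin_raw <- samples$skin_temp_c[o]
  n <- length(ts)

  if (n >= 2 * hampel_half_window + 1) {
    med_dt <- stats::median(diff(as.numeric(ts)))
    tr <- hampel_filter_temp(signal_trace(skin_raw, fs = 1 / med_dt, t0 = ts[1]),
                             half_window = hampel_half_window, k = hampel_k)
    skin <- tr$values
  } else skin <- skin_raw

  wts <- weather$timestamp
  if (!inherits(wts, "POSIXct")) wts <- as.POSIXct(wts, tz = "UTC")
  idx <- vapply(as.numeric(ts), function(tt)
    which.min(abs(as.numeric(wts) - tt)), integer(1))
  gap <- abs(as.numeric(wts[idx]) - as.numeric(ts)) / 60
  if (any(gap > 90))
    stop(sprintf(
      "no weather sample within 90 min of device sample(s) starting %s",
      format(ts[which(gap > 90)[1]])), call. = FALSE)
  ambient <- weather$ta_c[idx]
  core <- estimate_core_temperature(skin, ambient, part = body_part)

  abnormal <- vapply(seq_len(n), function(i) {
    mu <- evaluate_memberships(sys, list(h = hr[i], ct = core[i], t = 0))
    .dominant_set(mu$hr) != "Normal" || .dominant_set(mu$ct) != "Normal"
  }, logical(1))
  T_min <- track_abnormal_duration(ts, abnormal)

  res <- predict(sys, data.frame(h = hr, ct = core, t = T_min))
  assess <- data.frame(timestamp = ts, hr = hr, skin_temp = skin,
                       ambient = ambient, core_temp = core, T_min = T_min,
                       rl = res$rl, category = res$category,
                       alert = res$alert, stringsAsFactors = FALSE)

  in_ep <- FALSE
  alerts <- list()
  for (i in seq_len(n)) {
    if (assess$alert[i] && !in_ep) {
      in_ep <- TRUE
      alerts[[length(alerts) + 1]] <- data.frame(
        timestamp = ts[i], category = as.character(assess$category[i]),
        rl = assess$rl[i],
        reason = sprintf("HR %.0f bpm, core %.1f degC, abnormal %d min",
                         hr[i], core[i], round(T_min[i])),
        stringsAsFactors = FALSE)
    } else if (!assess$alert[i]) in_ep <- FALSE
  }
  alerts <- if (length(alerts)) do.call(rbind, alerts) else
    data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
               category = character(), rl = numeric(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(assessments = assess, alerts = alerts, profile = prof),
            class = "worker_evaluation")
}

#' @export
print.worker_evaluation <- function(x, ...) {
  a <- x$assessments
  cat(sprintf(
    "<worker_evaluation> %d samples, RL %.1f-%.1f, %d alert episode(s)\n",
    nrow(a), min(a$rl), max(a$rl), nrow(x$alerts)))
  print(table(a$category))
  invisible(x)
}

#' Graded-exercise-test error report
#'
#' Absolute percentage error per stage between a reference (treadmill GXT)
#' heart-rate series and the device's, with per-subject mean and maximum
#' and the overall mean — the indoor-validation statistic.
#'
#' @param reference numeric reference heart rates, bpm.
#' @param device numeric device heart rates, bpm (same length).
#' @param subject optional subject labels (same length); a single subject
#'   is assumed when omitted.
#' @return Object of class `gxt_error_report`: `errors` (per-row data
#'   frame with `pct_error`), `by_subject` (mean and max per subject) and
#'   `overall_mean`.
#' @examples
#' gxt_error_report(c(100, 120), c(101, 120))
#' @export
gxt_error_report <- function(reference, device, subject = NULL) {
  if (length(reference) != length(device))
    stop("reference and device must have equal length", call. = FALSE)
  if (any(reference <= 0)) stop("reference rates must be positive",
                                call. = FALSE)
  if (is.null(subject)) subject <- rep("subject 1", length(reference))
  pct <- abs(device - reference) / reference * 100
  errors <- data.frame(subject = subject, reference = reference,
                       device = device, pct_error = pct,
                       stringsAsFactors = FALSE)
  means <- tapply(pct, subject, mean)
  maxs <- tapply(pct, subject, max)
  by_subject <- data.frame(subject = names(means),
                           mean_pct_error = as.numeric(means),
                           max_pct_error = as.numeric(maxs),
                           stringsAsFactors = FALSE)
  structure(list(errors = errors, by_subject = by_subject,
                 overall_mean = mean(pct)),
            class = "gxt_error_report")
}

#' @export
print.gxt_error_report <- function(x, ...) {
  cat("GXT vs device heart-rate error\n")
  b <- x$by_subject
  b$mean_pct_error <- round(b$mean_pct_error, 3)
  b$max_pct_error <- round(b$max_pct_error, 3)
  print(b, row.names = FALSE)
  cat(sprintf("overall mean: %.3f%%\n", x$overall_mean))
  invisible(x)
}

#' Indoor validation against the packaged GXT table
#'
#' Runs [gxt_error_report()] on the packaged treadmill-test fixture (three
#' subjects, rest plus eight stages of the modified Balke protocol) or on a
#' user-supplied CSV with columns `subject,stage,gxt_bpm,pwb_bpm`.
#'
#' @param path CSV path; the packaged table when NULL.
#' @return A [gxt_error_report()].
#' @export
validate_gxt_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gxt_table8.csv", package = "heatwatch",
                        mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "gxt_bpm", "pwb_bpm")
  if (!all(req %in% names(d)))
    stop("table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  gxt_error_report(d$gxt_bpm, d$pwb_bpm, subject = d$subject)
}
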