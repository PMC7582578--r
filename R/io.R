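# Readers and writers for the plain-text dialects shared by the modules:
# weather CSV, roster CSV, device-stream CSV / JSON-lines, assessment CSV,
# alert JSON-lines, run manifests.

# Parse ISO-8601-ish timestamps; unparseable entries become NA (callers
# decide whether NA is an error or a countable malformed row).
.parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  fmts <- c("%Y-%m-%dT%H:%M:%OS%z", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (f in fmts) {
    if (!anyNA(out) || all(is.na(x))) break
    p <- as.POSIXct(strptime(x, f, tz = "UTC"))
    fill <- is.na(out) & !is.na(p)
    out[fill] <- p[fill]
  }
  out
}

.fmt_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S%z")

#' Read / write weather CSV
#'
#' Columns `timestamp,ta_c,rh_pct`, ISO-8601 timestamps.
#'
#' @param path file path.
#' @param weather data frame with `timestamp`, `ta_c`, `rh_pct`.
#' @return `read_weather_csv` returns the parsed data frame.
#' @export
read_weather_csv <- function(path) {
  if (!file.exists(path)) stop("weather file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("timestamp", "ta_c", "rh_pct")
  if (!all(req %in% names(d)))
    stop("weather CSV must have columns ", paste(req, collapse = ","),
         call. = FALSE)
  d$timestamp <- .parse_ts(d$timestamp)
  d
}

#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(weather, path) {
  weather$timestamp <- .fmt_ts(weather$timestamp)
  utils::write.csv(weather, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write worker roster CSV
#' @param path file path.
#' @param roster roster data frame (see [simulate_scenario()] for fields).
#' @export
read_roster_csv <- function(path) {
  if (!file.exists(path)) stop("roster file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"worker_id" %in% names(d))
    stop("roster must have a worker_id column", call. = FALSE)
  if (anyDuplicated(d$worker_id))
    stop("duplicate worker_id in roster", call. = FALSE)
  d
}

#' @rdname read_roster_csv
#' @export
write_roster_csv <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a device-sample stream
#'
#' CSV or JSON-lines (chosen by extension: `.jsonl`/`.ndjson` vs anything
#' else) with columns `timestamp,worker_id,hr_bpm,skin_temp_c,lat,lon,
#' acc_x,acc_y,acc_z` (`ppg` chunks may replace `hr_bpm` upstream).
#'
#' @param path file path.
#' @param stream device-sample data frame.
#' @export
read_device_stream <- function(path) {
  if (!file.exists(path)) stop("stream file not found: ", path, call. = FALSE)
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    d <- do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(d) && "timestamp" %in% names(d))
    d$timestamp <- .parse_ts(d$timestamp)
  d
}

#' @rdname read_device_stream
#' @export
write_device_stream <- function(stream, path) {
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    stream$timestamp <- .fmt_ts(stream$timestamp)
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(stream)))
      writeLines(jsonlite::toJSON(as.list(stream[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA), con)
  } else {
    stream$timestamp <- .fmt_ts(stream$timestamp)
    utils::write.csv(stream, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write assessment outputs
#'
#' OHS assessments go to `timestamp,tw_c,tci_raw,weight,tci,stage,action`;
#' worker assessments to `timestamp,worker_id,hr,core_temp,T_min,rl,
#' category,alert`.
#'
#' @param assessment an `ohs_assessment` data frame.
#' @param path file path.
#' @export
write_ohs_csv <- function(assessment, path) {
  d <- as.data.frame(assessment)
  d <- d[, c("timestamp", "tw_c", "tci_raw", "weight", "tci", "stage",
             "action")]
  d$timestamp <- .fmt_ts(d$timestamp)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @param evaluations named list of `worker_evaluation` objects (names are
#'   worker ids).
#' @rdname write_ohs_csv
#' @export
write_assessments_csv <- function(evaluations, path) {
  rows <- lapply(names(evaluations), function(id) {
    a <- evaluations[[id]]$assessments
    data.frame(timestamp = .fmt_ts(a$timestamp), worker_id = id,
               hr = a$hr, core_temp = round(a$core_temp, 3),
               T_min = round(a$T_min, 2), rl = round(a$rl, 3),
               category = as.character(a$category), alert = a$alert,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write alerts as JSON-lines
#' @inheritParams write_assessments_csv
#' @param path file path.
#' @export
write_alerts_jsonl <- function(evaluations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(evaluations)) {
    al <- evaluations[[id]]$alerts
    for (i in seq_len(nrow(al)))
      writeLines(jsonlite::toJSON(list(
        worker_id = id, timestamp = .fmt_ts(al$timestamp[i]),
        category = al$category[i], rl = round(al$rl[i], 3),
        reason = al$reason[i]), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seed and package/R versions next to a run's
#' outputs so the run can be reproduced byte-identically.
#'
#' @param config named list of run parameters.
#' @param seed integer seed used for the run (NA if none).
#' @param path output path (JSON).
#' @export
write_manifest <- function(config, seed, path) {
  jsonlite::write_json(list(
    config = config, seed = seed,
    package = as.character(utils::packageVersion("heatwatch")),
    r_version = R.version.string,
    written = .fmt_ts(Sys.time())), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
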