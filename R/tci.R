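# Group-level heat assessment: wet-bulb temperature, thermal comfort index
# (TCI), time-of-day/environment correction weights, five-stage classification.

#' Wet-bulb temperature from dry-bulb temperature and relative humidity
#'
#' Stull-type closed-form psychrometric approximation, valid for standard
#' sea-level pressure. Accurate to a few tenths of a degree over ordinary
#' outdoor conditions; a warning is issued outside the stated validity region
#' ta in \[-20, 50\] degC.
#'
#' @param ta dry-bulb air temperature, degC.
#' @param rh relative humidity, percent in \[0, 100\].
#' @return Wet-bulb temperature, degC (vectorized).
#' @examples
#' wet_bulb_temperature(20, 50)   # ~13.7
#' @export
wet_bulb_temperature <- function(ta, rh) {
  if (!is.numeric(ta) || !is.numeric(rh) || anyNA(ta) || anyNA(rh) ||
      any(!is.finite(ta)) || any(!is.finite(rh)))
    stop("ta and rh must be finite numeric", call. = FALSE)
  if (any(rh < 0 | rh > 100))
    stop("rh must be in [0, 100]", call. = FALSE)
  if (any(ta < -20 | ta > 50))
    warning("ta outside the approximation's validity region [-20, 50] degC")
  ta * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(ta + rh) - atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) - 4.686035
}

#' Raw thermal comfort index
#'
#' Quadratic polynomial in wet-bulb and dry-bulb temperature used by the KMA
#' thermal comfort index (a WBGT-derived heat-stress index), before any
#' environment/time-of-day correction weight.
#'
#' @param tw wet-bulb temperature, degC.
#' @param ta dry-bulb temperature, degC.
#' @return Index value (vectorized).
#' @examples
#' tci_raw(0, 0)    # the intercept, -0.24418
#' tci_raw(wet_bulb_temperature(33, 60), 33)
#' @export
tci_raw <- function(tw, ta) {
  if (!is.numeric(tw) || !is.numeric(ta) ||
      any(!is.finite(tw)) || any(!is.finite(ta)))
    stop("tw and ta must be finite numeric", call. = FALSE)
  -0.24418 + 0.553991 * tw + 0.455346 * ta - 0.00217 * tw^2 +
    0.002782 * tw * ta
}

# KMA correction weights by 3-hour slot and target environment.
.tci_weights <- local({
  m <- rbind(
    `3`  = c(0,    1.0, 0,   0,   0.3, 1.2, 0),
    `6`  = c(0,    0,   0,   0,   0.5, 1.0, 0),
    `9`  = c(2.9,  0.7, 0.1, 2.3, 1.2, 1.3, 1.7),
    `12` = c(2.5,  1.7, 0.5, 4.0, 1.4, 1.6, 2.2),
    `15` = c(1.2,  0.9, 1.1, 4.0, 1.3, 1.2, 1.0),
    `18` = c(-0.9, 0.3, 0.6, 2.1, 0.9, 0.7, 0),
    `21` = c(0,    5.0, 0,   1.0, 0.5, 1.4, 0),
    `24` = c(0,    2.5, 0,   0.5, 0.3, 1.2, 0))
  colnames(m) <- c("children", "heat_vulnerable_area", "farming_area",
                   "greenhouse", "road", "construction_site", "shipyard")
  m
})

#' Target environments with TCI correction weights
#'
#' @return Character vector of the seven supported site-environment names.
#' @export
site_environments <- function() colnames(.tci_weights)

#' TCI correction weight table
#'
#' The full table of time-of-day correction weights: one row per 3-hour slot
#' (03, 06, ..., 24 local time), one column per target environment. Weights
#' may be negative (evening shading for children).
#'
#' @return Data frame with a `slot_hour` column and one column per
#'   environment.
#' @export
tci_weight_table <- function() {
  data.frame(slot_hour = as.integer(rownames(.tci_weights)), .tci_weights,
             row.names = NULL, check.names = FALSE)
}

#' Time-of-day TCI correction weight
#'
#' Looks up the correction weight for a site environment at the 3-hour slot
#' nearest to the given hour (the table is published at 3-hour resolution;
#' hour 0 maps to the 24 h slot).
#'
#' @param hour hour of day, 0-23 (local site time).
#' @param env one of [site_environments()].
#' @return Correction weight (additive, index units).
#' @examples
#' time_of_day_weight(12, "construction_site")  # 1.6
#' @export
time_of_day_weight <- function(hour, env) {
  env <- match.arg(env, site_environments())
  if (!is.numeric(hour) || any(!is.finite(hour)) ||
      any(hour < 0 | hour > 23))
    stop("hour must be in [0, 23]", call. = FALSE)
  slot <- 3 * round(hour / 3)
  slot[slot == 0] <- 24
  unname(.tci_weights[as.character(slot), env])
}

.stage_levels <- c("Attention", "Concern", "Caution", "Warning", "Severe")

.stage_actions <- c(
  Severe  = paste("All workers should stop working immediately and rest in",
                  "a cool environment until further notice"),
  Warning = "All workers should preferably stop working as soon as it is possible",
  Caution = "Need to reduce work time or workload and take breaks frequently",
  Concern = "Attention should be given to those who are vulnerable to heat dissipation",
  Attention = "")

#' Classify a TCI value into the five heat-stress stages
#'
#' Partition of the index into Severe (above 30), Warning (28, 30],
#' Caution (25, 28], Concern (21, 25] and Attention (at or below 21),
#' with the recommended responsive action for outdoor work environments.
#' Boundaries are half-open, closed on the upper end, so the transition into
#' the work-stoppage stage sits strictly above 30.
#'
#' @param tci index value (vectorized).
#' @return Data frame with columns `tci`, `stage` (ordered factor,
#'   Attention < ... < Severe) and `action`.
#' @examples
#' classify_stage(c(20, 26, 31))
#' @export
classify_stage <- function(tci) {
  if (!is.numeric(tci) || any(!is.finite(tci)))
    stop("tci must be finite numeric", call. = FALSE)
  stage <- cut(tci, breaks = c(-Inf, 21, 25, 28, 30, Inf),
               labels = .stage_levels, right = TRUE, ordered_result = TRUE)
  data.frame(tci = tci, stage = stage,
             action = unname(.stage_actions[as.character(stage)]),
             stringsAsFactors = FALSE)
}

#' Full heat assessment of weather samples
#'
#' Composes wet-bulb temperature, the raw index, the additive time-of-day
#' correction for the site environment, and stage classification; all
#' intermediate values are retained.
#'
#' @param weather data frame with columns `timestamp` (POSIXct or ISO-8601
#'   character), `ta_c` and `rh_pct`.
#' @param env one of [site_environments()].
#' @return Data frame of class `ohs_assessment` with columns `timestamp`,
#'   `ta_c`, `rh_pct`, `tw_c`, `tci_raw`, `weight`, `tci`, `stage`, `action`.
#' @examples
#' w <- data.frame(timestamp = as.POSIXct("2020-08-01 12:00", tz = "UTC"),
#'                 ta_c = 33, rh_pct = 60)
#' ohs_assess(w, "construction_site")
#' @export
ohs_assess <- function(weather, env) {
  env <- match.arg(env, site_environments())
  req <- c("timestamp", "ta_c", "rh_pct")
  if (!all(req %in% names(weather)))
    stop("weather must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  ts <- weather$timestamp
  if (!inherits(ts, "POSIXct"))
    ts <- as.POSIXct(ts, tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in weather data", call. = FALSE)
  ta <- weather$ta_c
  rh <- weather$rh_pct
  if (any(ta < -40 | ta > 60))
    stop("ta_c outside plausible range [-40, 60]", call. = FALSE)
  tw <- wet_bulb_temperature(ta, rh)
  raw <- tci_raw(tw, ta)
  hour <- as.integer(format(ts, "%H"))
  wgt <- time_of_day_weight(hour, env)
  cls <- classify_stage(raw + wgt)
  out <- data.frame(timestamp = ts, ta_c = ta, rh_pct = rh, tw_c = tw,
                    tci_raw = raw, weight = wgt, tci = raw + wgt,
                    stage = cls$stage, action = cls$action,
                    stringsAsFactors = FALSE)
  class(out) <- c("ohs_assessment", "data.frame")
  attr(out, "env") <- env
  out
}

#' @export
print.ohs_assessment <- function(x, ...) {
  cat(sprintf("Heat assessment (%s), %d sample(s)\n", attr(x, "env"), nrow(x)))
  y <- as.data.frame(x)
  y$action <- NULL
  y$tw_c <- round(y$tw_c, 2); y$tci_raw <- round(y$tci_raw, 2)
  y$tci <- round(y$tci, 2)
  print(utils::head(y, 10), row.names = FALSE)
  if (nrow(y) > 10) cat("... (", nrow(y) - 10, " more rows)\n", sep = "")
  invisible(x)
}
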