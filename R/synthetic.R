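# Seeded generators for device streams, weather traces and treadmill-test
# sessions with known ground truth, so every processing stage can be scored
# without external data. All generators are pure functions of their
# arguments and the seed.

#' Synthetic pulsatile PPG trace with ground truth
#'
#' A periodic asymmetric raised-cosine pulse (fast systolic rise, slower
#' decay, both scaled to the instantaneous beat period) at a
#' piecewise-constant target heart rate, plus sub-0.5 Hz baseline wander,
#' white noise at the stated SNR and optional saturating clip artifacts.
#' Morphological realism beyond what rate estimation needs is not
#' attempted.
#'
#' @param hr_profile single bpm value, or data frame with `t_start_s` and
#'   `bpm` for piecewise-constant targets (each in \[40, 220\]).
#' @param duration_s trace length, seconds.
#' @param fs sampling rate, Hz (>= 25).
#' @param snr_db white-noise signal-to-noise ratio, dB; `Inf` for clean.
#' @param artifact_frac fraction of samples replaced by saturation
#'   artifacts (short clipped bursts).
#' @param seed integer seed; the trace is a pure function of the arguments.
#' @return A [signal_trace()] with attributes `beats` (ground-truth pulse
#'   peak times, s), `artifacts` (indices of artifact samples) and
#'   `hr_true` (function mapping time to target bpm).
#' @examples
#' tr <- generate_ppg(72, duration_s = 30, seed = 1)
#' length(attr(tr, "beats"))
#' @export
generate_ppg <- function(hr_profile, duration_s = 60, fs = 50,
                         snr_db = 20, artifact_frac = 0, seed = 1) {
  if (fs < 25) stop("fs must be >= 25 Hz", call. = FALSE)
  if (is.numeric(hr_profile) && is.null(dim(hr_profile)))
    hr_profile <- data.frame(t_start_s = 0, bpm = hr_profile[1])
  if (any(hr_profile$bpm < 40 | hr_profile$bpm > 220))
    stop("hr targets must be in [40, 220]", call. = FALSE)
  hr_at <- function(t) {
    i <- findInterval(t, hr_profile$t_start_s)
    hr_profile$bpm[pmax(i, 1)]
  }
  set.seed(seed)
  # beat onsets by stepping through instantaneous periods
  onsets <- numeric(0)
  tb <- 0
  while (tb < duration_s) {
    onsets <- c(onsets, tb)
    tb <- tb + 60 / hr_at(tb)
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  peaks <- numeric(0)
  for (tb in onsets) {
    per <- 60 / hr_at(tb)
    rise <- 0.3 * per
    fall <- 0.45 * per
    i <- which(t >= tb & t < tb + rise + fall)
    u <- t[i] - tb
    pulse <- ifelse(u < rise, 0.5 * (1 - cos(pi * u / rise)),
                    0.5 * (1 + cos(pi * (u - rise) / fall)))
    x[i] <- x[i] + pulse
    peaks <- c(peaks, tb + rise)
  }
  peaks <- peaks[peaks < duration_s]
  # baseline wander below the 0.5 Hz passband edge
  x <- x + 0.3 * sin(2 * pi * 0.2 * t + stats::runif(1, 0, 2 * pi)) +
    0.15 * sin(2 * pi * 0.08 * t + stats::runif(1, 0, 2 * pi))
  if (is.finite(snr_db)) {
    p_sig <- mean((x - mean(x))^2)
    x <- x + stats::rnorm(n, sd = sqrt(p_sig / 10^(snr_db / 10)))
  }
  artifacts <- integer(0)
  if (artifact_frac > 0) {
    n_art <- round(artifact_frac * n)
    burst <- max(1L, round(0.06 * fs))   # ~60 ms clipped bursts
    starts <- sample.int(n - burst, max(1L, round(n_art / burst)))
    artifacts <- sort(unique(unlist(lapply(starts, function(s)
      s:(s + burst - 1)))))
    x[artifacts] <- 5  # saturated amplitude, far outside the pulse range
  }
  out <- signal_trace(x, fs)
  attr(out, "beats") <- peaks
  attr(out, "artifacts") <- artifacts
  attr(out, "hr_true") <- hr_at
  out
}

#' Synthetic skin-temperature trace with labelled outlier spikes
#'
#' Baseline plus a bounded random walk (physiological drift) and white
#' sensor noise, with spikes of the stated magnitude injected at random
#' positions; spike positions are returned as ground-truth labels.
#'
#' @param baseline_c starting temperature, degC, in \[30, 40\].
#' @param duration_min trace length, minutes (one sample per minute).
#' @param drift_sd_c per-step standard deviation of the bounded walk.
#' @param noise_sd_c standard deviation of white measurement noise, degC.
#' @param spike_rate fraction of samples replaced by spikes.
#' @param spike_mag_c spike magnitude, degC (sign randomized, mostly up).
#' @param seed integer seed.
#' @param t0 start time.
#' @return A [signal_trace()] at 1/60 Hz with attribute `spikes` (indices).
#' @export
generate_skin_temp <- function(baseline_c = 35.5, duration_min = 120,
                               drift_sd_c = 0.02, noise_sd_c = 0.002,
                               spike_rate = 0, spike_mag_c = 4, seed = 1,
                               t0 = as.POSIXct("2020-08-01 08:00:00",
                                               tz = "UTC")) {
  if (baseline_c < 30 || baseline_c > 40)
    stop("baseline must be in [30, 40] degC", call. = FALSE)
  set.seed(seed)
  n <- duration_min
  steps <- stats::rnorm(n, sd = drift_sd_c)
  walk <- cumsum(steps)
  # smooth the walk so drift is slow relative to the sensor noise
  if (n >= 9) walk <- stats::filter(walk, rep(1 / 9, 9), circular = TRUE)
  x <- baseline_c + pmin(pmax(as.numeric(walk), -1.5), 1.5)
  if (noise_sd_c > 0) x <- x + stats::rnorm(n, sd = noise_sd_c)
  spikes <- integer(0)
  if (spike_rate > 0) {
    n_spk <- max(1L, round(spike_rate * n))
    spikes <- sort(sample.int(n, n_spk))
    x[spikes] <- x[spikes] +
      spike_mag_c * sample(c(1, 1, 1, -1), n_spk, replace = TRUE)
  }
  out <- signal_trace(x, fs = 1 / 60, t0 = t0)
  attr(out, "spikes") <- spikes
  out
}

#' Synthetic diurnal weather day
#'
#' Hourly dry-bulb temperature following a cosine diurnal cycle peaking in
#' mid-afternoon, with relative humidity in antiphase, plus optional noise.
#'
#' @param date day (Date or character).
#' @param ta_mean_c,ta_amp_c mean and half-range of the temperature cycle.
#' @param rh_mean_pct,rh_amp_pct mean and half-range of the humidity cycle.
#' @param peak_hour hour of maximum temperature (default 15).
#' @param noise_sd standard deviation of additive noise on both series.
#' @param seed integer seed.
#' @return Data frame with `timestamp`, `ta_c`, `rh_pct` (24 hourly rows).
#' @examples
#' w <- generate_weather_day(ta_mean_c = 30, ta_amp_c = 5, seed = 1)
#' @export
generate_weather_day <- function(date = "2020-08-01", ta_mean_c = 28,
                                 ta_amp_c = 4, rh_mean_pct = 60,
                                 rh_amp_pct = 15, peak_hour = 15,
                                 noise_sd = 0, seed = 1) {
  if (ta_mean_c - ta_amp_c < -10 || ta_mean_c + ta_amp_c > 45)
    stop("temperature curve must stay within [-10, 45] degC", call. = FALSE)
  set.seed(seed)
  h <- 0:23
  ta <- ta_mean_c + ta_amp_c * cos(2 * pi * (h - peak_hour) / 24)
  rh <- rh_mean_pct - rh_amp_pct * cos(2 * pi * (h - peak_hour) / 24)
  if (noise_sd > 0) {
    ta <- ta + stats::rnorm(24, sd = noise_sd)
    rh <- rh + stats::rnorm(24, sd = noise_sd)
  }
  rh <- pmin(pmax(rh, 10), 100)
  data.frame(
    timestamp = as.POSIXct(paste(date, sprintf("%02d:00:00", h)), tz = "UTC"),
    ta_c = ta, rh_pct = rh)
}

#' Synthetic graded-exercise-test session
#'
#' Emulates the modified Balke treadmill protocol (fixed speed, slope
#' increasing every minute): a monotone reference heart-rate series over
#' rest plus eight stages, and a paired device series equal to the
#' reference plus integer jitter in {-1, 0, 1} — the discrepancy pattern a
#' validated wearable shows against the treadmill reference.
#'
#' @param rest_hr resting heart rate, bpm.
#' @param hr_per_stage mean heart-rate increment per stage, bpm.
#' @param jitter maximum absolute device-reference discrepancy (0 or 1).
#' @param seed integer seed.
#' @return Data frame with `stage` ("Rest", "Stage 1"..."Stage 8"),
#'   `reference` and `device` bpm.
#' @export
generate_balke_session <- function(rest_hr = 85, hr_per_stage = 11,
                                   jitter = 1, seed = 1) {
  set.seed(seed)
  inc <- pmax(1, round(hr_per_stage +
                         c(stats::rnorm(1, 10, 3), stats::rnorm(7, 0, 2))))
  reference <- cumsum(c(rest_hr, inc))
  device <- reference + sample((-jitter):jitter, 9, replace = TRUE)
  data.frame(stage = c("Rest", paste("Stage", 1:8)),
             reference = reference, device = device,
             stringsAsFactors = FALSE)
}

#' Simulate a full monitoring scenario
#'
#' Produces everything one monitoring run consumes: a worker roster, a
#' per-minute device stream (heart rate from the worker's scripted profile
#' plus measurement noise, drifting skin temperature with spikes, a
#' stationary GPS fix with small scatter, idle accelerometer) and an hourly
#' weather day. Scripted heart-rate/skin-temperature episodes make the
#' downstream risk ground truth known by construction.
#'
#' @param n_workers number of workers.
#' @param duration_min stream length, minutes.
#' @param hr_profiles list (length `n_workers`, recycled) of data frames
#'   `t_start_min`, `bpm` scripting each worker's target heart rate.
#' @param skin_profiles list (recycled) of data frames `t_start_min`,
#'   `temp_c` scripting skin-temperature targets.
#' @param hr_noise_sd measurement noise on the reported heart rate, bpm.
#' @param spike_rate skin-temperature outlier fraction.
#' @param weather_args list of arguments for [generate_weather_day()];
#'   the default is a hot, stable summer day (32-34 degC) against which a
#'   resting skin temperature of 35.2 degC maps to a normal core
#'   temperature under the hand-worn gradient model.
#' @param ages,work_intensities roster fields (recycled).
#' @param seed integer seed.
#' @return List with `roster`, `stream` (device-sample data frame) and
#'   `weather`.
#' @export
simulate_scenario <- function(n_workers = 2, duration_min = 60,
                              hr_profiles = list(
                                data.frame(t_start_min = 0, bpm = 72)),
                              skin_profiles = list(
                                data.frame(t_start_min = 0, temp_c = 35.2)),
                              hr_noise_sd = 1, spike_rate = 0.01,
                              weather_args = list(ta_mean_c = 33,
                                                  ta_amp_c = 1),
                              ages = c(32, 41, 50),
                              work_intensities = c("medium", "high", "light"),
                              seed = 1) {
  set.seed(seed)
  weather <- do.call(generate_weather_day,
                     c(weather_args, list(seed = seed + 1000L)))
  day <- format(weather$timestamp[1], "%Y-%m-%d")
  t0 <- as.POSIXct(paste(day, "09:00:00"), tz = "UTC")
  roster <- data.frame(
    worker_id = sprintf("W%02d", seq_len(n_workers)),
    name = paste("Worker", seq_len(n_workers)),
    age = rep_len(ages, n_workers),
    height_cm = round(rep_len(c(172, 168, 176), n_workers)),
    weight_kg = round(rep_len(c(77, 73, 76), n_workers)),
    blood_type = rep_len(c("A", "B", "O"), n_workers),
    resting_hr = rep_len(60, n_workers),
    work_intensity = rep_len(work_intensities, n_workers),
    device_id = sprintf("PWB%03d", seq_len(n_workers)),
    sensor_body_part = "hand",
    stringsAsFactors = FALSE)
  streams <- lapply(seq_len(n_workers), function(i) {
    hp <- hr_profiles[[(i - 1) %% length(hr_profiles) + 1]]
    sp <- skin_profiles[[(i - 1) %% length(skin_profiles) + 1]]
    mins <- 0:(duration_min - 1)
    hr_target <- hp$bpm[pmax(findInterval(mins, hp$t_start_min), 1)]
    skin_target <- sp$temp_c[pmax(findInterval(mins, sp$t_start_min), 1)]
    st <- generate_skin_temp(baseline_c = sp$temp_c[1],
                             duration_min = duration_min,
                             spike_rate = spike_rate,
                             seed = seed + 10L * i, t0 = t0)
    skin <- st$values - sp$temp_c[1] + skin_target
    skin[attr(st, "spikes")] <- st$values[attr(st, "spikes")] -
      sp$temp_c[1] + skin_target[attr(st, "spikes")]
    data.frame(
      timestamp = t0 + 60 * mins,
      worker_id = roster$worker_id[i],
      hr_bpm = round(hr_target + stats::rnorm(duration_min, sd = hr_noise_sd), 1),
      skin_temp_c = round(skin, 2),
      lat = 37.20 + stats::rnorm(duration_min, sd = 2e-5),
      lon = 126.97 + stats::rnorm(duration_min, sd = 2e-5),
      acc_x = round(stats::rnorm(duration_min, sd = 0.05), 3),
      acc_y = round(stats::rnorm(duration_min, sd = 0.05), 3),
      acc_z = round(1 + stats::rnorm(duration_min, sd = 0.05), 3),
      stringsAsFactors = FALSE)
  })
  list(roster = roster, stream = do.call(rbind, streams), weather = weather)
}
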