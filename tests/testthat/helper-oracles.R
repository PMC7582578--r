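# Independent oracles used to cross-check the implementation.

# Wet-bulb temperature by numerically solving the ventilated-psychrometer
# equation with Magnus saturation vapour pressure at standard pressure —
# independent of the closed-form approximation under test.
oracle_wet_bulb <- function(ta, rh, p_hpa = 1013.25) {
  es <- function(t) 6.112 * exp(17.62 * t / (243.12 + t))
  e <- es(ta) * rh / 100
  f <- function(tw) es(tw) - 6.6e-4 * p_hpa * (ta - tw) * (1 + 0.00115 * tw) - e
  stats::uniroot(f, c(-40, ta + 0.01), tol = 1e-10)$root
}

# Plain-loop Mamdani inference over the constructed system: per-rule
# strengths computed clause by clause, aggregation point by point on a
# finer grid, centroid by the trapezoidal rule. Shares only the system's
# membership functions with the implementation.
oracle_mamdani <- function(sys, h, ct, t, w = NULL) {
  if (is.null(w)) w <- sys$profile$w
  crisp <- list(hr = h, ct = ct, w = w, t = t)
  mu <- list()
  for (v in names(sys$vars)) {
    u <- sys$vars[[v]]$universe
    xv <- min(max(crisp[[v]], u[1]), u[2])
    mu[[v]] <- sapply(sys$vars[[v]]$sets, function(f) f(xv))
  }
  grid <- seq(0, 40, by = 0.005)
  agg <- rep(0, length(grid))
  for (rule in sys$rules) {
    degs <- c()
    for (v in names(rule$`if`)) {
      d <- mu[[v]][[rule$`if`[[v]]]]
      if (v %in% rule$not) d <- 1 - d
      degs <- c(degs, d)
    }
    s <- if (identical(rule$op, "or")) max(degs) else min(degs)
    if (s > 0) agg <- pmax(agg, pmin(sys$out_sets[[rule$then]](grid), s))
  }
  # trapezoidal centroid
  wts <- c(0.5, rep(1, length(grid) - 2), 0.5)
  sum(wts * agg * grid) / sum(wts * agg)
}

# Amplitude of a sinusoid in a filtered trace, by FFT at the tone bin.
fft_amplitude <- function(x, fs, freq) {
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  bin <- round(freq * n / fs) + 1
  max(sp[max(1, bin - 1):min(n, bin + 1)])
}

# Ground-truth windowed heart rate from generator beat times, using the
# same rate definition as the estimator.
truth_hr_in_window <- function(beats, t_lo, t_hi) {
  b <- beats[beats >= t_lo & beats < t_hi]
  if (length(b) < 2) return(NA_real_)
  60 * (length(b) - 1) / (max(b) - min(b))
}
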