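# Mamdani fuzzy risk engine: pi-type input memberships anchored at the
# published physiological breakpoints, a Karvonen-anchored heartbeat
# partition, min/max rule semantics and centroid defuzzification onto a
# risk level in [0, 40] with four categories.

#' Age-predicted maximum heart rate
#'
#' `HRmax = 207 - 0.7 * age`, chosen for its wide validated age range.
#'
#' @param age age in years, in \[15, 80\].
#' @return Maximum heart rate, bpm.
#' @examples
#' hr_max(30)  # 186
#' @export
hr_max <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 15 | age > 80))
    stop("age must be in [15, 80]", call. = FALSE)
  207 - 0.7 * age
}

#' Karvonen caution threshold
#'
#' Target heart rate from heart-rate reserve:
#' `(HRmax - resting HR) * intensity + resting HR`. Anchors the lower edge
#' of the Caution fuzzy set for the heartbeat variable.
#'
#' @param hrmax maximum heart rate, bpm.
#' @param normal_hb resting ("normal") heart rate, bpm; must be below
#'   `hrmax`.
#' @param w work-intensity fraction in (0, 1\].
#' @return Threshold heart rate, bpm.
#' @examples
#' caution_threshold(186, 60, 0.5)  # 123
#' @export
caution_threshold <- function(hrmax, normal_hb, w) {
  if (any(normal_hb >= hrmax))
    stop("normal_hb must be below hrmax", call. = FALSE)
  if (any(w <= 0 | w > 1))
    stop("w must be in (0, 1]", call. = FALSE)
  (hrmax - normal_hb) * w + normal_hb
}

# work-intensity class -> crisp fraction (inverse scale as published:
# light work tolerates a higher fraction of heart-rate reserve).
.intensity_value <- c(light = 0.75, medium = 0.5, high = 0.25)

#' Worker profile
#'
#' @param age years, in \[15, 80\].
#' @param resting_hr resting heart rate, bpm (default 60, the lower normal
#'   bound).
#' @param work_intensity one of `"light"`, `"medium"`, `"high"`.
#' @return List of class `worker_profile` with the derived `hrmax`,
#'   intensity fraction `w` and Karvonen caution threshold.
#' @export
worker_profile <- function(age, resting_hr = 60,
                           work_intensity = c("medium", "light", "high")) {
  work_intensity <- match.arg(work_intensity)
  hrmax <- hr_max(age)
  if (resting_hr <= 0 || resting_hr >= hrmax)
    stop("resting_hr must be positive and below hrmax", call. = FALSE)
  w <- .intensity_value[[work_intensity]]
  tc <- caution_threshold(hrmax, resting_hr, w)
  structure(list(age = age, resting_hr = resting_hr,
                 work_intensity = work_intensity, w = w,
                 hrmax = hrmax, caution = tc),
            class = "worker_profile")
}

#' @export
print.worker_profile <- function(x, ...) {
  cat(sprintf(
    "<worker_profile> age %g, resting HR %g bpm, %s intensity (w=%.2f)\n",
    x$age, x$resting_hr, x$work_intensity, x$w))
  cat(sprintf("  HRmax %.1f bpm, Karvonen caution threshold %.1f bpm\n",
              x$hrmax, x$caution))
  invisible(x)
}

.rl_levels <- c("Safe", "Concern", "Attention", "Danger")

#' Default fuzzy rule base
#'
#' A complete, monotone reconstruction in two layers. The consequent
#' ladder is: both statuses Normal -> Safe; HR Caution or CT Low ->
#' Concern; HR Danger (above HRmax), CT High or CT Too low -> Attention;
#' CT Too high -> Danger. A heart rate above HRmax alone therefore starts
#' at Attention — which already alerts — rather than jumping straight to
#' Danger, so the severity ladder climbs one category at a time.
#' Core-temperature statuses at Concern severity or above carry their own
#' single-clause rules (an abnormal heartbeat can add severity but a
#' normal one cannot subtract it); heartbeat clauses appear only where
#' they change the consequent. Escalation rules then ADD the next-higher
#' consequent when the abnormal state has persisted into the Attention or
#' Danger time band; a fully normal reading stays Safe regardless of
#' elapsed time. Keeping the base layer free of time clauses means
#' escalation only ever adds higher-severity mass to the aggregate; this
#' layering, together with the minimal antecedents, is what keeps the
#' defuzzified risk level monotone in each input. Two additional rules
#' use OR and NOT logic: a supra-maximal heart rate or hyperthermia above
#' 40 degC carries Danger weight outright whatever the other readings,
#' and high-intensity work with a Caution heartbeat outside the Safe time
#' band is Attention.
#'
#' @return List of rules, each `list(if = list(var = set, ...),
#'   op = "and"|"or", not = character(), then = <output set>)`.
#' @export
default_rule_base <- function() {
  r <- function(.then, ..., op = "and", not = character(0))
    list(`if` = list(...), op = op, not = not, then = .then)
  esc <- function(.then, ...)
    list(r(.then, ..., t = "Attention"), r(.then, ..., t = "Danger"))
  c(list(
      r("Safe",      hr = "Normal",  ct = "Normal"),
      r("Concern",   hr = "Caution", ct = "Normal"),
      r("Attention", hr = "Danger",  ct = "Normal"),
      r("Concern",   ct = "Low"),
      r("Attention", hr = "Danger", ct = "Low"),
      r("Attention", ct = "TooLow"),
      r("Attention", ct = "High"),
      r("Danger",    ct = "TooHigh")),
    esc("Attention", hr = "Caution", ct = "Normal"),
    esc("Danger",    hr = "Danger",  ct = "Normal"),
    esc("Attention", ct = "Low"),
    esc("Danger",    hr = "Danger", ct = "Low"),
    esc("Danger",    ct = "TooLow"),
    esc("Danger",    ct = "High"),
    list(
      r("Danger", hr = "Danger", ct = "TooHigh", op = "or"),
      r("Attention", w = "High", hr = "Caution", t = "Safe", not = "t")))
}

#' Write / read a rule base as YAML
#'
#' The rule base ships as editable data so site policies can be audited and
#' adjusted without touching code.
#'
#' @param rules a rule list as returned by [default_rule_base()].
#' @param path file path.
#' @return `read_rules_yaml` returns the rule list; `write_rules_yaml`
#'   returns `path` invisibly.
#' @export
write_rules_yaml <- function(rules, path) {
  yaml::write_yaml(lapply(rules, function(r) {
    r$not <- as.list(r$not)
    r
  }), path)
  invisible(path)
}

#' @rdname write_rules_yaml
#' @export
read_rules_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    r$not <- as.character(unlist(r$not))
    if (is.null(r$op)) r$op <- "and"
    r
  })
}

#' Build the fuzzy risk system for a worker
#'
#' Constructs the four input variables (heartbeat `hr`, core temperature
#' `ct`, work intensity `w`, abnormal-duration `t`) with pi-type fuzzy
#' sets, the triangular risk-level output sets on \[0, 40\], and the rule
#' base. Heartbeat sets are worker-specific: Normal plateaus up to 99 bpm,
#' Caution is centred on the Karvonen threshold, Danger plateaus from the
#' age-predicted HRmax. Core-temperature plateaus span the published
#' ranges (gaps at 32-33 and 35-36 degC bridged by complementary ramps,
#' plateaus meeting at the shared 38 and 40 degC breakpoints); time sets
#' are anchored at 5/14-15/29-30 min.
#'
#' @param profile a [worker_profile()] (or an age, for convenience).
#' @param rules rule base (default [default_rule_base()]), or a path to a
#'   YAML rules file.
#' @param resolution defuzzification grid step on the output universe
#'   (<= 0.01).
#' @return Object of class `fuzzy_risk_system`.
#' @examples
#' sys <- fuzzy_risk_system(worker_profile(30))
#' predict(sys, data.frame(h = 75, ct = 37, t = 2))
#' @export
fuzzy_risk_system <- function(profile, rules = default_rule_base(),
                              resolution = 0.01) {
  if (is.numeric(profile)) profile <- worker_profile(profile)
  stopifnot(inherits(profile, "worker_profile"))
  if (is.character(rules)) rules <- read_rules_yaml(rules)
  if (resolution > 0.01) stop("resolution must be <= 0.01", call. = FALSE)
  hrmax <- profile$hrmax
  tc <- profile$caution
  # the Karvonen anchor must sit strictly between the normal plateau edge
  # and HRmax for the three sets to tile the universe
  if (tc <= 100 || tc >= hrmax - 1) {
    tc2 <- min(max(tc, 100), hrmax - 1)
    warning(sprintf(
      "caution threshold %.1f clamped to %.1f to stay inside (99, HRmax)",
      tc, tc2))
    tc <- tc2
  }
  vars <- list(
    hr = list(
      universe = c(30, hrmax + 60),
      sets = list(
        Normal  = pi_mf(-Inf, -Inf, 99, tc, name = "Normal"),
        Caution = pi_mf(99, tc, tc, hrmax, name = "Caution"),
        Danger  = pi_mf(tc, hrmax, Inf, Inf, name = "Danger"))),
    # plateaus span the published ranges; ramps bridge the printed gaps
    # (32-33, 35-36) with 0.5 crossovers at the gap midpoints, and
    # adjacent plateaus meet at the shared 38 and 40 degC breakpoints
    ct = list(
      universe = c(28, 44),
      sets = list(
        TooLow  = pi_mf(-Inf, -Inf, 32, 33, name = "TooLow"),
        Low     = pi_mf(32, 33, 35, 36, name = "Low"),
        Normal  = pi_mf(35, 36, 38, 39, name = "Normal"),
        High    = pi_mf(37, 38, 40, 41, name = "High"),
        TooHigh = pi_mf(39, 40, Inf, Inf, name = "TooHigh"))),
    w = list(
      universe = c(0, 1),
      sets = list(
        High   = pi_mf(-Inf, -Inf, 0.25, 0.5, name = "High"),
        Medium = pi_mf(0.25, 0.5, 0.5, 0.75, name = "Medium"),
        Light  = pi_mf(0.5, 0.75, Inf, Inf, name = "Light"))),
    # Safe and Concern plateaus meet at the shared 5 min breakpoint; the
    # 14-15 min gap is bridged by complementary ramps; the Attention and
    # Danger plateaus meet at 29.5 min (mid-gap) so that their union —
    # the escalation trigger — is monotone in elapsed time
    t = list(
      universe = c(0, 120),
      sets = list(
        Safe      = pi_mf(-Inf, -Inf, 5, 6, name = "Safe"),
        Concern   = pi_mf(4, 5, 14, 15, name = "Concern"),
        Attention = pi_mf(14, 15, 29.5, 30.5, name = "Attention"),
        Danger    = pi_mf(28.5, 29.5, Inf, Inf, name = "Danger"))))
  out_sets <- list(
    Safe      = tri_mf(0, 5, 10.5, name = "Safe"),
    Concern   = tri_mf(10, 15.5, 21, name = "Concern"),
    Attention = tri_mf(20, 25.5, 31, name = "Attention"),
    Danger    = tri_mf(30, 35.5, 40, name = "Danger"))
  for (r in rules) {
    for (v in names(r$`if`))
      if (is.null(vars[[v]]) || is.null(vars[[v]]$sets[[r$`if`[[v]]]]))
        stop(sprintf("rule references unknown set %s.%s", v, r$`if`[[v]]),
             call. = FALSE)
    if (!r$then %in% names(out_sets))
      stop("rule consequent must be a risk-level set", call. = FALSE)
  }
  grid <- seq(0, 40, by = resolution)
  structure(list(profile = profile, vars = vars, out_sets = out_sets,
                 out_mu = vapply(out_sets, function(f) f(grid),
                                 numeric(length(grid))),
                 grid = grid, rules = rules),
            class = "fuzzy_risk_system")
}

#' Evaluate membership degrees for one crisp input
#'
#' Inputs are clamped to the variable universes before fuzzification, so
#' out-of-range readings take the edge-set membership.
#'
#' @param sys a [fuzzy_risk_system()].
#' @param x named list or one-row data frame with `h` (bpm), `ct` (degC),
#'   `t` (minutes) and optionally `w` (intensity fraction; defaults to the
#'   profile's).
#' @return Named list (per variable) of named membership-degree vectors.
#' @export
evaluate_memberships <- function(sys, x) {
  stopifnot(inherits(sys, "fuzzy_risk_system"))
  x <- as.list(x)
  if (is.null(x$w)) x$w <- sys$profile$w
  crisp <- c(hr = x$h, ct = x$ct, w = x$w, t = x$t)
  if (anyNA(crisp) || any(!is.finite(unlist(crisp))))
    stop("inputs h, ct, t (and w) must be finite", call. = FALSE)
  out <- list()
  for (v in names(sys$vars)) {
    u <- sys$vars[[v]]$universe
    xv <- min(max(crisp[[v]], u[1]), u[2])
    out[[v]] <- vapply(sys$vars[[v]]$sets, function(f) f(xv), numeric(1))
  }
  out
}

.rule_strength <- function(rule, mu) {
  deg <- vapply(names(rule$`if`), function(v) {
    m <- mu[[v]][[rule$`if`[[v]]]]
    if (v %in% rule$not) 1 - m else m
  }, numeric(1))
  if (identical(rule$op, "or")) max(deg) else min(deg)
}

#' Mamdani inference: crisp risk level from one input
#'
#' Rule evaluation with min/max semantics (AND = min, OR = max,
#' NOT = 1 - mu), min-clipping implication, max aggregation and centroid
#' (centre-of-gravity) defuzzification over the \[0, 40\] output universe.
#'
#' @inheritParams evaluate_memberships
#' @param h heartbeat rate, bpm.
#' @param ct core temperature, degC.
#' @param t abnormal-duration time interval, minutes.
#' @param w work-intensity fraction; defaults to the worker profile's.
#' @return Object of class `risk_assessment`: crisp `rl`, `category`,
#'   `alert` (TRUE for Attention/Danger), the input memberships and the
#'   per-rule firing strengths.
#' @examples
#' sys <- fuzzy_risk_system(worker_profile(30))
#' mamdani_infer(sys, h = 75, ct = 37, t = 2)
#' @export
mamdani_infer <- function(sys, h, ct, t, w = NULL) {
  stopifnot(inherits(sys, "fuzzy_risk_system"))
  mu <- evaluate_memberships(sys, list(h = h, ct = ct, t = t, w = w))
  strength <- vapply(sys$rules, .rule_strength, numeric(1), mu = mu)
  if (all(strength <= 0))
    stop("internal inconsistency: no rule fired", call. = FALSE)
  # max-aggregation commutes with min-clipping per consequent set, so one
  # clip per output set suffices
  cons <- vapply(sys$rules, `[[`, character(1), "then")
  agg <- numeric(length(sys$grid))
  for (k in unique(cons[strength > 0])) {
    s <- max(strength[cons == k])
    agg <- pmax(agg, pmin(sys$out_mu[, k], s))
  }
  rl <- sum(agg * sys$grid) / sum(agg)
  category <- categorize_risk(rl)
  fired <- data.frame(
    rule = seq_along(sys$rules),
    then = vapply(sys$rules, `[[`, character(1), "then"),
    strength = strength)
  structure(list(rl = rl, category = category,
                 alert = category %in% c("Attention", "Danger"),
                 input = list(h = h, ct = ct, t = t,
                              w = if (is.null(w)) sys$profile$w else w),
                 memberships = mu,
                 fired_rules = fired[fired$strength > 0, ]),
            class = "risk_assessment")
}

#' Risk category from a crisp risk level
#'
#' Safe \[0, 10\], Concern (10, 20\], Attention (20, 30\], Danger (30, 40\]
#' (half-open convention over the published integer category bounds).
#'
#' @param rl crisp risk level in \[0, 40\] (vectorized).
#' @return Ordered factor Safe < Concern < Attention < Danger.
#' @export
categorize_risk <- function(rl) {
  if (!is.numeric(rl) || any(!is.finite(rl)) || any(rl < 0 | rl > 40))
    stop("rl must be in [0, 40]", call. = FALSE)
  cut(rl, breaks = c(-Inf, 10, 20, 30, Inf), labels = .rl_levels,
      right = TRUE, ordered_result = TRUE)
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment> RL = %.2f (%s)%s\n", x$rl,
              as.character(x$category), if (x$alert) "  ** ALERT **" else ""))
  cat(sprintf("  input: H=%.1f bpm, CT=%.2f degC, W=%.2f, T=%.1f min\n",
              x$input$h, x$input$ct, x$input$w, x$input$t))
  invisible(x)
}

#' @export
print.fuzzy_risk_system <- function(x, ...) {
  cat("Mamdani fuzzy risk system\n")
  print(x$profile)
  cat(sprintf("  %d rules; output universe [0, 40] at %.3g resolution\n",
              length(x$rules), diff(x$grid[1:2])))
  invisible(x)
}

#' @export
summary.fuzzy_risk_system <- function(object, ...) {
  print(object)
  for (v in names(object$vars)) {
    u <- object$vars[[v]]$universe
    cat(sprintf("  %s on [%g, %g]: %s\n", v, u[1], u[2],
                paste(names(object$vars[[v]]$sets), collapse = ", ")))
  }
  tab <- table(vapply(object$rules, `[[`, character(1), "then"))
  cat("  rule consequents:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(object)
}

#' Predict risk levels for a data frame of inputs
#'
#' @param object a [fuzzy_risk_system()].
#' @param newdata data frame with columns `h`, `ct`, `t` and optionally `w`.
#' @param ... unused.
#' @return `newdata` with `rl`, `category` and `alert` columns appended.
#' @export
predict.fuzzy_risk_system <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata),
            all(c("h", "ct", "t") %in% names(newdata)))
  res <- lapply(seq_len(nrow(newdata)), function(i)
    mamdani_infer(object, h = newdata$h[i], ct = newdata$ct[i],
                  t = newdata$t[i],
                  w = if ("w" %in% names(newdata)) newdata$w[i] else NULL))
  newdata$rl <- vapply(res, `[[`, numeric(1), "rl")
  newdata$category <- factor(vapply(res, function(r)
    as.character(r$category), character(1)), levels = .rl_levels,
    ordered = TRUE)
  newdata$alert <- vapply(res, `[[`, logical(1), "alert")
  newdata
}

#' Plot the membership functions of a fuzzy risk system
#'
#' One panel per variable (four inputs and the risk-level output), drawn
#' with base graphics.
#'
#' @param x a [fuzzy_risk_system()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.fuzzy_risk_system <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panels <- c(x$vars, list(rl = list(universe = c(0, 40), sets = x$out_sets)))
  labs <- c(hr = "Heartbeat (bpm)", ct = "Core temperature (degC)",
            w = "Work intensity", t = "Time interval (min)",
            rl = "Risk level")
  for (v in names(panels)) {
    u <- panels[[v]]$universe
    xx <- seq(u[1], u[2], length.out = 400)
    graphics::plot(NA, xlim = u, ylim = c(0, 1.05), xlab = labs[[v]],
                   ylab = "membership", main = v, ...)
    i <- 0
    for (s in names(panels[[v]]$sets)) {
      i <- i + 1
      graphics::lines(xx, panels[[v]]$sets[[s]](xx), col = i, lwd = 2)
    }
    graphics::legend("right", legend = names(panels[[v]]$sets),
                     col = seq_along(panels[[v]]$sets), lwd = 2, bty = "n",
                     cex = 0.7)
  }
  invisible(x)
}
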