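---
title: "Methods: heat-stress staging and fuzzy physiological risk"
author: "heatwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-stress staging and fuzzy physiological risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatwatch)
```

heatwatch implements the analytics of an IoT heat-stress monitoring
platform for outdoor workers: a group-level heat assessment driven by
weather data, and an individual-level risk engine driven by wearable
physiological streams. This vignette explains the models, the parameters
that matter, the choices made where the published material left the design
open, and what the synthetic-data tests do and do not demonstrate.

## Group-level heat assessment

The thermal comfort index (TCI) is a WBGT-derived heat-stress index used
operationally by the Korean meteorological service. It needs only
dry-bulb temperature $T_a$ (degC) and relative humidity $RH$ (%), both of
which a weather feed provides hourly.

**Wet-bulb temperature.** $T_w$ is computed with the Stull closed-form
psychrometric approximation,

$$T_w = T_a\,\arctan(0.151977\sqrt{RH + 8.313659}) + \arctan(T_a + RH)
  - \arctan(RH - 1.676331) + 0.00391838\,RH^{3/2}\arctan(0.023101\,RH)
  - 4.686035,$$

valid for sea-level pressure, $T_a \in [-20, 50]$ degC (a warning is
issued outside) and accurate to a few tenths of a degree over ordinary
outdoor conditions. The tests check both exact agreement with an
independent evaluation of the closed form and sub-0.5-degC agreement with
an iterative solution of the ventilated-psychrometer equation at
mid-range reference points; near the extremes of its domain the
approximation can deviate from the exact psychrometric solution by up to
about one degree, which is inherent to the closed form.

**Index and weights.** The raw index is the quadratic polynomial
$\mathrm{TCI} = -0.24418 + 0.553991\,T_w + 0.455346\,T_a - 0.00217\,T_w^2
+ 0.002782\,T_w T_a$. A correction weight, tabulated per target
environment (seven categories from children through shipyards) and
3-hour slot of the local day, is then **added** to the raw index. The
additive reading is forced by the table itself: one published entry is
negative (−0.9, children at 18 h), which no multiplicative scheme
accommodates. Hours are mapped to the nearest tabulated slot; hour 0
maps to the 24 h slot.

**Stages.** The weighted index is classified into five stages with
half-open intervals closed on the upper end — Severe $(30,\infty)$,
Warning $(28,30]$, Caution $(25,28]$, Concern $(21,25]$, Attention
$(-\infty,21]$ — so work stoppage begins strictly above 30. The
published ranges overlap at their endpoints; the half-open convention is
ours, and the staged grid test pins the Severe transition exactly at 30.
The Attention stage has no published action text and returns an empty
string.

## Wearable signal processing

**PPG band-pass.** The cardiac band is isolated with a 0.5–4 Hz
band-pass (fundamental heart-rate range 30–240 bpm), realised as an
order-4 Butterworth applied forward–backward (`signal::filtfilt`) so
beat timing is not delayed. Only the band was published; the filter
family, order and zero-phase realisation are our choices, standard for
offline PPG work. The response is flat to within a few percent over
roughly 1–2.5 Hz and rolls off toward the 4 Hz edge; rate estimation
depends on peak positions, not amplitudes, so the roll-off is harmless.

**Threshold filter.** Saturated or clipped samples outside a
configurable amplitude window are masked as artifacts (the device
firmware's own bounds are unknown, so the bounds are arguments, not
constants). Masked samples are linearly interpolated before filtering —
a saturated spike would otherwise be smeared across its neighbourhood by
the filter — and excluded from beat evidence.

**Beat detection and heart rate.** Beats are local maxima with
prominence at least 0.3 times the windowed standard deviation and a
240 ms refractory period (60/250 s, the shortest credible inter-beat
interval). Within non-overlapping windows (default 10 s) the rate is
$60(n-1)/\Delta t$ over the $n$ detected beats' span; windows with fewer
than two beats are flagged invalid rather than reported. No beat
detection procedure was published; this one is deliberately minimal.

**Skin-temperature outliers.** Contact-loss spikes are removed with a
Hampel filter: a sample deviating from its windowed median (half-window
5 samples) by more than 3 robust standard deviations
($1.4826\cdot\mathrm{MAD}$) is replaced by that median. The trace is
reflect-padded so edge samples see full windows, and the pass repeats
until nothing is flagged (recursive Hampel), which makes the filter
idempotent — in practice one or two passes. The outlier-removal method
itself was not published; Hampel is the standard robust choice for
step-free physiological drift.

**Core temperature.** Deep-body temperature is estimated from the
skin–ambient gradient, $T_{core} = T_{skin} + \alpha\,(T_{skin} -
T_{ambient})$, with a body-part-specific $\alpha$ (rectal 0.0699, head
0.3094, torso 0.5067, hand 0.7665, foot 2.1807); an arm-worn band uses
the hand value. The printed formula lacks parentheses; the gradient
reading is the only one consistent with body-part-specific coefficients.
Ambient temperature is taken from the nearest weather sample within
90 minutes (source unpublished; nearest-in-time is the natural choice
for hourly feeds). Note the model is sensitive: with the hand
coefficient, each degree of skin–ambient gradient adds 0.77 degC of
estimated core temperature, so consistent skin/ambient pairs matter more
than either value alone.

## The fuzzy risk engine

Risk is assessed by Mamdani inference over four inputs — heartbeat rate
$H$ (bpm), core temperature $CT$ (degC), work intensity $W$ and the
abnormal-duration time interval $T$ (min) — onto a risk level $RL \in
[0, 40]$ with categories Safe $[0,10]$, Concern $(10,20]$, Attention
$(20,30]$ and Danger $(30,40]$. An alert is raised at Attention level
and above.

**Input sets.** All inputs use pi-type memberships (plateau with smooth
S/Z ramps, 0.5 crossing at ramp midpoints). Published breakpoints fix
the plateaus; two conventions complete the geometry:

* printed *gaps* between ranges (core temperature 32–33 and 35–36 degC;
  time 14–15 min) are bridged by complementary ramps crossing at 0.5
  mid-gap;
* *shared* breakpoints (core temperature 38 and 40 degC; time 5 min)
  are where adjacent plateaus meet, so the boundary value belongs fully
  to both statuses rather than half to each.

The time Attention and Danger plateaus meet at 29.5 min (the midpoint of
the printed 29–30 gap) so that their union — the escalation trigger — is
monotone in elapsed time. Core temperature uses five statuses (Too low,
Low, Normal, High, Too high); the accompanying text says four, the table
lists five, and the table is the more specific source. Work intensity is
a crisp code (light 0.75, medium 0.5, high 0.25 — the published inverse
scale, implemented as printed) fuzzified with narrow pi sets.

**Worker-specific heartbeat sets.** Normal plateaus up to 99 bpm. The
Caution set is anchored at the Karvonen target
$(HR_{max} - HR_{rest})\,W + HR_{rest}$ with $HR_{max} = 207 -
0.7\,\mathrm{age}$, and Danger plateaus from $HR_{max}$. "Normal HB" in
the Karvonen formula is read as the worker's resting rate (default 60,
the published lower normal bound). For high-intensity work with a low
resting rate the Karvonen value can fall below the 99 bpm plateau; the
anchor is then clamped into $(99, HR_{max})$ with a warning, since the
three sets must tile the axis in order.

**Rule base.** The published rule screenshot is illegible, so the rule
base is a documented reconstruction, shipped as an editable YAML file
(`inst/extdata/risk_rules.yaml`) and generated by `default_rule_base()`.
It has two layers. *Base rules* depend only on $H$ and $CT$: both
normal is Safe; $H$ Caution or $CT$ Low is Concern; $H$ Danger, $CT$
High or $CT$ Too low is Attention; $CT$ Too high is Danger. A
supra-maximal heart rate alone therefore starts at Attention — which
already alerts — and the ladder climbs one category at a time.
*Escalation rules* add the next-higher consequent when the abnormal
state has persisted into the $T$ Attention or Danger bands; a fully
normal reading never escalates. Core-temperature statuses at Concern
severity and above carry single-clause rules (a normal heartbeat cannot
subtract from a temperature emergency). Two further rules exercise the
published OR/NOT connectives: $H$ Danger **or** $CT$ Too high carries
Danger weight outright, and high-intensity work with a Caution heartbeat
**not** in the Safe time band is Attention.

**Inference and defuzzification.** AND is min, OR is max, NOT is
$1-\mu$; implication clips the consequent triangle at the rule strength;
aggregation is pointwise max; the crisp level is the centroid of the
aggregate on a 0.01-resolution grid over $[0,40]$. The output triangles
are centred at 5, 15.5, 25.5 and 35.5 with feet bridging the printed
category gaps. The tests compare the whole path against a brute-force
oracle (independent loop, finer grid, trapezoidal centroid) to within
0.05.

**Monotonicity.** The layered rule structure was chosen specifically so
that the risk level responds monotonically to each input: base mass
never leaves the aggregate and escalation only adds higher-severity
mass. This is verified on sweeps of each input with the others held at
status plateaus (e.g. $CT$ at 37, 39 or 41 degC). A known limitation:
when a *held* input sits astride two statuses (e.g. $CT = 38.5$, fully
High and half Normal), centroid defuzzification can ripple by up to
about one RL unit (2.5 % of scale) during handoffs — an inherent
property of Mamdani max-aggregation with clipped sets, not of this rule
base; it never crosses more than one category boundary and does not
affect the plateau-held ordering. For high-intensity profiles the NOT
rule adds early escalation and can locally flatten or bump the response
near simultaneous extremes.

## Stream orchestration

Per worker and sample: Hampel-filter the skin temperature, estimate core
temperature against matched weather, update the abnormal-duration clock,
infer the risk level. $T$ is the time since the current abnormal episode
began, where "abnormal" means the dominant (highest-membership) set of
$H$ or $CT$ is not Normal; it resets to zero on any return to normal.
One alert is emitted per contiguous Attention/Danger episode (hysteresis:
the episode closes when the category falls to Concern or below), not per
sample. The published behaviour is only "alert at attention level"; the
episode convention avoids flooding a manager with one alert per minute.

The indoor-validation statistic compares device and reference heart
rates over rest plus eight stages of a modified Balke treadmill test
(fixed 5.1 km/h, slope +2.5 % per minute): absolute percentage error per
stage, then per-subject mean and maximum and the overall mean. Which
statistic the published "< 1 %" denotes is not stated, so both mean and
maximum are reported; on the packaged three-subject table every
per-subject mean is 0.18–0.43 % and the overall mean 0.32 %.

## Synthetic data: what it emulates, what it does not

All tests run on seeded generators; every generator is a pure function
of its arguments and seed and returns its ground truth.

* **PPG** (`generate_ppg`): an asymmetric raised-cosine pulse (rise 30 %,
  decay 45 % of the instantaneous beat period) at a piecewise-constant
  target rate, sub-0.5 Hz baseline wander, white noise at a stated SNR
  (default 20 dB; tests use 10 dB) and saturating ~60 ms clip bursts at
  a stated fraction. This emulates what rate estimation must survive —
  it does not reproduce PPG morphology (dicrotic notch, respiratory
  modulation), so the tests say nothing about waveform analytics.
* **Skin temperature** (`generate_skin_temp`): a smoothed bounded random
  walk (drift step 0.02 degC/min) plus small white sensor noise
  (0.002 degC) and labelled spikes. The drift-dominated regime reflects
  a device reporting per-minute averages of a thermally inert sensor;
  on noise-dominated traces a 3-MAD Hampel flags more clean samples
  than the sub-1 % the tests demonstrate.
* **Weather** (`generate_weather_day`): cosine diurnal cycles, humidity
  in antiphase with temperature, hourly cadence.
* **Treadmill sessions** (`generate_balke_session`): a monotone reference
  ramp with ±1 bpm integer device jitter, the discrepancy pattern of a
  validated wearable.
* **Scenarios** (`simulate_scenario`): rosters, per-minute device
  streams and a weather day in the exact file dialects the pipeline
  consumes. The default resting scenario pairs 35.2 degC skin with a
  stable 32–34 degC day so the gradient model lands in the normal core
  band; the scripted heat-strain scenario (175 bpm, 39.5 degC skin
  sustained half an hour) must raise exactly one alert episode.

Problem sizes were chosen so the full suite runs in well under a minute
of CPU: 60 s PPG traces at 50 Hz, 240-minute temperature traces,
45–50-minute scenarios, 200 random inputs for the defuzzification
oracle. Passing these tests demonstrates correctness of the pipeline's
mechanics and its behaviour under the stated noise models — not field
performance of any physical device.

## Degenerate inputs and numerical conventions

Out-of-universe fuzzy inputs are clamped to the universe edge before
fuzzification. Traces shorter than the Hampel window are returned
unchanged with a warning; windows with fewer than two beats yield no
rate. Timestamps are ISO-8601, parsed to UTC; Table-2 hours use local
site time. The defuzzification grid step is 0.01 (checked against a
0.005-grid oracle); stage and category boundaries are half-open, closed
above. All randomness flows from explicit integer seeds; identical
seeds reproduce byte-identical artifacts, which the round-trip tests
assert.
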