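---
title: "Wheel-running analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wheel-running analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelrun)
```

`wheelrun` implements the data path of reed-switch wheel-running loggers:
raw switch edges → debounced rotations → per-minute records → session CSV
files → absolute-time series → behavioural metrics and figure matrices.
This vignette explains the underlying models and the reasoning behind
every tunable default, so that users know what the package assumes and
what its validation does and does not demonstrate.

## 1. The signal model and debouncing

A magnet mounted on the wheel closes a reed switch once per rotation. The
raw signal is a stream of timestamped edges (`OPEN`/`CLOSED`) per channel;
a logger multiplexes up to 13 channels. Two physical facts shape the
decoder:

* a rotation corresponds to an OPEN→CLOSED *transition*, and
* mechanical switches *bounce*: a single pass can emit a burst of spurious
  edges over a few milliseconds.

`detect_rotations()` therefore accepts a closure as a rotation only if it
occurs at least `lockout_ms` (default 30 ms) after the previously
**detected** rotation on that channel. The lockout is non-retriggerable:
ignored edges do not restart the timer. This exactly reproduces the
behaviour of a polling microcontroller that stores the time of the last
accepted rotation. The 30 ms default is roughly ten times the duration of
a typical reed-switch bounce burst, and it imposes a speed ceiling of

$$v_{\max} = \frac{C}{\text{lockout}} \times 3.6 \ \text{km/h},$$

about 47.9 km/h for the default 127 mm wheel (circumference
$C = \pi \times 0.127$ m) — far above what a mouse can sustain, so no real
rotations are lost. The circumference is configuration, not a constant:
if a wheel's effective rolling circumference is calibrated (for example
0.458 m gives a ceiling of ≈ 55 km/h), `analysis_config(circumference_m=)`
propagates it consistently through distance, speed and the ceiling.

Edge-case conventions, chosen to make the decoder total (a logger must
never crash on a glitchy switch):

* the initial switch state is inferred from the first observed edge (the
  state before it is the opposite), and its dwell time accrues from the
  session start;
* duplicate edges (`CLOSED,CLOSED`) are tolerated: both are counted as
  events, only the first changes state, and the second cannot register a
  rotation because it is not a transition;
* channels with no events at all are treated as resting open.

Minute bins are left-closed, right-open — `[k·60000, (k+1)·60000)` ms —
anchored at logger reset, so a rotation at 59 999.5 ms belongs to minute
0. Switch state is carried across bin boundaries; for every complete
minute `open_dur_ms + closed_dur_ms = 60000` exactly.

## 2. Session files and time reconstruction

The reference CSV dialect is pinned (header
`minute,channel,open_events,close_events,open_dur_ms,closed_dur_ms,rotations`,
UNIX newlines, no quoting, integer fields) so files round-trip bit-stably;
legacy headers can be mapped with `read_log(col_map=)`.

Loggers without a functioning real-time clock are reset daily by hand and
the reset clock time written down. `build_timemap()` rebuilds absolute
session starts from that log. Missing entries are imputed as the previous
start plus the **overall arithmetic mean** of the gaps between adjacent
recorded days (a per-study constant, exposed as `fallback_interval_s`),
rather than a running mean — with one reset per day the gaps cluster
tightly around 24 h, the overall mean is the lower-variance estimator, and
it remains defined when the missing entries come first. Every imputed
session is flagged `IMPUTED` so downstream users can audit or drop them.

Sessions are never resampled onto a fixed daily grid. A session that
started ten minutes late keeps its true timestamps; all downstream binning
(hourly profiles, actograms) works from absolute time. Analysis "days"
are sessions, not calendar midnights. Overlapping sessions on one logger
are rejected outright as a consistency error.

## 3. Metrics and exclusion rules

For one animal-day with per-minute rotation counts $r_1,\dots,r_{1440}$
and circumference $C$:

* **distance** $= \sum_i r_i \cdot C / 1000$ km, over *all* minutes;
* **active minutes**: minutes with $r_i > \theta$ (strictly — a minute
  with exactly $\theta$ rotations is inactive; `strict = FALSE` relaxes
  to $\ge$ for users who read the threshold inclusively);
* **active speed** $=$ (distance over active minutes) / (active minutes /
  60) km/h. This aggregate ratio — not the mean of per-minute speeds —
  is robust to how many minutes an animal ran; the per-minute mean is
  available via `speed_method = "per_minute_mean"`.

The threshold $\theta$ is 30 rotations/min for short (acquisition-phase)
studies. For chronic studies it is derived from the data as the lower
quartile of per-minute counts **after excluding zero minutes**, pooled
across the whole cohort. Both choices were genuinely open:

* *zero exclusion* is forced by the data's structure — typically ~85–90%
  of all minutes are zero for every wheel, so a zero-inclusive quartile
  would always be 0 and classify every nonzero minute as active;
* *cohort pooling* (rather than per-animal or per-day quartiles) keeps a
  single threshold interpretable across groups and stabilises the
  estimate; per-animal thresholds would make "duration" incomparable
  between animals.

The quartile uses the nearest-rank convention (the
$\lceil n/4 \rceil$-th order statistic) by default because it always
returns an attained count; R's interpolating type-7 quantile is available
via `quantile_method = "type7"`. The result is rounded to the nearest
integer.

Exclusions are annotations, never deletions. A day is flagged when:

* it recorded no switch events at all (`OFFLINE` — broken or unplugged
  wheel);
* it has fewer than 20 active minutes (`TOO_FEW_ACTIVE_MIN`; screens out
  partially broken wheels and mirrors adult physical-activity guidelines
  of roughly 20–40 min/day);
* its active speed exceeds an absolute cap (default 20 km/h) **or**
  exceeds the animal's own median + 5·MAD over its other days
  (`SPEED_OUTLIER`). Published analyses have excluded such days by
  inspection; the codified rule makes the same judgement reproducible and
  auditable (`write_exclusion_audit()`), and both knobs are configuration.

Weekly summaries collapse days → animal-week means → group mean ± SEM,
with the **animal** as the experimental unit (SEM = SD across animals /
$\sqrt n$; reported as `NA` at $n = 1$ rather than 0). Weeks are
consecutive 7-session blocks from day 1; a final short week (6 sessions
in a 13-day study) is kept as its own block.

The High/Average/Low runner partition labels the top and bottom
$\lfloor n/4 \rfloor$ animals by total distance, the rest Average; ties
break by stable input order, and cohorts of fewer than 4 animals are all
labelled Average with a warning rather than forcing a degenerate split.

## 4. Figure layers

Figure content is computed as matrices and tested as matrices; rendering
never alters data.

* **Actograms**: rotations in 10-min bins, one row per calendar day,
  columns anchored to clock midnight (configurable bin width; must divide
  1440). Rows are double-plotted — row $d$ is day $d$ beside day
  $d{+}1$ — the standard device for visualising phase drift. Columns are
  clock-anchored rather than ZT-anchored because published actograms of
  this kind carry clock-time axes; the light mask (from `lights_off`,
  default 10:20, and the photoperiod) is an attribute. Missing sessions
  and gap days are `NA` (masked), never zero: an offline wheel must not
  masquerade as a resting mouse. Bar heights scale to each row's maximum,
  the classic convention.
* **Cohort heatmaps**: animals × consecutive 10-min bins across the
  study; row sums times circumference reproduce per-animal total distance
  exactly. Values are counts per bin; `rate_scale = TRUE` multiplies by
  `60/bin_min` for readers who prefer rotations/hour.
* **Hourly profiles**: distance per clock hour averaged over days per
  animal, then mean ± SEM across animals per group; the ZT relabelling
  uses the floor hour of lights-off and never changes values.
* **Density summaries**: nonzero per-minute counts with mean and median
  markers; zero minutes are excluded because the object of interest is
  behaviour *while running*, and no day-level exclusion filtering is
  applied at this layer.

## 5. The simulator: what it emulates and what it does not

`simulate_behavior()` generates rotation times from an alternating-renewal
bout model: bout starts are Poisson within each light phase, with rates
split so that an expected `dark_activity_fraction` of rotations fall in
the dark phase; bout lengths are exponential (truncated at the phase
boundary, so a fully nocturnal parameterisation emits nothing in the
light); within a bout, rotations follow a hard-core renewal process with
mean rate `rot_per_min` and a hard minimum gap. `emit_switch_events()`
then renders rotations as CLOSED/OPEN edge pairs, optionally adding
bounce bursts (edge pairs inside a 3 ms window) and faults (offline
intervals that emit nothing; drag that thins rotations).

Defaults describe a strongly nocturnal laboratory mouse under a 12:12
light/dark cycle with lights off at 10:20 (a reversed cycle; sessions
start at lights-off): 90% of activity in the dark, 1.2 bout starts per
dark hour, 10-min mean bouts, 90 rotations/min while running. The
within-bout numbers are order-of-magnitude choices (plausible range
60–120 rotations/min), not fitted values — no public dataset pins them
for these strains — and they land emergent quantities in realistic
ranges: ~4–6 km/day, ~2 km/h active speed, ~90% zero minutes (cf. the
76–85% reported for real acute/chronic studies).

The hard minimum inter-rotation gap (default 150 ms, i.e. a ~9.6 km/h top
speed on the 127 mm wheel) plays two roles: it is physically honest (a
mouse cannot exceed the lockout ceiling), and it makes the emitted truth
*exactly* recoverable through the 30 ms lockout, which is what allows the
round-trip validation to demand machine-precision equality rather than
approximate agreement.

What the simulator does **not** emulate: free-running (non-24 h) periods,
ultradian structure beyond exponential bouts, within-bout speed ramps,
inter-animal correlation, or realistic bounce waveforms (bursts are
uniform in a fixed window). Passing round-trip tests therefore
demonstrates that the *data path* is lossless and the *metrics* are
arithmetically correct under realistic load — not that the generative
model is a faithful description of mouse physiology.

All randomness flows from explicit seeds through an internal helper that
restores global RNG state; identical seeds give byte-identical session
files.

## 6. Validation problem sizes

The shipped test-suite and acceptance script exercise: exact
bill-of-materials/print-plan arithmetic in integer cents and minutes; the
streaming debouncer against a naive $O(n^2)$ replay oracle on 1,000+
random glitchy streams; machine-precision round trips
(simulate → emit → decode → summarise) on 3-day simulations; invariance
of decoded counts under saturating bounce (`p_bounce = 1`, 3 ms bursts,
30 ms lockout); recovery of a 0.9 dark-activity fraction from decoded
data within 3 Monte-Carlo standard errors over 20 replicate 2-day
simulations; strict threshold and inclusion boundaries (30/31 rotations,
19/20 active minutes); actogram double-plot identity and binning
conservation on simulated cohorts; and reset-time imputation against the
arithmetic-mean oracle on randomised logs. These sizes were chosen to
make the suites sharp but quick; all scale linearly if users want larger
replications.

## 7. Known limitations

* The chronic quartile threshold depends on the cohort analysed; merging
  cohorts changes it. Freeze it explicitly
  (`analysis_config(active_threshold = )`) when comparing across studies.
* Imputed session starts inherit the mean-interval assumption; a genuinely
  irregular reset schedule with missing records will misplace those days
  by minutes. The `IMPUTED` flag lets users exclude them.
* The hourly profile bins by clock hour; a light schedule not aligned to
  a whole hour (e.g. 10:20) is handled by the mask, but the ZT relabelling
  uses the floor hour.
* Exclusion rules are heuristics standing in for experimenter judgement;
  the audit log, not silent filtering, is the contract.
* Free-running circadian period estimation (constant-light protocols) is
  out of scope.
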