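---
title: "Methods: simulating and quantifying dendritic spine dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying dendritic spine dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedyn)
```

`spinedyn` analyzes longitudinal annotations of dendritic spines — weekly
positions of laterally protruding spines along short stretches of apical
dendrite — and turns them into the quantities that chronic two-photon
studies of cortical plasticity report: density, turnover, survival and
transience, compared between experimental groups. This vignette documents
the model behind each stage, the parameters that matter, and the choices we
made where more than one defensible design existed.

## The birth–death model of spine dynamics

Sessions are weekly (days 1, 8, …, 43 by default), which fixes the
granularity of everything downstream: turnover is observable only per
interval, so elimination is modelled as a **per-interval Bernoulli event**,
not a continuous-time hazard. Each spine occupies a fixed base position on
a dendrite of length `L ~ U(25, 35)` µm; the initial count is Poisson with
mean `baseline_density_per_um × L`, and initial spines count as mature. In
every interval:

* a mature spine is eliminated with probability `p_elim_per_week`;
* a spine formed in the immediately preceding interval is eliminated with
  `p_elim_new_per_week` — newly formed spines are distinctly less stable,
  and making this a separate generative parameter is what lets the
  simulator express group differences in gained-spine survival;
* new spines arise as a Poisson count with mean
  `formation_rate_per_um_per_week × L`, at uniform positions subject to the
  separation rule below.

An enriched-environment (EE) regime starting at `ee_start_day` modifies the
probabilities from that day on: the mature elimination probability declines
by `ee_elim_decline_per_week` for each EE interval (clamped at 0) — the
simplest mechanism producing a gradual weekly decline in elimination and
hence a steady density gain — and `p_elim_new_per_week` is replaced by
`ee_new_spine_stabilization`, expressing stabilization of newly gained
spines. Mouse-level correlation is off by default (dendrites independent);
setting `frailty_sd > 0` applies a log-normal multiplicative frailty to a
mouse's rates.

### Default parameter values

| parameter | default | unit | rationale |
|---|---|---|---|
| `n_mice` | 5 | mice/group | middle of the 4–6 range typical for chronic imaging cohorts |
| `dendrites_per_mouse` | 10 | — | middle of the typical 8–12 range |
| `dendrite_length_um` | U(25, 35) | µm | length of an analyzable dendritic stretch |
| `session_days` | 1, 8, …, 43 | d | two baseline sessions, then five weeks under the manipulation |
| `baseline_density_per_um` | 0.40 | µm⁻¹ | plausible for apical tuft dendrites; **an assumption, not a measured value** — no absolute density is available for these data, and the value is configurable |
| `p_elim_per_week` | 0.06 | — | together with the two values below gives ≈ 8 %/week turnover and a stationary density under standard housing |
| `p_elim_new_per_week` | 0.30 | — | new spines are several-fold less stable than mature ones |
| `formation_rate_per_um_per_week` | 0.032 | µm⁻¹wk⁻¹ | balances expected births and deaths at the baseline density |
| `lateral_fraction` | 0.6 | — | fraction of spines protruding laterally enough to score |
| `position_jitter_um` | 0.1 | µm | sub-tolerance re-identification drift |
| `min_separation_um` | 0.6 | µm | larger than the matching tolerance, keeping the same-spine rule well posed |

The EE presets (`cohort_presets()`) use `ee_elim_decline_per_week = 0.01`
and `ee_new_spine_stabilization = 0.15` for the responding groups
(`control-EE`, `deltaE9-EE-rescued`) and no EE effect for `deltaE9-EE`:
elimination then falls from ≈ 8 % to ≈ 3 % per week over five weeks and
density rises by 10–20 %, the magnitude such experiments typically show.

### Observation model and geometric guarantees

Observed positions are the base position plus Gaussian jitter of scale
`position_jitter_um` **truncated at ±1.5 scale units**, so two observations
of one spine in consecutive sessions differ by at most
`3 × position_jitter_um` (0.3 µm at the default) — below the 0.5 µm
matching tolerance. Base positions are kept at least
`min_separation_um + 3 × position_jitter_um` apart (births also respect the
positions occupied in the *previous* session, so a newborn is never
confusable with a spine that just disappeared). Under the defaults this
makes correct identity assignment geometrically guaranteed, which is what
allows the tracker to be scored against ground truth at the event level.
Only spines drawn lateral (probability `lateral_fraction`) are annotated;
non-lateral spines exist in the ground truth but are invisible to the
analysis, exactly like spines pointing into the z-axis of an image stack.
A spine that cannot be placed within 100 rejection-sampling attempts is
skipped and counted in `n_skipped`.

What the simulator does **not** emulate: annotation errors (missed or
hallucinated spines), spine morphology, dendrite curvature, drift of the
imaged field, within-mouse correlation beyond the optional frailty, and
plaque-distance effects. Tests passing on synthetic cohorts therefore
validate the bookkeeping, the matching logic and the statistics — not
robustness to annotation noise, which real data would add on top.

## Tracking: the same-spine rule as an optimal matching

The field's rule — same spine if the position moved ≤ 0.5 µm — is stated
for a human scrolling through stacks and is silent about conflicts. We
resolve it as the **maximum-cardinality, minimum-total-displacement
matching** between the two position sets, which is deterministic,
order-independent, and never declares turnover that a feasible pairing
could avoid. Because costs are absolute differences on a line, an optimal
non-crossing matching exists, and a dynamic program over the two sorted
lists finds it in `O(nm)`; ties are broken toward pairing the smaller
position of the earlier session, then of the later one. The exhaustive
search over all matchings (used as the test oracle) agrees on every random
instance with up to 8 spines per session.

Lineages chain stable pairs with **no gap-bridging**: formed/eliminated are
defined relative to the previous session, so a one-session disappearance
must end the identity — bridging gaps would contradict the definition of a
transient spine. The tolerance is a parameter (`tolerance_um`) for
sensitivity analyses.

One wording note: we map *disappeared → eliminated* and *emerged → formed*.
Descriptions of this rule in the literature occasionally transpose the two
words in prose while the accompanying figures use the mapping above; we use
the biologically coherent one throughout.

## Metrics: definitions and conventions

* **Turnover denominators** are the earlier session's count. The
  per-interval fractions `|eliminated|/N_prev` and `|formed|/N_prev` are
  the standard in the field; the convention matters only in strongly
  non-stationary regimes.
* **Relative density** uses the mean of the two pre-manipulation sessions
  as baseline (`baseline_sessions = c(1, 2)`); a single-session baseline is
  available. Baseline = 100 %.
* **Normalized turnover** scales each unit's series by `100 /
  first-interval value`; only the first interval is computable from imaging
  points one and two, so it is the baseline. The division is done as
  `100 × (x / x[1])` so the first value is *exactly* 100 in floating point.
  Default normalization is per dendrite, mirroring per-unit analysis;
  because per-dendrite first-interval fractions are small-count ratios,
  they are noisy, and dendrites with a zero first-interval fraction drop
  out (their normalization is undefined). `normalize_after_aggregation()`
  offers the alternative — normalize the mouse-mean series — which avoids
  both effects; the package computes whichever the analyst requests and the
  report states the dendrite-level default.
* **Gained-spine survival** indexes spines first seen at `index_session`
  (default 3: formed during the first week under the manipulation, which
  starts at session 2).
* **Transient spines** are newly formed lineages observed at exactly one
  session. Spines formed at the final session cannot be classified
  (right-censored) and are excluded from the denominator.
* **Aggregation order**: metric per dendrite → unweighted mean per mouse →
  group statistics on mice, because `N` is the number of mice. Undefined
  values (zero denominators) are **excluded, never imputed as zero** —
  imputing zero would bias survival and turnover systematically.

## Statistics

* `fit_line()` is exact ordinary least squares; `extra_ss_f_test()`
  implements the nested-model F statistic from residual sums of squares
  and degrees of freedom. `trend_f_test()` compares group trends; since it
  is not documented in the original analyses whether the nested comparison
  freed slopes only or slopes and intercepts, both nestings are
  implemented (`"lines"`, the default and what Prism's line comparison
  does, and `"slope"`), and the report names which one ran.
* `one_way_anova()` uses the standard between/within decomposition;
  `two_tailed_t_test()` is the pooled-variance Student test by default
  (matching the classical name), with Welch behind a flag.
* `newman_keuls()` implements the step-down Studentized-range procedure:
  means ordered, each span of `r` means tested at `q(α, r, df_within)`,
  and any non-significant span *seals* every nested pair as
  non-significant. Critical values come from the distribution function
  (`ptukey`/`qtukey`), not hard-coded tables; tests verify them against
  published table entries to three decimals. Unequal group sizes use the
  harmonic mean of the pair's sizes, the usual convention for the
  procedure.
* Degenerate inputs (zero variance everywhere, perfect fits in both nested
  models) return explicit `NA` p-values with a note rather than silent
  `NaN`, so tiny synthetic fixtures cannot crash the pipeline.

## Problem sizes and numerical checks

The test suite validates each stage at the size where its statistical
guarantee is stated: matcher-versus-exhaustive-search on 1 000 random
session pairs (≤ 8 spines each); tracking fidelity and parameter recovery
on 1 000-dendrite cohorts (event-level agreement ≥ 99 %; generative
`p_elim = 0.20` recovered from the first interval, where every spine is
mature, and `p_elim_new = 0.50` from the transient fraction, each within
3 SE); survival against the closed-form hazard product; and
type-I-error calibration of the three tests over 2 000 null replicates
each. End-to-end report checks use the shipped presets at the study-design
size (5 mice × 10 dendrites per group) and assert effect *directions*, not
magnitudes — the generative magnitudes are package choices, so only their
ordering is a meaningful check.

## Known limitations

* The analysis assumes positions are comparable across sessions (the µm
  coordinate along the dendrite is stable up to jitter); real data require
  registration before annotation, which is out of scope.
* With few spines per dendrite, per-dendrite normalized turnover is noisy
  and its group mean can drift below 100 even under stationarity (ratio
  bias plus exclusion of zero-baseline dendrites); prefer
  `normalize_after_aggregation()` or the raw fractions when counts are
  small.
* Newman–Keuls does not control the family-wise error rate in all
  configurations (a known property of the procedure); it is provided
  because it is the field's convention, not as a recommendation.
* The simulator's stationarity and effect sizes are idealized; passing
  tests demonstrate correctness of the computation, not the biology of any
  particular dataset.
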