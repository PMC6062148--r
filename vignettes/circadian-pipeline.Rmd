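---
title: "Scoring fly circadian behaviour and companion expression statistics"
author: "circafly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring fly circadian behaviour and companion expression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circafly)
```

# What the package computes

`circafly` implements the desk-scale analysis chain behind a typical
Drosophila circadian locomotor study: beam-cross counts from activity
monitors (5-min bins), recorded over a few entrained light--dark (LD 12:12)
days and about a week of constant darkness (DD), are turned into per-fly
calls and phase metrics, then cohort summaries; a companion expression arm
covers the statistics usually paired with such cohorts (probe filtering,
quantile normalization, two-class SAM, target-overlap enrichment,
qPCR relative quantification, intensity and luciferase normalization).
Because raw recordings are rarely shareable, a seeded generator produces
activity cohorts, expression matrices and Ct tables with known ground
truth; every analysis stage is validated against that truth.

# The behavioural model and its metrics

## Time base

Zeitgeber time (ZT) is hours since lights-on; ZT0 = lights-on, ZT12 =
lights-off under LD 12:12. In DD the projection continues on a strict 24-h
cycle from the last entrained lights-on and is read as circadian time
(CT). We deliberately do **not** re-anchor CT at each fly's own fitted
period: cohort DD-phase tables conventionally report a common projection,
and re-anchoring would entangle the phase estimate with the period
estimate. Bins are half-open intervals labelled by their start time; all
phase metrics quote the bin-start ZT/CT. Data are acquired at 5-min bins
and analysed at 30-min bins, except sleep (below).

## Death

Cohort tables distinguish tested from surviving flies but no death rule is
ever printed; operationally we call a fly dead when its *terminal* run of
all-zero bins spans at least 24 h (`detectDeath`, threshold exposed). A
long mid-recording pause followed by activity is not death. Dead flies are
excluded from every downstream statistic but keep a row in per-fly output.

## Rhythmicity and period

Two independent arms must agree (`classifyRhythmicity`):

* **Chi-square periodogram** (Enright/Sokolove--Bushell): for each
  candidate period $P$ (18--30 h in 0.1-h steps) the DD series is folded
  into cycles; $Q_P = n \sum_h n_h(M_h-\bar M)^2 / \sum_i (x_i-\bar M)^2$
  is chi-square with (columns $-$ 1) df under the null. Non-integer bin
  periods are handled by whole-bin truncation of each folded cycle. The
  significance line uses a Bonferroni-adjusted level $\alpha/121$ across
  the candidate grid: with the per-candidate level the family-wise false
  positive rate on unstructured flies is far above $\alpha$, and measured
  arrhythmic-fly specificity drops below what a dual-method call should
  deliver. The peak is refined by 3-point parabolic interpolation, exact
  grid ties resolving toward 24 h.
* **Autocorrelation**: the rhythmicity statistic RS is the circadian-lag
  (18--30 h) autocorrelation peak divided by the white-noise band
  $2/\sqrt{n}$; RS $\ge 1$ counts as rhythmic.

A fly is rhythmic iff the periodogram peak is significant *and* RS $\ge$
1; its period $\tau$ is the refined periodogram peak. The first DD day is
excluded as an entrainment transient (configurable). On simulated cohorts
this rule recovers $\tau$ to well within one grid step on average and
classifies both planted classes with $\ge$ 0.9 recall at the default
amplitudes.

## Phase metrics

All LD metrics are read from the average-day profile (mean activity per
30-min ZT bin over the three LD days):

* **Morning index**: $(A_{late}-A_{early})/(A_{late}+A_{early})$ with
  $A_{late}$ the mean over ZT21--24 and $A_{early}$ over ZT18--21 — a
  bounded, dimensionless contrast of pre-dawn build-up. The windows are
  configurable; the bounded form keeps cohort means on the order of
  published morning-index values (0--0.25).
* **Anticipation** (fly-by-fly): the 3 h before a light transition are
  split into 1-h thirds $a_1,a_2,a_3$; anticipation requires
  $a_3 > a_2 \ge a_1$, $a_3 > 0$, and $a_3 \ge 1.5\,a_1$. The last
  condition is ours: pure ordering passes by chance roughly one time in
  six on a flat profile, and a minimum rise restores $\ge$ 0.9
  specificity while leaving every genuinely ramped fly detected.
* **Evening onset**: a mechanized transcription of the manual rule — the
  evening peak (ZT6--13, ties late), a preceding rest (two or more
  consecutive bins under 25% of the profile maximum, from ZT2 onward),
  and a backward walk from the peak over non-decreasing bins tolerating at
  most one interior zero; the onset is the first bin of that run, valid
  only when a rest precedes it. Flies without a qualifying rest or rise
  have no onset and drop out of the cohort onset mean, which is why onset
  N is below cohort N. The window and threshold defaults are free
  parameters of a manual rule and are all exposed.
* **DD phase**: the CT of the maximum of DD day 4 after a centred 3-bin
  moving average (edges truncated, ties early).

## Sleep

Fly sleep is operationally 5 min of consecutive inactivity, so on the
5-min acquisition grid every zero bin contributes 5 sleep minutes;
`sleepSummary` refuses coarser grids because the rule is undefined there.
Minutes are attributed to light/dark phase by bin start. Sleep plus active
bin time partitions the 1440-min day by construction.

# The synthetic cohorts

`simulateFly` draws independent Poisson counts per 5-min bin around a
crepuscular rate template: bouts at lights-on and at lights-off (+
configurable offset), each a linear *anticipation ramp* rising to a peak
at the transition followed by a 1.5-h raised-cosine decay. We place all
pre-transition mass in the ramp — the bump itself is the post-transition
half of a raised cosine — so that a fly simulated with ramp 0 genuinely
lacks anticipation; a symmetric bump would smear activity into the
pre-dawn windows and make the morning index and anticipation detectors
structurally positive for every fly, defeating their validation. Under DD
the bout centres recur every $\tau$ hours from the last entrained cycle.
Arrhythmic flies keep the same mean rate, flattened in time, so they stay
"alive" under the death rule; `deathDay` zeroes activity from that day
on. Cohort defaults (baseline 2 counts per 5-min bin, peak amplitudes 4
times baseline, 3-h ramps, $\tau$ = 24 h, LD 3 d + DD 7 d at lights-on
08:00) are fixed study conditions, not tuning knobs.

What the generator does *not* emulate: light-driven startle (masking),
relative coordination, temperature cycles, inter-fly rate heterogeneity,
bout ultradian structure, and realistic sleep consolidation (Poisson
baselines yield little consolidated immobility, so simulated sleep totals
are far below real fly sleep). Passing tests therefore demonstrate
correctness of the *algorithms* under known truth, not field realism.

The expression generator plants per-probe log2 baselines
$\mathcal N(8, 1.5)$, a two-group design (default 4 + 4), a DE subset at
$\pm$`log2Effect` (half up, half down), Gaussian noise, and
missing-completely-at-random masking. The Ct generator encodes a known
fold change in its noiseless $\Delta\Delta$Ct exactly.

# The expression arm

Stage order is fixed: **filter** (drop probes with > 50% missing) →
**quantile normalization** (columns forced onto the mean order-statistic
distribution; ties get the mean of the tied ranks' reference values;
columns with missing entries map through quantile-position interpolation)
→ **two-class SAM** → **overlap/enrichment** (exact hypergeometric upper
tail via `phyper`).

SAM follows the original two-class recipe: $d_i = (\bar x_{i1}-\bar
x_{i2})/(s_i+s_0)$ with the pooled per-probe scatter, $s_0$ the percentile
of the $s$ distribution (grid 0--100 by 5) minimizing the coefficient of
variation of windowed MADs of $d$; the null comes from balanced column
relabelings (all 70 for a 4 + 4 design); calling scans the observed order
statistics against their mean permuted counterparts from the origin
outward at threshold $\delta$; FDR is the median permuted count beyond
the cuts, $\pi_0$-adjusted ($\pi_0$ from the central 50% of permuted
$d$), over the number called. $\delta$ can be fixed or tuned to a target
FDR (a 7% operating point is a config default, never hard-coded). Probes
with fewer than two usable values per group are flagged out.

One measured caveat: on *pure-null* matrices with $\delta$ tightened
until only a few dozen probes are called, the median-based estimate sits
well below the realized false-discovery proportion (we measure 0.5--0.8
against 1.0). The cut is placed exactly where this realization's tail
first clears the expected order statistics, so the observed count beyond
the cut is selection-biased high relative to a typical permutation. The
estimator behaves (0.83--0.91) at looser cuts and is accurate in the
spiked regime the method is used in; we document rather than patch this,
since the procedure is pinned to the published recipe.

Small closed-form utilities round out the arm: `log2FoldChange`,
`deltaDeltaCt` (replicates averaged before $2^{-\Delta\Delta Ct}$),
`perIntensity` (percentage over local background), and
`luciferaseRelativeActivity` (Firefly/Renilla over a negative-control
ratio).

# Numerical choices and degenerate inputs

* Rebinning truncates a trailing partial bin (with a warning) rather than
  padding: fabricated counts would bias totals.
* Constant (zero-variance) series are a degenerate input: the
  autocorrelogram refuses them and the classifier returns an arrhythmic
  call without a period.
* Periodogram candidates with fewer than two complete folds are skipped
  with a warning.
* Percentages in cohort summaries round half-up to 2 decimals (matching
  printed-table arithmetic; banker's rounding does not); SEM uses the
  $n-1$ sample standard deviation.
* All generators route randomness through a seed-scoped RNG so they are
  pure functions of their seed and never disturb the caller's stream; fly
  $i$ of a cohort uses seed $+ i$, so cohorts extend without changing
  existing flies.

# Problem sizes

The validation suites use 30--100 flies per behavioural check (10-day
recordings, 2880 bins per fly), 1000--2000 probes at 4 + 4 replicates for
the expression checks, and 50 flies per period-recovery condition — sizes
at which the stochastic tolerances (for example $\pm$0.2 h on a cohort
mean period, $\pm$0.5 h on an onset separation) are comfortably resolved.

# Known limitations

* The evening-onset rule transcribes a manual scoring procedure; its
  window and threshold defaults matter more than any other parameter in
  the package and should be reviewed against each lab's convention.
* CT is projected at 24.0 h, not at the fly's fitted period; for strongly
  short/long-period flies late-DD phases drift accordingly.
* The rhythmicity call is a conjunction of two correlated tests; its
  operating point is calibrated on the synthetic cohorts, not on real
  genotypes.
* SAM's null-regime FDR caveat above.
* No MESA/Lomb--Scargle/wavelet spectral options, no sleep-bout
  architecture, no actogram rendering pipeline.
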