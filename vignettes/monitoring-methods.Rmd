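---
title: "Monitoring a HIIT shock microcycle: models and methods"
author: "loadmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring a HIIT shock microcycle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loadmark)
```

## The monitoring problem

A shock microcycle packs ten high-intensity interval sessions (5x4 min at
90-95% of individual maximum heart rate) into seven days, with doubles on
days 2, 3, 6 and 7 and a resting day 4. One intervention arm (HSM) runs the
sessions as prescribed; a second (HSM_LIT) appends 30 min of low-intensity
running to every session (+300 min, +75% volume); controls (CG) keep their
usual training. Around the intervention sit an 8-9 day lead-in and a 14-day
recovery phase. Blood is drawn at rest at nine timepoints (T0, T1, T2,
day 4, T3, +1, T4, T5, T6), a 32-marker panel is assayed (12 cytokines,
creatine kinase, urea, ferritin, transferrin, 16 differential-count
parameters), athletes file daily self-reports, and VO2max is measured at
four exercise tests.

`loadmark` implements the complete analysis chain for such a study:
individualized training-load quantification from heart-rate traces,
longitudinal and chronic biomarker statistics, correlation rankings and
networks against load, soreness and VO2max, and an exploratory combined
log-ratio biomarker. Because no participant-level data are deposited for
this design, the package ships a seeded synthetic-study generator so that
every stage is exercised end-to-end and every statistical property can be
verified against planted truth.

## Training load

**Zone model.** Each athlete's three-zone model is anchored at two
individual landmarks: the heart rate at a blood-lactate concentration of
1.5 mmol/L (zone 1/2 boundary) and 90% of maximum heart rate (zone 2/3
boundary). From the incremental test (1.5 km/h steps every 3 min), the
speed at 1.5 mmol/L is interpolated linearly between the two bracketing
stages — the speed-lactate curve is convex, so a straight line through all
stages would bias the crossing — while the HR at that speed comes from an
ordinary least-squares regression of HR on speed over all stages
(`fitZoneModel()`). Boundaries are lower-inclusive: a sample exactly at a
boundary belongs to the higher zone. The model refuses, with diagnostics,
stage data whose lactate never brackets the threshold and configurations
where the lactate-anchored HR is not below 90% HRmax.

**TRIMP.** Session load is time-in-zone weighted 1/2/3 and summed
(`zoneTimes()`, `sessionTRIMP()`); zone minutes always sum exactly to the
trace duration.

**expTRIMP.** Daily loads (rest days enter as zero — skipping them would
leave the decay semantics undefined) are smoothed by an exponentially
weighted moving average with decay `lambda = 2/(N+1)` over horizons
N = 3, 5, 7 days, initialized with the first recorded load:

```{r}
expTRIMP(c(80, 0, 80), N = 7)
```

The recursion printed in the source description,
`load * lambda + ((1 - lambda) + EWMA_yesterday)`, is not a convex
combination: it adds at least `1 - lambda` every day and grows without
bound even at zero load. The standard EWMA above is therefore the default,
and the printed variant is kept behind `variant = "as-printed"` purely for
audit. Initialization with the first load (rather than zero) follows the
stated procedure; both are supported.

## Longitudinal biomarker statistics

**Phase mixed model.** Timepoints are summarized into pre (T0, T1),
intervention (T2, day 4, T3, +1) and post (T4, T5, T6). Per marker,
`phaseMixedModel()` fits a REML linear mixed model of the log
concentration (biomarkers are positive and right-skewed) with fixed
effects group, phase and their interaction and a random intercept per
athlete. The reported contrasts are the group-by-phase interaction
effects of each intervention group against CG relative to the pre phase
(difference-in-differences). These are the treatment-coded interaction
coefficients, tested with Satterthwaite degrees of freedom; a
within-phase group contrast would be dominated by stable between-subject
differences and is not what a "group x time interaction" star denotes.
No multiplicity adjustment is applied by default (stars are reported raw
across the 32 markers, at 0.05/0.01/0.001/0.0001); failed fits are
flagged, never silently dropped.

**Percent change and the SD threshold.** `percentChange()` is the raw
percent difference to each athlete's own T0. `sdThreshold()` is the
sample SD of each marker over the pooled T0 and T1 values of all
athletes — a per-marker yardstick separating measurement noise from
meaningful change.

**Chronic change (AUC).** For each athlete and marker the difference to
baseline `d(t) = value(t) - value(T0)` is integrated by the trapezoid rule
over the study-day axis within the pre window (T0-T1) and the post window
(T5-T6). The integrand is the raw difference (a percent-difference variant
is switchable); each window AUC is divided by its length in days, because
the two windows span 8 and 7 days and would not compare otherwise (the
unnormalized variant is also available). Pre vs post is compared with a
paired Wilcoxon signed-rank test — robust at n = 10; paired t is an
option — per group and for the pooled intervention groups, the pooled
analysis always being a recomputation on the concatenated athletes, never
an average of p-values. The between-group comparison of
`deltaAUC = AUC_pre - AUC_post` uses Mann-Whitney.

## Correlations, rankings, networks

`buildAlignedTable()` assembles one row per athlete and blood-draw
timepoint (T0 is excluded: no previous-day load exists before the
observation window) holding the absolute marker values, the 3/5/7-day
expTRIMP of the day *before* the draw, same-day self-reports, and VO2max
carried forward from the most recent test (T1 covers T1/T2/day 4; T4
covers T3/+1/T4; T5 and T6 cover themselves — a total, deterministic map).

`pearsonMatrix()` computes pairwise-complete Pearson r with two-sided
p-values, pooling all timepoints; only pairs with p < 0.05 pass the
significance mask that gates rankings and networks. Strength classes use
the conventional bands (|r| <= 0.295 low, <= 0.495 moderate, above that
strong; the published band gaps at 0.29-0.30 and 0.49-0.50 are closed at
the midpoints). Pooling repeated measures overstates the effective sample
size — each athlete contributes up to eight rows — so a per-athlete-mean
sensitivity mode (`collapse = "participant"`) is provided; the pooled
matrix remains the default because that is how the aggregate analysis is
defined. `rankAgainst()` orders the significantly correlated markers by r
(ties broken by name for determinism); `buildNetwork()` keeps an edge only
where the correlation is significant, with weight |r| and the sign stored
separately (the edge-weight transform affects plotting only);
`groupNetworks()` recomputes matrices within each group and keeps the
top-k edges by |r|.

## The combined log-ratio biomarker

`selectRatioCandidates()` picks the markers with the most positive and
most negative *significant* correlation against the 7-day expTRIMP;
`ratioSeries()` forms `log(numerator)/log(denominator)` per observation
(natural logs; the name "log-X-to-log-Y" is read as a quotient of logs,
and a difference-of-logs variant is switchable since the algebra is not
written out anywhere). The quotient is only meaningful when both logs are
positive, i.e. concentrations are well above 1 in their native units
(CK in U/L and red cells in 10^6/uL are), so `ratioSeries()` refuses
values at or below 1 with an instruction to normalize units rather than
silently shifting. `combinedBiomarker()` applies exactly that remedy when
selection lands on a low-concentration cytokine: the offending marker is
rescaled by the smallest power of ten that puts all its values above 1,
and the factor is reported — the quotient of logs is not unit-invariant,
which is why the factor is surfaced.

A statistical remark on what the ratio can and cannot gain: if the two
components couple to one shared latent load with correlations `rho1` and
`rho2` and otherwise independent noise, no combination of them — the
log-ratio included — can exceed a population correlation of
`sqrt(rho1^2 + rho2^2)` with that load. For couplings like +0.4/-0.15 the
headroom over the stronger component is only ~0.03, smaller than the
sampling spread of a 30-athlete study, so the ratio's advantage over CK
alone is a tendency, not a near-certainty; it becomes systematic only
when the components also share load-independent noise (plasma-volume and
assay-batch effects are the physiological candidates) that division can
exploit. The package's improvement test is therefore a one-sided
binomial test against the chance level across replicate cohorts.

## The synthetic-study generator

The generator (`simulateStudy()`) emulates the study conditions:

* **Cohort** — 3 x 10 athletes; sex ratios 9/1, 6/4, 8/2 (no sex effect is
  planted; none is claimed); HRmax from an age-anchored rule within
  160-210 bpm; VO2max near the reported group means (60.3/60.3/59.5
  mL/min/kg); an individual lactate-threshold speed and HR (76-84% of
  HRmax, always below the 90% boundary) and an HR-vs-speed slope.
* **Sessions** — the exact shock-microcycle plan; REGULAR sessions get
  individual durations (a stable habitual-volume offset per athlete plus
  day-to-day variation around 60 min, log-normal with SD 0.2 each):
  "usual training" differs between and within athletes, and without that
  variation the load signal would be constant within group x day — an
  artifact no real cohort shows, which would distort every pooled
  correlation downstream.
* **HR traces** — 1 Hz; HIIT = 10-min sub-threshold warm-up ramp, five
  4-min bouts at a configurable fraction of HRmax (default 0.925, the
  middle of the prescribed 90-95% band) and four 2.5-min recoveries; LIT
  strictly below the lactate threshold; REGULAR 3/4 easy + 1/4 moderate.
  Gaussian noise (SD 2 bpm) bounded at 3 SD, clamped to (40, HRmax].
* **Timepoint grid** — study days {-9, -1, 2, 4, 7, 8, 10, 14, 21} for
  {T0, T1, T2, D4, T3, +1, T4, T5, T6}. The source protocol gives phases,
  not calendar offsets; a fixed configurable grid keeps every AUC x-axis
  reproducible.
* **Biomarkers** — log-normal around `baseline * (1 + shift(group,
  phase))`. Baselines are clinical reference mid-ranges (not printed in
  the source; config-overridable), and each marker's total log-SD is
  split into a stable between-subject part and day-to-day noise with
  magnitudes chosen from known biological variability (CK highly
  variable, ~0.67 total log-SD; RBC tight, ~0.07). A marker's `load_rho`
  couples its log-concentration to the standardized previous-day 7-day
  expTRIMP implied by the session plan, constructed so that `load_rho`
  *is* the marginal log-scale correlation. Cross-marker structure comes
  from shared day-level factors with per-marker loadings
  (`defaultFactorLoadings()`): hemoconcentration (plasma-volume shifts
  move red-cell parameters strongly and serum concentration markers
  weakly, in the same direction), a leukocyte factor (granulocytes
  dominate the white count, so GR and WBC move in near-lockstep and LYM%
  mirrors them), and a shared cytokine factor (common immune state plus
  multiplex-assay batch). Each factor is 70% stable trait, 30% day
  effect.
* **Planted effects** — `defaultEffectConfig()` reproduces the reported
  response pattern: CK +10% during the intervention in both HIIT groups
  and below baseline afterwards; RBC/HCT/HGB down post (HGB also in CG);
  IL-2, IL-9, TNF-a, IL-17A, IL-17F around -25% post in HSM; IL-4 and
  ferritin down; RDWCV up and staying up.
* **Self-reports** — monotone functions of the standardized previous-day
  load plus noise, clipped to their scales (sleep 1-7, VAS 0-100,
  fatigue 1-10); the soreness slope and noise give a load-soreness
  correlation of about 0.6.
* **Determinism** — one global integer seed; every stage draws from a
  derived sub-stream, so identical seeds give bitwise-identical studies
  and byte-identical CSV exports, including under partial regeneration.

**What the generator does not emulate.** Responses are first-order:
no cardiovascular drift within sessions, no circadian structure, no
missing data by default (a dropout rate is a config option), no
acute-response dynamics. The last point matters for interpretation: the
load coupling is a single linear (log-scale) channel, so a marker cannot
simultaneously show a strong pooled load correlation and a small median
phase change the way real CK does (real CK responses are acute,
right-skewed and fast-decaying). Planted-effect analyses therefore use
the channel appropriate to the question — shifts when recovering percent
changes, couplings when studying rankings, networks and the ratio — and
passing tests demonstrate correctness of the statistics on data with
known truth, not physiological completeness of the generator.

## Numerical and design choices

* Zone boundaries half-open, lower-inclusive at each zone start; tie
  handling is unstated in the source, so it is fixed here and tested.
* Lactate threshold by bracketing-stage interpolation; HR mapping by
  least squares over all stages ("simple linear regression").
* EWMA initialized with the first load; rest days as zero load.
* AUC on raw difference-to-baseline, per-day normalized; both choices
  switchable because the source wording leaves them open.
* Paired test Wilcoxon by default (n = 10), t as option; between-group
  deltaAUC by Mann-Whitney.
* No multiple-testing correction by default; Benjamini-Hochberg can be
  applied externally to any p-value column.
* Correlation scale: raw ("absolute") marker values by default, log
  switchable.
* Degenerate inputs error loudly: empty traces, unbracketed thresholds,
  constant markers (zero SD threshold with a warning; mixed model refuses
  a fully constant panel), zero-variance variables in the correlation
  matrix (flagged NA, not dropped).

## Problem sizes used by the test-suite simulations

Calibration and recovery properties run on replicate cohorts at the study
size (3 x 10 athletes): 200 replicates for the null-calibration,
percent-change-recovery, chronic-power and ratio-improvement suites
(four-marker panels where a property does not need all 32), and 20 seeds
for the full trace-based group-ordering check. These sizes put the
Monte-Carlo standard errors well below the tolerances they are compared
against while keeping a complete run in a few minutes on one CPU.

## Known limitations

* The pooled correlation matrix ignores within-athlete dependence by
  construction (the aggregate analysis is defined that way); use the
  per-athlete sensitivity mode before interpreting effective sample
  sizes.
* Marker baselines and variances are reference-range choices, not fitted
  to any dataset; absolute concentrations are only as meaningful as
  those choices.
* The combined-biomarker improvement is margin-limited (see the
  statistical remark above); on real data its size will depend on shared
  noise structure the generator only partially models.
* Group allocation is deterministic by construction (first n CG, next n
  HSM, ...); randomization effects such as behavior change in controls
  are out of scope.
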