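---
title: "Methods: photometry preprocessing, discriminability and behavioral scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photometry preprocessing, discriminability and behavioral scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctaphot)
```

This vignette documents the models, parameter choices and numerical
decisions behind `ctaphot`. The package analyzes intraoral-infusion
experiments in which two-channel fiber photometry (a 465 nm
sensor-dependent channel and a 405 nm isosbestic control) is recorded
while a tastant is infused on a fixed trial structure, alongside
pose-based behavioral reactivity and two-bottle sucrose preference.

## Preprocessing model

### Control fit and subtraction

Both channels share two nuisance processes — slow photobleaching and
motion artifacts from fiber/brain displacement — while only the 465 nm
channel carries the sensor signal. We therefore regress the signal channel
on the control channel with a whole-session affine fit and form

$$\Delta F/F \;=\; \frac{F_{465} - \widehat{F}}{\widehat{F}},
\qquad \widehat{F} = \hat\beta_0 + \hat\beta_1 F_{405}.$$

Two choices here were genuinely open:

* **The denominator.** "Scaled-and-subtracted" pipelines differ in whether
  they report the raw residual or divide by a baseline estimate. We divide
  by the fitted control, the common choice in open photometry toolkits: it
  yields a dimensionless fractional change and makes sessions with
  different absolute brightness comparable *before* z-scoring.
* **The fit.** Ordinary least squares over the full session is the
  default. Large evoked transients have leverage on the fit; a robust
  (Tukey bisquare) option is exposed (`method = "robust"` in
  `fit_and_subtract_control()`) for sessions where transients occupy a
  substantial fraction of the recording. On the standard 30-trial session
  (5-s infusions in ~45-s intervals) the transient duty cycle is low and
  OLS and robust fits agree closely.

A zero-variance control channel, or a fitted control that crosses zero,
aborts with an explicit error rather than producing unusable ΔF/F.

### Bandpass filter

The smoothing filter is a fifth-order Butterworth bandpass with cutoffs
0.05 and 2.25 Hz, applied forward and backward so the net phase is zero
and event-aligned latencies are preserved (a causal single-pass option is
exposed). Zero-phase application squares the magnitude response, which is
what the package's analytic reference `bandpass_gain()` reports.

Numerically, a tenth-order transfer-function realization of this bandpass
is unstable at common sampling rates — the 0.05 Hz corner places poles so
close to the unit circle that rounded polynomial coefficients move them
outside (we observed divergence at 100 Hz). The filter is therefore
designed in zero–pole–gain form (analog Butterworth prototype →
lowpass-to-bandpass transform → bilinear transform with prewarping) and
applied as a cascade of five biquads, the standard remedy. Two further
edge decisions:

* ends are padded by odd reflection (30 samples per section) before each
  pass, and
* each biquad is initialized at its steady state for the first sample, so
  a constant trace maps exactly to the filter's DC gain (zero) instead of
  exciting a minutes-long start-up transient at the 0.05 Hz corner.

The implementation is validated in the test suite against the closed-form
prewarped magnitude response at passband, transition and stopband
frequencies, and for the zero-phase property (cross-correlation of a
passband sinusoid with its filtered version peaks at lag 0).

### Normalization and trial statistics

The filtered trace is standardized by the whole-recording mean and
*population* SD (n denominator): `z = (x − mean)/sd`. Using the entire
session, inter-trial intervals included, anchors the scale in each rat's
overall signal variability and makes the infusion-window statistic
comparable across sessions, days and rats.

Trials are aligned on infusion onset with a −5 to +10 s window. The onset
sample is the nearest sample at or before the event time; windows are
half-open `[start, stop)` so adjacent windows never share a sample. Trials
whose window leaves the recording are dropped with a warning (never
padded); if all trials fall outside, alignment errors. The per-trial
statistic is the arithmetic mean of z over `[0, 5)` s — the infusion
period — and the session statistic is its mean over trials.

## Ideal-observer ROC

Discriminability between two conditions (sucrose vs quinine; Unpaired vs
Paired) is quantified on single-trial statistics. The threshold sweep uses
a data-adaptive grid: pooled observed values are sorted, the step is the
mean difference between consecutive unique values, and the grid runs from
one step below the minimum to one step above the maximum. At each
threshold θ the hit rate is the fraction of positive-condition trials
strictly above θ and the false-alarm rate the fraction of
negative-condition trials strictly above θ (strict `>` for both keeps the
direction consistent when values tie a threshold). AUC is the trapezoidal
integral over the (false-alarm, hit) curve with (0,0) and (1,1) appended,
and AUC > 0.7 is the discriminability flag.

The grid rule densely covers the observed range but is not
metrically invariant: very uneven gaps between observed values can skip a
step of the empirical ROC. The package therefore also ships
`rank_auc_oracle()` — the exact Wilcoxon–Mann–Whitney probability
P(positive > negative) with half-weight ties — which *is* exactly
invariant under monotone transforms and exactly antisymmetric. The test
suite holds the grid AUC within 0.02 of the oracle for samples of ≥ 20
per group; published AUCs computed with other ROC software may differ in
the second decimal for the same reason. The "positive" condition is the
one expected to respond more (sucrose, or the Unpaired group), so
AUC > 0.5 means larger responses in that condition.

## Behavioral reactivity

Pose tracks (DeepLabCut CSV dialect: scorer/bodyparts/coords header rows;
x, y, likelihood per part at 10 fps) are cleaned by replacing points with
likelihood < 0.95 with linear interpolation between the nearest flanking
confident frames; leading/trailing low-confidence runs take the nearest
confident value (interior interpolation is the documented convention;
edge filling is our extension so windows at the recording boundaary remain
usable — it is recorded in the interpolation mask like any other
replacement). Pixel coordinates become cm via stationary landmarks
(chamber legs/corners): the scale is the mean over landmark pairs of
pixel distance / physical distance.

"Movement" is **total path length** in a window — the sum of inter-frame
Euclidean displacements — rather than mean speed or net displacement.
Aversive reactions (gapes, headshakes, forelimb flails) are oscillatory:
they produce large path length with little net displacement, so path
length is the statistic that separates them from quiet ingestion.
Reactivity is movement in the 5-s infusion window minus movement in the
5-s pre-infusion baseline, computed per trial and then averaged
(consistent with session-averaged reporting); the composite "forepaw"
score averages the left and right forepaws, and "head" is the midpoint of
the two ears. Reactivity is invariant to translation and rotation of the
camera frame and, given correct calibration, to the pixel scale.

Sucrose preference is sucrose consumed (g) / total fluid consumed (g)
from the 2-h two-bottle test; zero total consumption yields a flagged
missing value.

## Statistical layer

* **Paired t** on per-subject differences (second condition minus first),
  df = n − 1, two-tailed. Zero-variance differences are flagged rather
  than silently producing infinite statistics.
* **One-way RM ANOVA**: within-subject decomposition,
  F = MS_condition/MS_error. Greenhouse–Geisser epsilon (from the doubly
  centered condition covariance) multiplies both dfs by default — the
  non-integer dfs conventionally printed imply such a correction even
  where it is not named; Huynh–Feldt would be the alternative reading and
  gives slightly larger epsilon. The post hoc is Dunnett's many-to-one
  comparison against a reference condition (the first conditioning day),
  with family-wise p-values from Monte-Carlo quantiles of the equicorrelated
  (ρ = 0.5) multivariate t — 10^5 seeded draws, reproducible and
  dependency-free, agreeing with `multcomp`'s single-step values to well
  under 0.01 in the test suite.
* **Two-way mixed ANOVA** (between-subject group × within-subject day),
  balanced designs only: group is tested against subjects-within-group;
  day and group × day against the day × subject error. Between-group
  post hocs at each day use the pooled error
  (MS_subj + (d−1)·MS_error)/d with Satterthwaite dfs — the convention of
  mainstream GUI statistics packages — adjusted across days by Šidák, or
  reported unadjusted as Fisher's LSD (meaningful only alongside a
  significant omnibus F). The interaction test's type-I error is
  calibrated at 0.05 ± 0.01 over 2000 null simulations in the test suite.
* **Linear regression** with r², the two-tailed slope test and pointwise
  95% confidence bands, used for dopamine-versus-reactivity and
  dopamine-versus-preference relationships.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be tested
against known ground truth. Its defaults encode the study conditions: 30
infusions of 5 s per session, inter-trial intervals uniform on 35–55 s, a
60-s lead-in so baseline windows always exist, 10 fps pose, two-group
(Paired/Unpaired) cohorts of 10 rats (7 for extinction paradigms in the
acceptance runs, matching typical cohort sizes).

**Photometry.** The 465 nm channel is

bleach(t) + Σᵢ aᵢ·k(t − tᵢ) + spontaneous transients + motion + noise,

with `bleach(t) = baseline·exp(−t/τ)` (τ = 1500 s), a double-exponential
transient kernel k (rise 0.5 s, decay 2 s — matching slow GRAB/GCaMP
kinetics; exact kinetics are configurable since they are not published),
and per-trial amplitudes `aᵢ = A·s·lognormal(σ = 0.35)` where `s` is the
suppression factor (1 = full appetitive response, ≤ 0 = conditioned
suppression below baseline). Three modeling points matter:

* *Transients scale with the surviving fluorophore pool* (they are
  multiplied by the bleach fraction at onset). A fixed raw amplitude on a
  decaying baseline would make equal responses grow in ΔF/F terms across
  the session; with pool scaling, recovered trial statistics are exactly
  rank-monotone in the injected amplitudes on noise-free data.
* *Spontaneous transients* (rate 6/min, amplitude 4) occur throughout the
  session in the signal channel only. They overlap infusion windows at
  random, which is what gives trial statistics realistic overlap between
  conditions — without them, session z-scoring of a noise-dominated trace
  separates conditions almost perfectly and every ROC saturates at 1.
* *Motion artifacts enter both channels scaled by each channel's gain*
  (the 405 nm motion gain defaults to the bleach gain ratio). Motion
  perturbs the optical coupling and therefore scales with collected
  fluorescence; this is precisely the condition under which one affine
  control fit removes bleaching and motion simultaneously — the premise
  of isosbestic correction. The channel-specific gain is configurable to
  study imperfect correction.

The session z-score is scale-invariant, so a completely silent noise-free
trace makes day-to-day amplitude changes invisible; across-day
comparisons in the tests always run with background activity on.

**Cohorts.** The Paired group's suppression follows a per-day trajectory
(e.g. CD = 1, TD = −0.5 for single pairing; graded acquisition C1→C3 and
gradual recovery E1→E8 for repeated pairing); the Unpaired group stays at
1. Rats carry a persistent random effect (SD 0.1) and each session an
independent one (SD 0.15) — without the session-level term, within-rat
day contrasts are implausibly clean (paired t statistics an order of
magnitude beyond anything biological). Injected behavioral reactivity is
coupled to suppression as `gain = 1 + 2·(1 − s)` cm (appetitive ≈ 1 cm,
strong aversion ≈ 4 cm), and preference as
`clip(0.5 + 0.45·s, 0, 1) + N(0, 0.05)` — a linear link, chosen because
the empirical dopamine–preference relationship is analyzed by linear
regression. None of these effect sizes are published in physical units;
they are calibrated once to reproduce the qualitative pattern (chance AUC
on the conditioning day, AUC > 0.7 after pairing, recovery with
extinction) and not adjusted thereafter.

**Pose.** The body follows a bounded random walk (step SD 0.1 cm/axis at
10 fps); during infusion windows an extra displacement, collinear with
the baseline step so path lengths add exactly, injects a known total path
length per trial. Landmarks sit at known spacing (20 cm square);
a configurable fraction of frames gets likelihood < 0.95 and corrupted
coordinates. Injected reactivity is recovered within ~2% over 100 trials.

**What the generator does not emulate** — and therefore what passing
tests do and do not show: sensor saturation and nonlinearity, hemodynamic
and spectral crosstalk between channels, licking/chewing artifacts locked
to the infusion itself, non-stationary bleaching (bi-exponential or
light-dependent), correlated tracking errors (identity swaps, occlusion
runs), and genuinely uncoupled individual differences. The synthetic
dopamine–behavior couplings are much tighter than real biology (r² near
0.95 versus ~0.4–0.6 in vivo), so end-to-end tests validate sign,
ordering and calibration of the *pipeline*, not expected effect sizes in
real data.

## Problem sizes and runtime

The default test suite simulates cohorts of 2–10 rats per group with 4–30
trials per session at 40 Hz and runs in under two minutes on one CPU; the
acceptance script analyzes a 10-per-group single-pairing cohort and a
7-per-group extinction cohort (30-trial sessions throughout) plus a
5-point suppression grid, in about a minute. These sizes were chosen to
keep Monte-Carlo standard errors comfortably inside every asserted
tolerance while remaining quick to rerun.

## Known limitations

* Balanced designs only in the mixed ANOVA (equal group sizes, complete
  day coverage); unbalanced data error out rather than silently switching
  to a different sums-of-squares type.
* The ROC threshold grid follows the mean-consecutive-gap rule exactly as
  stated; an alternative reading (thresholds at the observed values
  themselves) is effectively what the rank oracle computes, and the two
  can differ by up to ~0.02 at small n.
* No HDF5 I/O: sessions are read and written as plain CSV
  (time/f465/f405 with the sampling rate in a header comment, events as
  trial/onset_s/duration_s/solution).
* The delayed-test paradigm is modeled identically to single pairing with
  a different calendar gap; the package does not model time-dependent
  forgetting — the suppression trajectory is whatever the user injects.

```{r example, eval = FALSE}
# a complete paradigm-level analysis
cfg <- paradigm_config("single_extinction", n_per_group = 7, seed = 1)
report <- run_paradigm(cfg)
summary(report)
save_report(report, "results/extinction")
```
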