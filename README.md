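# ctaphot

Fiber-photometry and behavioral analysis for conditioned taste aversion
(CTA) experiments in rodents.

Intraoral infusion paradigms deliver a tastant (sucrose, quinine) directly
into the mouth while dopamine sensor fluorescence (GRAB_DA in the NAc, or
GCaMP in VTA dopamine neurons) is recorded through an implanted fiber.
Pairing sucrose with LiCl-induced malaise conditions a taste aversion:
the same taste that once evoked a phasic dopamine transient now suppresses
dopamine, the rat's orofacial/somatic reactivity to the infusion rises, and
voluntary sucrose preference collapses — all of which recover under
extinction. `ctaphot` implements the full analysis chain for such
experiments, plus a synthetic-data generator with known ground truth so
every stage can be validated end to end. It is aimed at behavioral
neuroscientists analyzing two-channel photometry with trial-locked events,
DeepLabCut pose output, and two-bottle consumption data.

## What it computes

**Photometry preprocessing** (per session):

1. *Isosbestic correction.* The 405 nm control channel is mapped onto the
   465 nm signal channel by an ordinary least-squares affine fit over the
   whole session, and

   ΔF/F = (F₄₆₅ − fit(F₄₀₅)) / fit(F₄₀₅)

   removes photobleaching and motion artifacts while sparing
   sensor-dependent transients.
2. *Smoothing.* A fifth-order Butterworth bandpass (0.05–2.25 Hz), applied
   forward and backward (zero-phase), realized as a numerically stable
   cascade of second-order sections.
3. *Normalization.* z = (x − μ)/σ with the whole-recording mean and
   population SD, so sessions and rats are comparable.
4. *Trial statistics.* The z-scored trace is aligned to infusion onsets
   (−5 to +10 s windows) and the **mean z-score over the 5-s infusion
   window** is the per-trial response; its across-trial mean is the session
   response.

**Discriminability.** An ideal-observer ROC compares the trial statistics
of two conditions: hit and false-alarm rates are swept over a
data-adaptive threshold grid (step = mean gap between consecutive sorted
observed values), the AUC is the trapezoidal integral, and AUC > 0.7
flags the conditions as reliably discriminable. An exact
Wilcoxon–Mann–Whitney pair-counting AUC serves as the independent oracle.

**Behavioral reactivity.** DeepLabCut tracks are likelihood-filtered
(< 0.95 interpolated), converted to cm with stationary-landmark
calibration, and reactivity is the change in path length from the 5-s
pre-infusion baseline to the 5-s infusion window (nose/forepaws from the
below view; ear-midpoint head position from the above view). Two-bottle
preference = sucrose consumed (g) / total fluid consumed (g).

**Statistics.** Paired t-tests; one-way repeated-measures ANOVA with
Greenhouse–Geisser correction and a Dunnett versus-reference post hoc;
two-way mixed (group × day) ANOVA with Šidák or uncorrected Fisher LSD
post hocs; linear regression with r², slope test and 95% confidence bands.

**Synthetic experiments.** `simulate_cohort()` generates complete
paradigms — Single-pairing, Single-pairing with Extinction, Delayed-test,
Repeated-pairing with Extinction — with a known per-day suppression
trajectory for the Paired group, pose tracks with injected reactivity, and
preference records coupled to suppression.

## Worked example

Simulate one appetitive and one aversive 30-trial session, preprocess,
and ask how well an ideal observer separates them trial by trial:

```r
library(ctaphot)

ev    <- make_event_schedule(30, seed = 1)          # 5-s infusions, 35-55 s ITI
appet <- simulate_photometry_session(ev, sim_params(suppression_factor = 1,    seed = 2))
avers <- simulate_photometry_session(ev, sim_params(suppression_factor = -0.5, seed = 3))

stats    <- infusion_mean_zscore(align_trials(preprocess_session(appet$session)))
stats_av <- infusion_mean_zscore(align_trials(preprocess_session(avers$session)))

head(stats, 3)
#>   trial mean_z
#> 1     1 0.0668
#> 2     2 0.4120
#> 3     3 1.5276
session_mean_z(stats)       # 1.017
session_mean_z(stats_av)    # -0.234

ideal_observer_roc(stats$mean_z, stats_av$mean_z)
#> <io_roc> AUC = 0.916 (n+ = 30, n- = 30): discriminable
```

The per-trial values are mean z-scores in the infusion window: about +1 z
for the intact dopamine response, below zero once the transient is
inverted, and an AUC of 0.92 (> 0.7) says single trials from the two
conditions are reliably discriminable.

A whole paradigm runs in one call:

```r
cfg <- paradigm_config("single", n_per_group = 10, seed = 1)
report <- run_paradigm(cfg)
report          # per-day ROC table, paired t per group, regressions
save_report(report, "results/single")
```

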