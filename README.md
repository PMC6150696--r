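# stridelab

Stride-level analysis of hindlimb locomotor EMG and kinematics in R.

Treadmill studies of motor adaptation record two synchronized streams per
session: 3D marker trajectories of six hindlimb landmarks (rostral/caudal
pelvis, hip, knee, ankle, toe; 200 Hz) and intramuscular EMG of seven
muscles (VL, VM, RF, SM, BFp, TA, GRc; 5000 Hz). The questions live at the
level of the gait cycle: how stance duration, joint angles and ranges of
motion change across weeks of adaptation, and how much each muscle's
stance-related burst changes relative to its own baseline. `stridelab`
implements that chain end to end, for experimenters analyzing such
recordings and for methodologists who need a fully testable reference
pipeline:

- **EMG conditioning** — zero-phase 5–500 Hz Butterworth band-pass,
  rectification, 20 Hz linear envelopes, data-driven burst-onset detection.
- **Kinematics** — 10 Hz zero-phase marker low-pass, sagittal projection,
  knee reconstruction by two-circle triangulation from femur and tibia
  lengths (bypassing skin-movement artifact), joint angles with the
  0° = full flexion convention, global limb length/angle, stance detection
  from the toe's belt-locked velocity.
- **Strides** — segmentation at tibialis anterior burst onsets; screening by
  the 1.5 SD duration rule, the Tukey 1.5 IQR envelope-maximum rule and the
  strict > 20% missing-kinematics rule; time normalization to 100 samples.
- **Features** — stance percentage, per-joint ROM, angles and limb features
  at end-of-stance and mid-burst, integrated extension-burst EMG normalized
  to each subject's baseline mean.
- **Statistics** — linear mixed-effects models (`value ~ week` with
  by-subject random intercept and slope; `log(EMG) ~ week × muscle` with a
  session-within-subject level), Wald contrasts on Satterthwaite degrees of
  freedom with Bonferroni correction, paired t-tests for muscle masses,
  broom-style `tidy()`/`glance()` and ggplot2 `autoplot()` methods.
- **Synthesis** — `gait_scenario()` / `generate_experiment()` build whole
  experiments with known ground truth (stride boundaries, stance intervals,
  joint-angle series, per-muscle burst gains), so every stage is verifiable
  without access to raw recordings.

The core statistical quantity is the normalized integrated extension burst
of muscle $m$, stride $s$: $E_{ms} = \int_{W_s} \mathrm{env}_m(t)\,dt \big/
\overline{E}_m^{\,\mathrm{base}}$, the integral of the envelope over the
stance-related burst window divided by the subject's baseline mean, modelled
as $\log E \sim \mathrm{week} \times \mathrm{muscle} + (1 +
\mathrm{week}\,|\,\mathrm{subject}) + (1\,|\,\mathrm{session})$.

## Worked example

Simulate a two-week, two-subject experiment and run the full analysis:

```r
library(stridelab)
library(dplyr)

spec <- gait_scenario(n_subjects = 2, weeks = c("base", "week1"),
                      strides_per_session = 20, seed = 1)
gen <- generate_experiment(spec)
gen$trials$S01_base
#> <trial_recording> subject S01, base, session S01_base
#>   markers: 2915 frames @ 200 Hz (14.6 s), 2.15% masked
#>   EMG:     72873 samples @ 5000 Hz, belt 12 m/min

res <- analyze_experiment(gen$trials)
str(res$manifest)
#> List of 8
#>  $ trials_read               : int 4
#>  $ strides_segmented         : int 76
#>  $ strides_included          : int 53
#>  $ strides_excluded          : int 23
#>  $ excluded_duration_outlier : int 9
#>  $ excluded_emg_artifact     : int 12
#>  $ excluded_kinematic_missing: int 4
#>  $ features_emitted          : int 1484

res$features |>
  filter(feature %in% c("stance_pct", "rom_knee", "int_emg_RF", "int_emg_VM")) |>
  group_by(week, feature) |>
  summarise(mean = mean(value), sd = sd(value), n = n(), .groups = "drop")
#> # A tibble: 8 × 5
#>   week  feature     mean     sd     n
#>   <chr> <chr>      <dbl>  <dbl> <int>
#> 1 base  int_emg_RF  1    0.0613    29
#> 2 base  int_emg_VM  1    0.0596    29
#> 3 base  rom_knee   58.2  5.05      29
#> 4 base  stance_pct 62.0  2.99      29
#> 5 week1 int_emg_RF  2.53 0.248     24
#> 6 week1 int_emg_VM  1.02 0.0986    24
#> 7 week1 rom_knee   34.1  2.47      24
#> 8 week1 stance_pct 53.6  2.77      24
```

Reading the table: baseline-normalized integrated EMG averages exactly 1 at
baseline by construction; at week 1 the scenario injects an elevated RF
burst (recovered here as 2.53×) while VM stays near baseline (1.02×), and
stance percentage and knee ROM drop, matching the scenario's transient
kinematic deficit. Exclusion counts in the manifest always satisfy
segmented = included + excluded.

Model the features and test week effects:

```r
fit <- fit_emg_lmem(res$features)          # log(E) ~ week * muscle + ...
emg_contrasts(fit)                          # Bonferroni-corrected family
tidy(fit); glance(fit)
autoplot(emg_contrasts(fit))                # estimate ± CI dot plot
```

File-based workflows mirror the in-memory one: `write_synthetic_experiment()`
writes `markers.tsv` / `emg.tsv` / `meta.yaml` trial directories plus ground
truth, and `run_pipeline(data_dir, out_dir)` reads any such tree and emits
`features.tsv`, a stride ledger, contrast tables and a run manifest.

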