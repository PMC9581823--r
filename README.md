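# dynfc

Sliding-window dynamic functional connectivity (dFC) and its longitudinal
association with cognition, for three-group, two-timepoint resting-state
fMRI cohort designs — the setting of prospective studies of
cancer-related cognitive impairment, where chemotherapy-treated patients,
untreated patients and no-cancer controls are scanned and tested before
treatment and again months later.

The package is aimed at neuroimaging analysts who already have
parcellated region-by-time BOLD series (e.g. 90 AAL regions × 180
volumes) and want a tested, reproducible implementation of:

* **Connectivity variability.** Per scan, absolute Pearson correlations
  `|r_ij,w|` are computed in sliding windows (default: 28 volumes stepped
  by 5, i.e. 58.8 s / 10.5 s at TR = 2.1 s, 31 windows per 180-volume
  scan) and each connection is summarized by its coefficient of
  variation,

  `dFC_ij = SD_w(|r_ij,w|) / mean_w(|r_ij,w|)`,

  then averaged over network-to-rest connections (default mode network,
  frontoparietal network) and over the whole brain.
* **A surrogate null model.** Multivariate phase randomization with a
  common phase vector across regions preserves every full-length pairwise
  correlation and each region's power spectrum while destroying genuine
  coupling dynamics; a paired t-test compares observed whole-brain dFC
  against the mean of K = 20 surrogate copies per participant.
* **Normative cognitive change scores.** Raw HVLT-R immediate recall and
  TMT-B scores are z-standardized against the control group's baseline
  (TMT-B sign-flipped so lower z = worse everywhere); follow-up
  performance is corrected for baseline, age and premorbid IQ via an OLS
  model fitted in the norm group, leaving residual change scores that are
  compared across groups with one-way ANOVAs and pooled-SD effect sizes.
* **Repeated-measures ANCOVA.** Type-III (effect-coded,
  full-vs-reduced-model) tests of group, time, a continuous dFC change
  score, all interactions, and age/IQ covariates, built on the exact
  two-timepoint mean/difference decomposition; per-group slopes expose
  sign-reversing associations.
* **A synthetic-cohort generator** producing BOLD-like AR(1) signals with
  sinusoidally modulated network coupling of controllable depth and
  cognitive scores linearly coupled to the true connectivity change with
  group-specific slopes — so the entire pipeline is testable with known
  ground truth and no scanner data.

See `vignettes/dynamic-connectivity-pipeline.Rmd` for the full methods
account.

## Worked example

```r
library(dynfc)
regions <- default_region_table()      # 90 AAL regions, 78 cortical
spec    <- window_spec(28, 5)          # 58.8 s windows, 10.5 s step

## one synthetic scan with genuinely dynamic coupling (depth a = 0.2)
cfg <- sim_config(seed = 42)
ts  <- simulate_timeseries(cfg, a = 0.2, seed = 42)
round(dfc_summaries(ts, regions, spec), 4)
#> DMN_dFC FPN_dFC  WB_dFC
#>  0.6173  0.6289  0.6056

## the phase-randomization null says how much CoV static coupling produces
surrogate_whole_brain_dfc(ts, spec, K = 20, seed = 43)
#> [1] 0.5614
```

The observed whole-brain dFC (0.6056) exceeds its surrogate mean
(0.5614): this scan's connectivity varies more across windows than its
stationary correlation and autocorrelation structure alone can explain,
i.e. the imposed coupling dynamics are detected.

```r
## a full cohort (34/32/35) with a sign-reversing dFC-cognition coupling
cfg2 <- sim_config(seed = 7,
                   modulation_depth = matrix(c(0.15, 0.15, 0.15,
                                               0.25, 0.25, 0.25), 3, 2),
                   cognitive = list(slope = c(BCC_PLUS = -8,
                                              BCC_MINUS = 8, NC = -8)))
sim <- simulate_cohort(cfg2, timeseries = "none")
fit <- rm_ancova(sim$cohort, ancova_spec("HVLT_IR"))
fit$results[fit$results$term == "group:dfc_change", ]
#>               term f_value df_num df_den p_value significant
#> 3 group:dfc_change   8.111      2     93   6e-04        TRUE
round(fit$slopes, 2)
#>  BCC_PLUS BCC_MINUS        NC
#>    -11.82      8.84     -3.95
```

The group-by-dFC-change interaction is significant at the package's
α = 0.01, and the per-group slopes recover the generated pattern: memory
change rises with connectivity change in the untreated patient group and
falls in the other two.

A command-line front-end over the same functions is installed at
`system.file("cli", "dynfc.R", package = "dynfc")`, with subcommands
`simulate`, `dfc`, `surrogate-test`, `cognition` and `associate`; every
run writes CSV outputs plus a JSON sidecar recording parameters, seed and
package version.

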