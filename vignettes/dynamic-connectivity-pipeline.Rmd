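---
title: "Sliding-window dynamic connectivity and longitudinal cognition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window dynamic connectivity and longitudinal cognition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dynfc implements a complete analysis chain for asking whether the temporal
variability of resting-state brain networks — dynamic functional
connectivity (dFC) — changes over time in a three-group clinical cohort,
and whether that change tracks change in memory and executive function.
This vignette is the package's own account of the methods: the statistics
it computes, the modelling choices that were genuinely open, the synthetic
cohort generator used to validate everything, and the limits of what
passing tests demonstrate.

## The dFC statistic

The unit of input is one participant-timepoint scan: a region-by-volume
matrix of parcellated BOLD signal (the default parcellation is the
90-region cerebral subset of the AAL atlas, 78 cortical + 12 subcortical).
A rectangular window of `L` volumes slides along the scan in steps of `S`
volumes; only fully-contained windows count, so a scan of `T` volumes
yields `floor((T - L)/S) + 1` windows. The defaults `L = 28`, `S = 5`
correspond to 58.8 s windows advanced by 10.5 s at TR = 2.1 s, and give 31
windows in a 180-volume scan.

Within each window, all pairwise Pearson correlations are computed and
their absolute values taken — a coupling that swings between `+r` and
`-r` is treated as equally strong, and its *variability*, not its sign, is
the object of interest. Per connection, the dFC statistic is the
coefficient of variation across windows:

$$\mathrm{dFC}_{ij} = \frac{\mathrm{SD}_w\,(|r_{ij,w}|)}{\overline{|r_{ij,w}|}}$$

with the sample SD (denominator `W - 1`; the unbiased-variance
convention). Normalizing by the mean makes the statistic scale-free:
uniformly strong and uniformly weak connections with proportional
fluctuations get the same score. Connections whose mean absolute
correlation falls below `mean_floor` (default `1e-6`) are masked `NA`
rather than divided out — a near-zero denominator would otherwise produce
arbitrarily large ratios that carry no signal. The diagonal is always
masked, no Fisher z-transform is applied, and volume indexing is 1-based
everywhere a user sees it (internal indexing is also 1-based, plain R
convention).

Network summaries average the CoV over all connections between a
network's member regions and *the rest of the full parcellation*
(within-network pairs excluded): with `m` members among `N` regions,
exactly `m(N - m)` connections enter the mean, subcortical regions
included in "the rest". The whole-brain summary averages all
`N(N - 1)/2` unique connections. Only the default mode network (DMN,
memory-related) and frontoparietal network (FPN, executive-related) are
first-class labels; the other five canonical resting-state networks are
collapsed to `OTHER_CORTICAL` because no summary is ever computed for
them. The DMN/FPN membership ships as an editable CSV fixture
(`inst/extdata/aal90_yeo7.csv`) following the usual AAL-to-Yeo-7
correspondence; it is a reasonable default assignment, not a canonical
one, and swapping in another mapping requires no code change.

## The surrogate null model

A finite window over an autocorrelated signal produces variable
correlation estimates even when the underlying coupling is perfectly
static, so observed CoV values need a reference distribution. The package
uses multivariate phase-randomization surrogates: take the discrete
Fourier transform of each region's series, draw **one** random phase
offset per positive frequency (uniform on `[0, 2π)`), apply that common
phase vector to every region's spectrum with conjugate symmetry on
negative frequencies, and invert. The DC bin is untouched, and for
even-length series the Nyquist bin's phase is held at 0 so the output
stays exactly real.

Because every region is rotated by the same phases, all cross-spectra are
unchanged, so the surrogate preserves each region's amplitude spectrum
(hence variance and circular autocorrelation) and every full-length
pairwise correlation to numerical precision — while any genuine
time-localized coupling structure is scrambled. Independent per-region
phases would destroy the stationary correlations and make the null model
wrong, which is why the common-phase construction is not optional. Passing
`phases = 0` is a test hook that must reproduce the input exactly.

The test statistic is a two-sided paired Student t over participants:
observed whole-brain dFC versus the mean over `K = 20` surrogate copies
(per-copy sub-seeds are `seed + k`, a counter scheme that makes
regeneration bit-identical and parallel-safe). With the pooled study-sized
sample of 101 participants this has 100 degrees of freedom. Which
timepoint feeds the test is the user's choice; the CLI defaults to
baseline. A degenerate case is defined rather than errored: when observed
and surrogate values coincide exactly the test returns `t = 0, p = 1`;
zero-variance differences around a nonzero mean are an error.

## Cognitive change scores

Raw scores — HVLT-R immediate recall (words, higher better) and TMT-B
completion time (seconds, higher worse) — are z-standardized against the
normative control group's baseline mean and SD. TMT-B is sign-flipped at
standardization so that lower z uniformly means worse performance; raw
seconds are never compared across tests. The norm group is configurable
and may legitimately be larger than the imaging sample (controls with
cognitive data but no usable scans still inform the norms).

Follow-up performance is corrected for baseline with regression-based
change scores: an OLS model of follow-up z on baseline z, age and
premorbid IQ, fitted in the norm group only, generates predicted follow-up
scores for everyone; the residual (observed − predicted) is the
ANOVA-ready change score. Norm-group residuals average to zero by
construction. Group differences are tested with one-way ANOVAs, and
standardized effect sizes use the pooled-SD form
`(m1 - m2) / sqrt(((n1-1)s1² + (n2-1)s2²)/(n1+n2-2))`. Missing data are
handled by listwise exclusion per test, with excluded ids messaged — no
imputation. CSV outputs round effect sizes half-away-from-zero to two
decimals; full precision is kept internally.

## Longitudinal models

Connectivity change is summarized by simple delta scores (follow-up −
baseline); no linearity-of-change assumption is imposed on imaging
measures, so the regression-based correction used for cognition is *not*
applied to dFC.

With exactly two timepoints, repeated-measures models decompose exactly:
between-subject effects are ordinary linear models on per-subject means of
the two timepoints, and every effect involving time is an ordinary linear
model on per-subject differences, where the difference-model intercept is
the time main effect. The three-way ANCOVA relates a cognitive outcome to
group, time, and the continuous dFC change score, with age and IQ as
covariates. Although the change score is described as a within-subject
variable in the repeated-measures framing, it is one number per
participant; it is therefore modelled as a between-subject continuous
predictor that may interact with time, which reproduces the conventional
degrees-of-freedom pattern (`F(2, ·)` for group-by-change, `F(1, ·)` for
time).

Modelling choices that were genuinely open, and how they were fixed:

* **Sums of squares.** Type-III-style full-versus-reduced model
  comparisons with sum-to-zero (effect) coding for group, matching the
  full-factorial convention for unbalanced groups. The independent test
  oracle is `car::Anova(type = 3)`.
* **Centering.** The dFC change score and both covariates are
  grand-mean-centered before interactions are formed, so main effects
  remain interpretable in the presence of interactions. All F statistics
  are invariant to affine rescaling of the covariates.
* **Covariates in the within-subject stratum.** Age and IQ enter the
  difference model as nuisance regressors (their interaction-with-time F
  values are not reported), so both error strata share the same residual
  degrees of freedom — the convention of full-factorial repeated-measures
  ANCOVA in mainstream GUI statistics packages.
* **Significance threshold.** `alpha = 0.01` throughout, a deliberate
  guard against type-I inflation across the many terms of a full-factorial
  model; no further multiplicity correction is applied. The flag uses a
  strict inequality: `p` exactly equal to alpha is not significant.
* **Degenerate designs.** A constant continuous predictor makes the design
  rank-deficient; the error names the aliased term. A response with zero
  residual variance (e.g. follow-up identical to baseline everywhere)
  returns `F = 0` rather than `0/0`.

Per-group OLS slopes of the cognitive change on the centered dFC change
accompany every ANCOVA fit, for inspecting slope-inhomogeneity patterns
(the situation where the association runs in opposite directions in
different groups, which the interaction term formally tests).

## The synthetic cohort generator

No scanner data ships with the package; every pipeline stage is validated
on synthetic cohorts whose ground truth is known. The generator emulates:

* **BOLD-like autocorrelated noise.** All signals are stationary AR(1)
  processes (coefficient 0.3) — the minimal model that makes the
  surrogate's "autocorrelation preserved" guarantee non-trivial.
* **Time-varying coupling of controllable depth.** Each region tracks the
  latent signal of its network (DMN, FPN, or a shared "other") with
  coupling `w_r(t) = w0 + a sin(2πt/P_r + φ_r)`, period `P_r` drawn from
  40–80 volumes and phase `φ_r` uniform, per region. The modulation depth
  `a` is the dynamic ground truth: `a = 0` is truly static coupling (the
  null for calibration tests), and larger `a` produces genuinely deeper
  connectivity dynamics. Headroom `w0 + a ≤ 1` keeps the noise-mixing
  weight `sqrt(1 - w²)` real. Sinusoidal modulation was chosen over
  regime-switching because a single depth parameter makes monotonicity
  properties precise; regime-switching is a documented alternative, not
  implemented.
* **A global signal.** The three network latents share a common component
  (`latent_correlation = 0.8` of their variance). This serves two
  purposes: mean between-region |r| lands near 0.25–0.3, the regime
  typical of parcellated resting-state data without global-signal
  regression; and member-to-rest connections — the ones the network
  summaries average — actually carry modulated coupling. With fully
  independent latents, between-network correlations sit below the
  windowed sampling noise, where the CoV is provably insensitive to
  modulation depth, and network-level dFC would not respond to the ground
  truth at all. `w0 = 0.55` was fixed together with this choice.
* **Three groups, two timepoints, dFC-coupled cognition.** Default group
  sizes 34/32/35; age ~ Normal(50, 9), IQ ~ Normal(104, 13). Modulation
  depths are set per group × timepoint, with per-participant jitter
  (`modulation_depth_sd = 0.05`) — without individual variability in the
  true dynamics, within-group dFC–cognition slopes would be
  unidentifiable. Cognitive follow-up z-scores are linear in the *true*
  depth change with group-specific slopes, so the measured dFC delta acts
  as a noisy proxy and attenuation is visible and honest in power
  studies. The default slopes (+ for the untreated patient group, − for
  the other two) emulate a sign-reversing association, the pattern the
  interaction test exists to detect. TMT-B is generated on the seconds
  scale so the standardization sign-flip is exercised end to end.

All randomness flows from one master seed; scan-level sub-seeds are
`master + 7919·participant + timepoint` reduced into 32-bit range.

What the generator does **not** emulate: hemodynamic response convolution,
physiological noise and scanner drift, head motion, spatial structure
within regions, non-stationary noise variance, and realistic
between-region heterogeneity of coupling strength. Passing tests therefore
demonstrate that the statistics are computed correctly and are calibrated
and powered under a plausible dynamic-coupling model — not that the
pipeline's scientific conclusions transfer to any particular scanner or
population.

## Problem sizes and numerical checks

The test suite validates window enumeration against exhaustive
enumeration, windowed correlations against a two-pass textbook Pearson
oracle (1e−12), the CoV and network averages against brute-force
enumeration, the repeated-measures decomposition against `aov` error
strata and `car::Anova` Type-III fits (1e−8), and the surrogate's
preservation guarantees at 1e−8 on full-size 90 × 180 inputs. Stochastic
guarantees are checked at sizes chosen to keep the default run fast while
retaining power: type-I calibration of the ANCOVA over 500 null cohorts of
n = 101 (term-wise rejection rates inside exact binomial 95% bounds at
alpha = 0.01); interaction power above 0.8 over 200 cohorts with
opposite-sign slopes of 0.8 SD-units; dFC monotonicity in modulation depth
over 50 seeds per level at 30–90 regions; and calibration of the surrogate
paired test over 200 small cohorts (8 participants, 10 regions, 100
volumes) of truly static coupling. Monte-Carlo comparisons across depth
levels share seeds (common random numbers), which is what makes strict
ordering of means a reasonable assertion at 50 seeds.

## Known limitations

* The CoV is undefined for connections with near-zero mean correlation;
  masking is a pragmatic floor, and cohorts with globally weak coupling
  will propagate many `NA`s into network averages.
* The two-timepoint decomposition is exact but does not generalize to
  three or more timepoints; no sphericity machinery is included because
  none is needed at two.
* The surrogate preserves the *circular* autocovariance implied by the
  periodogram; edge effects make the non-circular sample ACF agree only
  approximately, which is inherent to Fourier surrogates.
* Group labels beyond the three-arm design (chemotherapy-treated,
  untreated, no-cancer control) are not supported without relabelling.
* The AAL-to-Yeo fixture is a sensible default correspondence, not a
  published lookup table; analyses sensitive to exact network membership
  should supply their own mapping.
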