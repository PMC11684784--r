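---
title: "Decoding anticipatory tone representations: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding anticipatory tone representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predecode)
```

This vignette is the package's own account of its models and the choices
behind them: what the synthetic-data generator emulates and what it does not,
how the decoder and the prediction score are defined, how the inference
procedures are parameterized, and where the design was genuinely open.

## 1. The stimulus model

Tone sequences are first-order Markov chains over `K = 4` carrier
frequencies at a 3 Hz stimulation rate (SOA 1/3 s). Each condition's
transition matrix has its diagonal pinned at `1/K = 0.25`, so self-repetition
probability never varies with regularity; the remaining 0.75 of each row is
concentrated on one *designated successor* per tone with condition-dependent
strength and spread evenly over the other two tones:

| condition | successor mass | mean row entropy (bits) |
|-----------|---------------:|------------------------:|
| random    | 0.25           | 2.000 |
| midminus  | 0.416          | 1.889 |
| midplus   | 0.583          | 1.552 |
| ordered   | 0.75           | 0.811 |

The two intermediate successor probabilities are not published for the
original paradigm; we interpolate the successor concentration linearly
between the flat and fully ordered endpoints (0.25 → 0.75 in equal steps),
which reproduces both stated endpoints and yields a strictly monotone
entropy gradient. The successor map is the cyclic permutation
`tone i → i+1 mod K`; any fixed derangement-free permutation is statistically
equivalent, and the cyclic one makes the confusion-matrix bias score (below)
well defined. Omissions (10% in the four-condition design) are drawn as
exactly `round(rate · n)` positions without replacement — the design reports
exact counts (900 sounds + 100 omissions per block), so a per-trial Bernoulli
draw would be wrong. The first tone of each sequence is uniform, which is the
stationary distribution of every condition matrix (rows are
permutation-symmetric with fixed diagonal).

Two presets cover the two study designs: four entropy conditions with 1000
stimuli per block, carriers 200/431/928/2000 Hz, epochs (−1, 1) s; and
random + ordered only, 1500 stimuli per condition in alternating 500-stimulus
segments, carriers 440/587/782/1043 Hz, epochs (−0.4, 0.5) s. Carrier sets
are geometric (log-spaced) between their endpoints, rounded to the hertz.

## 2. The sensor model and epoch generator

Epoched sensor data live on a 100 Hz grid (the analysis resolution after
down-sampling in MEG practice). Each tone evokes
`topography(tone) ⊗ kernel(t − onset)`: topographies are unit-norm spatially
smooth patterns, one per tone, redrawn until all pairwise |cosines| are below
0.8 (discriminable but far from orthogonal); the temporal kernel is causal
with two Gaussian components — early (peak 100 ms) and late (peak 450 ms,
the reactivation window that matters for anticipatory decoding). Because the
SOA (333 ms) is shorter than the kernel support (600 ms), neighbouring tones
overlap inside every epoch. This is deliberate: it reproduces the paradigm's
structural confound that, in ordered sequences, the pre-stimulus interval
systematically contains the responses of *predictive* neighbouring tones.
Noise is stationary Gaussian with a squared-exponential spatial covariance
(correlation length 5 channel units at 102 channels, shrinking
proportionally for smaller arrays) and mild temporal smoothing; there is no
1/f component, no artifacts, and no forward model — sufficient for
exercising the decoding contract, not a biophysical simulation.

The group effect is a pre-stimulus term added on ordered-condition trials
only: `alpha_pre · topography(predicted tone) ⊗ bump(t)`, where the
predicted tone is the transition-matrix successor of the *previous* tone
(predictions follow the learned regularity, so on self-repeat trials the
prediction is wrong by design), and the bump is a late-component-scaled
Gaussian centred at −380 ms with sd 70 ms. Controls default to
`alpha_pre = −0.3 · a_late` (deactivation) and tinnitus-like subjects to 0,
mirroring the conclusion that below-chance decoding in controls drives the
group difference; both signs are supported.

### Generator calibration

The published results give no sensor-unit effect size, so the generator's
amplitude parameters are calibration targets, set once from a pilot grid and
not revisited: `a_early = 1`, `a_late = 1`, `snr = 1.5` (per-channel evoked
peak over per-channel noise sd). Two facts from the pilot shaped these
choices. First, the anticipatory term is ~7× weaker than the evoked
components and flips classifier decisions only near decision boundaries, so
its downstream visibility depends jointly on snr and trial count — at
`snr = 1.5` with 200 trials per condition and 20 subjects per group, the
one-sided group cluster test recovers the effect in ≥ 80% of replicate
cohorts, which is the regime the replicate-cohort checks run in (16
channels; the full 102-channel array behaves the same but costs more).
Second, single-subject peak decoding accuracy at these settings is ≈ 0.5–0.6
against 0.25 chance — on the optimistic side of real MEG tone decoding, a
consequence of favouring a strong late template so the anticipatory contrast
is expressible at desk-scale cohort sizes.

### What passing tests do and do not show

The generator emulates the stimulus design, the response-overlap structure,
spatially correlated noise, and a controllable anticipatory effect. It does
not emulate inter-subject topography variability (all subjects share one
sensor model), realistic artifact structure, 1/f noise, or source geometry.
Tests passing on this generator therefore validate the *pipeline* — its
algebra, calibration, and inferential error rates — not any claim about real
cohorts.

One structural finding deserves emphasis: with overlapping deterministic
templates, cross-validated accuracy after label permutation sits slightly
*above* 25% at small trial counts (~+2 pp at 320 trials, shrinking toward 0
as trials grow), because a frozen permutation's incidental context–label
associations are partially learnable from duplicate context templates. An
independent LDA implementation reproduces the same value on the same data,
and the effect vanishes on exchangeable (iid) epochs, where accuracy is
0.252 ± 0.002. Chance-calibration checks therefore use exchangeable epochs;
analyses of real paradigms with temporally overlapping epochs should expect
the same small finite-sample elevation under label permutation.

## 3. The decoder

Per time point, a multiclass linear discriminant with a pooled within-class
covariance shrunk toward the scaled identity, `S* = (1−λ)S + λν̄I`, with λ
the Ledoit–Wolf analytic estimate by default (the original toolbox's exact
regularization is not published; analytic shrinkage is the standard stable
choice at trials ≈ channels, and λ is configurable). Degenerate zero-variance
fits fall back to nearest-class-mean. Folds are stratified by tone class
under a fixed seed — fivefold CV is stated in the design, stratification is
our choice to guarantee every class in every fold. Omission trials are
excluded from all decoding.

Three decoding routes share this core: (i) CV decoding of the random
condition per time point, with temporal generalization by applying each
training-time classifier to every testing time of the held-out folds;
(ii) cross-condition decoding — classifiers fit once per training time on
all random-condition trials, applied to any other condition at all testing
times, including training post-stimulus and testing pre-stimulus; (iii)
pre-stimulus testing on the random condition itself, which reuses the CV
folds (train post-stimulus on training folds, test pre-stimulus on held-out
folds) to avoid leakage. Confusion tensors are accumulated at
train-time = test-time; the bias score is the mean row-normalized mass on
`predicted = true+1` minus `predicted = true+2` along the cyclic transition
direction (a non-cyclic variant restricted to the strictly-upper diagonals
is provided; the cyclic reading matches the cyclic transition structure and
is the default).

## 4. Prediction scores and windows

The β-slope score regresses accuracy on a numeric condition code at every
(training, testing) point, keeping the slope and discarding the intercept;
the default coding is equally spaced integers 0..3 (random → ordered), which
the original analysis does not state — with equal spacing the slope is a
linear contrast, and any affine recoding rescales all subjects identically,
leaving group statistics unchanged. The two-condition difference score
`A_ordered − A_random` equals the β-slope under 0/1 coding (tested exactly).

Inference windows default to 470–570 ms training × −400–0 ms testing. The
two-condition design's epochs end at +500 ms, so the training window
overhangs the epoch by 70 ms; how the original analysis resolved this is not
stated. We clip the window to the epoch with an explicit warning (the
configuration validator flags it up front), and both the windows and the
epoch are configurable so the longer-epoch reading is also runnable.

## 5. Inference

*Cluster-based permutation tests.* Mass-univariate t maps (pooled-variance
two-sample, or sign-flip one-sample) on 1-D time courses or 2-D time–time
grids; threshold at the parametric t quantile for `cluster_alpha = 0.05`
(read as both the cluster-forming and cluster-level alpha, the convention of
the cited nonparametric framework; both are configurable); clusters are
maximal contiguous runs (1-D) or 4-neighbourhood components (2-D) scored by
summed t; the null is the maximum cluster score over label permutations or
sign flips; p-values use the `(b+1)/(m+1)` estimator, so p = 0 is
unattainable and the minimum p is `1/(n_perm+1)`. One-sided tests only form
clusters of the tested sign. The group test for the anticipatory effect is
one-sided (tinnitus > control), matching the directional replication
hypothesis; the 2-D matrix-wide variant defaults to two-sided.

*Bayes factors.* JZS (Cauchy-prior, scale √2/2) Bayes factors via numerical
integration of the g-scale-mixture marginal likelihood; the tests verify the
implementation against an independent quadrature of the noncentral-t ×
Cauchy representation — two mathematically equal but distinct routes — to
1% relative error, and BF reciprocity to 1e-10. BF > 3 is reported as
supportive, the convention used with this prior.

*Equivalence.* TOST with two one-sided Welch tests. The original equivalence
bounds are not stated; the default is δ = 0.5 standardized units, and the
bound (and raw/standardized interpretation) is always reported alongside the
decision.

*Logistic models.* Tinnitus status on the windowed prediction score with
mean hearing ability (PTA-4, optionally extended to 6000/8000 Hz) as a
covariate; odds ratios are reported per 1 sd of score; (quasi-)perfect
separation is detected and flagged rather than silently diverging; the
reversed linear model (score on group) is also reported.

*Multiplicity.* Corrections are applied within each analysis (Bonferroni
over time points, cluster-level control over a window) but not across the
several reported analyses, matching the reporting convention of the original
studies; this is a documented property, not an oversight.

## 6. Numerical and degenerate-input choices

Zero rows in entropy computation use `0·log 0 = 0`. Constant accuracy
columns in pointwise tests produce an undefined 0/0 t only when the mean
equals chance — flagged non-significant with a warning; constant columns
away from chance keep their infinite t (p = 0). Spearman on constant input
returns NA with a warning. The JZS integrand is integrated with
`rel.tol = 1e-9` and fails loudly. All stochastic stages take explicit
integer seeds; a master seed derives per-stage and per-subject seeds by a
fixed affine rule modulo 2³¹−1 (`derive_seed()`), making entire pipeline
runs byte-reproducible (tested).

## 7. Problem sizes used by the checks

The package's own verification runs use reduced but honest sizes chosen as
the package's simulation scale: replicate-cohort checks use 20 + 20
subjects, 16 channels, 200 stimuli per condition and 199 permutations (50
effect cohorts, 40 null cohorts); decoder-calibration checks use 320-trial
iid-epoch sets; cluster-test calibration uses 500 null datasets of 20 + 20
subjects over 41 time points. The design-level constants (transition
statistics, window definitions, trial economies) are checked at full scale
(100 000-tone sequences, full block structures).

## 8. Known limitations

Single shared sensor model per cohort (no between-subject spatial
variability); white-in-frequency noise; the anticipatory effect enters as an
additive deterministic template rather than a trial-varying latent process;
no source-space stage (out of scope); and the label-permutation elevation
described in §2 means chance should be established by permutation on
exchangeable surrogates, not assumed, when epochs overlap.
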