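---
title: "Methods: dominant-emotion patterns, shuffled nulls and AUC masking"
author: "cyberface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-emotion patterns, shuffled nulls and AUC masking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyberface)
```

`cyberface` analyses frame-level facial emotion-intensity streams recorded
while subjects play the Cyberball social inclusion/exclusion game. This
vignette documents the models and procedures, the tunable parameters, the
synthetic-data generator that stands in for patient recordings, and the
numerical and design choices made where the underlying protocol leaves
room.

## Input data and calibration

A recording is one subject x condition stream of per-frame intensities in
[0, 1] for the seven primary emotions (happiness, sadness, anger, surprise,
fear, disgust, contempt) plus an optional neutral channel, at 30 or 60
frames per second. The first `lead_s = 14` seconds — the time the monitor
spends setting up the game — are discarded and the clock re-zeroed, so
analysis second 1 is the first full second of play.

Automated facial coders offer a *continuous calibration* when no neutral
reference face is available: the corrected intensity of frame $i$ is

$$\max\!\left(0,\ \frac{l_a - l_m}{1 - l_a}\right),$$

with $l_a$ the raw intensity in frame $i$ and $l_m$ the per-emotion mean
over frames $1..i-1$, and the corrected neutral is
$(N_a + (1 - l_{\max,m}))/2$ with $l_{\max,m}$ the maximum of the running
means across emotions. Three edge cases are fixed by design:

* **Frame 1** has no prior frames; it uses $l_m = l_{\max,m} = 0$, so raw
  intensities pass through ("no prior evidence").
* **$l_a = 1$** makes the denominator zero; such frames are treated as
  $1 - 10^{-9}$ rather than dropped, and counted in the diagnostics.
* The ratio can exceed 1 when $l_a$ is large and $l_m$ small; calibrated
  values are **clamped to [0, 1]** (downstream types require bounded
  intensities) with a logged count.

Calibration is *off by default* in the pipeline: exported logs are already
the coder's calibrated output, and the functions exist to replay the
documented behaviour when raw streams are supplied.

## Timeline

Analysis seconds are 1-based and closed. Three temporal segments (1–59,
60–105, 106–145 s) are divided into ten intervals: 1–15, 16–30, 31–44,
45–59, 60–75, 76–90, 91–105, 106–120, 121–135, 136–145. Interval 3 spans
14 s, interval 5 spans 16 s and interval 10 spans 10 s; the others 15 s.
These boundaries are taken from the interval definitions used in the
results tables of the protocol; an alternative segment-3 start appearing
in its methods text (1:46) is noted but not used, since the interval
arithmetic and the reported grids are only consistent with the boundaries
above.

## Dominant-emotion patterns

Per-second scores are the arithmetic mean of the fps frames falling in
$[s-1, s)$; a trailing partial second is dropped. The *dominant emotion*
of a subject-second is the argmax over the seven emotions, with ties —
never addressed by the protocol, and essentially measure-zero on real
streams — broken by the fixed canonical order happiness, sadness, anger,
surprise, fear, disgust, contempt (the coder's column order). All-zero
seconds resolve the same way and are counted in a diagnostics attribute.
The neutral channel never competes.

Group patterns give, per second and condition, the percentage of subjects
whose dominant emotion is each emotion. Recording durations vary, so a
subject contributes to a second's denominator only while on-record;
seconds covered by no subject are missing. Interval grids average those
percentages over each interval's seconds (columns sum to 100 on complete
data), and the difference grid is exclusion minus inclusion (columns sum
to 0).

The **comparative error** screens a percentage swing between conditions
for significance at small samples:

$$\mathrm{CE} = 100\, z \sqrt{\frac{p_1(1-p_1)}{n_1} +
\frac{p_2(1-p_2)}{n_2}},$$

the half-width of the (for $z = 1.96$) 95% band for a difference of two
independent proportions; a swing exceeding it is deemed significant. The
functional form was reverse-engineered from the two published values it
must reproduce (28.54 at $n = 14$ and 23.88 at a hypothetical $n = 20$,
both for the 8.40% to 32.70% happiness swing) and matches both to the
printed precision.

## Shuffled white-noise null

For every second independently, the seven percentages are rearranged by a
uniform-random permutation (Fisher–Yates via R's generator, seeded). This
conserves each second's multiset of values — and hence its 100% sum —
while destroying temporal and identity structure, yielding a white-noise
twin of the pattern. Per emotion, the original and shuffled series are
compared across seconds with a two-sample t test.

Choices made where the protocol is silent:

* **Test variant**: Student's pooled-variance independent-samples t by
  default; Welch and paired variants are available behind a flag.
* **Realizations**: one shuffle per comparison by default (`k = 1`,
  faithful to the single-realization protocol); `k > 1` summarizes t over
  seeded realizations for stability.
* Seconds are treated as independent observations although the original
  series is autocorrelated; this mirrors the protocol as printed and is
  why the package also reports the null's operating characteristics: on
  patterns that are themselves white noise the false-rejection rate at
  $\alpha = 0.05$ sits in the 3–7% band (checked over 1,000 replicates in
  the test suite).
* Degenerate input (both series constant) is reported as t = 0, p = 1
  with a flag rather than an error.

## AUC and masking

Each emotion's per-second series is integrated by the trapezium rule
(`dx` = 1 s) per segment and over the full series. To make 30- and 60-fps
recordings comparable, the per-second AUC is multiplied by a reference
frame rate (30), expressing every subject on a common frame x intensity
axis; the per-second series has already absorbed the native frame rate,
so the standardized AUC is fps-invariant by construction. This reading of
the "multiply by the number of frames" standardization step is the one
that makes frame rates comparable and reproduces the published magnitude
range; it is documented as reverse-engineered. Totals are not renormalized
by duration (durations did not differ between conditions; variable-length
tails are integrated as far as data reach, and a segment with under 2 s of
data is missing).

Masking — smiling over a negative emotion — is emotion AUC + happiness
AUC within subject, condition and scope. Because the mean is linear, group
masked means equal the sum of the component group means, which is what
makes published masked tables recomputable from their component rows.
Composition shares (per-subject pie charts) divide each emotion's AUC by
the seven-emotion total, flagging all-zero scopes.

## Inference

* **Paired t** (NTS exclusion vs inclusion): classical, df $= n-1$;
  exactly constant differences are a degenerate-input error.
* **Wilcoxon signed-rank**: reported as a Z statistic (normal
  approximation with tie correction, no continuity correction — the
  convention of the major statistics suites). Zero differences are
  dropped before ranking (Wilcoxon's original treatment); ties get
  mid-ranks; all-zero differences yield a flagged Z = 0, p = 1. Against
  the exact distribution at $n \le 15$ the approximate p agrees to a few
  hundredths on random inputs (tested against `stats::wilcox.test` with
  `exact = TRUE`).
* **Two-way repeated-measures ANOVA** (condition x segment, both within):
  univariate mixed-model strata via `stats::aov` with
  `Error(subject/(condition*segment))`, giving the integer df (1/13 and
  2/26 at $n = 14$) of the classical tables. Partial $\eta^2$ is
  SS(effect)/(SS(effect)+SS(error)). Sphericity handling is not specified
  by the protocol; the uncorrected p matches its integer-df tables, and a
  Greenhouse–Geisser-corrected p (epsilon from the subject-level contrast
  covariance) is reported alongside. Normality is screened per cell by
  Shapiro–Wilk and reported, not enforced.
* **Normalizing transforms** per emotion before the ANOVA: arcsinh for
  anger, happiness, sadness, surprise; ordered-quantile rank normalization
  for fear ($\Phi^{-1}((r-0.5)/n)$ with mid-ranks); Yeo–Johnson for
  disgust with $\lambda$ estimated by maximum likelihood on the analysed
  vector itself (via `car::powerTransform`) — a deliberate
  normalize-then-test workflow with no train/test split, mirroring the
  protocol. Contempt is untransformed.
* **Extreme outliers**: values outside Q1 − 3·IQR or Q3 + 3·IQR, with
  type-7 (linear-interpolation) quartiles — the convention matters for
  the thresholds and is therefore fixed and documented. The ANOVA family
  runs with and without flagged subjects and both results are emitted so
  the sensitivity claim ("same conclusions with and without") can be
  checked rather than assumed.
* **Corrections**: Benjamini–Hochberg step-up across the 21-effect ANOVA
  family; Bonferroni (and raw p) for Spearman matrices — published scale
  correlations are captioned as corrected while their footnoted p-values
  look raw, so both are always reported.

## The synthetic cohort

No recordings of the original 14-patient cohort are public, so the
generator emulates the statistical structure the analysis assumes; it is
first-class, tested code, not a fixture.

**Intensity streams.** Per frame, emotion and recording, the latent
logit-scale value is baseline + subject intercept + injected effect +
AR(1) noise, pushed through the logistic link into [0, 1]. A latent
logistic model was chosen over Dirichlet-style sampling because coder
intensities are not constrained to sum to 1. The AR coefficient is
parameterized per second (`ar_coefficient = 0.7`, stationary
`noise_sd = 1` on the logit scale) and converted to a per-frame
coefficient as $\phi^{1/\mathrm{fps}}$, so the process is invariant to the
native frame rate. The per-subject, per-emotion intercept
(`subject_sd = 0.3`) is shared between a subject's two recordings, which
is what induces the moderate cross-condition rank correlation of AUCs
(~0.6–0.7) suggested by the few published cross-condition correlations; a
calibration choice, not a claim about the original data. The neutral
channel is 1 minus the frame's maximum emotion intensity, a plausible
complement (neutral is excluded from all analyses anyway).

**Defaults.** 14 subjects, 12 at 30 fps and 2 at 60 fps, two recordings
each with total durations uniform on 129–159 s including the 14 s lead.
The duration range was set so that the analysed timeline's tail (up to
second 145) is covered by a shrinking on-record denominator, matching how
the published interval grids extend to second 145 while mean durations
are near 130 s; the source material is not fully consistent on durations,
and this choice reconciles its timeline with its reported means. Latent
baselines (happiness −3.5, sadness −2.7, anger −3.4, surprise −4.0, fear
−4.6, disgust −4.9, contempt −3.2) were calibrated once so the defaults
reproduce the prescribed qualitative structure at the study size —
sadness the most frequent dominant emotion in both conditions (verified
across 15 seeds), contempt and anger next, fear and disgust rare — with
injected effects encoding the headline dynamics: anger ramps up over the
game during inclusion (+0.8 latent) and down during exclusion (−1.0), and
happiness (+1.2) and surprise (+1.0) ramp up over segments 2–3 of
exclusion.

**Clinical scores.** A Gaussian copula draws SCID-II, BIS-15, BEST,
DERS-E and NTS with copula correlations $2\sin(\pi\rho_S/6)$ so the
scores' Spearman matrix matches the published scale structure (e.g.
$\rho$(SCID-II, DERS-E) = 0.68, recovered within ±0.1 at $n = 500$);
non-positive-semidefinite targets are rejected. Marginals are normal with
the published means/SDs, censored to each scale's range — a monotone map,
so the copula's Spearman structure survives; censoring produces realistic
ceiling effects (and slightly shrinks moments of scales whose mean sits
near a bound, like BIS-15). Subscales load 0.75 on their total's latent
factor. The two NTS scores are a correlated pair with means 78.50 and
110.57 and SD 29; the cross-condition correlation 0.69 is implied by the
published paired t statistic (it fixes the SD of the paired difference at
about 22.9), so the paired t at $n = 14$ rejects in well over 80% of
replicates while the mean shift stays near 32.

**What the generator does not emulate**: classifier noise structure,
blinks/occlusions, sub-second expression dynamics, co-occurring
expressions beyond the injected effects, or any real-data skew beyond the
logistic-AR family. Passing tests therefore demonstrate that the pipeline
recovers structure *of this kind* at the study's size and noise level —
not that the original cohort's specific statistics are reproducible; its
subject-level statistics (published t, Z, F and correlation values for
the patient recordings) are not reproduction targets.

## Problem sizes, seeds, tolerances

Monte-Carlo checks in the test suite use sizes chosen to keep the whole
suite a few minutes on one CPU while leaving comfortable margins:
1,000 replicates for the shuffle-null false-rejection band (3–7% at
$\alpha = 0.05$), 200 for the RM-ANOVA type-I rate, 100 for power checks
(anger interaction at latent δ = 1.5, NTS paired t), 50 for
effect-direction recovery in difference grids, and $n = 500$ for copula
calibration. All stochastic stages derive child seeds deterministically
from one master seed (kept within 32-bit range), so identical
configurations produce byte-identical output trees; emitted tables carry
a hash of the configuration. Exact identities (grid column sums, masking
linearity, trapezium values) are asserted to 1e-9 or tighter; published
printed values to their printed precision.

## Known limitations

* The shuffle-null t tests inherit the protocol's independence assumption
  across seconds; with strong autocorrelation their p-values are
  anti-conservative for the original series (the null's size is verified
  only for white-noise sources).
* The RM-ANOVA requires complete balanced tables; recordings too short to
  cover a segment (under 2 s of data) make that emotion's table
  incomplete, and no imputation is attempted.
* Normalizing transforms are fitted on the analysed vector; p-values do
  not account for transform selection.
* The comparative-error formula and the AUC standardization step are
  reverse-engineered readings, each validated against the printed values
  it must reproduce.
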