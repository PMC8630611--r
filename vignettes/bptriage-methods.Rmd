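---
title: "Methods: three-zone triage for hypertension diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-zone triage for hypertension diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bptriage)
```

## The diagnostic model

The reference standard for hypertension here is the mean daytime
ambulatory blood pressure, hypertensive when SBP ≥ 135 and/or DBP ≥ 85
mmHg. Screening tests are office BP (hypertension threshold 140/90) and
home BP (135/85). Crossing a screening test with the reference defines
four phenotypes: concordant normotension (NT), white-coat hypertension
(WH: screen-positive, reference-negative), masked hypertension (MH:
screen-negative, reference-positive) and sustained hypertension (SH).

The triage partitions each screening measurement into three zones. The
lower boundary is an ROC cut-off at 95% sensitivity for detecting
reference hypertension: below it, hypertension is ruled out without
confirmatory measurement. The upper boundary is the cut-off at 95%
specificity: at or above it, hypertension is ruled in. Between the two
lies the intermediate zone, where the discordant phenotypes concentrate
and daytime ambulatory BP decides. SBP and DBP cut-offs are derived
*independently* against the same binary reference truth — four univariate
scans, no bivariate ROC — because zone membership then combines them with
worst-component logic: either component at or above the upper boundary
assigns the hypertension zone; both components below the lower boundary
assign the normotension zone; everything else is intermediate. This
matches the "and/or" convention of every guideline threshold.

Three cascade strategies traverse the zones: OBP-ABP (office, then
ambulatory if intermediate), OBP-HBP-ABP (office, then home if
intermediate, then ambulatory if still intermediate) and HBP-ABP (home,
then ambulatory). A cascade can only err in a *terminal* zone, so its
misclassifications are exactly the WH subjects in the screening arm's
hypertension zone plus the MH subjects in its normotension zone — an
identity the test suite asserts on arbitrary tables, and the reason
cascade sensitivity and specificity dominate the threshold-alone values
whenever the arm's threshold lies inside its intermediate zone.

## ROC cut-off conventions

Candidate cut-offs are the observed values themselves, with positivity
defined as value ≥ cut-off. The lower boundary is the *largest* candidate
with sensitivity ≥ 0.95; the upper boundary is the *smallest* candidate
with specificity ≥ 0.95, where specificity counts reference-negative
subjects strictly below the cut-off. Observed-value candidates (rather
than midpoint interpolation) are chosen because reported raw cut-offs in
this literature are non-integer observed means; the convention is
documented here precisely because ROC software differs silently on it.
Both scans are verified against an exhaustive brute-force enumeration in
the tests.

For clinical practicality the raw cut-offs are snapped to the nearest
multiple of 5 mmHg, with exact midpoints (x ≡ 2.5 mod 5) rounding up —
a fixed, documented rule rather than an attempt to guess intent case by
case. Degenerate results (lower ≥ upper after rounding) are an explicit
error carrying the raw cut-offs. `reference_zones()` provides the
published fixed boundaries (office 130–144/80–94, home 120–144/80–94,
written as normotension < 130/80, hypertension ≥ 145/95, etc.) so
analyses can bypass derivation entirely.

## Measurement aggregation

Office: three visits, triplicate readings. Under the development scheme
both arms are measured at visit 1; the index arm is the one with the
higher visit-1 mean SBP (ties: higher mean DBP, then the right arm), and
the office value is the mean of all index-arm readings across visits,
readings and visits weighted equally (the protocol is silent on visit
weighting; equal weighting keeps the noise-free limit exact). Under the
validation scheme both arms are measured at every visit and per-arm
whole-study means are compared instead.

Home: seven days, morning and evening triplicate sessions. The first-day
evening and second-day morning sessions are discarded; within each
remaining session readings 1 and 2 are averaged (the third is discarded;
a single-reading session contributes that reading); the home value is the
unweighted mean over session values. Validity requires, *after* the
discards, at least 5 distinct days with a ≥ 2-reading morning session and
5 with a ≥ 2-reading evening session. The discard-then-count order is a
design choice the protocol leaves open; discarded sessions are never
analyzed, so they should not confer validity either. Session-level (not
day-level) pooling is likewise chosen for simplicity and noise-free-limit
correctness. An eighth (or ninth) morning is accepted as an ordinary
session.

Ambulatory: 25 h at 30-min intervals. Validity requires strictly more
than 70% valid attempts, ≥ 14 valid daytime readings and ≥ 7 valid
nighttime readings. Clock windows are half-open `[start, end)` —
daytime 10:00–20:00 (development) or 09:00–21:00 (validation), nighttime
00:00–06:00 — with plain clock arithmetic and no time-zone logic. The
daytime mean is the reference standard; the full-span mean serves as the
24-h alternative reference, which reuses the same machinery and keeps the
135/85 threshold unless configured otherwise (no separate 24-h threshold
is assumed).

## The synthetic cohort generator

Each subject carries a latent 6-vector (office, home, daytime SBP/DBP)
drawn from a multivariate normal; readings are latent value plus
bivariate-normal reading noise (SBP/DBP noise correlation 0.7, so
physiologically implausible pulse-pressure inversions are rare and then
clamped); enrolment screens on the noisy first-visit office mean at
140/90. The defaults are **pre-screening** moments, calibrated once by
simulation so that the *screened* cohort reproduces the development
population's phenotype mix (NT 18.8%, WH 7.8%, MH 16.4%, SH 57.0%) within
a few percentage points:

| parameter | default | role |
|---|---|---|
| latent means | 126/80.5, 124.5/80, 123.5/80.8 mmHg | office, home, daytime centres |
| latent SDs | 13.5 (SBP), 10 (DBP) mmHg | between-subject spread |
| office–daytime correlation | 0.82 | controls WH/MH discordance |
| home–daytime correlation | 0.78 | home/ambulatory disagreement |
| office–home correlation | 0.62 | joint office×home distribution |
| SBP–DBP correlation | 0.60 | within and (scaled) across modalities |
| reading noise SD | office 15, home 10, ambulatory 12 mmHg | per-reading noise |
| missing session rate | 0.03 | home session dropout |
| circadian offsets | day 0, night −15 mmHg | nocturnal dip |

The large office reading noise is deliberate: screening on a noisy
visit-1 mean plus regression to the mean is what repopulates the
normotensive and masked phenotypes that a ≥ 140/90 screen would otherwise
remove. White-coat and masked structure arises purely from the
office–daytime correlation being below 1, not from explicit phenotype
labels; a subject's true phenotype is classified from the latent values.
The daytime circadian offset is 0 so that the daytime-window mean is
centred on the daytime latent value — this keeps the noise-free limit
exact (zero noise, zero dropout reproduces every latent value through the
whole aggregation chain), which the test suite uses as an oracle. The
`"validation"` preset shifts latent means up by ~1–2 mmHg and switches
the daytime window, mirroring the small reported population differences
without asserting a mechanism.

Randomness is rooted in one seed with per-subject derived substreams, so
enlarging a cohort leaves earlier subjects byte-identical and whole runs
are reproducible file for file.

What the generator does *not* emulate: autocorrelated ambulatory noise,
seasonal or treatment effects, device error, inter-arm asymmetry beyond a
constant offset, and informative missingness. Consequences observed in
the package's own checks: phenotype prevalences, the intermediate-zone
share under the published zones, and cascade accuracies are reproduced
well, but ROC-derived zones on synthetic cohorts come out roughly 5 mmHg
wider than the published ones — the Gaussian latent geometry plus
aggregate measurement noise spreads the conditional distributions more
than the real data apparently did. Passing tests therefore demonstrate
the *algorithmic* contracts, not that real BP data are Gaussian.

## Confidence intervals and comparison

All proportion metrics use exact central Clopper–Pearson intervals via
beta quantiles, chosen because they reproduce spot-checked published
intervals for sensitivity/specificity/accuracy (e.g. 186/188 →
96.2–99.9%); published PPV/NPV intervals in this literature sometimes use
prevalence-adjusted logit methods and may differ in the second decimal.
The AUC of a cascade is the single-operating-point value
(sensitivity + specificity)/2; its interval uses the Hanley–McNeil
standard error and is labelled as such — a large-sample approximation,
reported for completeness rather than exactness. Strategies are compared
by confidence-interval overlap with a closed-interval convention
(touching endpoints overlap), a deliberately conservative criterion.
Percentages print to one decimal, AUCs to three.

## Problem sizes and runtime choices

The bundled count tables make the published accuracy panels exactly
recomputable in milliseconds. Synthetic checks use cohorts of 2000
generated subjects (≈ 580 after screening and validity filters), the
Monte-Carlo orthant oracle uses 10^6 latent draws, brute-force ROC
comparisons use cohorts of ≤ 100 across dozens of random repetitions, and
interval coverage uses 2000 binomial draws — sizes at which every
stochastic contract is sharp while the full suite runs in well under a
minute.

## Known limitations

- Zone derivation assumes the observed-value candidate convention;
  software using interpolated thresholds will differ by fractions of the
  inter-observation spacing.
- The generator's Gaussian latent model widens derived zones relative to
  published ones (above); fixed-boundary mode exists precisely so that
  published zones can be applied exactly.
- The 24-h reference mode keeps the 135/85 threshold by default; a
  guideline 24-h threshold (e.g. 130/80) must be supplied explicitly.
- Count-level evaluation cannot reproduce the office→home→ambulatory
  cascade, which needs the joint office×home distribution; that strategy
  requires subject-level data (real or synthetic).
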