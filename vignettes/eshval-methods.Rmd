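---
title: "Methods: device validation statistics under the ESH International Protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: device validation statistics under the ESH International Protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The decision procedure

An ESH IP 2010 study alternates seven readings per session between a
criterion and a test device (criterion at positions 1, 3, 5, 7; test at
2, 4, 6). The protocol computes the six successive-pair absolute
differences and then classifies, per test reading, the *smaller* of its
two flanking differences — three classified differences per participant,
session and variable. We adopt this min-of-flanks reading deliberately:
it is the only interpretation that reconciles "six differences" with
"three classified pairs" and with totals of 3n per session. Note it is
favourable to the test device by construction (a min of two errors), which
is inherent to the protocol, not a choice of this package.

Band boundaries are **inclusive**: a difference of exactly 5 mm Hg (3 bpm
for heart rate) counts in the first band. Validation literature is
inconsistent here (tables sometimes print "<5"); we follow the protocol
text, and a difference landing exactly on a boundary is rare anyway once
readings are integer.

Pass thresholds are defined for the 33-subject base design and scaled by
a single integer factor `k = round(n/33)`. We chose integer scaling over
proportional scaling (`× 3n/99`) because the published 100-subject
thresholds (219/261/288, 195/243/279, 72, 9) are exactly 3× the base
counts, while proportional scaling reproduces none of them. Below 33
subjects the protocol is undefined and `scale_requirements()` refuses.

Both phases (pair-level counts; per-subject counts) are evaluated on
**each** session's data and the overall verdict is the conjunction of all
components. The protocol's sequential wording ("if the device does not
pass session 1, stop") is available as an `early_exit` flag, off by
default, because a full report of every component is more useful than a
truncated one.

Heart rate is handled exactly like blood pressure but with bands
3/5/8 bpm and the same count requirements — the convention of the study
this package models, since no version of the ESH IP defines an HR
procedure.

The mean ± SD summary of the classified differences is **signed**
(test − criterion, taking the sign of whichever flank was selected, the
preceding one on ties); an `absolute_differences` flag switches to
absolute values, which is what some published tables appear to report.

## Reliability

`icc_estimate()` computes single-measures ICC from the two-way ANOVA mean
squares (rows = participants, columns = repeated readings). The default
form is **two-way random effects, absolute agreement**,

ICC(A,1) = (MSR − MSE) / (MSR + (k−1)·MSE + k·(MSC − MSE)/n),

because the three readings of an automatic device are interchangeable
"raters" and a validation cares about absolute agreement; the
consistency form (MSR − MSE)/(MSR + (k−1)·MSE) is available by flag. The
underlying study never names its ICC form; single-measures
absolute-agreement is this package's default, not an assertion about
that study. 95% bounds use the F-distribution method (Satterthwaite
degrees of freedom for the absolute form); a simulation in the test
suite checks 93–97% coverage at a true ICC of 0.9. A matrix with no
variance at all yields a flagged degenerate result rather than an error,
so synthetic noise-free pipelines stay runnable.

SEM = SD·√(1−ICC) uses the pooled SD of all cells and the point ICC.
Landis–Koch labels use cutpoints 0.20/0.40/0.60/0.80 with ≥0.81 "almost
perfect"; the open gap (0.80, 0.81) is assigned to "substantial".

The paired session-change t-test returns t = 0, p = 1 on identical
sessions and a flagged infinite-t, p = 0 result on a constant non-zero
shift — degenerate synthetic inputs must not crash the pipeline.

The Lilliefors-corrected normality check computes the KS distance to a
normal with estimated mean/SD and obtains its p-value from Monte-Carlo
resamples (default 9,999, seed-controlled), re-estimating parameters in
each resample. Monte Carlo replaces the classical lookup tables: it has
no interpolation error and is exactly testable for calibration.

## Agreement and design power

Between-device comparisons operate on participant-level means (4
criterion and 3 test readings per session; the intersession scope
averages the two session means so sessions weigh equally). The default
between-device t-test is **independent-samples** — statistically
conservative given the pairing, but the convention of the validation
literature this models — with a paired mode available and labelled in
reports. Bland–Altman uses one point per participant and 1.96·SD limits;
CIs on the limits and proportional-bias regression variants are out of
scope.

Sample size uses the two-sided normal-approximation formula
n = ⌈((z₁₋α/₂ + z_pow)·σ/δ)²⌉ and divides by (1 − attrition), ceiling
both. With δ = 0.9 mm Hg, σ = 3.2 mm Hg, α = .05, power .80 and 20%
attrition this gives 100 completers and 125 recruits. z rather than
noncentral-t quantiles because z reproduces those published numbers
exactly; the t iteration is provided (`method = "t"`) and asks for one
or two more subjects.

## The synthetic-study generator

Per subject and variable the generator draws a true value T from a
truncated normal (SBP 127/16 on [90, 180], DBP 74/10 on [40, 130], HR
71/10 on [40, 180] — the eligibility ranges and baseline scale of a
healthy adult validation cohort); per session a shift S ~ N(0, 2²); per
position an independent serial fluctuation ε_p (default SD 3.0 mm Hg BP
/ 2.5 bpm HR); then device noise (SD 1.5 each side), the configured
constant and proportional test bias, and integer rounding. Each position
has its **own** latent value T + S + ε_p: readings are 2–3 minutes
apart, and it is exactly this serial variation that the flanking
criterion readings are meant to bracket. Truncation applies to T only,
emulating eligibility screening, not device clipping. A fraction
(default 0.2) of subjects completes only session 1. No position-order
effect is generated by default; a linear `position_drift` is available
because blood pressure typically falls over a resting session.

### Calibration of the packaged `paper_like` scenario

The scenario must represent a device that genuinely passes, on the scale
of a real passing study. Under the model above, the difference between a
test reading and a flanking criterion reading has SD
√(2w² + 1.5² + 1.5²) with the two flanks correlated at ρ = 0.5 (they
share the test reading's term). We fixed the serial SDs **once, ahead of
any acceptance run**, by Monte-Carlo inversion of the published band-1
proportions of a passing study (0.830 for SBP, 0.905 for DBP, 0.895 for
HR): w = 4.0 mm Hg (SBP), 3.0 mm Hg (DBP), 1.7 bpm (HR). These values
also reproduce that study's mean absolute classified differences
(≈3.4/2.4/1.6) with no further adjustment — a useful consistency check
that the error model is sane. The scenario recruits 125 subjects with
20% dropout, giving exactly 100 completers. `biased_device` (+20 mm Hg /
+10 bpm) pushes every difference beyond the last band; `noisy_device`
(bias 6, noise 4) sits below the decision boundary and fails in nearly
all replicates.

What a green calibration test establishes: the *decision rule* behaves
correctly on data with the assumed error structure. What it does not
establish: anything about real devices — the generator has no
oscillometric physics, no arrhythmia, no cuff-fit effects, no
reading-order dependence, and its noise is Gaussian and homoscedastic.
The generic `simulation_config()` defaults (serial SD 3.0/3.0/2.5) are
plausible mid-range values, stated as configuration rather than as any
study's truth.

## Numerical and degenerate-input choices

- Ties in flank selection go to the preceding criterion reading (affects
  only the sign attribution, never the classified magnitude).
- Values are stored as decimals; `integer_rounding` (on by default in
  the generator) mimics device displays. Rounding contributes variance
  1/12, which the ICC-recovery test accounts for.
- Plausibility bounds (30–300 mm Hg, 30–250 bpm) are wider than both
  devices' operating ranges so loading never silently truncates;
  violations warn.
- Incomplete series are flagged and excluded from protocol counts but
  retained for descriptive statistics; structural errors (parity,
  duplicates, unknown codes) are collected and reported together.
- All Monte-Carlo machinery (Lilliefors, pass-probability replicates)
  derives per-replicate seeds from a master seed and restores the
  caller's RNG state afterwards.

## Known limitations

The full ESH IP observer procedure (two human observers, 4 mm Hg
observer-agreement rule, entry-BP stratification into low/medium/high
ranges, device-error recusal rules) is not implemented; the package
follows the simplified single-criterion-device design with a possibly
non-multiple-of-33 completer count handled by integer requirement
scaling. Bland–Altman is participant-level only. ICC intervals are
F-based, not bootstrap; no multi-rater generalizability theory.
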