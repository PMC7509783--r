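---
title: "Methods: symbolic dynamics and stationarity-aware HRV under acute stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbolic dynamics and stationarity-aware HRV under acute stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvsd)
```

## The problem

Short-term heart rate variability (HRV) is usually quantified over 5-minute
RR-interval windows, and the frequency-domain parameters (LF, HF) assume the
window is *stationary* — its mean and variance do not drift. During an acute
psychosocial stressor (the Trier Social Stress Test, TSST: speech
preparation, speech delivery, mental arithmetic in front of an evaluative
panel) that assumption is systematically violated: cardiac autonomic
regulation changes *within* the analysis window. hrvsd implements a pipeline
built around that observation:

1. quantify how nonstationary each window is (two independent diagnostics),
2. compute the classical time- and frequency-domain parameters anyway, with a
   fully specified spectral recipe, and
3. compute pattern-category parameters from *binary symbolic dynamics of the
   difference series* \(\Delta RR_i = RR_{i+1} - RR_i\), which inherit the
   (much better) stationarity of the differences and remain interpretable in
   terms of sympathetic and parasympathetic drive.

A synthetic cohort generator emulates a 24-subject TSST session so that every
stage can be exercised and calibrated without any recording.

## Symbolic dynamics

Two binary encodings of the difference series:

* sign: \(S_i = 0\) if \(\Delta RR_i \ge 0\) (deceleration), \(1\) otherwise
  (acceleration). Parameter-free.
* threshold: \(S_{\tau,i} = 0\) if \(|\Delta RR_i| < \tau\), \(1\) if
  \(|\Delta RR_i| \ge \tau\), with \(\tau = 35\) ms by default —
  approximately 5% of a typical grand-average RR interval. Ties follow the
  inequalities exactly (a difference of 0 codes 0; a difference of exactly
  \(\tau\) codes 1). `tau_from_rr()` offers an adaptive per-subject 5%
  variant, off by default because a fixed threshold keeps windows comparable
  across subjects and periods.

All overlapping words of length \(k = 3\) (step 1 — "all subsequences"
implies overlap, and non-overlapping windows would discard two thirds of the
data) are classified by the number of symbol changes between successive
positions: 0V (`000`, `111`), 1V (`001`, `100`, `110`, `011`), 2V (`101`,
`010`). The three relative frequencies sum to 100% by construction; under an
i.i.d. fair-coin null they converge to 25/50/25. Higher P0V% tracks
sympathetic activation (long monotone runs of like symbols), higher P1V%
parasympathetic activity.

## Nonstationarity diagnostics

**Heuristic segmentation.** At every admissible split of a window the
pooled-variance two-sample statistic
\(t(i) = |\bar{x}_L - \bar{x}_R| / s_D\),
\(s_D = s_p\sqrt{1/n_L + 1/n_R}\), is evaluated (vectorized via cumulative
sums); the maximal \(t\) is accepted as a change point when its
Bernaola-Galván significance
\(P \approx \{1 - I_{[\nu/(\nu+t^2)]}(\delta\nu, \delta)\}^{\eta}\)
(\(\nu = n-2\), \(\delta = 0.40\), \(\eta = 4.19\ln n - 11.54\)) reaches
0.95, and the procedure recurses on both halves. Minimum segment length is
40 intervals so that LF-band oscillation (period \(\approx\) 10 s
\(\approx\) 13 beats) cannot masquerade as a trend. A window is stationary
iff it is never split. Design choices: the recursion re-tests each half
fresh rather than re-validating boundaries against neighbouring segments
(the refinement variant matters for long series, not 5-min windows); a split
with zero pooled variance but unequal means is treated as maximally
significant via a capped sentinel statistic; ties in the \(t\) profile
resolve to the first maximum, making the algorithm fully deterministic.
Pre-freeze calibration: false-split rate 3–4% on i.i.d. series of length
300; a 150 ms step at the window midpoint is recovered within ±5 intervals
essentially always.

**Restricted weak stationarity (RWS) test.** Eight subsequences of 50
intervals are drawn at random start indices (without replacement; overlap is
permitted — with realistic window lengths of ~340–480 intervals, eight
disjoint windows of 50 are usually impossible) and compared by a
Kruskal–Wallis test of location and a Brown–Forsythe (Levene-on-medians)
test of dispersion. Both p-values must exceed 0.05 for a stationary verdict.
The components are rank-based to match the package's consistently
nonparametric statistics; a parametric variant (one-way ANOVA + Bartlett) is
available via `method = "parametric"`. The draw is governed by an explicit
seed and the caller's RNG state is restored, so results are reproducible and
side-effect-free. Calibration at the defaults (N = 400): type-I error
\(\approx\) 5.7% (means) and 2.9% (variances), power \(\approx\) 1.0 against
a 200 ms linear trend.

## Time- and frequency-domain parameters

Mean RR, SDNN (sample, \(N-1\) denominator — the HRV-software convention;
configurable) and RMSSD. The spectral recipe is fixed end to end: cubic
spline interpolation of the tachogram (RR plotted at interval onset)
resampled at 4 Hz; least-squares linear detrend; Hanning window; zero-pad to
2048 points; FFT; one-sided spectrum rescaled by a single global factor so
total power (all bins above 0 Hz) equals the variance of the detrended,
pre-taper series — this is what "adjusted to the variance" means here, and
it makes band powers in ms² independent of the taper's power loss. LF is
0.04–0.15 Hz, HF 0.15–0.4 Hz, with half-open `[low, high)` edges so the
shared 0.15 Hz boundary is counted exactly once (in HF). LF, HF and LF/HF
are ln-transformed before cohort statistics (their distributions are
right-skewed). Total power includes the VLF bins below 0.04 Hz by default,
which dilutes LF%/HF%; `include_vlf = FALSE` normalizes by LF + HF instead.
Zero-variance windows report zero power *flagged* (`power_defined = FALSE`)
with `NA` percentages instead of silently propagating NaN.

## Cohort statistics

All group-level procedures are nonparametric (small cohorts): median and
25%/75% percentiles (linear-interpolation convention, R type 7); Friedman
omnibus across the nine periods with midranks and tie correction
(implemented as \((k-1)\sum_j(R_j - n(k+1)/2)^2 / \sum_{ij}(r_{ij}-(k+1)/2)^2\),
which reduces to the textbook \(12/(nk(k+1))\) form without ties);
Skillings–Mack for matrices with missing cells (weighted centered midranks,
generalized-inverse covariance, \(\chi^2\) with rank(Σ) df) — on complete,
untied data it coincides exactly with Friedman, which the test suite
verifies to 1e-10. Post-hoc pairwise comparisons are gated on a significant
omnibus result and use Wilcoxon signed-rank with Holm step-down adjustment
over all 36 period pairs; a Siegel–Castellan mean-rank critical-difference
variant is available (`method = "rank-cd"`). Gender contrasts use the
Mann–Whitney U test. \(\alpha = 0.05\) throughout.

Friedman requires complete rows (listwise deletion); Skillings–Mack is used
automatically by `run_cohort()` wherever a parameter matrix has missing
cells, which in practice means the VAS scores.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 24 subjects (12 female),
nine 5-min periods. The instantaneous tachogram of each period is

\[ r(t) = \text{base} + \text{drift}\,(t/T - 1/2)
  + a_{LF}\sin(2\pi\,0.10\,t + \varphi_1)
  + a_{HF}\sin(2\pi\,0.25\,t + \varphi_2) + \varepsilon, \]

and beats are stepped through it (\(t_{n+1} = t_n + r(t_n)/1000\)) as one
continuous recording across all nine periods, so no artifact interval arises
at window seams. A per-subject baseline offset \(\sim N(0, 60^2)\) ms adds
between-subject variance. Per-beat stepping was chosen over an
integral-pulse-frequency-modulation model: it is transparent, exactly
seedable, and adequate for exercising an analysis chain that consumes beat
times. All randomness flows from one master seed through per-subject
substreams; the emitted files are byte-identical across reruns.

Default period parameters were tuned once against the qualitative profile of
a real TSST cohort and then frozen: baselines 855/813/750/616/672/839/882/
853/885 ms for T1–T9; stress windows (T4, T5) combine stronger LF modulation,
weaker HF modulation, less beat-to-beat noise and a larger within-window
drift (−120 ms at T4); VAS means rise from 5 (T1) through 59 (T5) back to 3
(T9), sd 5–25, with 5% missingness. Tests assert *orderings and directions*
(T4 vs T1: mean RR and RMSSD down, P0V% up, P1V% down), never the real
cohort's printed medians, which are properties of unpublished recordings.

What the generator does *not* emulate — and hence what passing tests do not
show about real data:

* no respiration or baroreflex physiology, no VLF fluctuations beyond the
  linear drift; consequently SDNN is dominated by the drift term and does
  **not** reproduce the real cohort's mild SDNN decrease under stress;
* modulation amplitudes are constant within a window, so the RWS variance
  component rarely fires on RR series (in the real data it fired in 200/216
  windows); nonstationarity is expressed through the mean component and the
  segmentation count instead;
* the sign-encoded P2V% does not fall under stress as it does in real
  recordings (the threshold-encoded P2V\(_\tau\)% does); P2V dynamics depend
  on fine-grained beat-to-beat structure the two-sine model lacks;
* ectopic beats are injected as single displaced "V" beats at a 0.2% rate —
  enough to exercise interpolation, not a model of real ectopy.

## Numerical and policy choices

* Window membership: interval **onset** in the half-open span
  `[marker − 300000, marker)` — each interval belongs to exactly one window;
  the convention is explicit because onset-vs-end membership is genuinely
  ambiguous in the field.
* Ectopic correction: linear interpolation of beat times between the
  flanking normal anchors (a run of \(m\) ectopics is respaced to equal
  fractions of the anchor gap) — the minimal defensible reading of
  "appropriately interpolated times"; a >5% correction load warns, edge
  ectopics without anchors are trimmed with a warning.
* Indices are 1-based everywhere, as is idiomatic in R; file formats are
  documented as 1-based line numbers.
* Units: milliseconds internally; the tachogram reader accepts seconds via
  `unit = "s"`.
* Degenerate inputs: constant series give SDNN = RMSSD = 0, zero spectral
  power (flagged), all-0 symbol sequences, a single stationary segment, and
  RWS p-values of exactly 1.
* Problem sizes in the test suite were chosen to give stable Monte-Carlo
  estimates at interactive runtimes: 1000-replicate calibrations for the RWS
  null, 200 seeds for segmentation recovery, 10 master seeds for the
  end-to-end cohort signature.

## Known limitations

* The Bernaola-Galván significance approximation is asymptotic; with
  `min_len = 40` its accuracy below ~100 samples is untested here (such
  windows are never split anyway, by the admissibility rule).
* Skillings–Mack uses the large-sample \(\chi^2\) reference; for very small
  or very sparse matrices an exact permutation reference would be better.
* The spectral module assumes the 5-min window; much shorter windows
  (< ~2 min) underestimate LF by construction of the band edges and taper.
* `run_cohort()` tests each parameter marginally; no multiplicity control is
  applied *across* parameters, matching common practice in descriptive HRV
  studies.
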