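---
title: "Boundary-line diagnostic models for forward head posture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-line diagnostic models for forward head posture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhpdiag)
```

## The problem and the two-stage procedure

Forward head posture (FHP) is common in adolescents and is screened
externally: the forward neck tilt angle (FNTA) between the vertical and the
tragus–acromion line is measured with a markerless depth sensor, and
thresholds at 12°, 25° and 40° grade it into Normal, Level 1, Level 2 and
Level 3, the last being the grade at which radiographic imaging is requested.
Intervals are half-open with the lower bound included, so `classify_fnta(25)`
is level 2.

Radiographic sagittal alignment, however, correlates only weakly with the
FNTA (within-cohort correlations around |r| ≤ 0.16), so a diagnosis resting
on the external angle alone is fragile exactly where it matters — near the
thresholds. The procedure implemented here therefore encodes the joint
distribution of each radiographic parameter and the FNTA into a
*per-parameter diagnostic model*: three straight lines

$$0 = K + L_1 X + L_2 Y, \qquad Y = -\frac{K + L_1 X}{L_2},$$

with $X$ one of the eight radiographic parameters (CSA, CCA, T1S, CL, CranT,
CervT, C7S, TK) and $Y$ the FNTA, separating adjacent levels 0|1, 1|2 and
2|3 over a parameter range $[LE, RE]$. The packaged constants bank
(`default_model_bank()`) carries the published values for all 24 lines; by
convention $L_2 < 0$, so larger FNTA always lies on the same side of a line.

At diagnosis time the radiographic parameter is *unknown* — the whole point
is to decide who needs a radiograph. Sweeping a boundary over its parameter
range collapses it to an FNTA interval $[y_{\min}, y_{\max}]$ (attained at
the endpoints, since the line is affine and monotone in $X$). An FNTA below
that interval is below the boundary no matter what the parameter turns out to
be; above it, above; strictly inside, the model cannot exclude either
adjacent level and keeps both as *candidates* (printed `0.1`, `1.2`). Each
of the eight models votes for every level in its candidate set;
`vote_diagnosis()` tallies the votes and the argmax is the diagnosis.

## Numerical choices and tie-breaks

* **Endpoint ties.** An FNTA exactly equal to $y_{\min}$ is classified below
  the boundary (lower level), exactly equal to $y_{\max}$ above it. This
  matches the published evaluation sheet at its borderline rows and makes the
  ambiguous state a strictly open interval.
* **Exact arithmetic.** Candidate generation always compares exact
  floating-point boundary values; rounding to 0.1° happens only in rendered
  reports. The published sheet appears to have used the *rounded* interval
  endpoints (printed to one decimal) in a handful of cells: at FNTA 10 the
  T1S interval starts at 9.96° (printed 10.0), and several CL cells at FNTA
  6–29 are printed unambiguous although the full-range CL interval contains
  them, consistent with the authors clipping CL to an unpublished observed
  data range. Exact evaluation therefore differs from a few printed candidate
  cells — never from any printed diagnosis, vote winner, or the published
  borderline tallies (FNTA 11: 7/8/0/0; FNTA 25: 0/8/7/0). Per-line
  `eff_LE`/`eff_RE` overrides in the bank schema exist for users who do know
  the observed range; the packaged default keeps the published `LE`/`RE`.
* **Vote ties.** No tie occurs on the published data; when one occurs the
  higher tied level wins and the result is flagged. Referral-side caution is
  the clinically conservative choice for a screening instrument.
* **Ordering.** A valid model must have its blue, pink and red boundary FNTA
  values strictly increasing at the midpoint of the common parameter range.
  Fitted models violating this raise an error; nothing is silently
  reordered.

## Fitting new banks

The published constants came from an unspecified multivariate analysis; this
package fits boundaries as two-class Fisher linear discriminants with equal
priors and pooled within-group covariance — the canonical linear boundary
between two Gaussian classes. The boundary passes through the midpoint of
the class means, with normal $S^{-1}(\mu_{hi} - \mu_{lo})$; the sign is
normalized to $L_2 < 0$ to match the published representation. Degenerate
inputs (singular pooled covariance, fewer than two points per class, a
boundary vertical in FNTA) are errors. An independent LDA implementation is
used in the test suite to cross-check the decision rule point by point.

Under near-noiseless conditions the discriminant between adjacent levels
converges to the midpoint of their mean FNTAs. With the study population's
level means (8.61, 17.25, 31.24 and 54.71° after truncation to the level
intervals) those midpoints are about 12.9°, 24.2° and 43.0°. Note the third:
because level-3 FNTAs reach far above the 40° cutoff, the fitted 2|3
boundary sits near 43°, *not* at 40° — the same effect visible in the
published red lines, whose FNTA intervals span roughly 40–50°. The practical
consequence is deliberate: participants just above 40° are not automatically
voted into level 3 by a fitted model; the screening thresholds, not the
boundary lines, own the referral cutoff.

## The synthetic cohort generator

`generate_cohort()` emulates the study population: per level, the FNTA is
drawn from the published level normal truncated (by inverse-CDF) to the
level's screening interval — truncation is on by default so `known_level`
agrees with `classify_fnta()`, and off it reproduces plain normals — and each
radiographic parameter from its level normal. Correlation between FNTA and a
parameter, zero by default to match the near-zero published correlations, can
be imposed through a shared Gaussian score,
$p = \mu + \sigma(r z_{\text{fnta}} + \sqrt{1-r^2}\,z)$; with truncation
active the parameter marginal is then mildly non-normal, which is accepted
and documented. One seeded PRNG stream drives the whole cohort; the seed is
recorded in the output and the caller's RNG state is preserved.

Per-level counts are not published; the default allocation (38, 55, 36, 16)
sums to the study's 145 participants with most mass at levels 0–1, as in any
school-age screening population, and is configurable. The 70/30
train/evaluation split (`split_cohort()`) takes
$\lfloor 0.3 n \rfloor$ evaluation participants — 43 of 145, matching the
study — and by default stratifies by level with largest-remainder rounding,
our reading of a split "balanced by level"; the study's exact allocation is
unknown.

What the generator does *not* emulate: depth-sensor measurement error,
inter-rater radiographic variability, age/sex structure, skewness or
outliers in the radiographic parameters, and any real FNTA–parameter
dependence beyond a single correlation coefficient. Tests that pass on
synthetic cohorts therefore validate the pipeline's arithmetic and
statistical plumbing, not the clinical performance of refitted banks on real
adolescents.

## Problem sizes and determinism

The test suite exercises candidate generation against a brute-force
parameter-sweep oracle on all 24 packaged lines over FNTA 0–70° in 0.1°
steps (4001-point sweep grids), recovers generator moments at 10,000
participants per level, and fits low-noise banks at 200 per level — sizes at
which every stochastic check is stable at its fixed seed (42) while the
whole suite runs in well under a minute. All randomness flows through
explicit seeds; `simulate → fit → diagnose → evaluate` is bit-reproducible
file-to-file.

## Known limitations

* The packaged bank is used verbatim; the published fitting procedure is not
  fully specified, so refitting on a synthetic replica of the study
  population reproduces the published constants only approximately.
* The evaluation fixture's two borderline candidate-cell discrepancies
  (rounded vs exact endpoints, the CL range) are documented above and kept
  as printed; one printed vote count (row 12) is internally inconsistent
  with its own candidate cells and is preserved verbatim as well.
* Correlation reporting treats the FHP level as an integer score 0–3 when
  correlating against it; Shapiro–Wilk is restricted to its standard
  3 ≤ n ≤ 5000 domain; Spearman/Pearson p-values use the t-approximation
  with an optional Monte-Carlo permutation alternative for small cohorts.
* The agreement ratio weights all levels equally; with only two level-3
  participants in the evaluation set, the headline 95.35% is dominated by
  levels 0–2, which is why the per-level TPR/FNR/PPV/FDR margins of
  `confusion_report()` are reported alongside it.
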