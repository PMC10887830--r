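# fhpdiag

Screening and preliminary diagnosis of forward head posture (FHP) in
adolescents from a single external angle measurement.

FHP — the "text neck" posture — is graded here into four levels from the
**forward neck tilt angle** (FNTA), the angle between the vertical and the
tragus–acromion line, measured with a markerless depth sensor. Pure threshold
screening assigns level 0 (Normal) for 0° ≤ FNTA < 12°, level 1 for
12° ≤ FNTA < 25°, level 2 for 25° ≤ FNTA < 40°, and level 3 (radiographic
imaging requested) for FNTA ≥ 40°. Because external posture correlates only
weakly with radiographic sagittal alignment, threshold screening alone risks
misdiagnosis; the preliminary diagnostic procedure implemented here combines
it with eight radiographic parameters measured on standing lateral
radiographs: CSA, CCA, T1S, CL, CranT, CervT, C7S and TK.

## The model

For each radiographic parameter `X`, a diagnostic model consists of three
linear boundary lines in the (X, FNTA) plane,

```
0 = K + L1·X + L2·Y        (Y = FNTA, L2 < 0)
```

separating adjacent levels 0|1, 1|2 and 2|3 (the blue, pink and red lines of
the scatter plots). Each line is valid over a parameter range `[LE, RE]`;
solving for `Y = −(K + L1·X)/L2` at the endpoints gives the line's FNTA
interval. New lines are fitted as two-class Fisher linear discriminants with
equal priors and pooled covariance (`fit_boundary()`, `fit_model_bank()`).

At diagnosis time only the FNTA is known. Relative to one boundary an FNTA at
or below the interval minimum is *below* the line, at or above the maximum
*above* it, and strictly inside *ambiguous* — the model then cannot exclude
either adjacent level and keeps both as candidates. Each of the eight models
votes for every level in its candidate set and the diagnosis `D` is the level
with the most votes (ties, which do not occur on the published evaluation
data, break toward the higher level and are flagged). Agreement between `D`
and the threshold classification `PC`, and a confusion chart with TPR/FNR/PPV/
FDR margins, summarize performance.

The published constants bank (eight models, 24 lines) and the published
43-participant evaluation sheet ship with the package. A seeded synthetic
cohort generator reproduces the study population's per-level means and SDs
(truncated-normal FNTA per level) so fitting and evaluation can be exercised
end to end without patient data.

## Worked example

```r
library(fhpdiag)

# a borderline participant: FNTA exactly at the 25-degree screening cutoff
vote_diagnosis(default_model_bank(), 25)
#> FNTA 25.0 deg: screened level 2, voted diagnosis 1
#>   votes: Normal=0, Level 1=8, Level 2=7, Level 3=0
#>   candidates: CSA:1  CCA:1.2  T1S:1.2  CL:1.2  CranT:1.2  CervT:1.2  C7S:1.2  TK:1.2
```

Seven of the eight models find 25° ambiguous between levels 1 and 2 (cells
`1.2`), but the CSA model's 1|2 boundary stays above 25° across its whole
range, so level 1 wins the vote 8–7 even though threshold screening says
level 2.

```r
sheet <- diagnose_cohort(packaged_evaluation_sheet()$fnta)
confusion_report(sheet$PC, sheet$D, ids = sheet$participant)
#> FHP diagnosis evaluation: n = 43, agreement = 95.35%
#> confusion matrix (rows = screened PC, cols = voted D):
#>    D
#> PC  0  1 2 3
#>   0 8  1 0 0
#>   1 0 25 0 0
#>   2 0  1 6 0
#>   3 0  0 0 2
#> TPR% per level:  88.9 100.0  85.7 100.0
#> FNR% per level:  11.1   0.0  14.3   0.0
#> PPV% per level: 100.0  92.6 100.0 100.0
#> FDR% per level:   0.0   7.4   0.0   0.0
#> disagreements:
#>  participant pc d
#>            8  0 1
#>           25  2 1
```

The FNTA-only voted diagnosis agrees with threshold screening for 41 of the
43 evaluation participants (95.35%); the two disagreements are the borderline
FNTAs 11° and 25°, both voted level 1. Both participants screened at level 3
(FNTA 52° and 62°) are voted level 3 — the referral-to-radiology decision is
recovered for every participant who needs it, and for no one else.

A full pipeline (simulate → fit → diagnose → evaluate → report) is available
as `run_pipeline()` and as a thin command-line wrapper:

```sh
Rscript inst/scripts/fhp.R simulate --out cohort.csv --seed 11
Rscript inst/scripts/fhp.R fit --input cohort.csv --out bank.json --split
Rscript inst/scripts/fhp.R diagnose --input cohort.csv --bank bank.json --out sheet.csv
Rscript inst/scripts/fhp.R evaluate --input sheet.csv --out eval.csv
```

See `vignettes/fhp-diagnostic-models.Rmd` for the full account of the method,
its tunable parameters and its limitations.

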