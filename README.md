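# notchsurv

Estimating the population prevalence of **high-frequency audiometric
notches** — the audiogram signature of noise-induced hearing loss — from
complex survey data.

Noise-induced hearing loss typically carves a localized deterioration
("notch") into pure-tone thresholds around 3–6 kHz, with partial sparing
at 8 kHz. Surveys like NHANES measure audiograms on stratified,
clustered, unequally weighted samples, so estimating how common notches
are — and how they associate with sex, age, socioeconomic factors and
self-reported noise exposure — requires design-based methods throughout.
`notchsurv` is for epidemiologists and hearing researchers who want that
full chain in one place: the notch rule, the survey estimators, a
ground-truth synthetic cohort generator to validate against, and an
end-to-end pipeline producing publication-style tables.

## The rule and the estimators

For one ear with thresholds $t_f$ (dB HL), baseline
$b = (t_{0.5} + t_1)/2$, a notch is present when

$$\max(t_3, t_4, t_6) - b \ge 15 \quad\text{and}\quad \max(t_3, t_4, t_6) - t_8 \ge 5,$$

both inclusive; an ear missing any of 0.5, 1, 3, 4, 6, 8 kHz is
unclassifiable. Participants are classified none / unilateral /
bilateral when both ears are classifiable.

Estimation is design-based: Hájek ratio prevalences
$\hat p = \sum_D w_i y_i / \sum_D w_i$ with Taylor-linearized standard
errors under stratified with-replacement PSU sampling; weighted
population totals; and survey-weighted logistic regression
(pseudo-maximum-likelihood via IRLS) with clustered sandwich
covariances, t-based confidence intervals at design degrees of freedom
(PSUs − strata), and a small-sample-scaled (Hotelling-type) group Wald
test. Subpopulations are zero-weighted, never subset. A Rao–Wu
stratified bootstrap is included as an independent variance cross-check.

## Worked example

```r
library(notchsurv)

# classify one ear
ear <- ear_audiogram(c("0.5" = 10, "1" = 10, "2" = 15, "3" = 15,
                       "4" = 40, "6" = 30, "8" = 25))
classify_ear_notch(ear)
#> <ear_notch_result: notch PRESENT | baseline 10.0 dB HL,
#>  worst high freq 40.0, depth 30.0, 8 kHz recovery 15.0>

# a synthetic survey cohort with known ground truth, end to end
spec <- cohort_spec(n_participants = 4000, seed = 20)
res <- run_pipeline(analysis_config("synthetic", cohort_spec = spec))
res
#> Notch prevalence analysis
#> Inclusion report
#>   interviewed (age-eligible): 4000
#>   ...
#>   response rate:              100.0%
#> design df = 15; 66 estimate rows; 21 fitted models
#>   any        notch: 29.3% (SE 0.80)
#>   bilateral  notch: 2.7% (SE 0.32)
#>   unilateral notch: 26.6% (SE 0.81)

tab <- res$table
render_table(tab[tab$characteristic %in% c("overall", "exposure") &
                   tab$outcome == "any", ], style = "text")
#>  stratum characteristic   level outcome    n     pct_se            or_ci
#>  overall        overall overall     any 4000 29.3 (0.8)                —
#>  overall       exposure      No     any 2621 25.7 (1.1)         Referent
#>  overall       exposure     Yes     any 1379 36.2 (1.7) 1.64 (1.33–2.02)
```

Reading the output: 29.3% of the (synthetic) population has a notch in
at least one ear, with a Taylor-linearized SE of 0.8 percentage points;
exposed participants have 1.64 times the odds of a notch (95% CI
1.33–2.02). The generator injected notches with a true participant-level
exposure odds ratio of 2.0; the gap to 1.64 is attenuation from
measurement noise and marginal notch depths — nondifferential outcome
misclassification, visible by design. Prevalences and SEs render to one
decimal, odds ratios and CIs to two; all stored values are full
precision.

The same pipeline accepts generic audiogram/design CSVs
(`input = "csv"`; threshold columns `l_500`, `l_1000`, ..., `r_8000` in
Hz, empty cell = missing) and SAS XPORT survey files with a YAML
variable map (`input = "nhanes"`); `stratify_by = "exposure"` repeats
the table within exposure strata. See the methods vignette
(`vignettes/notch-survey-methods.Rmd`) for the model details, generator
design and known limitations.

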