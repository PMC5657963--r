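---
title: "Audiometric notch prevalence from complex survey data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audiometric notch prevalence from complex survey data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchsurv)
```

# The scientific problem

Chronic exposure to loud noise damages the cochlea in a characteristic
pattern: hearing thresholds deteriorate most around 3–6 kHz while lower
frequencies and, partially, 8 kHz are spared. On a pure-tone audiogram
this appears as a localized *notch* in the high frequencies with some
recovery at 8 kHz, and it is widely used as an objective marker of
noise-induced hearing loss in populations where exposure histories are
self-reported and unreliable.

`notchsurv` implements the two halves of a population analysis of this
marker: (1) the per-ear notch classification rule, and (2) design-based
estimation of notch prevalence and of its association with demographic
and exposure covariates from a stratified multistage survey such as
NHANES, where every participant carries a sampling weight and variance
must respect strata and clusters. A synthetic cohort generator with
known ground truth makes the whole chain testable without access to the
survey microdata.

# The notch rule

For one ear with thresholds $t_f$ (dB HL) at $f \in \{0.5, 1, 3, 4, 6,
8\}$ kHz, define the low-frequency baseline $b = (t_{0.5} + t_1)/2$.
A notch is present when both:

* **depth**: some high-frequency threshold exceeds the baseline by at
  least 15 dB, $\max(t_3, t_4, t_6) - b \ge 15$; and
* **recovery**: the 8 kHz threshold is at least 5 dB better than the
  worst high frequency, $\max(t_3, t_4, t_6) - t_8 \ge 5$.

Both comparisons are inclusive. The 2 kHz threshold is carried in the
data model but never consulted. An ear missing any of the six rule
frequencies is *unclassifiable*; a participant enters analysis only when
both ears are classifiable, which is the most conservative reading of
"complete audiometric data" (single-ear inclusion would be a one-line
change in `apply_inclusion_filters()`, but it changes the analytic
denominator and we deliberately do not offer it as a default).
Participant categories are `none`, `unilateral`, `bilateral`, or
`unclassifiable`.

Since "any of $t_3, t_4, t_6$ exceeds $b$ by ≥ 15" is equivalent to the
maximum doing so, the reported `notch_depth` diagnostic is the depth at
the worst high frequency. Because the rule is a pair of inequalities on
linear combinations of thresholds, it is translation invariant (adding a
constant to all seven thresholds changes nothing) and monotone in the
high-frequency thresholds while recovery holds; the test suite checks
both properties and verifies exact agreement with an independently coded
literal transcription of the rule on threshold grids of up to $10^6$
audiograms.

Thresholds must lie in $[-10, 120]$ dB HL. Values off the 5 dB
audiometric grid are accepted with a warning rather than rejected: some
instruments report 1 dB steps, and quantization is a property of the
measurement, not of the rule.

# Design-based estimation

## Prevalence and totals

Prevalence over a subpopulation (domain) $D$ is the Hájek ratio
$\hat p = \sum_{i \in D} w_i y_i / \sum_{i \in D} w_i$, reported in
percent, with the weighted count $\sum_{i \in D} w_i y_i$ as the
population-scale numerator. Variance uses Taylor linearization of the
ratio: the linearized variate $u_i = w_i \mathbf{1}_D(i) (y_i - \hat p)
/ \sum_D w$ is summed within PSUs, and PSU totals are combined with the
stratified with-replacement estimator
$\widehat{\mathrm{var}} = \sum_h \frac{n_h}{n_h - 1} \sum_c
(u_{hc} - \bar u_h)^2$. With-replacement first-stage sampling is the
standard approximation for public-use designs with masked variance
units. Two consequences worth knowing:

* **Domains are never subset.** Out-of-domain rows stay in the variance
  computation with zero weight, preserving the PSU structure; this is
  the design-correct treatment of subpopulations and it is why
  `svy_prevalence()` and `svy_logit()` take a `domain` argument instead
  of expecting pre-filtered data.
* **Lonely PSUs are loud.** A stratum with a single PSU makes the
  within-stratum variance undefined; the default is an error, with an
  explicit `lonely_psu = "collapse"` mode that merges each lonely
  stratum into its neighbour in sort order. Silent defaults hide design
  problems.

Under the degenerate design (equal weights, each row its own PSU, one
stratum) the prevalence reduces exactly to the sample proportion and the
Taylor SE equals the textbook binomial SE up to the factor
$\sqrt{n/(n-1)}$.

## Survey-weighted logistic regression

`svy_logit()` maximizes the weighted pseudo-log-likelihood
$\sum_i w_i [y_i \eta_i - \log(1 + e^{\eta_i})]$ by iteratively
reweighted least squares. Weights are normalized to mean one internally
(estimates are invariant to weight scale); iteration stops when the
largest absolute score component falls below $10^{-10}$ or the largest
relative coefficient change does, with a cap of 100 iterations.
Divergence past $|\beta| > 30$ — quasi-separation — is an error, and
complete separation (a factor level whose domain outcomes are constant)
is detected up front and reported with the offending level's name,
because a silently exploding odds ratio is worse than a refusal.

The covariance is the design sandwich $A^{-1} B A^{-1}$ with
$A = X'\Lambda X$ the weighted information and $B$ the same stratified
between-PSU covariance as above applied to the weighted score
contributions $w_i (y_i - \mu_i) x_i$. Confidence intervals are formed
on the log-odds scale with a t reference at the design degrees of
freedom $d$ = (number of PSUs) − (number of strata), then exponentiated.

The group Wald test for a categorical predictor uses the Hotelling-type
small-sample scaling: with $W = \hat\beta' \hat V^{-1} \hat\beta$ over
$k$ coefficients, the statistic $F = W (d - k + 1)/(k d)$ is referred to
$F(k, d - k + 1)$. The scaling matters: $\hat V$ is estimated from only
$d$ degrees of freedom (here typically 15), and without it the test
over-rejects badly — in our null simulations the unscaled statistic
rejected at ~10% for a nominal 5% test, while the scaled version holds
4–7%. For $k = 1$ the statistic reduces to the squared t ratio on
$F(1, d)$.

## Per-characteristic models

Each characteristic is fitted in its own unadjusted model (one covariate
at a time), matching the referent structure of a prevalence table most
plainly; nothing in the pipeline precludes fitting a mutually adjusted
model by passing a wider formula to `svy_logit()` directly. Default
referents: male; ages 20–29; White non-Hispanic; more than high school;
poverty–income ratio ≥ 5; no work-noise exposure; excellent/good
self-reported hearing.

## The bootstrap cross-check

The Rao–Wu rescaling bootstrap (`svy_bootstrap_se()`) resamples
$n_h - 1$ PSUs with replacement per stratum and rescales weights by
$r \, n_h/(n_h - 1)$. It exists as an *independent route* to the same
variance, used in the tests to confirm the Taylor SEs (agreement within
a few percent on the cohorts tested, asserted at 15%); it is not the
production variance estimator.

# The synthetic cohort generator

`generate_cohort()` emulates the features of audiometric survey data the
estimators are sensitive to:

* **Design**: 15 strata × 2 PSUs by default (the masked-variance shape of
  a two-year survey cycle, giving 15 design df), log-normal weights
  (sdlog 0.5, CV ≈ 0.53) rescaled to a population of 160 million —
  approximately US adults aged 20–69. An optional PSU-level shift on the
  3–8 kHz thresholds (`psu_shift_sd`) induces intra-cluster correlation
  when a design effect above the Kish $1 + \mathrm{CV}^2$ is wanted.
* **Audiograms**: per-frequency baselines plus an age slope applied to
  3–8 kHz only (the presbycusis pattern; defaults 4/6/8/9 dB per decade
  at 3/4/6/8 kHz). Because 8 kHz worsens at least as fast as 3–6 kHz,
  pure aging loss fails the recovery condition and is rule-negative —
  the generator deliberately separates age-driven sloping loss from
  notches.
* **Notch injection**: per-ear Bernoulli with exposure-dependent
  probability; ears independent. The injected bump has full depth at a
  center frequency drawn from {3, 4, 6} kHz (probabilities
  0.25/0.5/0.25), half depth at adjacent high frequencies, and zero at
  0.5, 1, 2 and 8 kHz, so recovery stays meaningful. Depth is normal
  (mean 25, SD 5, truncated at 0). Ground-truth flags record *injection*
  events, never rule verdicts: a 10 dB injected notch is real to the
  generator and invisible to the rule, and a test asserts exactly that
  gap.
* **Measurement**: Gaussian test-retest noise (default SD 2 dB), then
  rounding to the 5 dB audiometric step and clipping to $[-10, 120]$.
* **Covariates**: round-number marginals (50% male, uniform ages 20–69,
  34% exposed — the approximate exposed share of the analytic sample the
  study conditions describe — race 40/20/20/20, education 20/30/50, PIR
  20/60/20, 80% reporting excellent/good hearing).

The default per-ear injection probabilities are $1 - \sqrt{0.8}$
(unexposed) and $1 - \sqrt{2/3}$ (exposed). With independent ears these
give participant-level any-notch probabilities of exactly 0.20 and 1/3,
i.e. a true participant-level exposure odds ratio of exactly 2.0 and an
overall prevalence of $0.66 \times 0.20 + 0.34/3 = 24.5\%$ — chosen once
as the study conditions for every recovery simulation.

**What the generator does not emulate**: physiological cochlear-damage
models, longitudinal threshold trajectories, correlated left/right ear
damage, non-response and post-stratification weight adjustments, and
NHANES-matched covariate joint distributions. Passing recovery tests
therefore demonstrates estimator correctness under a faithful design
structure, not that real-survey point estimates would be reproduced.

**RNG contract**: one seed fully determines the cohort, and generation
restores the caller's RNG state. Draws are vectorized
attribute-by-attribute, so enlarging `n_participants` redraws the cohort
rather than extending it; determinism is per (seed, n) pair.

# Simulation study sizes and what the tests assert

The verification suite uses sizes chosen to make Monte-Carlo bands tight
enough to detect real defects:

* Rule fidelity: exact agreement with the independent literal oracle on
  $10^6$ audiograms sampled from the $\{0, 5, \ldots, 60\}^6$ grid plus
  exhaustive small grids.
* Taylor vs bootstrap: one n = 2,000 cohort, 2,000 bootstrap
  replicates, asserted within 15% (observed ~1–2%).
* Odds-ratio recovery: 200 cohorts of n = 3,000 under exact detection
  (fixed 30 dB depth, zero noise, zero age slope — detection equals
  injection, isolating estimator bias from misclassification
  attenuation, which is a *generator* property, not an estimator one);
  mean log-OR within 3 Monte-Carlo SEs of $\log 2$, and 95% CI coverage
  required in [0.91, 0.98] (observed ~94%).
* Null Wald size: 500 cohorts of n = 1,000 with no generated age
  effect; rejection at $\alpha = 0.05$ required in [0.03, 0.08]
  (observed ~5–7%).

With measurement noise and marginal notch depths switched on,
nondifferential misclassification attenuates the odds ratio toward 1
(the default-settings pipeline shows this clearly, estimating ~1.8
against an injected 2.0); that attenuation is epidemiologically real and
intentionally visible rather than calibrated away.

# Survey-file harmonization

`read_xpt_table()` reads SAS XPORT (v5) files. Harmonization is entirely
config-driven: a YAML variable map names the id, threshold, demographic,
questionnaire and design columns and the code collapses; an unmapped
code is an error naming the code and variable, never a silent drop. The
shipped map encodes one reading of the NHANES 2011–2012 codebooks
(MEC exam weights; the first 1 kHz measurement with the retest filling
gaps, with `best` and `mean` policies available; sentinel codes 666/888
as missing) and is explicitly an overridable assumption. Poverty–income
ratio cuts are inclusive outward: 1.0 is "≤1", 5.0 is "≥5".

Because no XPORT writer exists in the R ecosystem the package depends
on, a minimal one (numeric variables, IBM hexadecimal floating point) is
implemented internally so fixtures can be built in code; the IEEE 53-bit
mantissa always fits the IBM 56-bit mantissa, so the writer round-trips
doubles bit-exactly through the reader, and the tests assert that.

The inclusion chain counts participants at each step (age-eligible
interviewed → any audiometry → complete audiometry in both ears →
analytic n) and reports the response rate as 100 × analytic n /
interviewed. The published analytic counts (3,583 of 4,677; 76.6%)
depend on the survey's own completeness and QC rules, which are not
fully restated in public documentation, so exact reproduction of the
analytic n is not guaranteed by the default filter; the filter and the
map are both configurable for sensitivity analysis.

# Known limitations

* With-replacement first-stage variance slightly overestimates the
  true variance when first-stage sampling was actually without
  replacement — the standard, conservative convention.
* The unadjusted per-characteristic odds ratios are the default; whether
  a published table was adjusted is often unstated, and adjusted fits
  require composing the formula manually.
* The sandwich covariance at 15 design df makes group Wald tests with
  many levels imprecise even with the Hotelling scaling; tests of ≥ 8
  levels against 15 df should be read cautiously.
* The generator's ears are independent; real notches are bilaterally
  correlated, so the synthetic unilateral/bilateral split is not
  calibrated to any population.
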