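---
title: "Methods: modelling long-term cognitive course in a two-wave case-control cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling long-term cognitive course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogcourse)
```

## The analytical problem

Longitudinal studies of cognition in schizophrenia-spectrum disorders ask
whether patients' cognitive deficits are stable, narrowing, or widening over
time relative to healthy peers. Answering this requires four linked analyses,
which this package implements as one pipeline:

1. **Normative scoring** — raw scores from a heterogeneous neuropsychological
   battery are placed on a common scale by z-scoring against the healthy
   controls' baseline distribution, then averaged into theory-based domain
   scores and a global composite.
2. **Group-level course** — a random-intercept linear mixed model per domain
   estimates time trends, group gaps, and time-by-group interactions.
3. **Individual-level course** — a regression-based reliable change index
   (RCI) classifies each subject's observed change as a significant decrease,
   increase, or stability, correcting for practice effects and regression to
   the mean.
4. **Clinical impairment** — domain scores below a severity cut-off, combined
   with an extent criterion (several domains at once), yield prevalence at
   each wave and a baseline-to-follow-up transition analysis.

Because clinical cohort data of this kind cannot be redistributed, the package
also ships a seeded synthetic cohort generator with the statistical structure
the analyses assume, so that every stage is exercised end to end by the test
suite without any external data.

## Normative scoring

Norms are the per-subtest mean and standard deviation (n − 1 denominator) of
the control group at baseline. Follow-up scores are standardised against
these same baseline norms rather than refreshed follow-up norms: a decade of
practice gains in the controls is then visible as positive change rather than
being absorbed into the scale, which is what makes long-term change
interpretable.

Timed measures (the colour-word completion times) are sign-flipped at
z-scoring — `z = (mean − raw)/sd` — so higher z always means better
performance. Direction is explicit per-subtest metadata, never inferred from
the data. Domain scores are means of member-subtest z-scores; the composite
is the mean of the domain scores and by default requires all eight domains
(a relaxed minimum is configurable). Domains whose member subtests are all
missing are missing, never zero.

The battery comprises 14 subtests in eight domains: learning and memory (list
learning and story recall, immediate and delayed), attention (digit span),
psychomotor processing speed (digit-symbol coding), mental processing speed
(colour naming and reading times), working memory (letter-number sequencing),
verbal fluency (letter, category, switching) and cognitive control
(interference and interference-switching times). Raw units are
battery-specific and the implementation is unit-agnostic given the direction
metadata.

## Group-level growth model

For each domain (and the composite) the two-group model is

$$Y_{ij} = \beta_1 + b_{1j} + \beta_2\,t_{ij} + \beta_3\,g_j + \beta_4\,a_j +
\beta_5\,t_{ij} g_j + \beta_6\,t_{ij} a_j + e_{ij}$$

with time $t$ in years since baseline, group $g$ coded 0 = control /
1 = patient, baseline age $a$ mean-centred on the analysis sample, a subject
random intercept $b_{1j}$ with a single variance component, and ML (not REML)
estimation via `lme4`. Per-group growth curves use the same model without the
group terms, fitted within each group.

Design choices that were genuinely open:

- **Degrees of freedom.** Wald t statistics with residual df
  (`n_obs` − number of fixed effects) by default. Satterthwaite df (via
  lmerTest) are available through `df_method = "satterthwaite"`; at these
  sample sizes the difference is immaterial for the terms of interest.
- **Age.** Age is baseline age, time-invariant and mean-centred. With only
  two waves, a within-subject ageing term would be collinear with the
  time-by-subject structure; centring also gives the intercept its natural
  reading as the control mean at baseline and mean age.
- **Group coding.** Control is the reference, so $\beta_3$ and $\beta_5$ are
  patient effects: a negative $\beta_5$ means patients gain less (or lose
  more) per year than controls.
- **Random-effects covariance.** The random-intercept "identity" structure is
  read as a single intercept variance (scaled identity G-matrix). No random
  slopes and no model selection: the model is fixed by design.
- **Degenerate designs.** `lme4`'s observation-count checks are relaxed so
  that a single-wave data set still returns the OLS fixed effects (with an
  unidentified intercept variance); non-convergence is flagged on the fit
  object, never silently ignored.

Estimated marginal means are linear combinations of the fixed effects at
requested covariate values; at the reference group, time 0 and mean age the
EMM equals the intercept. Requests outside the observed time range warn
rather than error.

## Regression-based reliable change

Within each group and measure, observed change (follow-up − baseline) is
regressed on baseline by OLS. Writing $\bar{Y}$ for the group mean change,
$\bar{X}$ for the group baseline mean and $B$ for the slope, the expected
change for a subject with baseline $x$ is

$$\hat{\Delta}(x) = \bar{Y} + B\,(x - \bar{X}),$$

and the reliable-change limits are $\hat{\Delta}(x) \pm z_{crit}\,
SEE$, where $SEE$ is the residual standard error of the change regression and
$z_{crit}$ is the two-sided standard-normal quantile (1.645 at the default
90 % level). $\bar{Y}$ absorbs the group's average practice effect; $B$ (
typically negative) encodes regression to the mean, widening effective
expectations at the extremes. Change below the lower limit classifies as
*decrease*, above the upper limit as *increase*, otherwise *stable*; ties on
a limit are stable (conservative).

Two variants exist in the literature; the package uses the residual standard
error, not the leverage-adjusted prediction SE, as the denominator. With the
group mean change and baseline mean as explicit reference points this is the
centred-form construction the fitted parameters support directly, and at the
sample sizes involved the leverage correction is negligible except at extreme
baselines. Each group gets its own model — patients' practice effects differ
from controls' — and the composite RCI is fitted directly on composite
scores, not aggregated from domain-level classifications. Under the null
(data generated from the fitted model with Gaussian residuals) the expected
flag rate is exactly $1 - $ the confidence level, split evenly between
decrease and increase; the test suite verifies this by Monte Carlo at
n = 10 000. A perfectly linear change pattern leaves numerically zero
residual variance; residual SEs below 1e−10 are snapped to the exactly
degenerate model and the collapsed limits flagged.

## Clinically significant impairment

A domain is impaired when its z-score is strictly below −1.5 (control-baseline
SD units); a subject is clinically impaired when at least 2 of the 8 domains
are impaired. Both thresholds are configurable. The composite is excluded
from the domain count: it averages the domains and would double-weight them.
Follow-up impairment is judged against the baseline control norms — the same
scale as all other scoring — so prevalence is comparable across waves.
Records with fewer observed domains than the required minimum get a missing
status and are excluded from (reported) denominators; the transition analysis
uses complete two-wave cases only, with exclusions counted.

The transition analysis stratifies by baseline status. Within the
baseline-impaired stratum it reports the percentage improving beyond
threshold on at least one domain, no longer clinically impaired, reaching
criteria on additional domains, and impaired on all domains at follow-up;
within the baseline-unimpaired stratum, the percentage improving, declining,
and becoming clinically impaired. A subject can legitimately appear in
several categories — e.g. impaired on two domains at baseline and one at
follow-up counts as improved on a domain *and* as no longer clinically
impaired.

## The synthetic cohort generator

The generator draws a two-group, two-wave cohort on the control-baseline z
scale and maps to raw units. For subtest $k$ of subject $s$ in group $g$ at
time $t$:

$$z = -\delta_k\,[g = \text{pat}] - \gamma\,[\text{impaired subgroup}] + u_s +
\alpha_k (a_s - a_0) + \pi_{kg}\,t + \varepsilon,\qquad
\text{raw} = \mu_k + s_k\, z\, \sigma_k$$

with $s_k = +1$ for higher-better and $-1$ for lower-better subtests.
Generating on the z scale makes direction handling and z-recovery exactly
testable; the raw means $\mu_k, \sigma_k$ only anchor plausible raw scales.

Default parameters are the study conditions the package is designed around,
chosen once and documented here:

| parameter | default | reading |
|---|---|---|
| n (patient/control) | 75 / 108 | typical retained two-wave FES cohort |
| baseline age, patients | N(26.0, 7.7) yr | patients younger than controls |
| baseline age, controls | N(30.9, 7.4) yr | |
| group deficit $\delta_k$ | 1.0 SD, all subtests | the canonical ~1 SD global deficit |
| random intercept SD | 0.8 | with residual 0.5 ⇒ ICC ≈ 0.7, typical test-retest structure |
| residual SD | 0.5 | per subtest per wave |
| practice slope, controls | 0.03 SD/yr | ~0.3 SD gain over a decade |
| practice slope, patients | 0.015 SD/yr | blunted practice benefit |
| age slope $\alpha_k$ | −0.01 SD/yr | older subjects score slightly lower |
| impaired subgroup | 30 % of patients, extra 1.0 SD | the widespread-impairment minority |
| follow-up | 10 yr, no attrition | attrition is opt-in |

The age effect enters through baseline age only, matching the analysis
model's age term; $a_0$ is the group-size-weighted mean of the configured age
means. Attrition removes only wave-2 records, either at random or
worst-baseline-first (for attrition-bias experiments). An MCAR missingness
injector is off by default.

**What the generator does and does not emulate.** It reproduces the moment
structure the analyses assume: group deficits, practice and age effects,
between-subject heterogeneity, a globally impaired subgroup, and
within-subject correlation via a shared random intercept. It does not emulate
domain-specific deterioration patterns, floor/ceiling effects, non-Gaussian
raw-score distributions, item-level scoring, diagnosis subtypes, medication,
or symptom trajectories. Passing tests therefore demonstrate correctness of
the statistical machinery under the assumed data-generating process, not
robustness to every pathology of real clinical data. The within-subject
correlation model (random intercept + independent residuals) is itself an
assumption: two-wave data cannot distinguish it from richer covariance
structures.

## Numerical choices and problem sizes

- Sample SDs use n − 1 throughout; norms with zero variance or fewer than two
  observations raise errors naming the subtest.
- Boundary conventions are strict everywhere they matter: impairment is
  z < cutoff, RCI categories use strict inequalities with ties stable.
- Percentages are reported to one decimal; the decrease/increase/stable
  identity (sum 100) holds exactly before rounding.
- Seeded runs are bit-identical; the pipeline reruns reproduce every table.
- Test-suite problem sizes: calibration and recovery experiments use cohorts
  of 400–1200 subjects and 10 000-draw Monte Carlo nulls, sizes at which
  binomial and sampling error put 3-SE bands of about ±1 percentage point or
  less around the checked quantities while the whole suite runs in seconds.

## Known limitations

- Two waves only; the linear time trend is unidentifiable from curvature.
- The RCI is built for intervention-scale retest intervals; over a decade it
  conflates practice with development, a caveat inherent to the method.
- No multiple-testing correction is applied anywhere: the growth-model table
  reports unadjusted p-values by design.
- Demographic summary tests (`t_from_summary`, `chi_square_2x2`, `paired_t`)
  operate on published-style group summaries and are pooled-variance by
  default; Welch and continuity-corrected variants are flags.
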