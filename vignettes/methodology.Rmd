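---
title: "Design and methodology of the screenbias simulation and estimator suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and methodology of the screenbias simulation and estimator suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Population-based studies of screening colonoscopy face two entangled
obstacles. First, *exposure measurement error with a perverse direction*: a
person in whom colorectal cancer (CRC) is developing often receives a
colonoscopy **because of** the incipient cancer — the diagnostic work-up —
so a naive design that counts any colonoscopy as "screened" and counts
cancers from the start of observation will find colonoscopy strongly
*associated with* cancer. Second, *selection and confounding*: who gets
referred for screening depends on measured characteristics (age, sex,
income, recent hospitalization), on the referring physician's habits, and on
unmeasured patient-level factors that also predict cancer risk.

`screenbias` provides a synthetic-registry generator in which all of these
mechanisms are explicit and switchable, two cohort designs that differ only
in how they separate exposure ascertainment from outcome ascertainment, and
six estimators of the absolute risk reduction (ARR). Because the generator
is synthetic, every estimate can be compared against the **counterfactual
truth** computed by re-simulating each subject's outcomes with screening
forced on and forced off.

## The data-generating model

Time is a discrete annual calendar:

* years 1–5: the **exposure window** (screening colonoscopies occur here);
* years 6–12: **incidence follow-up** (7 years);
* years 6–10: **mortality follow-up** (5 years);
* the restricted design starts counting outcomes in year 6.

Subjects aged 50–74 are nested in primary-care physicians (PCPs). Each PCP
has a latent colonoscopy-referral propensity \(z_j \sim N(\mu, \sigma^2)\)
on the logit scale — the source of the instrumental variable — and an
eligible panel drawn from a shifted negative-binomial distribution. Subject
covariates (age group, sex, neighborhood-income quintile, rural residence,
a 3-level hospitalization/comorbidity category) are drawn independently from
configured marginal frequencies, together with an unmeasured standard-normal
confounder \(u_i\).

Screening uptake is Bernoulli with

\[
\operatorname{logit} P(\text{screen}_i) =
\beta_0 + \beta_z z_{j(i)} + x_i^\top \beta_x + \beta_u u_i ,
\]

with the event year uniform over the window. Independently, **incipient
window CRC** arises with a small probability; such a case is diagnosed in a
uniform window year and, with probability `p_diagnostic_given_window_crc`,
receives a *diagnostic* colonoscopy in the diagnosis year. This is the
measurement-error mechanism: in a design that counts any colonoscopy as
exposure, the cancer itself produces the "exposure".

Follow-up CRC (diagnosed in years 6–12) occurs with probability

\[
\operatorname{logit} P(\text{CRC}_i) =
\operatorname{logit}\bigl(r_{a(i), s(i)}\bigr)
+ \log(\mathrm{RR}) \cdot \text{screen}_i + \gamma u_i ,
\]

where \(r_{a,s}\) is the baseline 7-year risk of the subject's age–sex cell
and RR is the true causal risk ratio of screening. A CRC case dies of CRC
within the mortality window with a fixed probability; other-cause death is
an independent annual hazard that truncates any later event (an event in the
death year still counts). All per-subject draws use fixed-length uniform
streams under per-stage seeds, which is what makes the common-random-numbers
counterfactual in `true_marginal_arr()` exact: rerunning the outcome stage
with screening forced to 1 or 0 replays the identical randomness.

### Parameters and defaults

| Parameter | Default | Units / scale | Why this value |
|---|---|---|---|
| `n_pcps` | 2000 | count | with `mean_panel = 100` gives ≈ 200,000 subjects — large enough for stable rare-outcome estimates on one CPU in seconds |
| `mean_panel` | 100 | subjects/PCP | typical screen-eligible panel size |
| `panel_dispersion` | 0.2 | — | mild overdispersion so panels vary realistically (var = μ + 0.2μ²) |
| `pcp_propensity_mu`, `pcp_propensity_sigma` | 0, 0.6 | logit | σ = 0.6 yields roughly 2.5-fold odds variation across physicians — enough preference heterogeneity for a strong instrument without implausible extremes |
| `beta_exposure$intercept` | −4.9 | log-odds | anchors overall any-colonoscopy uptake near 7% given the other loadings |
| `beta_exposure$instrument` | 1.0 | per logit of \(z\) | the latent propensity passes through to uptake one-for-one |
| age/sex/income/rural loadings | see `default_beta_exposure()` | log-odds | shaped so colonoscopy users are older within 60–69 but less often 70–74, slightly more often female, higher-income |
| comorbidity loadings | +2.70, +2.29 | log-odds | recent hospitalization is by far the strongest measured driver of colonoscopy; it also gives the propensity model a c-statistic near 0.75 |
| `beta_exposure$confounder`, `gamma_confounder` | 0.4, 0.4 | log-odds per SD of \(u\) | moderate unmeasured confounding that biases covariate-adjusted estimates toward the null without overwhelming them |
| `window_crc_rate` | 0.005 | probability | window cancers are rare but, via the diagnostic work-up, dominate the unselected design's exposed-arm incidence |
| `p_diagnostic_given_window_crc` | 0.6 | probability | most, not all, incipient cancers get a diagnostic colonoscopy |
| `baseline_risk_7y` | 0.6–2.6% by age × sex | probability | rises with age, higher in men; averages ≈ 1.3% over the default covariate mix |
| `rr_colonoscopy` | 0.6 | risk ratio | a strongly protective true effect, so the unselected design's positive association is unambiguously an artifact |
| `p_death_given_crc_5y` | 0.30 | probability | case fatality within the mortality window |
| `p_other_death` | 0.01 | annual probability | competing mortality that censors follow-up |

The defaults were calibrated **once**, before any estimator comparison was
run, to a handful of descriptive anchors (≈ 7% exposed in the unselected
design, ≈ 1.3% restricted-cohort incidence, ≈ 54% female) and then frozen.
No parameter was revisited afterwards.

## The two cohort designs

**Unselected** (`build_unselected_cohort()`): every subject enters; exposure
is *any* colonoscopy in the window, screening or diagnostic; outcomes count
from year 1. Window cancers therefore appear as exposed cases and the
unadjusted risk difference for incidence is strongly **positive** —
colonoscopy looks harmful.

**Restricted** (`build_restricted_cohort()`): subjects must be alive and
CRC-free at the end of year 5; outcomes count from year 6; and subjects are
dropped if their PCP has fewer than 10 linked eligible patients or an
any-colonoscopy referral rate of at most 3 per 100 (the rule is strictly
"more than 3%"). Remaining exposures are screening colonoscopies by
construction and the unadjusted risk difference is **negative**. The sign
reversal between the two designs — same registry, same outcome — is the
package's headline property.

Two bookkeeping rules matter:

* the **instrument** (each PCP's *discretionary*-colonoscopy rate per 100
  eligible panel members) is computed on the full pre-restriction panel, so
  the restriction step cannot leak outcome information into it;
* a colonoscopy is *discretionary* when it is a screening-type outpatient
  procedure with no CRC diagnosis at the procedure or within the following
  3 years; the 3% PCP filter, by contrast, uses the *any*-colonoscopy
  referral rate.

## Estimators

All model-based estimators are built on one hand-written core,
`fit_logistic()`: an iteratively-reweighted-least-squares logistic fit with
a cluster-robust sandwich covariance that sums score contributions within
PCPs (no small-sample correction). Point estimates coincide with an
independence-working-correlation GEE; the sandwich supplies the clustering
adjustment. Effects are reported as marginal ARRs via g-computation
(`marginal_arr()`): predict every subject's outcome probability with
exposure set to 1, then 0, average both, and difference. The default CI is
the delta method on the averaged predictions using the cluster-robust
covariance; a seeded cluster-resampled percentile bootstrap is available.

1. **Unadjusted** — arm proportions with the unpooled Wald interval.
2. **Covariate-adjusted logistic (GEE-style)** — outcome ~ exposure + the
   five measured covariates, marginally standardized.
3. **PS quintile stratification** — propensity ranks split into five
   equal-size strata (`ties.method = "first"`, so stratum sizes agree to
   within one); the pooled ARR is the stratum-size-weighted mean of
   stratum differences; strata missing an arm are excluded and noted.
4. **IPTW** — unstabilized weights 1/PS and 1/(1−PS) enter the IRLS working
   weights of the outcome model (treated as fixed in the sandwich),
   followed by marginal standardization.
5. **PS matching** — greedy 1:1 digit matching without replacement at 5
   decimal places of the score, then 4, … down to 1; within a pass, treated
   subjects are processed in a seeded order derived from sorted subject ids
   (so row order is irrelevant) and take the nearest available control by
   raw score, ties to the smaller id. The matched contrast uses the
   paired-proportion variance and a McNemar test (exact binomial when there
   are fewer than 25 discordant pairs). A supplementary signed-rank test of
   event-time homogeneity (`wilcoxon_km_pairs()`) pools and midranks the
   event years of pairs in which both members experience the event and
   applies the Wilcoxon signed-rank normal approximation to the within-pair
   rank differences. Because it discards censored pairs it conditions on a
   double event and is an approximation, not a censoring-aware survival
   test; it is reported as a descriptive supplement only.
6. **Instrumental variable (two-stage predictor substitution)** — first
   stage: logistic exposure ~ instrument + covariates, with strength
   diagnostics (partial F from an auxiliary least-squares first stage,
   likelihood-ratio chi-square, first-stage odds ratio); second stage:
   logistic outcome ~ predicted exposure probability + covariates,
   cluster-robust, with the ARR evaluated at predicted exposure 1 versus 0.
   The default variance ignores first-stage estimation error; a seeded
   two-stage cluster bootstrap is available.

### Estimands: a caution

The matched estimator contrasts outcomes over the *matched treated*
population (an ATT-type estimand). Under a constant risk-*ratio* effect the
treated — older, sicker — have higher baseline risk, so their true ARR is
larger in magnitude than the population ATE. Recovery checks therefore
compare the matched estimate against the counterfactual truth computed over
the matched treated subjects, and every other estimator against the
population truth. This is estimand bookkeeping, not a tolerance choice.

The IV estimand is also marginal in its own way: preference-style
instruments identify effects in the subjects whose exposure the instrument
sways. The package reports this by construction (the second-stage contrast
extrapolates the predicted-exposure range to 0 and 1) and warns when the
predicted-exposure range is narrower than 0.05.

## Scenario configurations

Three frozen scenario constructors support the package's recovery checks:

* `config_measured_confounding()` — unmeasured confounder and window
  mechanism off; the measured age gradient in uptake strengthened (+0.8,
  +1.2 log-odds). All confounding is recorded, so estimators 2–5 are
  consistent and the unadjusted contrast is biased.
* `config_unmeasured_confounding()` — window mechanism off; confounder
  loadings raised to +0.8 on both uptake and outcome. Only the IV remains
  consistent; at ~100,000 subjects its per-replicate standard deviation is
  still large (≈ 0.7 pp for a truth of ≈ −0.66 pp), which is why recovery
  is assessed on the *median* over 50 replicates. Its confidence intervals
  are systematically wider than the adjusted model's — the price of
  consistency.
* `config_null_effect()` — risk ratio 1, all confounding off: every
  estimator's ARR is zero up to Monte-Carlo error.

## Numerical choices

* Linear predictors are clipped at ±30 before `plogis()`; coefficients
  diverging beyond |30| raise an explicit separation error.
* IRLS stops when the maximum absolute score is below 1e−8 or the relative
  deviance change is below 1e−10, with step-halving against non-finite
  overshoots; rank-deficient designs raise an error naming the aliased
  columns.
* The c-statistic uses the midrank Mann–Whitney identity (ties get half
  credit), identical to brute-force pair enumeration.
* Propensity scores are clipped to [1e−6, 1−1e−6] before weighting.
* All randomness derives from one user seed via fixed per-stage streams
  (`pcps`, `subjects`, `exposure`, `outcomes`, `match`, `boot`), so e.g.
  enlarging panels never perturbs the PCP-level draws, and runs are
  deterministic end to end — two pipeline runs with one seed are
  byte-identical on disk.
* Exported data never contain the latent confounder; it exists only inside
  the in-memory registry, which is also why counterfactual truth requires
  the in-memory object.

## Limitations

* Covariates are drawn independently; real populations have correlated
  covariates, which mainly affects how much overlap the propensity methods
  enjoy.
* The discrete annual calendar makes "censoring at the death year" coarse;
  the Kaplan–Meier utilities operate on that yearly grid.
* The IV second stage is predictor substitution with logistic stages, not
  linear two-stage least squares or residual inclusion; with rare outcomes
  and plug-in nonlinearity it is approximately, not exactly, unbiased, and
  it is noisy — single-replicate IV estimates should never be interpreted
  without their (wide) intervals.
* No trimming, stabilization, optimal matching, or weak-IV-robust inference
  is provided; the estimators implement the standard forms of each method.
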