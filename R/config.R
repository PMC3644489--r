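# Categorical level sets shared by the generator, cohort builder and design
# matrices. Reference levels (first element) are fixed: age 50-59, male,
# income quintile 1, urban, not hospitalized.
AGE_LEVELS <- c("50-59", "60-69", "70-74")
SEX_LEVELS <- c("male", "female")
INCOME_LEVELS <- as.character(1:5)
COMORBIDITY_LEVELS <- c("not_hospitalized", "hospitalized_no_comorbidity",
                        "one_plus_comorbidity")

# Discrete annual calendar: exposure window years 1..5 (1996-2000),
# incidence follow-up through year 12 (2007), mortality through year 10
# (2005), outcome follow-up for the restricted design starting year 6 (2001).
EXPOSURE_WINDOW <- 1:5
INCIDENCE_END_YEAR <- 12L
MORTALITY_END_YEAR <- 10L
FOLLOWUP_START_YEAR <- 6L

ANALYSIS_COVARIATES <- c("age_group", "sex", "income_quintile", "rural",
                         "comorbidity")

#' Default covariate frequencies
#'
#' Marginal frequencies of the subject-level covariates used by the registry
#' generator: age group, sex, neighborhood income quintile, rural residence
#' and the three-level hospitalization/comorbidity category. Defaults follow
#' the baseline composition of a large population-based screening-eligible
#' cohort (about 54.3% female, 42.3/34.9/22.8% across age bands).
#'
#' @return Named list of probability vectors; each block sums to one.
#' @export
default_covariate_freqs <- function() {
  list(
    age_group = stats::setNames(c(0.423, 0.349, 0.228), AGE_LEVELS),
    sex = stats::setNames(c(0.457, 0.543), SEX_LEVELS),
    income_quintile = stats::setNames(c(0.172, 0.201, 0.203, 0.202, 0.222),
                                      INCOME_LEVELS),
    rural = c(urban = 0.863, rural = 0.137),
    comorbidity = stats::setNames(c(0.477, 0.368, 0.155), COMORBIDITY_LEVELS)
  )
}

#' Default screening-uptake coefficients
#'
#' Log-odds coefficients of the screening-colonoscopy uptake model. The
#' covariate loadings reproduce the typical composition shift between
#' colonoscopy users and nonusers (users older within 60-69 but less often
#' 70-74, slightly more often female, higher-income, and far more often
#' recently hospitalized); `instrument` scales the latent physician referral
#' propensity and `confounder` the unmeasured subject-level confounder.
#'
#' @return Named list with elements `intercept`, `instrument`, `age_group`
#'   (length 3, reference first), `female`, `income_quintile` (length 5),
#'   `rural`, `comorbidity` (length 3) and `confounder`.
#' @export
default_beta_exposure <- function() {
  list(
    intercept = -4.9,
    instrument = 1.0,
    age_group = stats::setNames(c(0, 0.18, -0.22), AGE_LEVELS),
    female = 0.06,
    income_quintile = stats::setNames(c(0, 0.06, 0.11, 0.15, 0.27),
                                      INCOME_LEVELS),
    rural = 0.05,
    comorbidity = stats::setNames(c(0, 2.70, 2.29), COMORBIDITY_LEVELS),
    confounder = 0.4
  )
}

#' Default baseline 7-year colorectal-cancer risk by age and sex
#'
#' Probability of an incident CRC diagnosis during the 7-year outcome
#' follow-up for an unscreened subject, by age group (rows) and sex
#' (columns). Values rise with age and are higher in men, and average to
#' roughly 1.3% over the default covariate mix.
#'
#' @return 3 x 2 numeric matrix with dimnames `AGE_LEVELS` x `SEX_LEVELS`.
#' @export
default_baseline_risk <- function() {
  matrix(c(0.008, 0.016, 0.026,   # male
           0.006, 0.012, 0.020),  # female
         nrow = 3, dimnames = list(AGE_LEVELS, SEX_LEVELS))
}

#' Registry generator configuration
#'
#' Builds and validates the configuration object for [generate_registry()].
#' The defaults define the package's reference study conditions: about
#' 200,000 subjects nested in 2,000 primary-care physicians (PCPs), a latent
#' logit-normal PCP referral propensity (the instrument source), screening
#' uptake around 7%, a protective causal risk ratio of 0.6, an unmeasured
#' confounder acting on both uptake and outcome, and an exposure
#' measurement-error mechanism in which incipient CRC arising during the
#' 5-year exposure window can trigger a diagnostic colonoscopy.
#'
#' @param seed Integer seed; all generator randomness derives from it via
#'   per-stage streams, so PCP draws are unaffected by the subject count.
#' @param n_pcps Number of PCPs.
#' @param mean_panel Mean number of screen-eligible subjects per PCP.
#' @param panel_dispersion Nonnegative overdispersion of panel sizes;
#'   0 gives (shifted) Poisson panels, otherwise negative binomial with
#'   variance `mu + panel_dispersion * mu^2`.
#' @param pcp_propensity_mu,pcp_propensity_sigma Mean and SD (logit scale)
#'   of the latent PCP colonoscopy-referral propensity.
#' @param covariate_freqs See [default_covariate_freqs()].
#' @param beta_exposure See [default_beta_exposure()].
#' @param window_crc_rate Probability that incipient CRC arises during the
#'   5-year exposure window.
#' @param p_diagnostic_given_window_crc Probability that a window CRC case
#'   receives a diagnostic colonoscopy in its diagnosis year.
#' @param baseline_risk_7y See [default_baseline_risk()].
#' @param rr_colonoscopy True causal risk ratio of screening colonoscopy on
#'   follow-up CRC incidence (< 1 protective).
#' @param gamma_confounder Unmeasured-confounder effect on the outcome
#'   (log-odds per SD).
#' @param p_death_given_crc_5y Probability a CRC case dies of CRC within the
#'   mortality window.
#' @param p_other_death Annual other-cause death probability.
#' @return Object of class `registry_config`.
#' @export
registry_config <- function(seed = 1L,
                            n_pcps = 2000L,
                            mean_panel = 100,
                            panel_dispersion = 0.2,
                            pcp_propensity_mu = 0,
                            pcp_propensity_sigma = 0.6,
                            covariate_freqs = default_covariate_freqs(),
                            beta_exposure = default_beta_exposure(),
                            window_crc_rate = 0.005,
                            p_diagnostic_given_window_crc = 0.6,
                            baseline_risk_7y = default_baseline_risk(),
                            rr_colonoscopy = 0.6,
                            gamma_confounder = 0.4,
                            p_death_given_crc_5y = 0.30,
                            p_other_death = 0.01) {
  cfg <- list(
    seed = as.integer(seed),
    n_pcps = as.integer(n_pcps),
    mean_panel = mean_panel,
    panel_dispersion = panel_dispersion,
    pcp_propensity_mu = pcp_propensity_mu,
    pcp_propensity_sigma = pcp_propensity_sigma,
    covariate_freqs = covariate_freqs,
    beta_exposure = beta_exposure,
    window_crc_rate = window_crc_rate,
    p_diagnostic_given_window_crc = p_diagnostic_given_window_crc,
    baseline_risk_7y = baseline_risk_7y,
    rr_colonoscopy = rr_colonoscopy,
    gamma_confounder = gamma_confounder,
    p_death_given_crc_5y = p_death_given_crc_5y,
    p_other_death = p_other_death
  )
  class(cfg) <- "registry_config"
  validate_registry_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("configuration error: field '%s' %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    config_error(field, "must be a probability in [0, 1]")
}

validate_registry_config <- function(cfg) {
  if (!is.finite(cfg$seed)) config_error("seed", "must be a finite integer")
  if (cfg$n_pcps < 1) config_error("n_pcps", "must be >= 1")
  if (cfg$mean_panel < 1) config_error("mean_panel", "must be >= 1")
  if (cfg$panel_dispersion < 0)
    config_error("panel_dispersion", "must be nonnegative")
  if (!is.finite(cfg$pcp_propensity_mu))
    config_error("pcp_propensity_mu", "must be finite")
  if (cfg$pcp_propensity_sigma < 0)
    config_error("pcp_propensity_sigma", "must be nonnegative")
  fr <- cfg$covariate_freqs
  need <- c("age_group", "sex", "income_quintile", "rural", "comorbidity")
  if (!all(need %in% names(fr)))
    config_error("covariate_freqs",
                 paste("must contain blocks:", paste(need, collapse = ", ")))
  lens <- c(age_group = 3L, sex = 2L, income_quintile = 5L, rural = 2L,
            comorbidity = 3L)
  for (bl in need) {
    check_prob(fr[[bl]], paste0("covariate_freqs$", bl))
    if (length(fr[[bl]]) != lens[[bl]])
      config_error(paste0("covariate_freqs$", bl),
                   sprintf("must have %d entries", lens[[bl]]))
    if (abs(sum(fr[[bl]]) - 1) > 1e-9)
      config_error(paste0("covariate_freqs$", bl), "must sum to 1")
  }
  be <- cfg$beta_exposure
  need_b <- c("intercept", "instrument", "age_group", "female",
              "income_quintile", "rural", "comorbidity", "confounder")
  if (!all(need_b %in% names(be)))
    config_error("beta_exposure",
                 paste("must contain:", paste(need_b, collapse = ", ")))
  if (!all(is.finite(unlist(be))))
    config_error("beta_exposure", "must be finite")
  check_prob(cfg$window_crc_rate, "window_crc_rate")
  check_prob(cfg$p_diagnostic_given_window_crc,
             "p_diagnostic_given_window_crc")
  br <- cfg$baseline_risk_7y
  if (!is.matrix(br) || !all(dim(br) == c(3, 2)))
    config_error("baseline_risk_7y", "must be a 3 x 2 age-by-sex matrix")
  check_prob(as.vector(br), "baseline_risk_7y")
  if (any(br <= 0) || any(br >= 1))
    config_error("baseline_risk_7y", "must be strictly inside (0, 1)")
  if (!is.finite(cfg$rr_colonoscopy) || cfg$rr_colonoscopy <= 0)
    config_error("rr_colonoscopy", "must be > 0")
  if (!is.finite(cfg$gamma_confounder))
    config_error("gamma_confounder", "must be finite")
  check_prob(cfg$p_death_given_crc_5y, "p_death_given_crc_5y")
  check_prob(cfg$p_other_death, "p_other_death")
  invisible(cfg)
}

#' Scenario configurations for estimator-recovery studies
#'
#' Fixed study conditions used throughout the package's simulation checks.
#'
#' `config_measured_confounding()` switches the unmeasured confounder and the
#' window measurement-error mechanism off and strengthens the measured age
#' gradient in uptake (log-odds +0.8 and +1.2 for ages 60-69 and 70-74), so
#' that all confounding is captured by recorded covariates: covariate-aware
#' estimators are consistent while the unadjusted contrast is biased.
#'
#' `config_unmeasured_confounding()` keeps the measurement-error mechanism
#' off but gives the unmeasured confounder strong loadings (+0.8 on uptake
#' and +0.8 on outcome log-odds), the setting in which only the
#' instrumental-variable estimator remains consistent.
#'
#' `config_null_effect()` sets the causal risk ratio to 1 with no
#' confounding, so every estimator's absolute risk reduction should be zero
#' up to Monte-Carlo error.
#'
#' @param seed,n_pcps,mean_panel Passed to [registry_config()].
#' @return A `registry_config`.
#' @export
config_measured_confounding <- function(seed = 1L, n_pcps = 500L,
                                        mean_panel = 100) {
  be <- default_beta_exposure()
  be$age_group <- stats::setNames(c(0, 0.8, 1.2), AGE_LEVELS)
  be$confounder <- 0
  registry_config(seed = seed, n_pcps = n_pcps, mean_panel = mean_panel,
                  beta_exposure = be, window_crc_rate = 0,
                  gamma_confounder = 0)
}

#' @rdname config_measured_confounding
#' @export
config_unmeasured_confounding <- function(seed = 1L, n_pcps = 500L,
                                          mean_panel = 100) {
  be <- default_beta_exposure()
  be$confounder <- 0.8
  registry_config(seed = seed, n_pcps = n_pcps, mean_panel = mean_panel,
                  beta_exposure = be, window_crc_rate = 0,
                  gamma_confounder = 0.8)
}

#' @rdname config_measured_confounding
#' @export
config_null_effect <- function(seed = 1L, n_pcps = 2000L, mean_panel = 100) {
  be <- default_beta_exposure()
  be$confounder <- 0
  registry_config(seed = seed, n_pcps = n_pcps, mean_panel = mean_panel,
                  beta_exposure = be, window_crc_rate = 0,
                  rr_colonoscopy = 1, gamma_confounder = 0)
}

# Per-stage seed derivation: one user-facing seed feeds an independent,
# order-stable stream for each generation stage, so e.g. enlarging panels
# never perturbs the PCP-level draws. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stages <- c(pcps = 1, subjects = 2, exposure = 3, outcomes = 4,
              match = 5, boot = 6)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  val <- ((as.double(seed) %% 2147483647) * 1009 +
            stages[[stage]] * 7919) %% 2147483647
  as.integer(val)
}

clip_logit <- function(eta, bound = 30) pmin(pmax(eta, -bound), bound)
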