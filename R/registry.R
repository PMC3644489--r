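#' Generate primary-care physician profiles
#'
#' Draws one profile per PCP: an eligible-panel size (shifted Poisson when
#' `panel_dispersion` is 0, otherwise shifted negative binomial with variance
#' `mu + panel_dispersion * mu^2`) and a latent colonoscopy-referral
#' propensity on the logit scale. Physician heterogeneity in referral
#' propensity is the source of the downstream instrumental variable.
#'
#' @param config A [registry_config()].
#' @return data.frame with columns `pcp_id`, `propensity_logit`,
#'   `n_eligible`.
#' @export
generate_pcps <- function(config) {
  validate_registry_config(config)
  set.seed(stage_seed(config$seed, "pcps"))
  n <- config$n_pcps
  mu <- config$mean_panel - 1
  if (config$panel_dispersion == 0 || mu == 0) {
    n_eligible <- stats::rpois(n, mu) + 1L
  } else {
    n_eligible <- stats::rnbinom(n, size = 1 / config$panel_dispersion,
                                 mu = mu) + 1L
  }
  propensity_logit <- stats::rnorm(n, config$pcp_propensity_mu,
                                   config$pcp_propensity_sigma)
  data.frame(pcp_id = seq_len(n), propensity_logit = propensity_logit,
             n_eligible = as.integer(n_eligible))
}

#' Generate subject covariates
#'
#' Assigns each eligible subject to their PCP and draws covariates
#' independently from the configured marginal frequencies, plus a latent
#' standard-normal unmeasured confounder. No exposure or outcome fields are
#' filled at this stage.
#'
#' @param config A [registry_config()].
#' @param pcps Output of [generate_pcps()].
#' @return data.frame of subjects (one row per subject).
#' @export
generate_subjects <- function(config, pcps) {
  validate_registry_config(config)
  if (is.null(pcps) || nrow(pcps) == 0) stop("pcps must be nonempty")
  set.seed(stage_seed(config$seed, "subjects"))
  n <- sum(pcps$n_eligible)
  fr <- config$covariate_freqs
  data.frame(
    subject_id = seq_len(n),
    pcp_id = rep(pcps$pcp_id, pcps$n_eligible),
    age_group = sample(AGE_LEVELS, n, TRUE, fr$age_group),
    sex = sample(SEX_LEVELS, n, TRUE, fr$sex),
    income_quintile = as.integer(sample(1:5, n, TRUE, fr$income_quintile)),
    rural = stats::runif(n) < fr$rural[["rural"]],
    comorbidity = sample(COMORBIDITY_LEVELS, n, TRUE, fr$comorbidity),
    confounder_u = stats::rnorm(n),
    stringsAsFactors = FALSE
  )
}

# Linear predictor of screening-colonoscopy uptake for given subjects,
# excluding the intercept-free pieces supplied by the caller.
exposure_linpred <- function(config, subjects, z_pcp) {
  be <- config$beta_exposure
  eta <- be$intercept +
    be$instrument * z_pcp +
    be$age_group[subjects$age_group] +
    be$female * (subjects$sex == "female") +
    be$income_quintile[subjects$income_quintile] +
    be$rural * subjects$rural +
    be$comorbidity[subjects$comorbidity] +
    be$confounder * subjects$confounder_u
  clip_logit(unname(eta))
}

#' Assign colonoscopy exposure and window cancers
#'
#' Draws at most one screening colonoscopy per subject with probability
#' `plogis` of the uptake linear predictor (intercept, PCP referral
#' propensity, covariates, unmeasured confounder), with event year uniform
#' over the 5-year window. Independently, incipient CRC arises during the
#' window with probability `window_crc_rate`; such cases are diagnosed in a
#' uniform window year and, with probability
#' `p_diagnostic_given_window_crc`, receive a diagnostic colonoscopy in the
#' diagnosis year. This is the exposure measurement-error mechanism: a
#' diagnostic procedure triggered by the cancer itself counts as colonoscopy
#' exposure in an unselected design.
#'
#' @param config A [registry_config()].
#' @param pcps,subjects Outputs of the previous stages.
#' @return `subjects` with event columns `screening`, `screening_year`,
#'   `screening_inpatient`, `window_crc`, `crc_dx_year`, `diagnostic_year`.
#' @export
assign_exposure <- function(config, pcps, subjects) {
  if (!is.null(subjects$screening))
    stop("exposure already assigned")
  set.seed(stage_seed(config$seed, "exposure"))
  n <- nrow(subjects)
  u_screen <- stats::runif(n)
  u_syear  <- stats::runif(n)
  u_window <- stats::runif(n)
  u_wyear  <- stats::runif(n)
  u_diag   <- stats::runif(n)

  z <- pcps$propensity_logit[match(subjects$pcp_id, pcps$pcp_id)]
  p_screen <- stats::plogis(exposure_linpred(config, subjects, z))

  subjects$screening <- as.integer(u_screen < p_screen)
  subjects$screening_year <- ifelse(subjects$screening == 1L,
                                    pmin(floor(u_syear * 5) + 1L, 5L),
                                    NA_integer_)
  subjects$screening_inpatient <- FALSE

  subjects$window_crc <- u_window < config$window_crc_rate
  subjects$crc_dx_year <- ifelse(subjects$window_crc,
                                 pmin(floor(u_wyear * 5) + 1L, 5L),
                                 NA_integer_)
  diag <- subjects$window_crc &
    u_diag < config$p_diagnostic_given_window_crc
  subjects$diagnostic_year <- ifelse(diag, subjects$crc_dx_year, NA_integer_)
  subjects
}

#' Simulate cancer and death outcomes
#'
#' For subjects without a window cancer, follow-up CRC (diagnosis years
#' 6..12) occurs with probability `plogis(qlogis(baseline risk) +
#' log(rr_colonoscopy) * screening + gamma_confounder * u)`. Any CRC case
#' dies of CRC within the mortality window (through year 10) with
#' probability `p_death_given_crc_5y`, the death year uniform between
#' diagnosis and year 10. Other-cause death occurs each year independently
#' of exposure with probability `p_other_death`. Other-cause death truncates
#' later events: a diagnosis (and its diagnostic colonoscopy), a CRC death,
#' or a screening colonoscopy scheduled after the death year is removed.
#'
#' All per-subject random draws use a fixed-length stream, so rerunning this
#' stage with exposure forced to 1 or 0 yields common-random-number
#' counterfactuals.
#'
#' @param config A [registry_config()].
#' @param subjects Output of [assign_exposure()].
#' @return `subjects` with `crc_dx_year`, `crc_death_year`,
#'   `other_death_year` filled.
#' @export
simulate_outcomes <- function(config, subjects) {
  if (is.null(subjects$screening))
    stop("exposures must be assigned before outcomes")
  set.seed(stage_seed(config$seed, "outcomes"))
  n <- nrow(subjects)
  u_crc   <- stats::runif(n)
  u_dxy   <- stats::runif(n)
  u_death <- stats::runif(n)
  u_dy    <- stats::runif(n)
  u_other <- stats::runif(n)

  br <- config$baseline_risk_7y
  base <- br[cbind(match(subjects$age_group, AGE_LEVELS),
                   match(subjects$sex, SEX_LEVELS))]
  eta <- clip_logit(stats::qlogis(base) +
                      log(config$rr_colonoscopy) * subjects$screening +
                      config$gamma_confounder * subjects$confounder_u)
  p_follow <- stats::plogis(eta)

  follow_crc <- !subjects$window_crc & u_crc < p_follow
  follow_year <- pmin(FOLLOWUP_START_YEAR +
                        floor(u_dxy * (INCIDENCE_END_YEAR -
                                         FOLLOWUP_START_YEAR + 1L)),
                      INCIDENCE_END_YEAR)
  dx <- ifelse(subjects$window_crc, subjects$crc_dx_year,
               ifelse(follow_crc, follow_year, NA_integer_))

  # CRC death: only possible when diagnosed within the mortality window
  can_die <- !is.na(dx) & dx <= MORTALITY_END_YEAR
  dies <- can_die & u_death < config$p_death_given_crc_5y
  dspan <- MORTALITY_END_YEAR - dx + 1L
  dyear <- dx + pmin(floor(u_dy * dspan), dspan - 1L)
  crc_death <- ifelse(dies, dyear, NA_integer_)

  # Other-cause death: geometric first-success time, annual hazard q
  q <- config$p_other_death
  if (q > 0) {
    other <- ceiling(log(u_other) / log(1 - q))
    other <- ifelse(other <= INCIDENCE_END_YEAR, as.integer(other),
                    NA_integer_)
  } else {
    other <- rep(NA_integer_, n)
  }

  # Truncation by other-cause death (events in the death year still count)
  kill_screen <- !is.na(other) & !is.na(subjects$screening_year) &
    other < subjects$screening_year
  subjects$screening[kill_screen] <- 0L
  subjects$screening_year[kill_screen] <- NA_integer_

  kill_dx <- !is.na(other) & !is.na(dx) & other < dx
  dx[kill_dx] <- NA_integer_
  crc_death[kill_dx] <- NA_integer_
  subjects$window_crc[kill_dx] <- FALSE
  subjects$diagnostic_year[kill_dx] <- NA_integer_

  kill_cd <- !is.na(other) & !is.na(crc_death) & other < crc_death
  crc_death[kill_cd] <- NA_integer_

  subjects$crc_dx_year <- as.integer(dx)
  subjects$crc_death_year <- as.integer(crc_death)
  subjects$other_death_year <- other
  subjects
}

#' Generate a complete synthetic registry snapshot
#'
#' Composes [generate_pcps()], [generate_subjects()], [assign_exposure()]
#' and [simulate_outcomes()]. Deterministic given the config (including its
#' seed); all record invariants are checked before returning.
#'
#' @param config A [registry_config()].
#' @return Object of class `registry_snapshot`: list with `config`, `pcps`,
#'   `subjects`.
#' @export
generate_registry <- function(config) {
  pcps <- generate_pcps(config)
  subjects <- generate_subjects(config, pcps)
  subjects <- assign_exposure(config, pcps, subjects)
  subjects <- simulate_outcomes(config, subjects)
  snap <- structure(list(config = config, pcps = pcps, subjects = subjects),
                    class = "registry_snapshot")
  check_registry_invariants(snap)
  snap
}

check_registry_invariants <- function(snap) {
  s <- snap$subjects
  stopifnot(
    !anyDuplicated(s$subject_id),
    all(s$pcp_id %in% snap$pcps$pcp_id),
    # CRC death requires a diagnosis and cannot precede it
    all(is.na(s$crc_death_year) |
          (!is.na(s$crc_dx_year) & s$crc_death_year >= s$crc_dx_year)),
    # diagnostic colonoscopies occur only in window-diagnosed subjects,
    # in the diagnosis year
    all(is.na(s$diagnostic_year) |
          (s$window_crc & s$diagnostic_year == s$crc_dx_year &
             s$diagnostic_year %in% EXPOSURE_WINDOW)),
    all(is.na(s$screening_year) | s$screening_year %in% EXPOSURE_WINDOW)
  )
  invisible(snap)
}

#' @export
print.registry_snapshot <- function(x, ...) {
  s <- x$subjects
  any_colo <- !is.na(s$screening_year) | !is.na(s$diagnostic_year)
  cat("Synthetic screening registry\n")
  cat(sprintf("  PCPs:      %d\n", nrow(x$pcps)))
  cat(sprintf("  subjects:  %d\n", nrow(s)))
  cat(sprintf("  any colonoscopy in window: %d (%.1f%%)\n",
              sum(any_colo), 100 * mean(any_colo)))
  cat(sprintf("  CRC diagnoses: %d (window %d, follow-up %d)\n",
              sum(!is.na(s$crc_dx_year)),
              sum(!is.na(s$crc_dx_year) & s$crc_dx_year <= 5),
              sum(!is.na(s$crc_dx_year) & s$crc_dx_year > 5)))
  cat(sprintf("  CRC deaths: %d\n", sum(!is.na(s$crc_death_year))))
  invisible(x)
}

# Columns of the exported subjects table. The latent confounder is
# deliberately absent: exported analysis data must never contain it.
SUBJECT_EXPORT_COLUMNS <- c(
  "subject_id", "pcp_id", "age_group", "sex", "income_quintile", "rural",
  "comorbidity", "screening_year", "inpatient_flag", "diagnostic_year",
  "crc_dx_year", "crc_death_year", "other_death_year"
)

#' Write / read a registry snapshot as delimited text
#'
#' Writes `subjects.csv`, `pcps.csv` and `config.json` under `dir`. The
#' subjects table serializes events as flat columns (empty field = none) and
#' excludes the latent confounder, which must never reach analysis data.
#' `read_registry()` restores the snapshot for cohort building (the latent
#' confounder is not recoverable from disk, by design).
#'
#' @param snap A `registry_snapshot`.
#' @param dir Output directory (created if needed).
#' @return `write_registry()` the directory, invisibly; `read_registry()` a
#'   `registry_snapshot` without `confounder_u`.
#' @export
write_registry <- function(snap, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- snap$subjects
  s$inpatient_flag <- s$screening_inpatient
  utils::write.csv(s[, SUBJECT_EXPORT_COLUMNS],
                   file.path(dir, "subjects.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(snap$pcps, file.path(dir, "pcps.csv"),
                   row.names = FALSE, na = "")
  cfg <- snap$config
  class(cfg) <- NULL
  cfg$baseline_risk_7y <- as.data.frame(cfg$baseline_risk_7y)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  s <- utils::read.csv(file.path(dir, "subjects.csv"),
                       stringsAsFactors = FALSE)
  p <- utils::read.csv(file.path(dir, "pcps.csv"), stringsAsFactors = FALSE)
  s$screening <- as.integer(!is.na(s$screening_year))
  s$screening_inpatient <- as.logical(s$inpatient_flag)
  s$inpatient_flag <- NULL
  s$window_crc <- !is.na(s$crc_dx_year) & s$crc_dx_year <= max(EXPOSURE_WINDOW)
  s$rural <- as.logical(s$rural)
  structure(list(config = NULL, pcps = p, subjects = s),
            class = "registry_snapshot")
}
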