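#' Counterfactual true marginal risk difference
#'
#' The recovery target for estimator checks: re-simulates every subject's
#' outcomes under screening forced to 1 and forced to 0 with common random
#' numbers (the outcome stage redraws from the same per-stage seed, and its
#' random stream has fixed per-subject length, so both counterfactual worlds
#' share all draws), then contrasts the outcome proportions over the chosen
#' subjects. Requires an in-memory registry (the latent confounder never
#' reaches disk).
#'
#' @param registry A `registry_snapshot` with its `config`.
#' @param subject_ids Subjects to average over (e.g. a cohort's rows, or the
#'   matched treated subjects for a treated-population contrast). Default:
#'   all subjects.
#' @param outcome `"crc_incident"` or `"crc_death"`.
#' @param spec A [cohort_spec()] defining the outcome windows (default
#'   restricted: outcomes counted after the exposure window).
#' @return True ARR in percentage points (exposed minus unexposed).
#' @export
true_marginal_arr <- function(registry,
                              subject_ids = registry$subjects$subject_id,
                              outcome = c("crc_incident", "crc_death"),
                              spec = cohort_spec("restricted")) {
  outcome <- match.arg(outcome)
  if (is.null(registry$config))
    stop("counterfactual truth requires the generating config")
  s <- registry$subjects
  outcome_flag <- function(subj) {
    if (spec$cohort_kind == "restricted") {
      w_end <- max(spec$exposure_window)
      if (outcome == "crc_incident")
        !is.na(subj$crc_dx_year) & subj$crc_dx_year > w_end &
          subj$crc_dx_year <= spec$incidence_end_year
      else
        !is.na(subj$crc_death_year) & subj$crc_death_year > w_end &
          subj$crc_death_year <= spec$mortality_end_year
    } else {
      if (outcome == "crc_incident")
        !is.na(subj$crc_dx_year) & subj$crc_dx_year <= spec$incidence_end_year
      else
        !is.na(subj$crc_death_year) &
          subj$crc_death_year <= spec$mortality_end_year
    }
  }
  counterfactual <- function(e) {
    sx <- s
    sx$screening <- e
    # reset outcome fields the outcome stage fills, keeping window cancers
    sx$crc_dx_year <- ifelse(sx$window_crc, sx$crc_dx_year, NA_integer_)
    sx$crc_death_year <- NA_integer_
    sx$other_death_year <- NULL
    simulate_outcomes(registry$config, sx)
  }
  s1 <- counterfactual(1L)
  s0 <- counterfactual(0L)
  keep <- s$subject_id %in% subject_ids
  100 * (mean(outcome_flag(s1)[keep]) - mean(outcome_flag(s0)[keep]))
}
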