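#' Cohort specification
#'
#' Parameters of the two cohort designs. The unselected design includes all
#' generated subjects and measures exposure concurrently with outcomes; the
#' restricted design keeps only subjects alive and cancer-free at the end of
#' the exposure window, drops patients of physicians with small panels
#' (fewer than `min_pcp_eligible` eligible patients) or low referral rates
#' (at most `min_referral_rate_pct` percent of panel members with any
#' colonoscopy — the rule is strictly "more than"), and counts outcomes only
#' after the window.
#'
#' @param cohort_kind "unselected" or "restricted".
#' @param min_pcp_eligible Minimum eligible panel size retained (default 10).
#' @param min_referral_rate_pct Any-colonoscopy referral-rate cutoff in
#'   percent; PCPs at or below it are excluded (default 3).
#' @param discretionary_lookahead_years Years after a colonoscopy during
#'   which a CRC diagnosis disqualifies it as discretionary (default 3).
#' @param exposure_window,incidence_end_year,mortality_end_year Year ranges
#'   of the discrete calendar.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_kind = c("unselected", "restricted"),
                        min_pcp_eligible = 10L,
                        min_referral_rate_pct = 3,
                        discretionary_lookahead_years = 3L,
                        exposure_window = EXPOSURE_WINDOW,
                        incidence_end_year = INCIDENCE_END_YEAR,
                        mortality_end_year = MORTALITY_END_YEAR) {
  cohort_kind <- match.arg(cohort_kind)
  if (min_referral_rate_pct < 0 || min_referral_rate_pct > 100)
    stop("min_referral_rate_pct must be in [0, 100]")
  if (discretionary_lookahead_years < 0)
    stop("discretionary_lookahead_years must be >= 0")
  if (max(exposure_window) >= incidence_end_year)
    stop("incidence follow-up must extend past the exposure window")
  structure(list(cohort_kind = cohort_kind,
                 min_pcp_eligible = as.integer(min_pcp_eligible),
                 min_referral_rate_pct = min_referral_rate_pct,
                 discretionary_lookahead_years =
                   as.integer(discretionary_lookahead_years),
                 exposure_window = exposure_window,
                 incidence_end_year = as.integer(incidence_end_year),
                 mortality_end_year = as.integer(mortality_end_year)),
            class = "cohort_spec")
}

#' Classify colonoscopies as discretionary
#'
#' A colonoscopy is discretionary when it is a screening-type (not
#' diagnostic) procedure, not performed during an inpatient stay, and not
#' associated with a CRC diagnosis at the time of the procedure or within
#' `lookahead_years` years after it.
#'
#' @param kind Character vector, "screening" or "diagnostic".
#' @param year Integer event year.
#' @param inpatient Logical, performed during an inpatient stay.
#' @param crc_dx_year Subject's CRC diagnosis year (NA if none).
#' @param lookahead_years Lookahead window in years (default 3).
#' @return Logical vector, one flag per event.
#' @export
classify_discretionary <- function(kind, year, inpatient, crc_dx_year,
                                   lookahead_years = 3L) {
  dx_near <- !is.na(crc_dx_year) & !is.na(year) &
    crc_dx_year >= year & crc_dx_year <= year + lookahead_years
  kind == "screening" & !inpatient & !is.na(year) & !dx_near
}

#' Compute per-PCP referral rates and the discretionary-rate instrument
#'
#' On the full pre-restriction panel, counts each PCP's linked eligible
#' subjects, their any-colonoscopy referrals, and their discretionary
#' colonoscopies, and derives two rates per 100 eligible persons: the
#' any-colonoscopy `referral_rate` (used by the restricted design's PCP
#' filter) and the `discretionary_rate` (the instrumental variable). PCPs
#' with no linked subjects get `NA` rates and an exclusion flag, never a
#' number.
#'
#' @param pcps,subjects Registry tables.
#' @param spec A [cohort_spec()] (supplies the discretionary lookahead).
#' @return `pcps` with columns `n_linked`, `n_any_colonoscopy`,
#'   `n_discretionary`, `referral_rate`, `discretionary_rate`, `excluded_empty`.
#' @export
compute_pcp_instrument <- function(pcps, subjects,
                                   spec = cohort_spec("restricted")) {
  disc <- classify_discretionary(
    kind = ifelse(!is.na(subjects$screening_year), "screening", "none"),
    year = subjects$screening_year,
    inpatient = subjects$screening_inpatient,
    crc_dx_year = subjects$crc_dx_year,
    lookahead_years = spec$discretionary_lookahead_years
  )
  any_colo <- !is.na(subjects$screening_year) |
    !is.na(subjects$diagnostic_year)
  idx <- factor(subjects$pcp_id, levels = pcps$pcp_id)
  n_linked <- as.integer(table(idx))
  n_any <- as.integer(tapply(as.numeric(any_colo), idx, sum, default = 0))
  n_disc <- as.integer(tapply(as.numeric(disc), idx, sum, default = 0))
  pcps$n_linked <- n_linked
  pcps$n_any_colonoscopy <- n_any
  pcps$n_discretionary <- n_disc
  pcps$excluded_empty <- n_linked == 0L
  pcps$referral_rate <- ifelse(n_linked > 0, 100 * n_any / n_linked, NA_real_)
  pcps$discretionary_rate <- ifelse(n_linked > 0, 100 * n_disc / n_linked,
                                    NA_real_)
  pcps
}

analysis_rows <- function(subjects, pcps, spec) {
  inst <- pcps$discretionary_rate[match(subjects$pcp_id, pcps$pcp_id)]
  exposed <- as.integer(!is.na(subjects$screening_year) |
                          !is.na(subjects$diagnostic_year))
  if (spec$cohort_kind == "unselected") {
    incident <- !is.na(subjects$crc_dx_year) &
      subjects$crc_dx_year <= spec$incidence_end_year
    death <- !is.na(subjects$crc_death_year) &
      subjects$crc_death_year <= spec$mortality_end_year
  } else {
    w_end <- max(spec$exposure_window)
    incident <- !is.na(subjects$crc_dx_year) &
      subjects$crc_dx_year > w_end &
      subjects$crc_dx_year <= spec$incidence_end_year
    death <- !is.na(subjects$crc_death_year) &
      subjects$crc_death_year > w_end &
      subjects$crc_death_year <= spec$mortality_end_year
  }
  data.frame(
    subject_id = subjects$subject_id,
    pcp_id = subjects$pcp_id,
    exposed = exposed,
    crc_incident = as.integer(incident),
    crc_death = as.integer(death),
    age_group = subjects$age_group,
    sex = subjects$sex,
    income_quintile = subjects$income_quintile,
    rural = subjects$rural,
    comorbidity = subjects$comorbidity,
    instrument = inst,
    crc_dx_year = subjects$crc_dx_year,
    crc_death_year = subjects$crc_death_year,
    other_death_year = subjects$other_death_year,
    stringsAsFactors = FALSE
  )
}

new_cohort <- function(spec, rows, exclusions, pcps) {
  counts <- list(
    n_subjects = nrow(rows),
    n_exposed = sum(rows$exposed),
    n_incident = sum(rows$crc_incident),
    n_deaths = sum(rows$crc_death),
    n_pcps_retained = length(unique(rows$pcp_id)),
    n_pcps_excluded = nrow(pcps) - length(unique(rows$pcp_id))
  )
  structure(list(spec = spec, rows = rows, counts = c(counts, exclusions),
                 pcps = pcps),
            class = "cohort")
}

#' Build the unselected cohort
#'
#' All generated subjects enter (the generator emits only screen-eligible
#' subjects with a stable PCP). Exposure is any colonoscopy — screening or
#' diagnostic — during the window, and outcomes are counted from year 1, so
#' a cancer whose diagnostic workup included a colonoscopy appears as an
#' exposed case: the design that produces the paradoxical positive
#' association between colonoscopy and cancer.
#'
#' @param registry A `registry_snapshot`.
#' @param spec A [cohort_spec()]; kind is forced to match the builder.
#' @return Object of class `cohort`.
#' @export
build_unselected_cohort <- function(registry,
                                    spec = cohort_spec("unselected")) {
  spec$cohort_kind <- "unselected"
  s <- registry$subjects
  if (is.null(s) || nrow(s) == 0) stop("empty registry: no subjects")
  pcps <- compute_pcp_instrument(registry$pcps, s, spec)
  rows <- analysis_rows(s, pcps, spec)
  new_cohort(spec, rows, list(n_excluded_baseline = 0L,
                              n_excluded_pcp = 0L), pcps)
}

#' Build the restricted cohort
#'
#' Nested in the unselected cohort: keeps subjects alive and CRC-free at the
#' end of the exposure window, then drops patients of PCPs with fewer than
#' `min_pcp_eligible` linked eligible subjects or an any-colonoscopy
#' referral rate of at most `min_referral_rate_pct` percent. The instrument
#' (PCP discretionary rate) is computed on the full pre-restriction panel so
#' restriction cannot leak outcome information into it. Remaining exposures
#' are screening colonoscopies by construction, and outcomes are counted
#' from year 6 onward.
#'
#' @inheritParams build_unselected_cohort
#' @return Object of class `cohort`.
#' @export
build_restricted_cohort <- function(registry,
                                    spec = cohort_spec("restricted")) {
  spec$cohort_kind <- "restricted"
  s <- registry$subjects
  if (is.null(s) || nrow(s) == 0) stop("empty registry: no subjects")
  pcps <- compute_pcp_instrument(registry$pcps, s, spec)

  w_end <- max(spec$exposure_window)
  dead_or_dx <- (!is.na(s$crc_dx_year) & s$crc_dx_year <= w_end) |
    (!is.na(s$other_death_year) & s$other_death_year <= w_end) |
    (!is.na(s$crc_death_year) & s$crc_death_year <= w_end)
  keep_subject <- !dead_or_dx

  pcp_ok <- !pcps$excluded_empty &
    pcps$n_linked >= spec$min_pcp_eligible &
    pcps$referral_rate > spec$min_referral_rate_pct
  keep_pcp <- s$pcp_id %in% pcps$pcp_id[pcp_ok]
  if (!any(pcp_ok))
    stop(sprintf("all %d PCPs excluded by panel-size/referral-rate filters",
                 nrow(pcps)))

  kept <- s[keep_subject & keep_pcp, , drop = FALSE]
  rows <- analysis_rows(kept, pcps, spec)
  new_cohort(spec, rows,
             list(n_excluded_baseline = sum(dead_or_dx),
                  n_excluded_pcp = sum(keep_subject & !keep_pcp)),
             pcps)
}

#' @export
print.cohort <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf("%s cohort: %d subjects, %d exposed (%.1f%%)\n",
              x$spec$cohort_kind, c0$n_subjects, c0$n_exposed,
              100 * c0$n_exposed / max(c0$n_subjects, 1)))
  cat(sprintf("  CRC incident: %d (%.2f%%), CRC deaths: %d (%.2f%%)\n",
              c0$n_incident, 100 * c0$n_incident / max(c0$n_subjects, 1),
              c0$n_deaths, 100 * c0$n_deaths / max(c0$n_subjects, 1)))
  cat(sprintf("  PCPs retained: %d, excluded: %d\n",
              c0$n_pcps_retained, c0$n_pcps_excluded))
  if (x$spec$cohort_kind == "restricted")
    cat(sprintf("  excluded subjects: %d at baseline, %d by PCP filters\n",
                c0$n_excluded_baseline, c0$n_excluded_pcp))
  invisible(x)
}

#' Write a cohort to delimited text
#'
#' One analysis row per line, plus a JSON sidecar with the selection-flow
#' counts and exclusion tallies.
#'
#' @param cohort A `cohort`.
#' @param path Output CSV path; the sidecar uses the same stem with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$rows, path, row.names = FALSE, na = "")
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    c(list(cohort_kind = cohort$spec$cohort_kind), cohort$counts),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort_rows <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  rows$rural <- as.logical(rows$rural)
  rows
}
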