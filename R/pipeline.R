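ALL_METHODS <- c("unadjusted", "logistic_gee", "ps_quintile", "ps_iptw",
                 "ps_matched", "iv")

#' Run every requested estimator on a cohort
#'
#' Applies the selected methods to one cohort for one outcome, sharing one
#' propensity derivation and one matched sample across the PS methods. A
#' method that fails is recorded with its error message rather than
#' aborting the rest.
#'
#' @param cohort A `cohort`.
#' @param outcome Outcome column name.
#' @param methods Subset of `"unadjusted"`, `"logistic_gee"`,
#'   `"ps_quintile"`, `"ps_iptw"`, `"ps_matched"`, `"iv"`.
#' @param seed Seed for the matching order (and any bootstrap).
#' @param ps Optional precomputed [derive_propensity()] result.
#' @param pairs Optional precomputed [greedy_match()] result.
#' @param ci CI method for model-based estimates.
#' @return List of [risk_estimate()] objects (failed methods appear as a
#'   list with `method`, `outcome`, `failed = TRUE`, `error`).
#' @export
estimate_cohort <- function(cohort, outcome, methods = ALL_METHODS,
                            seed = 1L, ps = NULL, pairs = NULL,
                            ci = "delta") {
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  rows <- cohort$rows
  need_ps <- any(c("ps_quintile", "ps_iptw", "ps_matched") %in% methods)
  if (need_ps && is.null(ps)) ps <- derive_propensity(rows)
  if ("ps_matched" %in% methods && is.null(pairs))
    pairs <- greedy_match(ps$scores, rows$exposed, seed = seed,
                          ids = rows$subject_id)
  run <- function(method) {
    tryCatch(switch(method,
      unadjusted = unadjusted_risk_difference(rows, outcome),
      logistic_gee = adjusted_arr(rows, outcome, ci = ci)$estimate,
      ps_quintile = quintile_stratified_rates(rows, ps$scores,
                                              outcome)$estimate,
      ps_iptw = iptw_arr(rows, ps$scores, outcome, ci = ci)$estimate,
      ps_matched = matched_arr(pairs, rows, outcome)$estimate,
      iv = fit_iv(rows, outcome, ci = ci, boot_seed = seed)$estimate
    ), error = function(e)
      list(method = method, outcome = outcome, failed = TRUE,
           error = conditionMessage(e)))
  }
  stats::setNames(lapply(methods, run), methods)
}

#' Flatten risk estimates into a comparison table
#'
#' One row per method x outcome x cohort, in the layout of a
#' method-comparison table: averaged predicted probability per arm with 95%
#' CI and the absolute risk reduction with 95% CI. Failed methods keep their
#' row, marked with the failure reason.
#'
#' @param estimates Named list of [risk_estimate()] (or failure records),
#'   possibly nested by cohort/outcome.
#' @param cohort_label Label recycled across rows.
#' @return data.frame.
#' @export
comparison_table <- function(estimates, cohort_label = NA_character_) {
  flat <- list()
  add <- function(e) flat[[length(flat) + 1]] <<- e
  walk <- function(x) {
    if (inherits(x, "risk_estimate") ||
        (is.list(x) && isTRUE(x$failed))) add(x)
    else if (is.list(x)) lapply(x, walk)
  }
  walk(estimates)
  do.call(rbind, lapply(flat, function(e) {
    if (isTRUE(e$failed)) {
      data.frame(cohort = cohort_label, method = e$method,
                 outcome = e$outcome, p_unexposed = NA_real_,
                 p_unexposed_lo = NA_real_, p_unexposed_hi = NA_real_,
                 p_exposed = NA_real_, p_exposed_lo = NA_real_,
                 p_exposed_hi = NA_real_, arr = NA_real_,
                 arr_lo = NA_real_, arr_hi = NA_real_, n = NA_integer_,
                 note = paste("FAILED:", e$error),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cohort = cohort_label, method = e$method,
                 outcome = e$outcome,
                 p_unexposed = e$p_unexposed,
                 p_unexposed_lo = e$ci_unexposed[1],
                 p_unexposed_hi = e$ci_unexposed[2],
                 p_exposed = e$p_exposed,
                 p_exposed_lo = e$ci_exposed[1],
                 p_exposed_hi = e$ci_exposed[2],
                 arr = e$arr, arr_lo = e$ci_arr[1], arr_hi = e$ci_arr[2],
                 n = e$n,
                 note = if (is.null(e$note)) "" else e$note,
                 stringsAsFactors = FALSE)
    }
  }))
}

format_comparison <- function(tab) {
  hdr <- sprintf("%-12s %-22s %-12s %-22s %-22s %-22s",
                 "cohort", "method", "outcome",
                 "p_unexposed (95% CI)", "p_exposed (95% CI)",
                 "ARR (95% CI)")
  fmt <- function(v, lo, hi) {
    ifelse(is.na(v), "--", sprintf("%.2f (%.2f, %.2f)", v, lo, hi))
  }
  body <- sprintf("%-12s %-22s %-12s %-22s %-22s %-22s",
                  tab$cohort, tab$method, tab$outcome,
                  fmt(tab$p_unexposed, tab$p_unexposed_lo,
                      tab$p_unexposed_hi),
                  fmt(tab$p_exposed, tab$p_exposed_lo, tab$p_exposed_hi),
                  fmt(tab$arr, tab$arr_lo, tab$arr_hi))
  c(hdr, body)
}

#' Unadjusted table row from printed cell counts
#'
#' Worked-example arithmetic: arm proportions (percent) with Wald intervals
#' and their difference, from the four cells of a 2x2 exposure-by-outcome
#' table. For instance 84 events among 10,000 exposed against 136 events
#' among 10,000 unexposed gives a difference of -0.52 percentage points.
#'
#' @param events_exposed,n_exposed,events_unexposed,n_unexposed Cell counts.
#' @param outcome Label.
#' @param level Confidence level.
#' @return A [risk_estimate()], method `"unadjusted_counts"`.
#' @export
table1_from_counts <- function(events_exposed, n_exposed, events_unexposed,
                               n_unexposed, outcome = "crc_incident",
                               level = 0.95) {
  if (n_exposed <= 0 || n_unexposed <= 0)
    stop("zero denominator in unadjusted table")
  p1 <- events_exposed / n_exposed
  p0 <- events_unexposed / n_unexposed
  se1 <- sqrt(p1 * (1 - p1) / n_exposed)
  se0 <- sqrt(p0 * (1 - p0) / n_unexposed)
  risk_estimate("unadjusted_counts", outcome,
                p_unexposed = 100 * p0, p_exposed = 100 * p1,
                arr = 100 * (p1 - p0),
                ci_unexposed = 100 * wald_ci(p0, se0, level),
                ci_exposed = 100 * wald_ci(p1, se1, level),
                ci_arr = 100 * wald_ci(p1 - p0, sqrt(se1^2 + se0^2), level),
                n = n_exposed + n_unexposed)
}

#' Run the full simulation-and-comparison pipeline
#'
#' Generates a registry, builds the unselected and restricted cohorts, runs
#' the unadjusted and covariate-adjusted estimators on both cohorts and the
#' propensity-score and instrumental-variable estimators on the restricted
#' cohort, and (optionally) writes all artifacts — registry CSVs, cohort
#' CSV/JSON, the comparison table as CSV/JSON/text, and a run manifest —
#' under `out_dir`. Outputs are deterministic given `(config, seed)`.
#'
#' @param config A [registry_config()].
#' @param seed Seed overriding `config$seed`; drives every random stage.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param methods Methods for the restricted cohort (the unselected cohort
#'   gets the subset of `unadjusted`/`logistic_gee` that is requested).
#' @param outcomes Outcome columns to analyse.
#' @return Object of class `sb_pipeline`: list with `table` (data.frame),
#'   `estimates`, `cohorts` (counts), `balance`, and `manifest`.
#' @export
run_pipeline <- function(config = registry_config(), seed = config$seed,
                         out_dir = NULL,
                         methods = ALL_METHODS,
                         outcomes = c("crc_incident", "crc_death")) {
  config$seed <- as.integer(seed)
  registry <- generate_registry(config)
  unsel <- build_unselected_cohort(registry)
  restr <- build_restricted_cohort(registry)

  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  m_unsel <- intersect(methods, c("unadjusted", "logistic_gee"))
  est_unsel <- if (length(m_unsel))
    lapply(stats::setNames(outcomes, outcomes), function(oc)
      estimate_cohort(unsel, oc, m_unsel, seed = seed)) else list()

  rows <- restr$rows
  need_ps <- any(c("ps_quintile", "ps_iptw", "ps_matched") %in% methods)
  ps <- if (need_ps) derive_propensity(rows) else NULL
  pairs <- if ("ps_matched" %in% methods)
    greedy_match(ps$scores, rows$exposed, seed = seed,
                 ids = rows$subject_id) else NULL
  est_restr <- lapply(stats::setNames(outcomes, outcomes), function(oc)
    estimate_cohort(restr, oc, methods, seed = seed, ps = ps,
                    pairs = pairs))
  balance <- if (!is.null(pairs)) balance_table(rows, pairs) else NULL

  tab <- rbind(
    if (length(est_unsel)) comparison_table(est_unsel, "unselected"),
    comparison_table(est_restr, "restricted")
  )
  manifest <- list(
    seed = as.integer(seed),
    methods = methods,
    outcomes = outcomes,
    n_pcps = nrow(registry$pcps),
    n_subjects = nrow(registry$subjects),
    cohorts = list(unselected = unsel$counts, restricted = restr$counts),
    package_version = as.character(utils::packageVersion("screenbias"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_registry(registry, file.path(out_dir, "registry"))
    write_cohort(unsel, file.path(out_dir, "cohort_unselected.csv"))
    write_cohort(restr, file.path(out_dir, "cohort_restricted.csv"))
    utils::write.csv(tab, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(tab, file.path(out_dir, "estimates.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    writeLines(format_comparison(tab), file.path(out_dir, "estimates.txt"))
    if (!is.null(balance))
      utils::write.csv(balance, file.path(out_dir, "balance.csv"),
                       row.names = FALSE, na = "")
    manifest$config_md5 <- unname(tools::md5sum(
      file.path(out_dir, "registry", "config.json")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(table = tab,
                 estimates = list(unselected = est_unsel,
                                  restricted = est_restr),
                 cohorts = list(unselected = unsel$counts,
                                restricted = restr$counts),
                 balance = balance,
                 manifest = manifest),
            class = "sb_pipeline")
}

#' @export
print.sb_pipeline <- function(x, ...) {
  writeLines(format_comparison(x$table))
  invisible(x)
}
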