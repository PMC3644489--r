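# Predictors of the propensity model: probability of receiving colonoscopy
# given measured baseline covariates.
PS_PREDICTORS <- c("age_group", "sex", "income_quintile", "comorbidity",
                   "rural")

#' Derive propensity scores
#'
#' Fits the logistic model of exposure on age group, sex, income quintile,
#' comorbidity and rural residence and returns each subject's fitted
#' probability of receiving colonoscopy, clipped to \[1e-6, 1-1e-6\], in the
#' input row order. The derivation model's c-statistic records its
#' discrimination.
#'
#' @param rows Analysis rows.
#' @param cluster Cluster-id column for the derivation fit.
#' @return Object of class `propensity_result`: list with `scores` and
#'   `fit`.
#' @export
derive_propensity <- function(rows, cluster = "pcp_id") {
  fit <- fit_logistic(rows, "exposed", PS_PREDICTORS, cluster = cluster)
  scores <- pmin(pmax(predict(fit, rows), 1e-6), 1 - 1e-6)
  structure(list(scores = scores, fit = fit), class = "propensity_result")
}

#' @export
print.propensity_result <- function(x, ...) {
  cat(sprintf("Propensity scores: n = %d, range [%.4f, %.4f], c-statistic %.3f\n",
              length(x$scores), min(x$scores), max(x$scores),
              x$fit$c_statistic))
  invisible(x)
}

#' Propensity-quintile stratified event rates
#'
#' Splits subjects into five equal-size strata by propensity-score rank
#' (ties resolved by rank order, so stratum sizes agree to within one), and
#' tabulates per-stratum, per-arm event rates. The pooled risk difference is
#' the stratum-size-weighted mean of stratum differences; strata missing an
#' arm are excluded from pooling and noted.
#'
#' @param rows Analysis rows.
#' @param scores Propensity scores aligned with `rows`.
#' @param outcome Outcome column name.
#' @param n_strata Number of strata (default 5).
#' @param level Confidence level for the pooled estimate.
#' @return List with `table` (per-stratum rates) and `estimate` (a
#'   [risk_estimate()], method `"ps_quintile"`).
#' @export
quintile_stratified_rates <- function(rows, scores, outcome, n_strata = 5L,
                                      level = 0.95) {
  n <- nrow(rows)
  if (n < n_strata) stop("need at least one subject per stratum")
  rk <- rank(scores, ties.method = "first")
  qid <- floor((rk - 1) * n_strata / n) + 1L
  y <- as.numeric(rows[[outcome]])
  e <- as.numeric(rows$exposed)
  tab <- do.call(rbind, lapply(seq_len(n_strata), function(s) {
    in_s <- qid == s
    n1 <- sum(in_s & e == 1); n0 <- sum(in_s & e == 0)
    p1 <- if (n1 > 0) mean(y[in_s & e == 1]) else NA_real_
    p0 <- if (n0 > 0) mean(y[in_s & e == 0]) else NA_real_
    data.frame(stratum = s, n = sum(in_s), n_exposed = n1,
               n_unexposed = n0, rate_exposed = 100 * p1,
               rate_unexposed = 100 * p0,
               arr = 100 * (p1 - p0))
  }))
  ok <- tab$n_exposed > 0 & tab$n_unexposed > 0
  if (!any(ok)) stop("no stratum contains both exposure arms")
  w <- tab$n[ok] / sum(tab$n[ok])
  p1s <- tab$rate_exposed[ok] / 100
  p0s <- tab$rate_unexposed[ok] / 100
  p1 <- sum(w * p1s); p0 <- sum(w * p0s)
  v <- sum(w^2 * (p1s * (1 - p1s) / tab$n_exposed[ok] +
                    p0s * (1 - p0s) / tab$n_unexposed[ok]))
  note <- if (all(ok)) "all strata pooled" else
    sprintf("strata excluded (single-armed): %s",
            paste(tab$stratum[!ok], collapse = ", "))
  v1 <- sum(w^2 * p1s * (1 - p1s) / tab$n_exposed[ok])
  v0 <- sum(w^2 * p0s * (1 - p0s) / tab$n_unexposed[ok])
  est <- risk_estimate("ps_quintile", outcome,
                       p_unexposed = 100 * p0, p_exposed = 100 * p1,
                       arr = 100 * (p1 - p0),
                       ci_unexposed = 100 * wald_ci(p0, sqrt(v0), level),
                       ci_exposed = 100 * wald_ci(p1, sqrt(v1), level),
                       ci_arr = 100 * wald_ci(p1 - p0, sqrt(v), level),
                       n = sum(tab$n[ok]), note = note)
  list(table = tab, estimate = est)
}

#' Inverse-probability-of-treatment weights
#'
#' Unstabilized weights: 1/PS for exposed subjects, 1/(1-PS) for unexposed.
#' The extreme-weight diagnostics (maximum and 99th percentile) are attached
#' as attributes.
#'
#' @param scores Propensity scores in (0, 1).
#' @param exposed 0/1 exposure flags.
#' @return Numeric weight per subject.
#' @export
iptw_weights <- function(scores, exposed) {
  if (any(scores <= 0 | scores >= 1)) stop("scores must lie in (0, 1)")
  w <- ifelse(exposed == 1, 1 / scores, 1 / (1 - scores))
  attr(w, "max_weight") <- max(w)
  attr(w, "q99_weight") <- unname(stats::quantile(w, 0.99))
  w
}

#' IPTW-weighted marginal risk difference
#'
#' Propensity-score-weighted logistic outcome model (weights enter the IRLS
#' working weights; the sandwich treats them as fixed), controlling for the
#' standard covariates, followed by marginal standardization over the
#' unweighted population.
#'
#' @param rows Analysis rows.
#' @param scores Propensity scores.
#' @param outcome Outcome column name.
#' @param covariates Covariate terms of the weighted outcome model.
#' @param cluster Cluster-id column.
#' @param ci CI method passed to [marginal_arr()].
#' @return List with `fit`, `weights` and `estimate` (method `"ps_iptw"`).
#' @export
iptw_arr <- function(rows, scores, outcome,
                     covariates = ANALYSIS_COVARIATES, cluster = "pcp_id",
                     ci = "delta") {
  w <- iptw_weights(scores, rows$exposed)
  fit <- fit_logistic(rows, outcome, c("exposed", covariates),
                      cluster = cluster, weights = as.numeric(w))
  est <- marginal_arr(fit, rows, "exposed", "ps_iptw", ci = ci,
                      weights = as.numeric(w))
  list(fit = fit, weights = w, estimate = est)
}

#' Greedy digit-based propensity matching
#'
#' 1:1 matching without replacement. Exposed subjects are matched to unique
#' unexposed subjects at 5 decimal places of the propensity score, then the
#' still-unmatched at 4, and so on down to 1. Within a pass, exposed
#' subjects are processed in a seeded-random order derived from sorted
#' subject ids (so permuting input row order changes nothing), and each is
#' matched to the nearest available control agreeing at that precision
#' (raw-score distance, ties to the smaller id). Unmatched treated subjects
#' are allowed and counted.
#'
#' @param scores Propensity scores.
#' @param exposed 0/1 exposure flags.
#' @param seed Seed for the processing order.
#' @param ids Stable subject identifiers (default positional).
#' @param digits Precision schedule (default `5:1`).
#' @param caliper Optional maximum raw-score distance for an acceptable
#'   pair.
#' @return Object of class `matched_sample`: data.frame with `treated_id`,
#'   `control_id`, `distance`, and attributes `n_unmatched_treated`,
#'   `n_treated`.
#' @export
greedy_match <- function(scores, exposed, seed = 1L, ids = NULL,
                         digits = 5:1, caliper = NULL) {
  n <- length(scores)
  if (is.null(ids)) ids <- seq_len(n)
  stopifnot(length(exposed) == n, length(ids) == n, !anyDuplicated(ids))
  t_pos <- which(exposed == 1)
  c_pos <- which(exposed == 0)
  if (length(t_pos) == 0 || length(c_pos) == 0)
    stop("both exposure arms must be nonempty")

  # order-independent seeded processing order for treated subjects
  t_pos <- t_pos[order(ids[t_pos])]
  set.seed(stage_seed(seed, "match"))
  t_pos <- t_pos[sample.int(length(t_pos))]
  # controls sorted by (score, id) for nearest-neighbour scans
  c_pos <- c_pos[order(scores[c_pos], ids[c_pos])]
  c_score <- scores[c_pos]
  c_used <- rep(FALSE, length(c_pos))

  t_matched <- rep(NA_integer_, length(t_pos))  # index into c_pos

  for (d in digits) {
    open_t <- which(is.na(t_matched))
    if (length(open_t) == 0) break
    avail_c <- which(!c_used)
    if (length(avail_c) == 0) break
    key_t <- as.integer(round(round(scores[t_pos[open_t]], d) * 10^d))
    key_c <- as.integer(round(round(c_score[avail_c], d) * 10^d))
    buckets <- split(avail_c, key_c)
    for (j in seq_along(open_t)) {
      bucket <- buckets[[as.character(key_t[j])]]
      if (is.null(bucket)) next
      ti <- t_pos[open_t[j]]
      sc <- scores[ti]
      # nearest available control within the bucket by raw score
      k <- findInterval(sc, c_score[bucket])
      lo <- k; hi <- k + 1L
      best <- NA_integer_; best_d <- Inf
      while (lo >= 1 || hi <= length(bucket)) {
        cand <- c(if (lo >= 1) bucket[lo], if (hi <= length(bucket)) bucket[hi])
        cand <- cand[!c_used[cand]]
        if (length(cand)) {
          dd <- abs(c_score[cand] - sc)
          # tie-break: smaller control id
          ord <- order(dd, ids[c_pos[cand]])
          if (dd[ord[1]] < best_d) {
            best <- cand[ord[1]]; best_d <- dd[ord[1]]
          }
        }
        # stop expanding once flanking distances exceed current best
        lo_d <- if (lo >= 1) abs(c_score[bucket[lo]] - sc) else Inf
        hi_d <- if (hi <= length(bucket)) abs(c_score[bucket[hi]] - sc) else Inf
        if (!is.na(best) && best_d <= min(lo_d, hi_d)) break
        lo <- lo - 1L; hi <- hi + 1L
      }
      if (!is.na(best) && (is.null(caliper) || best_d <= caliper)) {
        t_matched[open_t[j]] <- best
        c_used[best] <- TRUE
      }
    }
  }

  got <- !is.na(t_matched)
  out <- data.frame(
    treated_id = ids[t_pos[got]],
    control_id = ids[c_pos[t_matched[got]]],
    distance = abs(scores[t_pos[got]] - c_score[t_matched[got]])
  )
  out <- out[order(out$treated_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmatched_treated") <- sum(!got)
  attr(out, "n_treated") <- length(t_pos)
  class(out) <- c("matched_sample", "data.frame")
  out
}

#' Standardized difference between two proportions
#'
#' `100 * |p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`, the scale-free
#' imbalance measure; values above 10% conventionally flag meaningful
#' imbalance. Degenerate equal proportions of 0 or 1 return 0 by convention.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @return Absolute standardized difference in percent.
#' @export
standardized_difference <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  ifelse(denom == 0, 0, 100 * abs(p1 - p2) / denom)
}

#' McNemar test for matched-pair binary outcomes
#'
#' Chi-square form `(b - c)^2 / (b + c)` on the discordant counts (b:
#' treated-only events, c: control-only events), 1 df. When fewer than 25
#' discordant pairs, an exact binomial p-value is also computed and used as
#' the reported p. Zero discordant pairs give p = 1 by convention.
#'
#' @param treated_outcome,control_outcome 0/1 outcomes, pair-aligned.
#' @return List with `b`, `c`, `statistic`, `p_chisq`, `p_exact`,
#'   `p_value`, `method`.
#' @export
mcnemar_pairs <- function(treated_outcome, control_outcome) {
  stopifnot(length(treated_outcome) == length(control_outcome))
  b <- sum(treated_outcome == 1 & control_outcome == 0)
  cc <- sum(treated_outcome == 0 & control_outcome == 1)
  if (b + cc == 0) {
    return(list(b = b, c = cc, statistic = 0, p_chisq = 1, p_exact = 1,
                p_value = 1, method = "no discordant pairs (p = 1)"))
  }
  stat <- (b - cc)^2 / (b + cc)
  p_chisq <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p_exact <- if (b + cc < 25)
    stats::binom.test(b, b + cc, 0.5)$p.value else NA_real_
  use_exact <- b + cc < 25
  list(b = b, c = cc, statistic = stat, p_chisq = p_chisq,
       p_exact = p_exact,
       p_value = if (use_exact) p_exact else p_chisq,
       method = if (use_exact) "exact binomial" else "chi-square")
}

#' Covariate balance table
#'
#' Per covariate level: arm proportions, chi-square p-value (per covariate)
#' and absolute standardized difference, before matching (all rows) and,
#' when a matched sample is supplied, after matching (matched treated vs
#' matched controls). Standardized difference is the balance criterion; the
#' p-values are descriptive only.
#'
#' @param rows Analysis rows.
#' @param pairs Optional [greedy_match()] result.
#' @return data.frame, one line per covariate level.
#' @export
balance_table <- function(rows, pairs = NULL) {
  covs <- list(
    sex = list(var = "sex", levels = "female"),
    age_group = list(var = "age_group", levels = AGE_LEVELS),
    income_quintile = list(var = "income_quintile", levels = 1:5),
    rural = list(var = "rural", levels = TRUE),
    comorbidity = list(var = "comorbidity", levels = COMORBIDITY_LEVELS)
  )
  arm_props <- function(dat1, dat0) {
    do.call(rbind, lapply(names(covs), function(nm) {
      v <- covs[[nm]]$var
      lv <- covs[[nm]]$levels
      x1 <- dat1[[v]]; x0 <- dat0[[v]]
      pv <- tryCatch(stats::chisq.test(
        table(factor(c(rep(1, length(x1)), rep(0, length(x0))),
                     levels = 0:1),
              factor(c(as.character(x1), as.character(x0)))))$p.value,
        error = function(e) NA_real_, warning = function(w) {
          suppressWarnings(stats::chisq.test(
            table(factor(c(rep(1, length(x1)), rep(0, length(x0))),
                         levels = 0:1),
                  factor(c(as.character(x1), as.character(x0)))))$p.value)
        })
      do.call(rbind, lapply(lv, function(l) {
        p1 <- mean(x1 == l); p0 <- mean(x0 == l)
        data.frame(covariate = nm, level = as.character(l),
                   p_exposed = p1, p_unexposed = p0,
                   std_diff = standardized_difference(p1, p0),
                   chisq_p = pv, stringsAsFactors = FALSE)
      }))
    }))
  }
  before <- arm_props(rows[rows$exposed == 1, ], rows[rows$exposed == 0, ])
  names(before)[3:6] <- paste0(names(before)[3:6], "_before")
  if (is.null(pairs)) return(before)
  rt <- rows[match(pairs$treated_id, rows$subject_id), ]
  rc <- rows[match(pairs$control_id, rows$subject_id), ]
  after <- arm_props(rt, rc)
  before$p_exposed_after <- after$p_exposed
  before$p_unexposed_after <- after$p_unexposed
  before$std_diff_after <- after$std_diff
  before$chisq_p_after <- after$chisq_p
  before
}

#' Kaplan-Meier cumulative event curves per arm
#'
#' Product-limit cumulative event probability on a yearly grid with at-risk
#' counts, per exposure arm, censoring at other-cause death or the horizon.
#'
#' @param time Event/censoring time in years from follow-up start (>= 1).
#' @param event 0/1 event indicator at `time`.
#' @param arm Arm labels.
#' @param horizon Last year of the grid.
#' @return data.frame with `year`, `arm`, `cum_inc`, `n_risk`.
#' @export
km_cumulative <- function(time, event, arm, horizon = max(time)) {
  sf <- survival::survfit(survival::Surv(time, event) ~ arm)
  sm <- summary(sf, times = seq_len(horizon), extend = TRUE)
  armv <- if (is.null(sm$strata)) rep(unique(arm)[1], length(sm$time))
  else sub("^arm=", "", as.character(sm$strata))
  data.frame(year = sm$time, arm = armv, cum_inc = 1 - sm$surv,
             n_risk = sm$n.risk, row.names = NULL)
}

#' Kaplan-Meier curves for a cohort outcome
#'
#' Builds per-subject event/censoring times from the cohort's calendar
#' (follow-up starts in year 6 for the restricted design, year 1 otherwise)
#' and calls [km_cumulative()]. Incidence events are CRC diagnoses;
#' mortality events are CRC deaths; censoring occurs at other-cause death or
#' the outcome horizon.
#'
#' @param cohort A `cohort`.
#' @param outcome `"crc_incident"` or `"crc_death"`.
#' @param rows Optional subset of rows (default all cohort rows).
#' @return data.frame from [km_cumulative()].
#' @export
km_curves <- function(cohort, outcome = c("crc_incident", "crc_death"),
                      rows = cohort$rows) {
  outcome <- match.arg(outcome)
  start <- if (cohort$spec$cohort_kind == "restricted")
    max(cohort$spec$exposure_window) + 1L else 1L
  end <- if (outcome == "crc_incident") cohort$spec$incidence_end_year
  else cohort$spec$mortality_end_year
  ev_year <- if (outcome == "crc_incident") rows$crc_dx_year
  else rows$crc_death_year
  event <- as.numeric(rows[[outcome]])
  cens_year <- pmin(ifelse(is.na(rows$other_death_year), end,
                           rows$other_death_year), end)
  yr <- ifelse(event == 1, ev_year, cens_year)
  time <- pmax(yr - start + 1L, 1L)
  km_cumulative(time, event, ifelse(rows$exposed == 1, "colonoscopy",
                                    "no_colonoscopy"),
                horizon = end - start + 1L)
}

#' Matched-cohort risk difference and subgroup table
#'
#' Event proportions among matched treated and matched control subjects,
#' their difference with the paired-proportion (McNemar-style) variance, the
#' McNemar test, and subgroup splits by sex and age group and by income
#' quintile (grouping pairs by the treated member's covariates). Subgroups
#' with no pairs are suppressed.
#'
#' @param pairs A [greedy_match()] result.
#' @param rows Analysis rows containing both pair members.
#' @param outcome Outcome column name.
#' @param level Confidence level.
#' @return List with `estimate` (method `"ps_matched"`), `mcnemar`,
#'   `subgroups`.
#' @export
matched_arr <- function(pairs, rows, outcome, level = 0.95) {
  if (nrow(pairs) == 0) stop("no matched pairs")
  it <- match(pairs$treated_id, rows$subject_id)
  ic <- match(pairs$control_id, rows$subject_id)
  if (anyNA(it) || anyNA(ic)) stop("pair members missing from rows")
  yt <- as.numeric(rows[[outcome]][it])
  yc <- as.numeric(rows[[outcome]][ic])
  n <- nrow(pairs)
  p1 <- mean(yt); p0 <- mean(yc)
  b <- sum(yt == 1 & yc == 0); cc <- sum(yt == 0 & yc == 1)
  dvar <- (b + cc - (b - cc)^2 / n) / n^2
  mc <- mcnemar_pairs(yt, yc)
  est <- risk_estimate(
    "ps_matched", outcome,
    p_unexposed = 100 * p0, p_exposed = 100 * p1, arr = 100 * (p1 - p0),
    ci_unexposed = 100 * wald_ci(p0, sqrt(p0 * (1 - p0) / n), level),
    ci_exposed = 100 * wald_ci(p1, sqrt(p1 * (1 - p1) / n), level),
    ci_arr = 100 * wald_ci(p1 - p0, sqrt(dvar), level),
    n = n, note = sprintf("McNemar p = %.3g (%s)", mc$p_value, mc$method))

  grp_tab <- function(key) {
    ok <- !is.na(key)
    do.call(rbind, lapply(split(seq_len(n)[ok], key[ok]), function(ix) {
      data.frame(group = key[ix[1]], n_pairs = length(ix),
                 rate_exposed = 100 * mean(yt[ix]),
                 rate_unexposed = 100 * mean(yc[ix]),
                 difference = 100 * (mean(yt[ix]) - mean(yc[ix])),
                 stringsAsFactors = FALSE)
    }))
  }
  sex_age <- paste(rows$sex[it], rows$age_group[it])
  income <- paste0("Q", rows$income_quintile[it])
  subgroups <- rbind(
    cbind(split_by = "sex_age", grp_tab(sex_age)),
    cbind(split_by = "income_quintile", grp_tab(income))
  )
  rownames(subgroups) <- NULL
  list(estimate = est, mcnemar = mc, subgroups = subgroups)
}

#' Signed-rank comparison of matched event times
#'
#' An approximate Wilcoxon signed-rank test of event-time homogeneity
#' between matched arms. Only pairs in which *both* members experience the
#' event contribute; all other (censored) pairs are excluded. The retained
#' event years are pooled and midranked, and the signed-rank test is applied
#' to the within-pair rank differences using the normal approximation.
#'
#' This is an approximation, not a censoring-aware survival test: excluding
#' censored pairs conditions on the event in both arms, so the result
#' describes relative timing among double-event pairs only. For an absolute
#' comparison of cumulative incidence use [km_curves()] or [matched_arr()].
#'
#' @param pairs A [greedy_match()] result.
#' @param rows Analysis rows containing both pair members.
#' @param outcome `"crc_incident"` or `"crc_death"`.
#' @return List with `statistic` (signed-rank V), `p_value` (normal
#'   approximation; 1 when every retained difference is zero), `n_pairs_used`
#'   and `n_pairs_excluded`.
#' @export
wilcoxon_km_pairs <- function(pairs, rows,
                              outcome = c("crc_incident", "crc_death")) {
  outcome <- match.arg(outcome)
  if (nrow(pairs) == 0) stop("no matched pairs")
  it <- match(pairs$treated_id, rows$subject_id)
  ic <- match(pairs$control_id, rows$subject_id)
  if (anyNA(it) || anyNA(ic)) stop("pair members missing from rows")
  yearcol <- if (outcome == "crc_incident") "crc_dx_year" else
    "crc_death_year"
  both <- rows[[outcome]][it] == 1 & rows[[outcome]][ic] == 1
  if (!any(both))
    stop("no pairs with events in both arms")
  tt <- rows[[yearcol]][it[both]]
  tc <- rows[[yearcol]][ic[both]]
  rk <- rank(c(tt, tc))
  d <- rk[seq_along(tt)] - rk[length(tt) + seq_along(tc)]
  if (all(d == 0)) {
    res <- list(statistic = 0, p_value = 1)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = FALSE))
    res <- list(statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  c(res, list(n_pairs_used = sum(both),
              n_pairs_excluded = sum(!both)))
}
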