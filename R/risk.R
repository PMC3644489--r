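#' Risk-estimate container
#'
#' Per-method result: predicted outcome probability (percent) in each
#' exposure arm and the absolute risk reduction (ARR, percentage points),
#' each with a 95% confidence interval. Sign convention: ARR = exposed minus
#' unexposed, so a protective exposure gives a negative ARR.
#'
#' @param method Method label.
#' @param outcome Outcome name.
#' @param p_unexposed,p_exposed Arm probabilities in percent.
#' @param ci_unexposed,ci_exposed,ci_arr Length-2 intervals (percent).
#' @param arr Absolute risk reduction in percentage points.
#' @param n Number of subjects (or pairs) used.
#' @param note Optional character note (CI method, exclusions, ...).
#' @return Object of class `risk_estimate`.
#' @export
risk_estimate <- function(method, outcome, p_unexposed, p_exposed, arr,
                          ci_unexposed, ci_exposed, ci_arr, n, note = NULL) {
  stopifnot(abs(arr - (p_exposed - p_unexposed)) < 1e-10,
            ci_arr[1] <= arr + 1e-10, arr <= ci_arr[2] + 1e-10)
  structure(list(method = method, outcome = outcome,
                 p_unexposed = p_unexposed, ci_unexposed = ci_unexposed,
                 p_exposed = p_exposed, ci_exposed = ci_exposed,
                 arr = arr, ci_arr = ci_arr, n = n, note = note),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.risk_estimate <- function(x, ...) {
  sprintf("%-22s %-12s %5.2f (%.2f, %.2f)  %5.2f (%.2f, %.2f)  %6.2f (%.2f, %.2f)",
          x$method, x$outcome,
          x$p_unexposed, x$ci_unexposed[1], x$ci_unexposed[2],
          x$p_exposed, x$ci_exposed[1], x$ci_exposed[2],
          x$arr, x$ci_arr[1], x$ci_arr[2])
}

wald_ci <- function(est, se, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  c(est - zq * se, est + zq * se)
}

#' Unadjusted risk difference between exposure arms
#'
#' Raw event proportions per arm (percent) with Wald confidence intervals,
#' and their difference with the standard unpooled-variance normal interval.
#'
#' @param rows Analysis rows with `exposed` and the outcome column.
#' @param outcome Outcome column name.
#' @param level Confidence level.
#' @return A [risk_estimate()], method `"unadjusted"`.
#' @export
unadjusted_risk_difference <- function(rows, outcome, level = 0.95) {
  y <- as.numeric(rows[[outcome]])
  e <- as.numeric(rows$exposed)
  n1 <- sum(e == 1); n0 <- sum(e == 0)
  if (n1 == 0 || n0 == 0) stop("both exposure arms must be nonempty")
  p1 <- mean(y[e == 1]); p0 <- mean(y[e == 0])
  se1 <- sqrt(p1 * (1 - p1) / n1)
  se0 <- sqrt(p0 * (1 - p0) / n0)
  sed <- sqrt(se1^2 + se0^2)
  risk_estimate("unadjusted", outcome,
                p_unexposed = 100 * p0, p_exposed = 100 * p1,
                arr = 100 * (p1 - p0),
                ci_unexposed = 100 * wald_ci(p0, se0, level),
                ci_exposed = 100 * wald_ci(p1, se1, level),
                ci_arr = 100 * wald_ci(p1 - p0, sed, level),
                n = n1 + n0)
}

#' Marginal standardization (g-computation) of a logistic fit
#'
#' Predicts every subject's outcome probability with the exposure term set
#' to 1, then to 0, averages each over the population, and reports the
#' averaged probabilities and their difference. Confidence intervals are by
#' the delta method on the averaged predictions using the cluster-robust
#' covariance, or by a cluster-resampled percentile bootstrap.
#'
#' @param fit A converged [fit_logistic()] containing `exposure` in its
#'   terms.
#' @param rows The analysis rows the marginal means are taken over.
#' @param exposure Name of the exposure term (default `"exposed"`; the
#'   instrumental-variable second stage passes its predicted-probability
#'   term instead).
#' @param method Label for the resulting estimate.
#' @param ci `"delta"` (default) or `"bootstrap"` (cluster-resampled
#'   percentile, `boot_reps` replicates, seeded).
#' @param level Confidence level.
#' @param boot_reps,boot_seed Bootstrap controls.
#' @param weights Optional weights to re-use when refitting in the
#'   bootstrap.
#' @return A [risk_estimate()].
#' @export
marginal_arr <- function(fit, rows, exposure = "exposed",
                         method = "logistic_gee",
                         ci = c("delta", "bootstrap"), level = 0.95,
                         boot_reps = 200L, boot_seed = 1L, weights = NULL) {
  ci <- match.arg(ci)
  if (!inherits(fit, "sb_logit")) stop("fit must be an sb_logit")
  if (!fit$converged) stop("fit did not converge")
  if (!exposure %in% fit$terms)
    stop("exposure term '", exposure, "' not in the fitted model")
  n <- nrow(rows)
  rows1 <- rows; rows1[[exposure]] <- 1
  rows0 <- rows; rows0[[exposure]] <- 0
  X1 <- build_design(rows1, fit$terms)
  X0 <- build_design(rows0, fit$terms)
  mu1 <- stats::plogis(drop(X1 %*% fit$coefficients))
  mu0 <- stats::plogis(drop(X0 %*% fit$coefficients))
  p1 <- mean(mu1); p0 <- mean(mu0)
  arr <- p1 - p0

  if (ci == "delta") {
    g1 <- drop(crossprod(X1, mu1 * (1 - mu1))) / n
    g0 <- drop(crossprod(X0, mu0 * (1 - mu0))) / n
    V <- fit$vcov_cluster
    se1 <- sqrt(drop(t(g1) %*% V %*% g1))
    se0 <- sqrt(drop(t(g0) %*% V %*% g0))
    gd <- g1 - g0
    sed <- sqrt(drop(t(gd) %*% V %*% gd))
    ci1 <- wald_ci(p1, se1, level); ci0 <- wald_ci(p0, se0, level)
    cid <- wald_ci(arr, sed, level)
    note <- "delta-method CI, cluster-robust covariance"
  } else {
    bs <- cluster_bootstrap(rows, fit$outcome, fit$terms, exposure,
                            fit$cluster, boot_reps, boot_seed, weights)
    alpha <- (1 - level) / 2
    qs <- function(v) unname(stats::quantile(v, c(alpha, 1 - alpha),
                                             na.rm = TRUE))
    ci1 <- qs(bs$p1); ci0 <- qs(bs$p0); cid <- qs(bs$arr)
    # widen degenerate percentile bounds to include the point estimate
    ci1 <- range(ci1, p1); ci0 <- range(ci0, p0); cid <- range(cid, arr)
    note <- sprintf("cluster percentile bootstrap CI (%d reps)", boot_reps)
  }
  risk_estimate(method, fit$outcome,
                p_unexposed = 100 * p0, p_exposed = 100 * p1,
                arr = 100 * arr,
                ci_unexposed = 100 * ci0, ci_exposed = 100 * ci1,
                ci_arr = 100 * cid, n = n, note = note)
}

cluster_bootstrap <- function(rows, outcome, terms, exposure, cluster,
                              reps, seed, weights = NULL) {
  set.seed(stage_seed(seed, "boot"))
  ids <- if (is.null(cluster)) seq_len(nrow(rows)) else rows[[cluster]]
  uc <- unique(ids)
  idx_by <- split(seq_len(nrow(rows)), ids)
  p1 <- p0 <- arr <- rep(NA_real_, reps)
  for (b in seq_len(reps)) {
    take <- sample(uc, length(uc), replace = TRUE)
    idx <- unlist(idx_by[as.character(take)], use.names = FALSE)
    rb <- rows[idx, , drop = FALSE]
    wb <- if (is.null(weights)) NULL else weights[idx]
    est <- tryCatch({
      fb <- fit_logistic(rb, outcome, terms, cluster = cluster,
                         weights = wb)
      r1 <- rb; r1[[exposure]] <- 1
      r0 <- rb; r0[[exposure]] <- 0
      m1 <- mean(predict(fb, r1)); m0 <- mean(predict(fb, r0))
      c(m1, m0)
    }, error = function(e) c(NA_real_, NA_real_))
    p1[b] <- est[1]; p0[b] <- est[2]; arr[b] <- est[1] - est[2]
  }
  list(p1 = p1, p0 = p0, arr = arr)
}

#' Covariate-adjusted marginal risk difference
#'
#' Convenience wrapper: fits the cluster-robust logistic model of the
#' outcome on exposure plus the standard covariate set (age group, sex,
#' income quintile, rural residence, comorbidity), then marginally
#' standardizes with [marginal_arr()].
#'
#' @inheritParams unadjusted_risk_difference
#' @param covariates Covariate terms (default the standard set).
#' @param cluster Cluster-id column.
#' @param ci CI method passed to [marginal_arr()].
#' @return List with `fit` (the `sb_logit`) and `estimate` (a
#'   [risk_estimate()], method `"logistic_gee"`).
#' @export
adjusted_arr <- function(rows, outcome, covariates = ANALYSIS_COVARIATES,
                         cluster = "pcp_id", ci = "delta") {
  fit <- fit_logistic(rows, outcome, c("exposed", covariates),
                      cluster = cluster)
  list(fit = fit,
       estimate = marginal_arr(fit, rows, "exposed", "logistic_gee",
                               ci = ci))
}
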