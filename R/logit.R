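# Design-matrix construction with fixed reference levels: age 50-59, male,
# income quintile 1, urban, not hospitalized. Terms may be the categorical
# covariate names (expanded to dummies) or any numeric column of `rows`.
build_design <- function(rows, terms) {
  if (anyDuplicated(terms))
    stop("duplicated covariate in design: ",
         paste(terms[duplicated(terms)], collapse = ", "))
  n <- nrow(rows)
  cols <- list("(Intercept)" = rep(1, n))
  for (tm in terms) {
    if (tm == "age_group") {
      for (lv in AGE_LEVELS[-1])
        cols[[paste0("age_group", lv)]] <- as.numeric(rows$age_group == lv)
    } else if (tm == "sex") {
      cols[["sexfemale"]] <- as.numeric(rows$sex == "female")
    } else if (tm == "income_quintile") {
      for (q in 2:5)
        cols[[paste0("income_quintile", q)]] <-
          as.numeric(rows$income_quintile == q)
    } else if (tm == "comorbidity") {
      for (lv in COMORBIDITY_LEVELS[-1])
        cols[[paste0("comorbidity", lv)]] <-
          as.numeric(rows$comorbidity == lv)
    } else if (tm == "rural") {
      cols[["rural"]] <- as.numeric(rows$rural)
    } else {
      if (!tm %in% names(rows)) stop("unknown design term: ", tm)
      cols[[tm]] <- as.numeric(rows[[tm]])
    }
  }
  do.call(cbind, cols)
}

#' Maximum-likelihood logistic regression with cluster-robust variance
#'
#' Iteratively reweighted least-squares fit of a binary-outcome logistic
#' model, with both the model-based covariance and a cluster-robust sandwich
#' covariance that sums score contributions within clusters (physicians).
#' Point estimates coincide with an independence-working-correlation GEE;
#' the sandwich supplies the clustering adjustment. Optional observation
#' weights enter the working weights (as in inverse-probability-of-treatment
#' weighting) and are treated as fixed in the sandwich.
#'
#' @param rows data.frame of analysis rows.
#' @param outcome Name of the 0/1 outcome column.
#' @param terms Character vector of design terms (see Details in
#'   `build_design()`); categorical covariates expand with fixed reference
#'   levels age 50-59, male, income quintile 1, urban, not hospitalized.
#' @param cluster Name of the cluster-id column (default `"pcp_id"`), or
#'   `NULL` to treat observations as independent (sandwich reduces to the
#'   heteroskedasticity-robust form).
#' @param weights Optional nonnegative observation weights.
#' @param maxit,score_tol,dev_tol Convergence controls: stop when the
#'   maximum absolute score is below `score_tol` (1e-8) or the relative
#'   deviance change is below `dev_tol` (1e-10).
#' @return Object of class `sb_logit` with coefficients, `vcov_model`,
#'   `vcov_cluster`, convergence information, log-likelihood and the
#'   c-statistic of the fitted scores.
#' @export
fit_logistic <- function(rows, outcome, terms, cluster = "pcp_id",
                         weights = NULL, maxit = 50L,
                         score_tol = 1e-8, dev_tol = 1e-10) {
  y <- as.numeric(rows[[outcome]])
  if (is.null(y)) stop("unknown outcome column: ", outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("outcome has no events or no non-events")
  X <- build_design(rows, terms)
  n <- nrow(X); p <- ncol(X)
  wt <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(wt) != n || any(wt < 0) || any(!is.finite(wt)))
    stop("weights must be nonnegative, finite, one per row")

  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }

  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(sum(wt * y) / sum(wt), 1e-6), 1 - 1e-6))
  dev <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(wt * mu * (1 - mu), 1e-12)
    score <- drop(crossprod(X, wt * (y - mu)))
    A <- crossprod(X * sqrt(W))
    step <- solve(A, score)
    dev_new <- -2 * sum(wt * (y * stats::plogis(eta, log.p = TRUE) +
                                (1 - y) * stats::plogis(-eta, log.p = TRUE)))
    if (max(abs(score)) < score_tol ||
        abs(dev - dev_new) / (abs(dev_new) + 0.1) < dev_tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    # step-halving if the full Newton step would overshoot
    half <- 0L
    beta_try <- beta + step
    while (half < 10 && any(!is.finite(beta_try))) {
      step <- step / 2; beta_try <- beta + step; half <- half + 1L
    }
    beta <- beta_try
    dev <- dev_new
    if (max(abs(beta)) > 30)
      stop("separation detected: coefficient diverged beyond |30| for ",
           colnames(X)[which.max(abs(beta))])
    if (iter >= maxit) break
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  W <- pmax(wt * mu * (1 - mu), 1e-12)
  A <- crossprod(X * sqrt(W))
  vcov_model <- solve(A)
  dimnames(vcov_model) <- list(colnames(X), colnames(X))

  U <- X * (wt * (y - mu))
  if (is.null(cluster)) {
    cl <- seq_len(n)
  } else {
    cl <- rows[[cluster]]
    if (is.null(cl)) stop("unknown cluster column: ", cluster)
  }
  S <- rowsum(U, group = cl, reorder = FALSE)
  meat <- crossprod(S)
  vcov_cluster <- vcov_model %*% meat %*% vcov_model
  dimnames(vcov_cluster) <- dimnames(vcov_model)

  loglik <- sum(wt * (y * stats::plogis(eta, log.p = TRUE) +
                        (1 - y) * stats::plogis(-eta, log.p = TRUE)))
  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    vcov_model = vcov_model,
    vcov_cluster = vcov_cluster,
    n_obs = n,
    n_clusters = length(unique(cl)),
    converged = converged,
    iterations = iter,
    loglik = loglik,
    deviance = dev,
    c_statistic = c_statistic(mu, y),
    fitted = mu,
    outcome = outcome,
    terms = terms,
    cluster = cluster,
    weighted = !is.null(weights)
  ), class = "sb_logit")
}

#' Concordance (c) statistic
#'
#' Probability that a randomly chosen event subject receives a higher score
#' than a randomly chosen non-event subject, ties credited one half.
#' Computed by the rank (Mann-Whitney) identity in O(n log n); equal to
#' brute-force enumeration over all case-control pairs.
#'
#' @param scores Numeric scores (e.g. fitted probabilities).
#' @param outcomes 0/1 outcomes.
#' @return Scalar in \[0, 1\].
#' @export
c_statistic <- function(scores, outcomes) {
  y <- as.numeric(outcomes)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("c-statistic undefined: only one outcome class present")
  r <- rank(scores)  # midranks give ties half credit
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
coef.sb_logit <- function(object, ...) object$coefficients

#' @export
vcov.sb_logit <- function(object, type = c("cluster", "model"), ...) {
  switch(match.arg(type), cluster = object$vcov_cluster,
         model = object$vcov_model)
}

#' @export
logLik.sb_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
predict.sb_logit <- function(object, newdata,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- build_design(newdata, object$terms)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.sb_logit <- function(x, ...) {
  cat(sprintf("Logistic fit of '%s' (%d obs, %d clusters)%s\n", x$outcome,
              x$n_obs, x$n_clusters,
              if (x$weighted) ", weighted" else ""))
  cat(sprintf("  converged: %s in %d iterations; c-statistic %.3f\n",
              x$converged, x$iterations, x$c_statistic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.sb_logit <- function(object, type = c("cluster", "model"), ...) {
  type <- match.arg(type)
  se <- sqrt(diag(vcov(object, type)))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, se_type = type,
                 n_obs = object$n_obs, n_clusters = object$n_clusters,
                 c_statistic = object$c_statistic,
                 outcome = object$outcome),
            class = "summary.sb_logit")
}

#' @export
print.summary.sb_logit <- function(x, ...) {
  cat(sprintf("Logistic fit of '%s' (%s standard errors)\n", x$outcome,
              if (x$se_type == "cluster") "cluster-robust" else "model-based"))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("n = %d, clusters = %d, c-statistic = %.3f\n",
              x$n_obs, x$n_clusters, x$c_statistic))
  invisible(x)
}
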