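make_ps_rows <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = seq_len(n),
    pcp_id = rep(seq_len(max(n %/% 10, 1)), length.out = n),
    age_group = sample(AGE_LEVELS, n, TRUE),
    sex = sample(SEX_LEVELS, n, TRUE),
    income_quintile = sample(1:5, n, TRUE),
    rural = sample(c(TRUE, FALSE), n, TRUE),
    comorbidity = sample(COMORBIDITY_LEVELS, n, TRUE),
    exposed = rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE)
}

test_that("propensity derivation returns clipped fitted probabilities", {
  rows <- make_ps_rows(4000, seed = 2)
  ps <- derive_propensity(rows)
  expect_s3_class(ps, "propensity_result")
  expect_length(ps$scores, nrow(rows))
  expect_true(all(ps$scores > 0 & ps$scores < 1))
  expect_equal(ps$scores,
               pmin(pmax(predict(ps$fit, rows), 1e-6), 1 - 1e-6),
               tolerance = 1e-12)
  # exposure independent of covariates: essentially no discrimination
  # (in-sample fit of ~11 null coefficients inflates it only slightly)
  expect_lt(abs(ps$fit$c_statistic - 0.5), 0.07)
  expect_output(print(ps), "Propensity scores")
})

test_that("quintile strata are equal-size rank splits with hand-checkable rates", {
  # constant scores: tie contract gives strata of equal size (+/- 1)
  rows <- make_ps_rows(23, seed = 3)
  q <- quintile_stratified_rates(rows, rep(0.4, 23), "exposed")
  expect_true(all(abs(q$table$n - 23 / 5) < 1))
  expect_equal(sum(q$table$n), 23)

  # 20-row hand fixture: scores order the rows, outcomes enumerated by hand
  rows2 <- make_ps_rows(20, seed = 4)
  rows2$exposed <- rep(c(1, 0, 0, 0), 5)
  rows2$y <- c(1, 0, 0, 0,   0, 1, 1, 0,   1, 1, 0, 0,   0, 0, 0, 0,
               1, 0, 1, 1)
  sc <- seq(0.05, 1, by = 0.05) - 0.025  # strictly increasing with row
  q2 <- quintile_stratified_rates(rows2, sc, "y")
  # stratum s holds rows 4s-3 .. 4s: exposed rate from row 4s-3, unexposed
  # from the other three
  expect_equal(q2$table$rate_exposed, c(100, 0, 100, 0, 100))
  expect_equal(q2$table$rate_unexposed,
               100 * c(0, 2 / 3, 1 / 3, 0, 2 / 3))
  expect_equal(q2$table$n, rep(4, 5))
  w <- 4 / 20
  p1 <- sum(rep(w, 5) * c(1, 0, 1, 0, 1)) / sum(rep(w, 5))
  p0 <- sum(rep(w, 5) * c(0, 2 / 3, 1 / 3, 0, 2 / 3)) / sum(rep(w, 5))
  expect_equal(q2$estimate$arr, 100 * (p1 - p0), tolerance = 1e-10)

  # single-armed strata are excluded and noted
  rows3 <- make_ps_rows(20, seed = 5)
  rows3$exposed <- rep(c(rep(1, 4), rep(0, 4)), length.out = 20)
  rows3$exposed[1:4] <- 1; rows3$exposed[5:20] <- rep(c(1, 0), 8)
  sc3 <- seq_len(20) / 21
  rows3$y <- rep(c(0, 1), 10)
  q3 <- quintile_stratified_rates(rows3, sc3, "y")
  expect_match(q3$estimate$note, "excluded")
  expect_error(quintile_stratified_rates(
    data.frame(exposed = rep(1, 10), y = rep(c(0, 1), 5)),
    seq(0.1, 1, 0.1), "y"), "both exposure arms")
})

test_that("inverse-probability weights follow the textbook values", {
  w <- iptw_weights(c(0.5, 0.8), c(1, 0))
  expect_equal(as.numeric(w[1]), 2.0)
  expect_equal(as.numeric(w[2]), 5.0)
  expect_equal(attr(w, "max_weight"), 5.0)
  expect_error(iptw_weights(c(0, 0.5), c(1, 0)), "in \\(0, 1\\)")
})

test_that("constant weights leave the weighted estimator unchanged", {
  set.seed(12)
  rows <- make_ps_rows(800, seed = 12)
  rows$y <- as.integer(runif(800) <
                         plogis(-1.5 - 0.4 * rows$exposed +
                                  0.5 * (rows$sex == "female")))
  un <- adjusted_arr(rows, "y")$estimate
  wt <- iptw_arr(rows, rep(0.5, 800), "y")$estimate
  expect_equal(wt$arr, un$arr, tolerance = 1e-7)
  expect_equal(wt$ci_arr, un$ci_arr, tolerance = 1e-6)
})

test_that("greedy matching honors its precision, tie and pigeonhole contracts", {
  # exact 5-digit agreement is matched first, at distance 0
  m <- greedy_match(c(0.3, 0.3, 0.9), c(1, 0, 0), ids = c(1L, 2L, 3L))
  expect_identical(m$treated_id, 1L)
  expect_identical(m$control_id, 2L)
  expect_identical(m$distance, 0)

  # equal distances break ties toward the smaller control id
  m2 <- greedy_match(c(0.32, 0.30, 0.34), c(1, 0, 0), ids = c(1L, 7L, 3L))
  expect_identical(m2$control_id, 3L)

  # pigeonhole: surplus treated subjects stay unmatched and are counted
  m3 <- greedy_match(rep(0.4, 7), c(1, 1, 1, 1, 1, 0, 0), ids = 1:7)
  expect_identical(nrow(m3), 2L)
  expect_identical(attr(m3, "n_unmatched_treated"), 3L)
  expect_identical(attr(m3, "n_treated"), 5L)

  # caliper rejects distant pairs
  m4 <- greedy_match(c(0.2, 0.29), c(1, 0), ids = 1:2, caliper = 0.05)
  expect_identical(nrow(m4), 0L)

  expect_error(greedy_match(c(0.2, 0.3), c(1, 1), ids = 1:2), "nonempty")
})

test_that("greedy matching equals the stepwise reference implementation", {
  set.seed(30)
  n <- 30
  # mixed-precision scores exercise every digit pass
  sc <- round(runif(n), sample(1:5, n, TRUE))
  ex <- c(rep(1, 12), rep(0, 18))
  ids <- sample(1000:9999, n)
  for (sd0 in c(1L, 7L)) {
    got <- greedy_match(sc, ex, seed = sd0, ids = ids)
    ref <- naive_greedy_match(sc, ex, seed = sd0, ids = ids)
    expect_equal(got$treated_id, ref$treated_id)
    expect_equal(got$control_id, ref$control_id)
    expect_equal(got$distance, ref$distance, tolerance = 1e-12)
  }
  # input row order is irrelevant given stable ids
  perm <- sample(n)
  g1 <- greedy_match(sc, ex, seed = 1L, ids = ids)
  g2 <- greedy_match(sc[perm], ex[perm], seed = 1L, ids = ids[perm])
  expect_equal(g1$treated_id, g2$treated_id)
  expect_equal(g1$control_id, g2$control_id)
})

test_that("standardized difference matches its formula and conventions", {
  expect_equal(standardized_difference(0.3, 0.3), 0)
  expect_equal(standardized_difference(0, 0), 0)
  expect_equal(standardized_difference(1, 1), 0)
  expect_equal(round(standardized_difference(0.557, 0.541), 2), 3.22)
  p1 <- 0.064; p2 <- 0.513
  expect_equal(standardized_difference(p1, p2),
               100 * abs(p1 - p2) /
                 sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2),
               tolerance = 1e-12)
  expect_error(standardized_difference(1.2, 0.5))
})

test_that("McNemar test follows the discordant-count formula", {
  mk <- function(b, cc, n = 40) {
    yt <- c(rep(1, b), rep(0, cc), rep(1, 5), rep(0, n - b - cc - 5))
    yc <- c(rep(0, b), rep(1, cc), rep(1, 5), rep(0, n - b - cc - 5))
    mcnemar_pairs(yt, yc)
  }
  expect_equal(mk(10, 0)$statistic, 10)
  expect_equal(mk(5, 15)$statistic, 5)
  expect_equal(mk(7, 7)$statistic, 0)
  expect_equal(mk(0, 0)$p_value, 1)
  expect_identical(mk(0, 0)$method, "no discordant pairs (p = 1)")
  # small discordant counts use the exact binomial p
  r <- mk(10, 0)
  expect_identical(r$method, "exact binomial")
  expect_equal(r$p_exact, binom.test(10, 10, 0.5)$p.value)
  # large discordant counts use the chi-square p, agreeing with
  # an uncorrected stats::mcnemar.test
  r2 <- mk(20, 10, n = 60)
  expect_identical(r2$method, "chi-square")
  ref <- mcnemar.test(matrix(c(5, 10, 20, 25), 2), correct = FALSE)
  expect_equal(r2$statistic, unname(ref$statistic))
  expect_equal(r2$p_value, unname(ref$p.value))
})

test_that("Kaplan-Meier curves match hand computation and the ECDF limit", {
  # 12-subject fixture, two arms, staggered censoring; product-limit by hand
  time <- c(1, 1, 2, 2, 3, 3,  1, 1, 1, 1, 1, 1)
  event <- c(1, 0, 1, 1, 0, 1,  0, 0, 0, 0, 0, 0)
  arm <- rep(c("a", "b"), each = 6)
  km <- km_cumulative(time, event, arm, horizon = 3)
  a <- km[km$arm == "a", ]
  expect_equal(a$cum_inc, c(1 - 5 / 6, 1 - 5 / 12, 1 - 5 / 24),
               tolerance = 1e-12)
  expect_equal(a$n_risk, c(6, 4, 2))
  b <- km[km$arm == "b", ]
  expect_equal(b$cum_inc, rep(0, 3))

  # no censoring: the curve is the empirical cumulative event fraction
  set.seed(9)
  t2 <- sample(1:5, 40, TRUE)
  km2 <- km_cumulative(t2, rep(1, 40), rep("x", 40), horizon = 5)
  expect_equal(km2$cum_inc, vapply(1:5, function(y) mean(t2 <= y),
                                   numeric(1)),
               tolerance = 1e-12)
})

test_that("cohort-level Kaplan-Meier curves use the design's calendar", {
  reg <- generate_registry(tiny_config(seed = 15L, n_pcps = 80L,
                                       mean_panel = 80))
  co <- build_restricted_cohort(reg)
  km <- km_curves(co, "crc_incident")
  expect_setequal(unique(km$arm), c("colonoscopy", "no_colonoscopy"))
  expect_equal(max(km$year), co$spec$incidence_end_year -
                 max(co$spec$exposure_window))
  expect_true(all(km$cum_inc >= 0 & km$cum_inc <= 1))
  expect_true(all(diff(km$cum_inc[km$arm == "colonoscopy"]) >= -1e-12))
})

test_that("matched analysis counts pairs correctly", {
  # 10 pairs: 3 treated-only events, 1 control-only event
  rows <- make_ps_rows(20, seed = 16)
  rows$exposed <- rep(c(1, 0), each = 10)
  rows$y <- 0
  rows$y[1:3] <- 1    # treated-only events (pairs 1-3)
  rows$y[14] <- 1     # control-only event (pair 4)
  pairs <- data.frame(treated_id = 1:10, control_id = 11:20,
                      distance = 0)
  res <- matched_arr(pairs, rows, "y")
  expect_equal(res$estimate$arr, 20)
  expect_equal(res$estimate$p_exposed, 30)
  expect_equal(res$estimate$p_unexposed, 10)
  expect_equal(res$mcnemar$b, 3)
  expect_equal(res$mcnemar$c, 1)
  expect_equal(res$estimate$n, 10)
  expect_match(res$estimate$note, "McNemar")
  expect_true(all(c("split_by", "group", "n_pairs", "difference") %in%
                    names(res$subgroups)))
  expect_equal(sum(res$subgroups$n_pairs[res$subgroups$split_by ==
                                           "sex_age"]), 10)

  # identical pair outcomes: zero difference
  rows$y <- rep(c(1, 0), 10)
  rows$y[11:20] <- rows$y[1:10]
  expect_equal(matched_arr(pairs, rows, "y")$estimate$arr, 0)
  expect_error(matched_arr(pairs[0, ], rows, "y"), "no matched pairs")
})

test_that("the matched signed-rank test uses double-event pairs only", {
  rows <- make_ps_rows(20, seed = 18)
  rows$exposed <- rep(c(1, 0), each = 10)
  pairs <- data.frame(treated_id = 1:10, control_id = 11:20,
                      distance = 0)
  rows$crc_incident <- 0
  rows$crc_dx_year <- NA_integer_
  # pairs 1-5 have events in both arms; pair 6 treated-only; rest censored
  rows$crc_incident[c(1:6, 11:15)] <- 1
  rows$crc_dx_year[1:6] <- c(2L, 3L, 8L, 4L, 6L, 7L)
  rows$crc_dx_year[11:15] <- c(5L, 6L, 1L, 4L, 9L)
  res <- wilcoxon_km_pairs(pairs, rows, "crc_incident")
  expect_equal(res$n_pairs_used, 5)
  expect_equal(res$n_pairs_excluded, 5)
  # reference: paired signed-rank test on pooled midranks via stats
  rk <- rank(c(rows$crc_dx_year[1:5], rows$crc_dx_year[11:15]))
  ref <- suppressWarnings(stats::wilcox.test(rk[1:5], rk[6:10],
                                             paired = TRUE, exact = FALSE,
                                             correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  # identical event years in every retained pair: p = 1 by convention
  rows$crc_dx_year[11:15] <- rows$crc_dx_year[1:5]
  tied <- wilcoxon_km_pairs(pairs, rows, "crc_incident")
  expect_identical(tied$statistic, 0)
  expect_identical(tied$p_value, 1)

  # no double-event pairs at all
  rows$crc_incident[11:15] <- 0
  expect_error(wilcoxon_km_pairs(pairs, rows, "crc_incident"),
               "events in both arms")
  expect_error(wilcoxon_km_pairs(pairs[0, ], rows, "crc_incident"),
               "no matched pairs")
})

test_that("balance table reports arm proportions and standardized differences", {
  rows <- make_ps_rows(500, seed = 17)
  tab <- balance_table(rows)
  f <- tab[tab$covariate == "sex" & tab$level == "female", ]
  p1 <- mean(rows$sex[rows$exposed == 1] == "female")
  p0 <- mean(rows$sex[rows$exposed == 0] == "female")
  expect_equal(f$p_exposed_before, p1)
  expect_equal(f$p_unexposed_before, p0)
  expect_equal(f$std_diff_before, standardized_difference(p1, p0))
  expect_false("std_diff_after" %in% names(tab))

  ps <- derive_propensity(rows)
  pairs <- greedy_match(ps$scores, rows$exposed, seed = 1L,
                        ids = rows$subject_id)
  tab2 <- balance_table(rows, pairs)
  expect_true(all(c("std_diff_after", "p_exposed_after") %in% names(tab2)))
  expect_identical(nrow(tab2), nrow(tab))
})
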