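test_that("discretionary classification follows the kind/timing rules", {
  # screening in year 2 with a diagnosis in year 4 (within 3-year lookahead)
  expect_false(classify_discretionary("screening", 2L, FALSE, 4L, 3L))
  # boundary: diagnosis exactly lookahead years later still disqualifies
  expect_false(classify_discretionary("screening", 2L, FALSE, 5L, 3L))
  # diagnosis after the lookahead does not
  expect_true(classify_discretionary("screening", 2L, FALSE, 6L, 3L))
  # outpatient screening with no cancer ever is discretionary
  expect_true(classify_discretionary("screening", 2L, FALSE, NA_integer_, 3L))
  # diagnostic procedures are never discretionary, whatever the timing
  expect_false(classify_discretionary("diagnostic", 2L, FALSE, NA_integer_,
                                      3L))
  # inpatient procedures are never discretionary
  expect_false(classify_discretionary("screening", 2L, TRUE, NA_integer_, 3L))
  # diagnosis before the procedure does not disqualify (only at/after)
  expect_true(classify_discretionary("screening", 4L, FALSE, 1L, 3L))
})

test_that("per-physician rates match a hand count on a 6-PCP/60-subject registry", {
  # panel layout: PCP 1 has 20 subjects, PCPs 2-5 have 10, PCP 6 has 0.
  pcp <- rep(c(1L, 2L, 3L, 4L, 5L), c(20L, 10L, 10L, 10L, 10L))
  scr <- rep(NA_integer_, 60)
  dx <- rep(NA_integer_, 60)
  diag <- rep(NA_integer_, 60)
  inpt <- rep(FALSE, 60)
  # PCP 1: 5 screening colonoscopies, one disqualified by a year-4 dx after
  # a year-2 procedure -> 4 discretionary, 5 any-colonoscopy
  scr[1:5] <- c(2L, 1L, 3L, 5L, 4L)
  dx[1] <- 4L
  # PCP 2: 2 screening, one inpatient -> 1 discretionary, 2 any
  scr[21:22] <- c(1L, 2L)
  inpt[22] <- TRUE
  # PCP 3: diagnostic colonoscopy only -> 0 discretionary, 1 any
  dx[31] <- 3L
  diag[31] <- 3L
  # PCP 4: screening in year 5 with follow-up dx year 9 (outside lookahead)
  # -> 1 discretionary, 1 any
  scr[41] <- 5L
  dx[41] <- 9L
  # PCP 5: no colonoscopies at all
  s <- make_subjects(60, pcp_id = pcp, screening_year = scr,
                     crc_dx_year = dx, diagnostic_year = diag,
                     screening_inpatient = inpt)
  pcps <- data.frame(pcp_id = 1:6, propensity_logit = 0,
                     n_eligible = c(20L, 10L, 10L, 10L, 10L, 0L))
  out <- compute_pcp_instrument(pcps, s)
  expect_identical(out$n_linked, c(20L, 10L, 10L, 10L, 10L, 0L))
  expect_identical(out$n_any_colonoscopy, c(5L, 2L, 1L, 1L, 0L, 0L))
  expect_identical(out$n_discretionary, c(4L, 1L, 0L, 1L, 0L, 0L))
  expect_equal(out$discretionary_rate,
               c(100 * 4 / 20, 100 * 1 / 10, 0, 100 * 1 / 10, 0, NA_real_))
  expect_equal(out$referral_rate,
               c(25, 20, 10, 10, 0, NA_real_))
  expect_identical(out$excluded_empty, c(rep(FALSE, 5), TRUE))
})

test_that("instrument arithmetic: 10 discretionary among 200 eligible is 5.0", {
  s <- make_subjects(200, pcp_id = rep(1L, 200),
                     screening_year = c(rep(3L, 10), rep(NA_integer_, 190)))
  pcps <- data.frame(pcp_id = 1L, propensity_logit = 0, n_eligible = 200L)
  out <- compute_pcp_instrument(pcps, s)
  expect_identical(out$discretionary_rate, 5)
})

test_that("unselected design counts diagnostic work-up as exposure", {
  # subject 1: only a diagnostic colonoscopy in year 3, cancer diagnosed in
  # year 3 -> exposed and incident (the measurement-error mechanism);
  # subject 2: no colonoscopy, follow-up cancer in year 8 -> unexposed,
  # incident; subject 3: nothing.
  s <- make_subjects(30, pcp_id = rep(1L, 30),
                     diagnostic_year = c(3L, rep(NA_integer_, 29)),
                     crc_dx_year = c(3L, 8L, rep(NA_integer_, 28)))
  reg <- make_registry(s)
  co <- build_unselected_cohort(reg)
  expect_identical(co$spec$cohort_kind, "unselected")
  r <- co$rows
  expect_identical(r$exposed[r$subject_id == 1], 1L)
  expect_identical(r$crc_incident[r$subject_id == 1], 1L)
  expect_identical(r$exposed[r$subject_id == 2], 0L)
  expect_identical(r$crc_incident[r$subject_id == 2], 1L)
  expect_identical(r$crc_incident[r$subject_id == 3], 0L)
  expect_identical(nrow(r), 30L)
  expect_error(build_unselected_cohort(make_registry(s[0, ], n_pcps = 1)),
               "empty registry")
})

test_that("restricted design applies the baseline and physician filters", {
  # 3 PCPs x variable panels. PCP 1: 100 subjects, 4 with colonoscopy (4% >
  # 3% -> kept). PCP 2: 100 subjects, exactly 3 with colonoscopy (3.0% not
  # more than 3% -> excluded). PCP 3: 9 subjects with colonoscopies
  # (panel < 10 -> excluded).
  pcp <- rep(c(1L, 2L, 3L), c(100L, 100L, 9L))
  scr <- rep(NA_integer_, 209)
  scr[1:4] <- 2L
  scr[101:103] <- 2L
  scr[201:209] <- 2L
  dx <- rep(NA_integer_, 209)
  odx <- rep(NA_integer_, 209)
  # within PCP 1: subject 5 diagnosed in year 4 (excluded at baseline),
  # subject 6 dies of another cause in year 5 (excluded), subject 7
  # diagnosed in follow-up year 7 (kept, incident)
  dx[5] <- 4L
  odx[6] <- 5L
  dx[7] <- 7L
  s <- make_subjects(209, pcp_id = pcp, screening_year = scr,
                     crc_dx_year = dx, other_death_year = odx)
  reg <- make_registry(s, n_pcps = 3L)
  co <- build_restricted_cohort(reg)
  r <- co$rows
  # only PCP 1 subjects, minus the two baseline exclusions
  expect_identical(sort(unique(r$pcp_id)), 1L)
  expect_identical(nrow(r), 98L)
  expect_false(any(r$subject_id %in% c(5L, 6L)))
  expect_identical(r$crc_incident[r$subject_id == 7], 1L)
  expect_identical(co$counts$n_excluded_baseline, 2L)
  expect_identical(co$counts$n_excluded_pcp, 109L)
  # outcome window: no restricted-cohort event has a window-year diagnosis
  expect_true(all(is.na(r$crc_dx_year[r$crc_incident == 1]) |
                    r$crc_dx_year[r$crc_incident == 1] >
                      max(co$spec$exposure_window)))

  # all physicians excluded -> explicit error
  s2 <- make_subjects(9, pcp_id = rep(1L, 9))
  expect_error(build_restricted_cohort(make_registry(s2, n_pcps = 1L)),
               "PCPs excluded")
})

test_that("restricted cohort nests in the unselected cohort with a shared instrument", {
  reg <- generate_registry(tiny_config(seed = 13L, n_pcps = 60L,
                                       mean_panel = 60))
  un <- build_unselected_cohort(reg)
  re <- build_restricted_cohort(reg)
  expect_true(all(re$rows$subject_id %in% un$rows$subject_id))
  expect_lt(nrow(re$rows), nrow(un$rows))
  # the instrument is computed pre-restriction, so both cohorts agree on it
  m <- match(re$rows$subject_id, un$rows$subject_id)
  expect_identical(re$rows$instrument, un$rows$instrument[m])
  expect_true(all(re$rows$instrument >= 0 & re$rows$instrument <= 100))
  # cohort rows never carry the latent confounder
  expect_false("confounder_u" %in% names(un$rows))
  expect_false("confounder_u" %in% names(re$rows))

  # cohort CSV round trip preserves the analysis rows
  f <- file.path(tempdir(), "cohort_rt.csv")
  write_cohort(re, f)
  back <- read_cohort_rows(f)
  expect_identical(back$subject_id, re$rows$subject_id)
  expect_identical(back$exposed, re$rows$exposed)
  expect_identical(back$crc_incident, re$rows$crc_incident)
  expect_equal(back$instrument, re$rows$instrument)
  expect_identical(back$rural, re$rows$rural)
  unlink(c(f, sub("\\.csv$", ".json", f)))
})
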