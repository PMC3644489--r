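# Shared fixtures and reference implementations for the test suite.

# Small, fast registry configuration for structural tests.
tiny_config <- function(seed = 1L, n_pcps = 50L, mean_panel = 40, ...) {
  registry_config(seed = seed, n_pcps = n_pcps, mean_panel = mean_panel, ...)
}

# Build a subjects table with every field the cohort builder reads, with
# sensible defaults, so individual tests can spell out only the fields they
# exercise.
make_subjects <- function(n, pcp_id = rep(1L, n),
                          screening_year = rep(NA_integer_, n),
                          diagnostic_year = rep(NA_integer_, n),
                          crc_dx_year = rep(NA_integer_, n),
                          crc_death_year = rep(NA_integer_, n),
                          other_death_year = rep(NA_integer_, n),
                          screening_inpatient = rep(FALSE, n)) {
  data.frame(
    subject_id = seq_len(n),
    pcp_id = pcp_id,
    age_group = rep(AGE_LEVELS, length.out = n),
    sex = rep(SEX_LEVELS, length.out = n),
    income_quintile = rep(1:5, length.out = n),
    rural = rep(c(FALSE, TRUE), length.out = n),
    comorbidity = rep(COMORBIDITY_LEVELS, length.out = n),
    confounder_u = 0,
    screening = as.integer(!is.na(screening_year)),
    screening_year = as.integer(screening_year),
    screening_inpatient = screening_inpatient,
    window_crc = !is.na(crc_dx_year) & crc_dx_year <= max(EXPOSURE_WINDOW),
    crc_dx_year = as.integer(crc_dx_year),
    diagnostic_year = as.integer(diagnostic_year),
    crc_death_year = as.integer(crc_death_year),
    other_death_year = as.integer(other_death_year),
    stringsAsFactors = FALSE
  )
}

# Wrap a hand-built subjects table as a registry snapshot.
make_registry <- function(subjects, n_pcps = max(subjects$pcp_id),
                          config = NULL) {
  structure(list(config = config,
                 pcps = data.frame(pcp_id = seq_len(n_pcps),
                                   propensity_logit = 0,
                                   n_eligible = as.integer(
                                     table(factor(subjects$pcp_id,
                                                  levels = seq_len(n_pcps))))),
                 subjects = subjects),
            class = "registry_snapshot")
}

# Straightforward reference implementation of the digit-based greedy match:
# same contract as greedy_match(), written as a plain double loop. Exposed
# subjects are processed in the identical seeded order; at each precision
# pass a treated subject takes the available control with equal rounded
# score, minimal raw distance, ties to the smaller control id.
naive_greedy_match <- function(scores, exposed, seed = 1L, ids = NULL,
                               digits = 5:1) {
  n <- length(scores)
  if (is.null(ids)) ids <- seq_len(n)
  t_pos <- which(exposed == 1)
  c_pos <- which(exposed == 0)
  t_pos <- t_pos[order(ids[t_pos])]
  set.seed(screenbias:::stage_seed(seed, "match"))
  t_pos <- t_pos[sample.int(length(t_pos))]
  c_free <- rep(TRUE, length(c_pos))
  t_match <- rep(NA_integer_, length(t_pos))
  key <- function(x, d) as.integer(round(round(x, d) * 10^d))
  for (d in digits) {
    for (j in seq_along(t_pos)) {
      if (!is.na(t_match[j])) next
      sc <- scores[t_pos[j]]
      cand <- which(c_free & key(scores[c_pos], d) == key(sc, d))
      if (length(cand) == 0) next
      dd <- abs(scores[c_pos[cand]] - sc)
      pick <- cand[order(dd, ids[c_pos[cand]])][1]
      t_match[j] <- pick
      c_free[pick] <- FALSE
    }
  }
  got <- !is.na(t_match)
  out <- data.frame(treated_id = ids[t_pos[got]],
                    control_id = ids[c_pos[t_match[got]]],
                    distance = abs(scores[t_pos[got]] -
                                     scores[c_pos[t_match[got]]]))
  out[order(out$treated_id), , drop = FALSE]
}

# Exhaustive O(n^2) concordance computation for c-statistic cross-checks.
brute_force_cstat <- function(scores, outcomes) {
  i1 <- which(outcomes == 1); i0 <- which(outcomes == 0)
  tot <- 0
  for (a in i1) for (b in i0) {
    tot <- tot + (scores[a] > scores[b]) + 0.5 * (scores[a] == scores[b])
  }
  tot / (length(i1) * length(i0))
}
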