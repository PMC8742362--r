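fix <- figure1_fixture()

test_that("case qualification follows the worked-example walk-through", {
  expect_setequal(qualify_cases(fix, "PP")$subject_id, c(2, 3, 8))
  itt <- qualify_cases(fix, "ITT")$subject_id
  expect_true(1 %in% itt)                    # switches exposure, still ITT
  expect_setequal(itt, c(1, 2, 3, 6, 8))
  none <- fix[is.infinite(fix$T), ]
  attr(none, "K") <- attr(fix, "K")
  expect_equal(nrow(qualify_cases(none, "ITT")), 0)
})

test_that("eligibility sets follow the event-free-at-window rule", {
  # row 1's event window: the case itself is part of its eligible set
  expect_setequal(eligible_controls(fix, 5, "risk-set"),
                  c(1, 4, 5, 6, 7, 8, 9))
  # first per-protocol case's window: every row is eligible
  expect_setequal(eligible_controls(fix, 3, "risk-set", "PP"), 1:9)
  # row 8's event window: the event-free set, and the case's own sampling
  # pool (which excludes the index case) is exactly the quartet of
  # never-failing rows
  expect_setequal(eligible_controls(fix, 7, "risk-set", "PP"),
                  c(4, 5, 7, 8, 9))
  expect_setequal(control_pool(fix, 8, 7, "risk-set", "PP"), c(4, 5, 7, 9))
  expect_setequal(eligible_controls(fix, 0, "risk-set"), 1:9)
  expect_setequal(eligible_controls(fix, scheme = "survivor"), c(4, 5, 7, 9))
  expect_setequal(eligible_controls(fix, scheme = "case-base"), 1:9)
  expect_error(eligible_controls(fix, 12, "risk-set"),
               class = "cc_argument_error")
})

test_that("single-draw schemes draw uniformly within their pools", {
  expect_equal(sample_case_base_controls(fix, 9, seed = 1)$S, rep(1L, 9))
  s1 <- sample_case_base_controls(fix, 4, seed = 3)
  expect_identical(s1$S, sample_case_base_controls(fix, 4, seed = 3)$S)
  expect_error(sample_case_base_controls(fix, 10, seed = 1),
               class = "cc_argument_error")

  sv <- sample_survivor_controls(fix, 3, seed = 2)
  expect_true(all(which(sv$S == 1) %in% c(4, 5, 7, 9)))
  all_events <- fix[is.finite(fix$T), ]
  attr(all_events, "K") <- attr(fix, "K")
  expect_error(sample_survivor_controls(all_events, 1, seed = 1),
               class = "cc_sampling_infeasible")

  # exact inclusion probabilities: every subject equally likely (m/N),
  # zero outside the pool; checked by Monte Carlo against the
  # hypergeometric truth at 3 binomial SEs
  R <- 3000
  counts <- integer(9)
  for (r in seq_len(R)) {
    counts <- counts + sample_case_base_controls(fix, 3, seed = 10000 + r)$S
  }
  p <- 3 / 9
  se <- sqrt(p * (1 - p) / R)
  expect_true(all(abs(counts / R - p) < 3 * se))
  countsv <- integer(9)
  for (r in seq_len(R)) {
    countsv <- countsv + sample_survivor_controls(fix, 2, seed = 20000 + r)$S
  }
  expect_true(all(countsv[c(1, 2, 3, 6, 8)] == 0))
  expect_true(all(abs(countsv[c(4, 5, 7, 9)] / R - 0.5) <
                    3 * sqrt(0.25 / R)))
})

test_that("risk-set sampling respects eligibility, self-exclusion and reuse", {
  found_out_of_pool <- FALSE
  self_paired <- FALSE
  row1_as_earlier_control <- FALSE
  for (r in 1:300) {
    sel <- sample_risk_set_controls(fix, 2, "ITT", seed = r)
    lk <- sel$links
    # controls for row 1's case come only from its pool
    for (i in which(lk$case_id == 1)) {
      if (!(lk$control_id[i] %in% c(4, 5, 6, 7, 8, 9))) {
        found_out_of_pool <- TRUE
      }
    }
    if (any(lk$case_id == lk$control_id)) self_paired <- TRUE
    if (any(lk$control_id == 1 & lk$window < 5)) {
      row1_as_earlier_control <- TRUE
    }
    # soundness: no selection while already failed
    K <- attr(fix, "K")
    for (k in 0:(K - 1)) {
      expect_true(all(fix$T[sel$S[, k + 1] == 1] >= k))
    }
  }
  expect_false(found_out_of_pool)
  expect_false(self_paired)
  expect_true(row1_as_earlier_control)   # a case serves as earlier control

  sel <- sample_risk_set_controls(fix, 2, "ITT", seed = 1)
  expect_identical(sel$links,
                   sample_risk_set_controls(fix, 2, "ITT", seed = 1)$links)
  expect_error(sample_risk_set_controls(fix, 9, "ITT", seed = 1),
               class = "cc_sampling_infeasible")
})

test_that("per-case risk-set sampling fractions track the case hazard", {
  s <- preset_dgp("constant-hazard")
  co <- sample_cohort(s, 20000, seed = 31)
  sel <- sample_risk_set_controls(co, 2, "ITT", seed = 32)
  # constant observed hazard by construction: realized per-window sampling
  # fractions are approximately equal across the three windows
  fr <- sel$sampling_fractions
  expect_lt(max(fr) / min(fr), 1.06)
  # and their level is m times the enumerated case hazard over at-risk mass
  at <- enumerate_trajectories(s)
  c0 <- 2 * sum(at$prob[at$T == 0]) / sum(at$prob[at$T >= 0])
  expect_lt(abs(fr[1] - c0) / c0, 0.1)
})

test_that("fraction-device risk-set sampling is constant by construction", {
  s <- preset_dgp("tv-confounding")
  co <- sample_cohort(s, 20000, seed = 41)
  sel <- sample_risk_set_controls(co, mode = "PP", seed = 42,
                                  sampling = "fraction", fraction = 0.15)
  expect_true(all(abs(sel$sampling_fractions - 0.15) < 0.02))
  K <- attr(co, "K")
  for (k in 0:(K - 1)) {
    expect_true(all(co$T[sel$S[, k + 1] == 1] >= k))
  }
  expect_error(sample_risk_set_controls(co, mode = "PP", seed = 1,
                                        sampling = "fraction"),
               class = "cc_argument_error")
})

test_that("matched sampling honours pools, match keys and degenerate cases", {
  s <- preset_dgp("confounded-binary")
  co <- sample_cohort(s, 3000, seed = 51)
  for (sch in c("case-base", "survivor", "risk-set")) {
    m <- sample_matched_controls(co, sch, "ITT", seed = 52)
    expect_identical(m, sample_matched_controls(co, sch, "ITT", seed = 52))
    src <- match(m$control_id, co$subject_id)
    ca <- match(m$case_id, co$subject_id)
    expect_true(all(co$L0[src] == co$L0[ca]))   # exact matching
    expect_true(all(m$control_exposure %in% 0:1))
    expect_true(all(m$case_id != m$control_id)) # self-exclusion default
    if (sch == "survivor") expect_true(all(is.infinite(co$T[src])))
    if (sch == "risk-set") expect_true(all(co$T[src] >= m$case_window))
  }
  mpp <- sample_matched_controls(preset_dgp("tv-confounding-homogeneous") |>
                                   sample_cohort(3000, seed = 53),
                                 "risk-set", "PP", seed = 54)
  expect_true(all(mpp$case_id != mpp$control_id))

  # single-subject cohort: the only possible source is the case itself
  one <- fix[2, ]
  attr(one, "K") <- attr(fix, "K")
  m1 <- sample_matched_controls(one, "case-base", seed = 1, allow_self = TRUE)
  expect_equal(m1$control_id, 2)
  expect_equal(m1$control_exposure, m1$case_exposure)
  # and with self-exclusion the case is dropped, with a logged key
  expect_warning(
    m0 <- sample_matched_controls(one, "case-base", seed = 1),
    class = "cc_empty_pool_warning")
  expect_equal(nrow(m0), 0)
  expect_equal(attr(m0, "dropped")$case_id, 2)
})

test_that("matched control exposure reproduces the pool prevalence", {
  # distribution-level: Pr(A' = 1 | case with L0 = l) equals the exposure
  # prevalence of the scheme's pool at that stratum (Monte Carlo vs exact)
  R <- 2000
  hits <- c(`0` = 0, `1` = 0); tries <- c(`0` = 0, `1` = 0)
  pool_prev <- vapply(c("0", "1"), function(l) {
    mean(fix$A0[fix$L0 == as.integer(l)])
  }, numeric(1))
  for (r in seq_len(R)) {
    m <- sample_matched_controls(fix, "case-base", seed = 30000 + r,
                                 allow_self = TRUE)
    for (l in c("0", "1")) {
      sel <- fix$L0[match(m$case_id, fix$subject_id)] == as.integer(l)
      hits[l] <- hits[l] + sum(m$control_exposure[sel])
      tries[l] <- tries[l] + sum(sel)
    }
  }
  for (l in c("0", "1")) {
    p <- pool_prev[l]
    expect_lt(abs(hits[l] / tries[l] - p), 3 * sqrt(p * (1 - p) / tries[l]))
  }
})

test_that("selection tables serialize to the documented CSV layout", {
  path <- tempfile(fileext = ".csv")
  write_selection(sample_case_base_controls(fix, 4, seed = 3), path)
  df <- utils::read.csv(path)
  expect_named(df, c("subject_id", "scheme", "mode", "window", "selected",
                     "times"))
  expect_true(all(df$window == -1))
  write_selection(sample_risk_set_controls(fix, 2, "ITT", seed = 1), path)
  df2 <- utils::read.csv(path)
  expect_true(all(df2$selected == 1))
  expect_true(all(df2$window >= 0))
  m <- sample_matched_controls(fix, "case-base", seed = 2)
  write_selection(m, path)
  df3 <- utils::read.csv(path)
  expect_named(df3, c("case_id", "case_window", "case_exposure",
                      "control_id", "control_exposure", "match_key"))
  unlink(path)
})
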