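test_that("saturated propensities recover exact conditional probabilities", {
  # fitted on the enumerated law (mass-weighted records) the stratum
  # frequencies must equal the exact conditional probabilities, computed
  # here independently with base-R aggregation
  s <- validate_spec(toy_spec())
  obs <- ccident:::observed_law(s)
  rec <- data.frame(exposure = obs$A0, L0 = obs$L0, wt = obs$prob)
  map <- fit_propensity(rec, "L0")
  for (l in 0:1) {
    num <- sum(obs$prob[obs$L0 == l & obs$A0 == 1])
    den <- sum(obs$prob[obs$L0 == l])
    expect_equal(unname(map$lookup[as.character(l)]), num / den,
                 tolerance = 1e-14)
  }
  # conditioning on nothing gives the overall prevalence in one stratum
  m0 <- fit_propensity(rec, character(0))
  expect_equal(nrow(m0$strata), 1)
  expect_equal(m0$strata$p, sum(obs$prob * obs$A0) / sum(obs$prob),
               tolerance = 1e-14)
})

test_that("degenerate strata are flagged and fail only when touched", {
  rec <- data.frame(exposure = c(1, 1, 0, 1), L0 = c(0, 0, 1, 1))
  map <- fit_propensity(rec, "L0")
  expect_true(map$strata$flagged[map$strata$key == "0"])
  expect_error(propensity_value(map, data.frame(L0 = 0)),
               class = "cc_positivity_violation")
  expect_silent(propensity_value(map, data.frame(L0 = 1)))
  expect_error(propensity_value(map, data.frame(L0 = 7)),
               class = "cc_positivity_violation")  # unseen stratum
})

test_that("time-fixed weights follow the inverse-propensity formula", {
  expect_equal(time_fixed_weight(1, 0.25), 4)
  expect_equal(time_fixed_weight(0, 0.25), 4 / 3)
  expect_error(time_fixed_weight(1, 1), class = "cc_positivity_violation")
  expect_error(time_fixed_weight(0, 0), class = "cc_positivity_violation")
})

test_that("time-varying weights telescope", {
  expect_equal(time_varying_weights(c(1, 1, 1), rep(0.5, 3)), c(2, 4, 8))
  set.seed(99)
  for (r in 1:20) {
    A <- rbinom(4, 1, 0.5)
    p <- runif(4, 0.05, 0.95)
    W <- time_varying_weights(A, p)
    f <- A / p + (1 - A) / (1 - p)
    expect_equal(W[-1], W[-4] * f[-1], tolerance = 1e-12)
  }
  expect_error(time_varying_weights(c(1, 0), c(0.5, 1)),
               class = "cc_positivity_violation")
})

test_that("exact per-window weights match an independent direct product", {
  # on the enumerated toy law, the package's cumulative weight matrix must
  # equal a brute-force product of inverse conditional probabilities
  # computed straight from the law table
  s <- validate_spec(toy_spec())
  obs <- ccident:::observed_law(s)
  maps <- lapply(0:1, function(j) {
    at <- obs$T >= j
    cols <- c(paste0("L", 0:j), if (j >= 1) "A0")
    df <- obs[at, cols, drop = FALSE]
    df$exposure <- obs[[paste0("A", j)]][at]
    df$wt <- obs$prob[at]
    fit_propensity(df, cols)
  })
  W <- ccident:::pp_weight_matrix(obs, maps)
  for (i in seq_len(nrow(obs))) {
    # window 0 factor
    p0 <- sum(obs$prob[obs$L0 == obs$L0[i] & obs$A0 == 1]) /
      sum(obs$prob[obs$L0 == obs$L0[i]])
    f0 <- if (obs$A0[i] == 1) 1 / p0 else 1 / (1 - p0)
    expect_equal(W[i, 1], f0, tolerance = 1e-12)
    if (obs$T[i] >= 1 && obs$A1[i] == obs$A0[i]) {
      sel <- obs$T >= 1 & obs$L0 == obs$L0[i] & obs$L1 == obs$L1[i] &
        obs$A0 == obs$A0[i]
      p1 <- sum(obs$prob[sel & obs$A1 == 1]) / sum(obs$prob[sel])
      f1 <- if (obs$A1[i] == 1) 1 / p1 else 1 / (1 - p1)
      expect_equal(W[i, 2], f0 * f1, tolerance = 1e-12)
    } else {
      expect_true(is.na(W[i, 2]))
    }
  }
})

test_that("weighting controls reconstructs each stratum total exactly", {
  # in the weighted control pseudopopulation, the exposed and unexposed
  # cells of every baseline stratum both recover the stratum mass
  s <- preset_dgp("confounded-binary")
  obs <- ccident:::observed_law(s)
  p <- vapply(sort(unique(obs$L0)), function(l) {
    sum(obs$prob[obs$L0 == l & obs$A0 == 1]) / sum(obs$prob[obs$L0 == l])
  }, numeric(1))
  W <- time_fixed_weight(obs$A0, p[obs$L0 + 1])
  for (l in sort(unique(obs$L0))) {
    tot <- sum(obs$prob[obs$L0 == l])
    expect_equal(sum((obs$prob * W)[obs$L0 == l & obs$A0 == 1]), tot,
                 tolerance = 1e-12)
    expect_equal(sum((obs$prob * W)[obs$L0 == l & obs$A0 == 0]), tot,
                 tolerance = 1e-12)
  }
})

test_that("weights collapse to a constant without confounding", {
  s <- validate_spec(dgp_spec(
    K = 2, init_L = c(0.5, 0.5),
    exposure_law = function(k, L, A, u) 0.35,     # ignores L entirely
    hazard_law = function(k, L, A, u) 0.1 * (1 + A[1]) * (1 + 0.5 * L[1]),
    freeze_exposure = TRUE))
  w <- evaluate_identifying_functional(s, "case-base")$estimate
  unw <- evaluate_identifying_functional(s, "case-base",
                                         weighted = FALSE)$estimate
  expect_equal(w, unw, tolerance = 1e-12)
})

test_that("censoring marks the first protocol deviation", {
  fx <- censor_at_deviation(figure1_fixture())
  expect_equal(fx$censor_time[1], 3)    # row 1 deviates before its event
  expect_true(fx$censor_time[1] < fx$T[1])
  expect_equal(fx$censor_time[6], 2)
  expect_true(all(is.na(fx$censor_time[c(2, 3, 4, 5, 7, 8, 9)])))
})
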