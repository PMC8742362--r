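test_that("spec validation rejects malformed models", {
  expect_error(dgp_spec(K = 0, init_L = c(1), exposure_law = function(...) 0.5,
                        hazard_law = function(...) 0.1),
               class = "cc_invalid_grid")
  bad_h <- dgp_spec(K = 2, init_L = c(0.5, 0.5),
                    exposure_law = function(k, L, A, u) 0.5,
                    hazard_law = function(k, L, A, u) 1.5)
  expect_error(validate_spec(bad_h), class = "cc_invalid_probability")
  bad_cov <- dgp_spec(K = 2, init_L = c(0.5, 0.5),
                      exposure_law = function(k, L, A, u) 0.5,
                      covariate_law = function(k, L, A, u) c(0.5, 0.4),
                      hazard_law = function(k, L, A, u) 0.1)
  expect_error(validate_spec(bad_cov), class = "cc_normalization_error")
  # presets are valid by construction
  expect_s3_class(validate_spec(preset_dgp("confounded-binary")),
                  "cc_dgp_spec")
})

test_that("enumeration normalizes to 1 for every preset", {
  for (nm in c("null", "confounded-binary", "confounded-homogeneous-RR",
               "confounded-homogeneous-OR", "hazard-homogeneous",
               "constant-hazard", "nonconstant-hazard", "tv-confounding",
               "tv-confounding-homogeneous", "unmeasured-U",
               "rare-outcome")) {
    at <- enumerate_trajectories(preset_dgp(nm))
    expect_lt(abs(sum(at$prob) - 1), 1e-12)
    # monotone outcomes: an event window, once assigned, is final by
    # construction; the at-risk convention must hold in the atom table
    K <- attr(at, "K")
    for (k in 1:(K - 1)) {
      gone <- at$T < k
      expect_true(all(is.na(at[[paste0("L", k)]][gone])))
      expect_true(all(is.na(at[[paste0("A", k)]][gone])))
      expect_true(all(!is.na(at[[paste0("A", k)]][!gone])))
    }
  }
})

test_that("enumerator matches an independently coded flat enumeration", {
  s <- validate_spec(toy_spec())
  expect_same_distribution(enumerate_trajectories(s), oracle_enumerate(s))
  s2 <- preset_dgp("unmeasured-U")  # exercises the U dimension
  expect_same_distribution(enumerate_trajectories(s2), oracle_enumerate(s2))
})

test_that("zero hazard yields an event-free cohort", {
  s <- dgp_spec(K = 2, init_L = c(0.5, 0.5),
                exposure_law = function(k, L, A, u) 0.5,
                hazard_law = function(k, L, A, u) 0)
  at <- enumerate_trajectories(s)
  expect_true(all(is.infinite(at$T)))
  co <- sample_cohort(s, 500, seed = 11)
  expect_true(all(is.infinite(co$T)))
})

test_that("enumeration cap raises a structured error", {
  s <- dgp_spec(K = 14, L_space = 0:3, init_L = rep(0.25, 4),
                exposure_law = function(k, L, A, u) 0.5,
                hazard_law = function(k, L, A, u) 0.1)
  expect_error(enumerate_trajectories(s, cap = 1e5),
               class = "cc_enumeration_too_large")
})

test_that("interventional distributions respect regime structure", {
  null <- preset_dgp("null")
  d1 <- interventional_distribution(null, "always")
  d0 <- interventional_distribution(null, "never")
  expect_equal(d1$risk, d0$risk, tolerance = 1e-12)
  expect_equal(d1$hazard, d0$hazard, tolerance = 1e-12)
  # frozen exposure: baseline-only and sustained interventions coincide
  frozen <- preset_dgp("constant-hazard")
  expect_equal(interventional_distribution(frozen, "set-A0-1")$risk,
               interventional_distribution(frozen, "always")$risk,
               tolerance = 1e-14)
  # g-formula oracle agreement on a confounded model with free switching
  cb <- preset_dgp("confounded-binary")
  for (rg in c("set-A0-1", "set-A0-0", "always", "never")) {
    expect_equal(interventional_distribution(cb, rg)$risk,
                 oracle_cf_risk(cb, rg), tolerance = 1e-12)
  }
  # conditioning on an impossible stratum errors
  expect_error(
    interventional_distribution(
      validate_spec(dgp_spec(K = 1, init_L = c(1, 0),
                             exposure_law = function(k, L, A, u) 0.5,
                             hazard_law = function(k, L, A, u) 0.2)),
      "always", conditioning = "L0")[["1"]],
    NA)  # absent stratum is simply not in the output
})

test_that("cohort simulation is seed-deterministic and law-consistent", {
  s <- preset_dgp("confounded-binary")
  a <- sample_cohort(s, 2000, seed = 42, attach_counterfactuals = TRUE)
  b <- sample_cohort(s, 2000, seed = 42, attach_counterfactuals = TRUE)
  expect_identical(a, b)
  expect_error(sample_cohort(s, 0, seed = 1), class = "cc_argument_error")

  # trajectory invariants: Y derived from T is monotone; at-risk convention
  K <- attr(a, "K")
  Y <- as.matrix(a[paste0("Y", 1:K)])
  expect_true(all(Y[, -1] - Y[, -K] >= 0))
  for (k in 1:(K - 1)) {
    expect_true(all(is.na(a[[paste0("A", k)]][a$T < k])))
    expect_true(all(!is.na(a[[paste0("A", k)]][a$T >= k])))
  }
})

test_that("counterfactual coupling satisfies consistency row-wise", {
  for (nm in c("confounded-binary", "tv-confounding")) {
    s <- preset_dgp(nm)
    co <- sample_cohort(s, 4000, seed = 7, attach_counterfactuals = TRUE)
    K <- attr(co, "K")
    A <- as.matrix(co[paste0("A", 0:(K - 1))])
    # observed path matches 'always' regime over at-risk windows
    all1 <- apply(A == 1 | is.na(A), 1, all) & !is.na(A[, 1]) & A[, 1] == 1
    expect_true(all(co$T[all1] == co$T_always[all1]))
    all0 <- apply(A == 0 | is.na(A), 1, all)
    expect_true(all(co$T[all0] == co$T_never[all0]))
    expect_true(all(co$T[A[, 1] == 1] == co$T_set1[A[, 1] == 1]))
    expect_true(all(co$T[A[, 1] == 0] == co$T_set0[A[, 1] == 0]))
    # counterfactual outcome sequences are monotone by construction
    expect_true(all(diff(t(counterfactual_Y(co, "always"))) >= 0))
  }
})

test_that("empirical hazards agree with enumeration at large n", {
  s <- preset_dgp("confounded-binary")
  n <- 50000
  co <- sample_cohort(s, n, seed = 123)
  at <- enumerate_trajectories(s)
  for (k in 0:(attr(co, "K") - 1)) {
    p_true <- sum(at$prob[at$T == k]) / sum(at$prob[at$T >= k])
    atrisk <- sum(co$T >= k)
    p_emp <- sum(co$T == k) / atrisk
    se <- sqrt(p_true * (1 - p_true) / atrisk)
    expect_lt(abs(p_emp - p_true), 3 * se)
  }
})

test_that("spec serialization round-trips the law exactly", {
  s <- validate_spec(toy_spec())
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_dgp_spec(s, path)
    s2 <- read_dgp_spec(path)
    expect_same_distribution(enumerate_trajectories(s),
                             enumerate_trajectories(s2))
    unlink(path)
  }
})

test_that("cohort CSV round-trip preserves trajectories", {
  s <- preset_dgp("confounded-binary")
  co <- sample_cohort(s, 200, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(co2$T, co$T)
  for (cc in grep("^[LAY]", names(co), value = TRUE)) {
    expect_equal(co2[[cc]], co[[cc]], ignore_attr = TRUE)
  }
  unlink(path)
})
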