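## Exact distribution-level evaluation of the identifying functionals: the
## same quantities each estimator targets, computed on the enumerated
## observed-data law with exact control-conditional propensities, exact
## eligible-set masses, and expected selection counts in place of realized
## draws. This is the surface on which identification (functional equals
## estimand) and its failure under assumption violations are verified.

## exact conditional exposure prevalence within a masked sub-law
exact_prev <- function(obs, mask, strat_key) {
  p <- numeric(0)
  for (s in unique(strat_key[mask])) {
    sel <- mask & strat_key == s
    m <- sum(obs$prob[sel])
    if (m <= 0) cc_stop("cc_zero_cell", "zero mass in stratum %s", s)
    p[s] <- sum(obs$prob[sel & obs$A0 == 1]) / m
  }
  p
}

mass_odds <- function(prob, a0, w, what) {
  m1 <- sum(prob[a0 == 1] * w[a0 == 1])
  m0 <- sum(prob[a0 == 0] * w[a0 == 0])
  if (m1 <= 0 || m0 <= 0) {
    cc_stop("cc_zero_cell", "zero weighted mass cell in %s", what)
  }
  m1 / m0
}

#' Evaluate an identifying functional at the distribution level
#'
#' Computes, exactly, the population functional that the corresponding
#' sample estimator targets under the chosen sampling scheme: expectations
#' over the enumerated observed-data law replace sample sums, exact
#' conditional probabilities replace fitted propensities, exact eligible-set
#' masses replace realized selections, and expected per-subject selection
#' counts (`m` times the case-hazard over the at-risk mass, summed over the
#' subject's eligible windows) replace the realized `n_selected`. Matched
#' variants integrate the exact pair probabilities `Pr(A_0 = x, A' = y)`
#' over the case law and the matched pool composition.
#'
#' Deliberately deficient variants are available as assumption-violation
#' witnesses: `controls_from = "survivor"` feeds survivor-only controls to
#' the case-base functional, and `weights = "time-fixed"` replaces the
#' per-protocol time-varying weights by their window-0 value.
#'
#' @param spec A [dgp_spec()].
#' @param scheme `"case-base"`, `"survivor"` or `"risk-set"`.
#' @param mode `"ITT"` or `"PP"` (risk-set only).
#' @param matched Evaluate the exact discordant-pair ratio instead of the
#'   unmatched functional?
#' @param m_per_case Controls per case assumed for risk-set selection counts
#'   (cancels from the functional; kept for interface symmetry).
#' @param conditioning For survivor sampling: `"L0"` (per-stratum odds
#'   ratio) or `"marginal"` (crude odds ratio, rare-disease use).
#' @param controls_from Override the control law (`"survivor"` under
#'   `scheme = "case-base"` reproduces the classical survivor-control
#'   mistake).
#' @param weighted Set `FALSE` for the crude (unweighted) case-base
#'   functional, a confounding-bias witness.
#' @param weights `"time-varying"` (correct per-protocol weights) or
#'   `"time-fixed"` (violation witness).
#' @param itt_weight_pool `"window0"` (literal weight derivation on
#'   window-0 controls) or `"pooled"` (all selection events).
#' @param sampling Risk-set selection device assumed for the expected
#'   selection counts: `"per-case"` (fixed number per qualifying case, so
#'   the per-eligible probability is proportional to the case hazard) or
#'   `"fraction"` (constant per-eligible probability by construction; its
#'   level cancels from the functional).
#' @param cap Enumeration cap.
#' @return A `cc_estimate` with `provenance = "distribution"`.
#' @export
evaluate_identifying_functional <- function(spec,
                                            scheme = c("case-base",
                                                       "survivor",
                                                       "risk-set"),
                                            mode = c("ITT", "PP"),
                                            matched = FALSE,
                                            m_per_case = 1,
                                            conditioning = c("L0", "marginal"),
                                            controls_from = NULL,
                                            weights = c("time-varying",
                                                        "time-fixed"),
                                            itt_weight_pool = c("window0",
                                                                "pooled"),
                                            sampling = c("per-case",
                                                         "fraction"),
                                            weighted = TRUE,
                                            cap = 1e7) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  conditioning <- match.arg(conditioning)
  weights <- match.arg(weights)
  itt_weight_pool <- match.arg(itt_weight_pool)
  sampling <- match.arg(sampling)
  if (scheme != "risk-set") mode <- "ITT"
  spec <- ensure_validated(spec, cap = cap)
  obs <- observed_law(spec, cap = cap)
  K <- attr(obs, "K")
  n_at <- nrow(obs)
  itt_case <- is.finite(obs$T)
  adh_T <- adherent_through(obs, ifelse(is.finite(obs$T), obs$T, NA))
  pp_case <- itt_case & adh_T
  l0key <- paste0("L0=", obs$L0)

  if (matched) {
    est <- matched_functional(spec, obs, scheme, mode, K)
    return(est)
  }

  if (scheme == "case-base") {
    cmask <- if (identical(controls_from, "survivor")) is.infinite(obs$T) else
      rep(TRUE, n_at)
    W <- if (weighted) {
      p <- exact_prev(obs, cmask, l0key)
      time_fixed_weight(obs$A0, unname(p[l0key]))
    } else rep(1, n_at)
    est <- mass_odds(obs$prob[itt_case], obs$A0[itt_case], W[itt_case],
                     "case cells") /
      mass_odds(obs$prob[cmask], obs$A0[cmask], W[cmask], "control cells")
    return(new_estimate("case-base", "ITT", "marginal-RR", est,
                        diagnostics = list(controls_from = controls_from %||%
                                             "case-base"),
                        provenance = "distribution"))
  }

  if (scheme == "survivor") {
    smask <- is.infinite(obs$T)
    if (conditioning == "marginal") {
      est <- mass_odds(obs$prob[itt_case], obs$A0[itt_case],
                       rep(1, sum(itt_case)), "case cells") /
        mass_odds(obs$prob[smask], obs$A0[smask], rep(1, sum(smask)),
                  "survivor cells")
      return(new_estimate("survivor", "ITT", "marginal-OR(rare-disease)",
                          est, diagnostics = list(),
                          provenance = "distribution"))
    }
    strata <- sort(unique(obs$L0))
    est <- vapply(strata, function(l) {
      sel <- obs$L0 == l
      mass_odds(obs$prob[itt_case & sel], obs$A0[itt_case & sel],
                rep(1, sum(itt_case & sel)), paste0("case cells L0=", l)) /
        mass_odds(obs$prob[smask & sel], obs$A0[smask & sel],
                  rep(1, sum(smask & sel)), paste0("survivor cells L0=", l))
    }, numeric(1))
    names(est) <- paste0("L0=", strata)
    return(new_estimate("survivor", "ITT", "conditional-OR-given-L0", est,
                        diagnostics = list(), provenance = "distribution"))
  }

  ## risk-set schemes
  r_k <- vapply(0:(K - 1), function(k) sum(obs$prob[obs$T >= k]), numeric(1))

  if (mode == "ITT") {
    q_k <- vapply(0:(K - 1), function(k) sum(obs$prob[obs$T == k]),
                  numeric(1))
    c_k <- if (sampling == "fraction") rep(1, K) else m_per_case * q_k / r_k
    # expected selection count: sum over the subject's at-risk windows
    Ensel <- rowSums(outer(obs$T, 0:(K - 1), ">=") *
                       matrix(c_k, n_at, K, byrow = TRUE))
    if (itt_weight_pool == "window0") {
      p <- exact_prev(obs, rep(TRUE, n_at), l0key)  # window-0 eligibles: all
    } else {
      obs_w <- obs; obs_w$prob <- obs$prob * Ensel
      p <- exact_prev(obs_w, Ensel > 0, l0key)
    }
    W <- time_fixed_weight(obs$A0, unname(p[l0key]))
    est <- mass_odds(obs$prob[itt_case], obs$A0[itt_case], W[itt_case],
                     "case cells") /
      mass_odds(obs$prob, obs$A0, W * Ensel, "control cells")
    return(new_estimate("risk-set", "ITT", "marginal-HR-ITT", est,
                        diagnostics = list(sampling_fractions = c_k,
                                           weight_pool = itt_weight_pool),
                        provenance = "distribution"))
  }

  ## risk-set PP
  adh_k <- vapply(0:(K - 1), function(k)
    at_risk_at(obs$T, k) & adherent_through(obs, rep(k, n_at)),
    logical(n_at))
  adh_k <- matrix(adh_k, n_at, K)
  q_k <- vapply(0:(K - 1), function(k)
    sum(obs$prob[obs$T == k & adh_k[, k + 1]]), numeric(1))
  c_k <- if (sampling == "fraction") rep(1, K) else m_per_case * q_k / r_k
  # exact per-window propensities Pr(A_j=1 | L_0..L_j, A_0..A_{j-1}, Y_j=0)
  Wm <- matrix(NA_real_, n_at, K)
  run <- rep(1, n_at)
  for (j in 0:(K - 1)) {
    at <- at_risk_at(obs$T, j)
    hkey <- do.call(paste, c(obs[c(paste0("L", 0:j),
                                   if (j >= 1) paste0("A", 0:(j - 1)))],
                             sep = "|"))
    pj <- exact_prev_on(obs, at, hkey, col = paste0("A", j))
    use <- adh_k[, j + 1]
    Aj <- obs[[paste0("A", j)]]
    run[use] <- run[use] * (Aj[use] / pj[hkey[use]] +
                              (1 - Aj[use]) / (1 - pj[hkey[use]]))
    Wm[use, j + 1] <- run[use]
  }
  if (weights == "time-fixed" && K > 1) {
    for (j in 1:(K - 1)) Wm[!is.na(Wm[, j + 1]), j + 1] <-
        Wm[!is.na(Wm[, j + 1]), 1]
  }
  w_case <- Wm[cbind(seq_len(n_at), pmin(obs$T, K - 1) + 1)]
  ctl_w <- rowSums(sweep(ifelse(is.na(Wm), 0, Wm) *
                           (adh_k * 1), 2, c_k, `*`))
  est <- mass_odds(obs$prob[pp_case], obs$A0[pp_case], w_case[pp_case],
                   "case cells") /
    mass_odds(obs$prob, obs$A0, ctl_w, "control cells")
  new_estimate("risk-set", "PP", "marginal-HR-PP", est,
               diagnostics = list(sampling_fractions = c_k,
                                  weights = weights),
               provenance = "distribution")
}

## exposure prevalence of an arbitrary 0/1 column within strata of a mask
exact_prev_on <- function(obs, mask, strat_key, col) {
  p <- numeric(0)
  x <- obs[[col]]
  for (s in unique(strat_key[mask])) {
    sel <- mask & strat_key == s
    m <- sum(obs$prob[sel])
    if (m <= 0) cc_stop("cc_zero_cell", "zero mass in stratum %s", s)
    p[s] <- sum(obs$prob[sel & x == 1]) / m
  }
  p
}

## Exact matched discordant-pair functional: integrates pair probabilities
## over the case law and the pool's exposure prevalence.
matched_functional <- function(spec, obs, scheme, mode, K) {
  n_at <- nrow(obs)
  itt_case <- is.finite(obs$T)
  adh_T <- adherent_through(obs, ifelse(is.finite(obs$T), obs$T, NA))
  case_mask <- if (scheme == "risk-set" && mode == "PP")
    itt_case & adh_T else itt_case

  if (scheme %in% c("case-base", "survivor")) {
    pool_mask <- if (scheme == "survivor") is.infinite(obs$T) else
      rep(TRUE, n_at)
    key <- paste0("L0=", obs$L0)
    p <- exact_prev(obs, pool_mask, key)
    pa <- unname(p[key])
  } else {
    # per event-window pools
    pa <- rep(NA_real_, n_at)
    for (k in sort(unique(obs$T[case_mask & is.finite(obs$T)]))) {
      if (mode == "ITT") {
        pool_mask <- at_risk_at(obs$T, k)
        key <- paste0("L0=", obs$L0)
      } else {
        pool_mask <- at_risk_at(obs$T, k) &
          adherent_through(obs, rep(k, n_at))
        key <- do.call(paste, c(obs[paste0("L", 0:k)], sep = ","))
      }
      p <- exact_prev(obs, pool_mask, key)
      sel <- case_mask & obs$T == k
      pa[sel] <- unname(p[key[sel]])
    }
  }
  m10 <- sum(obs$prob[case_mask & obs$A0 == 1] *
               (1 - pa[case_mask & obs$A0 == 1]))
  m01 <- sum(obs$prob[case_mask & obs$A0 == 0] *
               pa[case_mask & obs$A0 == 0])
  if (m01 <= 0) {
    cc_stop("cc_zero_cell", "zero (0,1) discordant-pair mass")
  }
  kind <- switch(paste(scheme, mode),
                 "case-base ITT" = "marginal-RR",
                 "survivor ITT" = "conditional-OR-given-L0",
                 "risk-set ITT" = "conditional-HR-given-L0",
                 "risk-set PP" = "conditional-HR-given-history")
  new_estimate(scheme, mode, kind, m10 / m01,
               diagnostics = list(matched = TRUE,
                                  pair_mass = c(m10 = m10, m01 = m01)),
               provenance = "distribution")
}
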