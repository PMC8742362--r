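## Sample-level identification-strategy estimators: every scheme compares
## cases with controls through a (possibly weighted) baseline-exposure odds
## ratio, even when the target estimand is a risk or hazard ratio.

new_estimate <- function(scheme, mode, estimand, estimate, diagnostics,
                         provenance = "sample") {
  structure(list(scheme = scheme, mode = mode, estimand = estimand,
                 estimate = estimate, diagnostics = diagnostics,
                 provenance = provenance),
            class = "cc_estimate")
}

#' @export
print.cc_estimate <- function(x, ...) {
  cat("<cc_estimate>", x$scheme, x$mode, "->", x$estimand,
      sprintf("[%s]", x$provenance), "\n")
  print(x$estimate)
  invisible(x)
}

#' Weighted odds of exposure in a subject set
#'
#' `sum(w * I(A = 1)) / sum(w * I(A = 0))`.
#'
#' @param exposure 0/1 exposure values.
#' @param weights Positive weights (default all 1).
#' @return The weighted exposure odds (scalar).
#' @export
weighted_exposure_odds <- function(exposure, weights = rep(1, length(exposure))) {
  w1 <- sum(weights[exposure == 1])
  w0 <- sum(weights[exposure == 0])
  if (w1 <= 0 || w0 <= 0) {
    cc_stop("cc_zero_cell", "zero weighted cell: exposed = %g, unexposed = %g",
            w1, w0)
  }
  w1 / w0
}

check_selection <- function(selection, scheme, mode = NULL) {
  if (!inherits(selection, "cc_selection") || selection$scheme != scheme) {
    cc_stop("cc_argument_error", "selection is not a %s selection", scheme)
  }
  if (!is.null(mode) && selection$mode != mode) {
    cc_stop("cc_argument_error", "selection mode %s, expected %s",
            selection$mode, mode)
  }
}

#' Case-base estimator of the marginal risk ratio
#'
#' Derives time-fixed IP weights from the selected controls' baseline
#' covariate/exposure data (saturated propensity on `L_0` unless a fitted
#' map is supplied), then takes the ratio of the `W`-weighted baseline
#' exposure odds among intention-to-treat cases to the `W`-weighted odds
#' among controls.
#'
#' @param cohort A `cc_cohort`.
#' @param selection A case-base `cc_selection`.
#' @param propensity Optional `cc_propensity` (must be fitted on control
#'   data); fitted from the selection when `NULL`.
#' @param weighted Set `FALSE` for the unweighted (crude) exposure-odds
#'   ratio, e.g. to exhibit confounding bias.
#' @return A `cc_estimate` targeting the marginal risk ratio.
#' @export
estimate_case_base_rr <- function(cohort, selection, propensity = NULL,
                                  weighted = TRUE) {
  check_selection(selection, "case-base")
  ctl <- which(selection$S == 1L)
  if (is.null(propensity) && weighted) {
    propensity <- fit_propensity(
      data.frame(exposure = cohort$A0[ctl], L0 = cohort$L0[ctl]), "L0")
  }
  cases <- match(qualify_cases(cohort, "ITT")$subject_id, cohort$subject_id)
  wgt <- function(idx) {
    if (!weighted) return(rep(1, length(idx)))
    time_fixed_weight(cohort$A0[idx],
                      propensity_value(propensity, cohort[idx, , drop = FALSE]))
  }
  w_case <- wgt(cases); w_ctl <- wgt(ctl)
  est <- weighted_exposure_odds(cohort$A0[cases], w_case) /
    weighted_exposure_odds(cohort$A0[ctl], w_ctl)
  new_estimate("case-base", "ITT", "marginal-RR", est, diagnostics = list(
    n_cases = length(cases), n_controls = length(ctl),
    weighted_cells = c(case1 = sum(w_case[cohort$A0[cases] == 1]),
                       case0 = sum(w_case[cohort$A0[cases] == 0]),
                       ctl1 = sum(w_ctl[cohort$A0[ctl] == 1]),
                       ctl0 = sum(w_ctl[cohort$A0[ctl] == 0]))))
}

#' Survivor-sampling estimator of the conditional odds ratio
#'
#' Per baseline-covariate stratum, the ratio of the (unweighted) baseline
#' exposure odds among intention-to-treat cases to the odds among selected
#' survivor controls. The unstratified (`"marginal"`) variant is the crude
#' exposure-odds ratio, which approximates the marginal risk ratio only
#' under the rare-disease assumption.
#'
#' @param cohort A `cc_cohort`.
#' @param selection A survivor `cc_selection`.
#' @param conditioning `"L0"` (default) or `"marginal"`.
#' @return A `cc_estimate`; per-stratum values are a named vector, with
#'   zero-cell strata `NA` and the reason recorded in the diagnostics.
#' @export
estimate_survivor_or <- function(cohort, selection,
                                 conditioning = c("L0", "marginal")) {
  conditioning <- match.arg(conditioning)
  check_selection(selection, "survivor")
  ctl <- which(selection$S == 1L)
  cases <- match(qualify_cases(cohort, "ITT")$subject_id, cohort$subject_id)
  if (conditioning == "marginal") {
    est <- weighted_exposure_odds(cohort$A0[cases]) /
      weighted_exposure_odds(cohort$A0[ctl])
    return(new_estimate("survivor", "ITT", "marginal-OR(rare-disease)", est,
                        diagnostics = list(n_cases = length(cases),
                                           n_controls = length(ctl))))
  }
  strata <- sort(unique(cohort$L0[c(cases, ctl)]))
  undefined <- character(0)
  est <- vapply(strata, function(l) {
    ca <- cases[cohort$L0[cases] == l]
    co <- ctl[cohort$L0[ctl] == l]
    tryCatch(weighted_exposure_odds(cohort$A0[ca]) /
               weighted_exposure_odds(cohort$A0[co]),
             cc_zero_cell = function(e) {
               undefined <<- c(undefined, as.character(l))
               NA_real_
             })
  }, numeric(1))
  names(est) <- paste0("L0=", strata)
  new_estimate("survivor", "ITT", "conditional-OR-given-L0", est,
               diagnostics = list(n_cases = length(cases),
                                  n_controls = length(ctl),
                                  undefined_strata = undefined))
}

#' Risk-set estimator of the marginal hazard ratio (intention-to-treat)
#'
#' Weights are the time-fixed IP weights with the propensity fitted on
#' window-0 selected controls (the literal reading of deriving the weights
#' with the selection indicator replaced by `S_0`); `pool_controls = TRUE`
#' fits instead on all selection events pooled across windows, a documented
#' practical variant. The estimate is the `W`-weighted baseline exposure
#' odds among cases over the exposure odds among ever-selected controls,
#' each control weighted by `W` times its selection count.
#'
#' @param cohort A `cc_cohort`.
#' @param selection A risk-set `cc_selection` with `mode = "ITT"`.
#' @param propensity Optional pre-fitted `cc_propensity` on `L0`.
#' @param pool_controls Pool control records across windows when fitting.
#' @return A `cc_estimate` targeting the marginal hazard ratio.
#' @export
estimate_risk_set_hr_itt <- function(cohort, selection, propensity = NULL,
                                     pool_controls = FALSE) {
  check_selection(selection, "risk-set", "ITT")
  times <- selection$times
  if (is.null(propensity)) {
    wt <- if (pool_controls) selection$n_selected else times[, 1]
    idx <- which(wt > 0)
    if (!length(idx)) {
      cc_stop("cc_positivity_violation",
              "no window-0 control selections to fit the propensity on; consider pool_controls = TRUE")
    }
    propensity <- fit_propensity(
      data.frame(exposure = cohort$A0[idx], L0 = cohort$L0[idx],
                 wt = wt[idx]), "L0")
  }
  cases <- match(qualify_cases(cohort, "ITT")$subject_id, cohort$subject_id)
  ctl <- which(selection$n_selected > 0)
  w_case <- time_fixed_weight(cohort$A0[cases],
                              propensity_value(propensity,
                                               cohort[cases, , drop = FALSE]))
  w_ctl <- time_fixed_weight(cohort$A0[ctl],
                             propensity_value(propensity,
                                              cohort[ctl, , drop = FALSE])) *
    selection$n_selected[ctl]
  est <- weighted_exposure_odds(cohort$A0[cases], w_case) /
    weighted_exposure_odds(cohort$A0[ctl], w_ctl)
  new_estimate("risk-set", "ITT", "marginal-HR-ITT", est, diagnostics = list(
    n_cases = length(cases), n_controls = length(ctl),
    selections = sum(selection$n_selected),
    sampling_fractions = selection$sampling_fractions))
}

## Cumulative time-varying weight matrix W[i, k+1] for windows where subject
## i is at risk and protocol-adherent; NA elsewhere. pmaps is a list of
## cc_propensity, one per window.
pp_weight_matrix <- function(cohort, pmaps) {
  K <- cohort_K(cohort)
  n <- nrow(cohort)
  W <- matrix(NA_real_, n, K)
  run <- rep(1, n)
  for (j in 0:(K - 1)) {
    at <- at_risk_at(cohort$T, j) &
      adherent_through(cohort, rep(j, n))
    if (!any(at)) break
    cols <- c(paste0("L", 0:j), if (j >= 1) paste0("A", 0:(j - 1)))
    p <- propensity_value(pmaps[[j + 1L]], cohort[at, cols, drop = FALSE])
    Aj <- cohort[[paste0("A", j)]][at]
    run[at] <- run[at] * (Aj / p + (1 - Aj) / (1 - p))
    W[at, j + 1L] <- run[at]
  }
  W
}

#' Risk-set estimator of the per-protocol hazard ratio
#'
#' Fits per-window saturated propensities on window-`j` selected controls
#' (conditioning on covariate history `L_0..L_j` and exposure history
#' `A_0..A_{j-1}`), builds the telescoping time-varying weights for cases
#' and controls alike, censors everyone from the first protocol deviation,
#' and returns the ratio of the baseline exposure odds among per-protocol
#' cases (each weighted by `W_k` of its event window) to the odds among
#' controls (each weighted by its weighted selection count
#' `sum_k W_k S_k` over uncensored windows).
#'
#' @param cohort A `cc_cohort`.
#' @param selection A risk-set `cc_selection` with `mode = "PP"`.
#' @param propensities Optional list of `cc_propensity`, one per window.
#' @param time_fixed_only Use `W_0` in place of `W_k` at every window (a
#'   deliberately deficient variant that ignores time-varying confounding).
#' @return A `cc_estimate` targeting the sustained-regime hazard ratio.
#' @export
estimate_risk_set_hr_pp <- function(cohort, selection, propensities = NULL,
                                    time_fixed_only = FALSE) {
  check_selection(selection, "risk-set", "PP")
  K <- cohort_K(cohort)
  times <- selection$times
  if (is.null(propensities)) {
    propensities <- lapply(0:(K - 1), function(j) {
      idx <- which(times[, j + 1] > 0)
      if (!length(idx)) return(NULL)
      cols <- c(paste0("L", 0:j), if (j >= 1) paste0("A", 0:(j - 1)))
      df <- cohort[idx, cols, drop = FALSE]
      df$exposure <- cohort[[paste0("A", j)]][idx]
      df$wt <- times[idx, j + 1]
      fit_propensity(df, cols)
    })
    if (any(vapply(propensities, is.null, logical(1)))) {
      cc_stop("cc_positivity_violation",
              "some window has no control selections to fit its propensity on")
    }
  }
  W <- pp_weight_matrix(cohort, propensities)
  if (time_fixed_only && K > 1) {
    for (j in 1:(K - 1)) W[!is.na(W[, j + 1L]), j + 1L] <-
        W[!is.na(W[, j + 1L]), 1L]
  }
  cases <- qualify_cases(cohort, "PP")
  cidx <- match(cases$subject_id, cohort$subject_id)
  w_case <- W[cbind(cidx, cases$event_window + 1L)]
  # controls: weighted selection count, censored/post-event windows drop out
  wsum <- rowSums(ifelse(is.na(W), 0, W) * times)
  ctl <- which(selection$n_selected > 0)
  est <- weighted_exposure_odds(cohort$A0[cidx], w_case) /
    weighted_exposure_odds(cohort$A0[ctl], wsum[ctl])
  new_estimate("risk-set", "PP", "marginal-HR-PP", est, diagnostics = list(
    n_cases = length(cidx), n_controls = length(ctl),
    selections = sum(selection$n_selected),
    selections_censored = sum(times[is.na(W) & times > 0])))
}

#' Matched discordant-pair ratio
#'
#' The ratio of the number of discordant case-control pairs with
#' `(A_0, A') = (1, 0)` to those with `(0, 1)`; concordant pairs are counted
#' in the diagnostics but never used. With zero pairs in the denominator
#' orientation the estimate is structurally undefined (`NA` with the reason
#' recorded), not continuity-corrected, unless `correct = TRUE` adds 0.5 to
#' both discordant cells (a finite-sample device, off by default).
#'
#' @param matched A `cc_matched` (or any data frame with `case_exposure`
#'   and `control_exposure` columns).
#' @param correct Apply a 0.5 continuity correction to the discordant cells?
#' @return A `cc_estimate` whose diagnostics carry the 2x2 pair counts.
#' @export
estimate_matched_ratio <- function(matched, correct = FALSE) {
  n10 <- sum(matched$case_exposure == 1 & matched$control_exposure == 0)
  n01 <- sum(matched$case_exposure == 0 & matched$control_exposure == 1)
  n11 <- sum(matched$case_exposure == 1 & matched$control_exposure == 1)
  n00 <- sum(matched$case_exposure == 0 & matched$control_exposure == 0)
  reason <- NULL
  if (correct) {
    est <- (n10 + 0.5) / (n01 + 0.5)
  } else if (n10 + n01 == 0) {
    est <- NA_real_; reason <- "no discordant pairs"
  } else if (n01 == 0) {
    est <- NA_real_; reason <- "no (0,1) discordant pairs"
  } else {
    est <- n10 / n01
  }
  new_estimate(attr(matched, "scheme") %||% "matched",
               attr(matched, "mode") %||% "ITT",
               "discordant-pair-ratio", est,
               diagnostics = list(pairs = c(n10 = n10, n01 = n01,
                                            n11 = n11, n00 = n00),
                                  dropped = attr(matched, "dropped"),
                                  reason = reason))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
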