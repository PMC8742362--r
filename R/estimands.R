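## Ground-truth causal estimands, computed by exact enumeration of the
## intervened model (never by simulation), plus checks of the structural
## side-conditions (constant hazards, effect homogeneity) that some
## identification results require.

new_estimand <- function(kind, value, window = NULL, meta = NULL) {
  structure(list(kind = kind, value = value, window = window, meta = meta),
            class = "cc_estimand")
}

#' @export
print.cc_estimand <- function(x, ...) {
  cat("<cc_estimand>", x$kind, "\n")
  print(x$value)
  invisible(x)
}

#' True marginal risk ratio of the intention-to-treat contrast
#'
#' `Pr(Y_K(1) = 1) / Pr(Y_K(0) = 1)` under the interventions that set
#' baseline exposure `A_0` to 1 versus 0, computed by exact enumeration.
#'
#' @param spec A [dgp_spec()].
#' @return A `cc_estimand` of kind `"marginal-RR"`.
#' @export
true_marginal_risk_ratio <- function(spec) {
  r1 <- interventional_distribution(spec, "set-A0-1")$risk
  r0 <- interventional_distribution(spec, "set-A0-0")$risk
  K <- length(r1)
  if (r0[K] <= 0) {
    cc_stop("cc_undefined_estimand",
            "Pr(Y_K(0)=1) = 0: marginal risk ratio undefined")
  }
  new_estimand("marginal-RR", r1[K] / r0[K],
               meta = list(regimes = c("set-A0-1", "set-A0-0")))
}

#' True conditional odds ratio given baseline covariates
#'
#' `Odds(Y_K(1) = 1 | L_0 = l) / Odds(Y_K(0) = 1 | L_0 = l)` per stratum `l`,
#' by exact enumeration. A stratum whose counterfactual outcome probability
#' is 0 or 1 under either regime makes the odds ratio undefined there and
#' raises an error rather than returning infinities.
#'
#' @param spec A [dgp_spec()].
#' @return A `cc_estimand` of kind `"conditional-OR-given-L0"` whose value is
#'   a named vector (one element per `L_0` stratum).
#' @export
true_conditional_odds_ratio <- function(spec) {
  d1 <- interventional_distribution(spec, "set-A0-1", conditioning = "L0")
  d0 <- interventional_distribution(spec, "set-A0-0", conditioning = "L0")
  K <- length(d1[[1]]$risk)
  strata <- names(d1)
  val <- vapply(strata, function(s) {
    p1 <- d1[[s]]$risk[K]; p0 <- d0[[s]]$risk[K]
    if (p1 <= 0 || p1 >= 1 || p0 <= 0 || p0 >= 1) {
      cc_stop("cc_undefined_estimand",
              "outcome probability 0 or 1 in stratum L0=%s", s)
    }
    (p1 / (1 - p1)) / (p0 / (1 - p0))
  }, numeric(1))
  new_estimand("conditional-OR-given-L0", val,
               meta = list(regimes = c("set-A0-1", "set-A0-0")))
}

#' True marginal odds ratio of the intention-to-treat contrast
#'
#' `Odds(Y_K(1) = 1) / Odds(Y_K(0) = 1)`. Computable from the model, but not
#' identified by survivor sampling; it approximates the marginal risk ratio
#' only when the outcome is rare (rare-disease assumption).
#'
#' @param spec A [dgp_spec()].
#' @return A `cc_estimand` of kind `"marginal-OR"` with
#'   `meta$identified_by_survivor_sampling = FALSE`.
#' @export
true_marginal_odds_ratio <- function(spec) {
  r1 <- interventional_distribution(spec, "set-A0-1")$risk
  r0 <- interventional_distribution(spec, "set-A0-0")$risk
  K <- length(r1)
  if (r0[K] <= 0 || r0[K] >= 1 || r1[K] >= 1) {
    cc_stop("cc_undefined_estimand", "marginal odds ratio undefined")
  }
  new_estimand("marginal-OR", (r1[K] / (1 - r1[K])) / (r0[K] / (1 - r0[K])),
               meta = list(identified_by_survivor_sampling = FALSE))
}

regime_pair_names <- function(regime_pair) {
  switch(regime_pair,
         baseline = c("set-A0-1", "set-A0-0"),
         sustained = c("always", "never"))
}

#' True discrete-time hazard ratios
#'
#' Per-window ratio of counterfactual hazards under a regime pair:
#' the baseline pair (`set A_0 = 1` vs `set A_0 = 0`, intention-to-treat) or
#' the sustained pair (always vs never exposed, per-protocol). Conditioning
#' `"marginal"` and `"L0"` enumerate the intervened model directly;
#' `"history"` returns, per window and covariate history, the hazard ratio
#' among protocol-adherent subjects, which equals the counterfactual
#' conditional hazard ratio by consistency.
#'
#' @param spec A [dgp_spec()].
#' @param regime_pair `"baseline"` or `"sustained"`.
#' @param conditioning `"marginal"`, `"L0"` or `"history"`.
#' @return A `cc_estimand`; value is a vector over windows (`"marginal"`), a
#'   strata-by-window matrix (`"L0"`), or a data frame with one row per
#'   (window, history) stratum (`"history"`). Windows with an empty
#'   counterfactual risk set are `NA` and flagged in `meta$undefined`.
#' @export
true_hazard_ratio <- function(spec,
                              regime_pair = c("baseline", "sustained"),
                              conditioning = c("marginal", "L0", "history")) {
  regime_pair <- match.arg(regime_pair)
  conditioning <- match.arg(conditioning)
  rgs <- regime_pair_names(regime_pair)
  kind <- switch(conditioning,
                 marginal = if (regime_pair == "baseline")
                   "marginal-HR-ITT" else "marginal-HR-PP",
                 L0 = "conditional-HR-given-L0",
                 history = "conditional-HR-given-history")

  if (conditioning == "marginal") {
    h1 <- interventional_distribution(spec, rgs[1])$hazard
    h0 <- interventional_distribution(spec, rgs[2])$hazard
    val <- h1 / h0
    return(new_estimand(kind, val, window = seq_along(val) - 1L,
                        meta = list(regimes = rgs,
                                    undefined = which(!is.finite(val)) - 1L)))
  }
  if (conditioning == "L0") {
    d1 <- interventional_distribution(spec, rgs[1], conditioning = "L0")
    d0 <- interventional_distribution(spec, rgs[2], conditioning = "L0")
    K <- length(d1[[1]]$hazard)
    val <- matrix(NA_real_, length(d1), K,
                  dimnames = list(names(d1), paste0("k", 0:(K - 1))))
    for (s in names(d1)) val[s, ] <- d1[[s]]$hazard / d0[[s]]$hazard
    return(new_estimand(kind, val, meta = list(regimes = rgs)))
  }
  # history: observed hazards among adherent subjects, by consistency
  spec <- ensure_validated(spec)
  obs <- observed_law(spec)
  K <- attr(obs, "K")
  Lcols <- paste0("L", 0:(K - 1))
  rows <- list()
  for (k in 0:(K - 1)) {
    sub <- obs[at_risk_at(obs$T, k) & adherent_through(obs, rep(k, nrow(obs))),
               , drop = FALSE]
    pathkey <- do.call(paste, c(sub[Lcols[1:(k + 1)]], sep = ","))
    for (pk in unique(pathkey)) {
      d <- sub[pathkey == pk, , drop = FALSE]
      hz <- vapply(0:1, function(a) {
        da <- d[d$A0 == a, , drop = FALSE]
        if (!nrow(da) || sum(da$prob) <= 0) return(NA_real_)
        sum(da$prob[da$T == k]) / sum(da$prob)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        window = k, history = pk, hazard1 = hz[2], hazard0 = hz[1],
        ratio = hz[2] / hz[1])
    }
  }
  val <- do.call(rbind, rows)
  new_estimand(kind, val, meta = list(regimes = rgs, via = "consistency"))
}

#' Check constancy of counterfactual hazards across windows
#'
#' Some risk-set identification results require the counterfactual hazards in
#' the numerator and denominator of the causal hazard ratio to be constant
#' across time windows. This verifies the condition by enumeration.
#'
#' @param spec A [dgp_spec()].
#' @param regime_pair `"baseline"` or `"sustained"`.
#' @param tol Maximum tolerated absolute deviation across windows.
#' @return List with `holds` and `max_abs_deviation` (over both regimes).
#' @export
check_constant_hazards <- function(spec,
                                   regime_pair = c("baseline", "sustained"),
                                   tol = 1e-10) {
  regime_pair <- match.arg(regime_pair)
  rgs <- regime_pair_names(regime_pair)
  dev <- vapply(rgs, function(rg) {
    h <- interventional_distribution(spec, rg)$hazard
    h <- h[is.finite(h)]
    if (length(h) <= 1L) 0 else max(abs(h - h[1]))
  }, numeric(1))
  list(holds = max(dev) < tol, max_abs_deviation = max(dev),
       regimes = rgs, deviation_by_regime = dev)
}

#' Check effect homogeneity across covariate strata on the observed law
#'
#' Verifies the side-conditions of the matched-design identification results:
#' constancy across baseline-covariate strata of the factual risk ratio
#' (`"risk-ratio"`), odds ratio (`"odds-ratio"`), per-window hazard ratio
#' across windows and strata (`"hazard-ratio"`), or the adherent-stratum
#' hazard ratio across windows and covariate histories
#' (`"hazard-ratio-history"`). Strata with a zero denominator are excluded
#' with a warning.
#'
#' @param spec A [dgp_spec()].
#' @param scale Homogeneity scale to check.
#' @param tol Maximum tolerated absolute deviation between stratum ratios.
#' @return List with `holds`, `max_abs_deviation`, and the per-stratum
#'   `values`.
#' @export
check_effect_homogeneity <- function(spec,
                                     scale = c("risk-ratio", "odds-ratio",
                                               "hazard-ratio",
                                               "hazard-ratio-history"),
                                     tol = 1e-10) {
  scale <- match.arg(scale)
  spec <- ensure_validated(spec)
  obs <- observed_law(spec)
  K <- attr(obs, "K")

  if (scale %in% c("risk-ratio", "odds-ratio")) {
    vals <- c()
    for (l in sort(unique(obs$L0))) {
      p <- vapply(0:1, function(a) {
        sel <- obs$L0 == l & obs$A0 == a
        m <- sum(obs$prob[sel])
        if (m <= 0) return(NA_real_)
        sum(obs$prob[sel & obs$T < K]) / m
      }, numeric(1))
      if (any(is.na(p)) || p[1] <= 0 ||
          (scale == "odds-ratio" && (p[1] >= 1 || p[2] >= 1))) {
        cc_warn("cc_zero_cell_warning",
                "stratum L0=%s excluded from homogeneity check", l)
        next
      }
      r <- if (scale == "risk-ratio") p[2] / p[1] else
        (p[2] / (1 - p[2])) / (p[1] / (1 - p[1]))
      vals <- c(vals, stats::setNames(r, paste0("L0=", l)))
    }
  } else if (scale == "hazard-ratio") {
    vals <- c()
    for (k in 0:(K - 1)) {
      for (l in sort(unique(obs$L0))) {
        h <- vapply(0:1, function(a) {
          sel <- obs$L0 == l & obs$A0 == a & at_risk_at(obs$T, k)
          m <- sum(obs$prob[sel])
          if (m <= 0) return(NA_real_)
          sum(obs$prob[sel & obs$T == k]) / m
        }, numeric(1))
        if (any(is.na(h)) || h[1] <= 0) {
          cc_warn("cc_zero_cell_warning",
                  "cell (k=%d, L0=%s) excluded from homogeneity check", k, l)
          next
        }
        vals <- c(vals, stats::setNames(h[2] / h[1],
                                        paste0("k", k, ":L0=", l)))
      }
    }
  } else {
    hist <- true_hazard_ratio(spec, "sustained", conditioning = "history")
    ok <- is.finite(hist$value$ratio)
    if (!all(ok)) {
      cc_warn("cc_zero_cell_warning",
              "%d (window, history) cells excluded from homogeneity check",
              sum(!ok))
    }
    vals <- stats::setNames(hist$value$ratio[ok],
                            paste0("k", hist$value$window[ok], ":L=",
                                   hist$value$history[ok]))
  }
  if (!length(vals)) {
    return(list(holds = TRUE, max_abs_deviation = 0, values = vals,
                note = "no usable strata: vacuously homogeneous"))
  }
  dev <- max(abs(vals - vals[1]))
  list(holds = dev < tol, max_abs_deviation = dev, values = vals)
}
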