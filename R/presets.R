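## Preset cohort models. Each preset is engineered to satisfy (or break)
## the assumption set of one or more identification results, and its
## documentation says which. Numerical hazard calibrations are solved at
## construction time with small per-window linear systems; see the methods
## vignette for the reasoning.

## Calibrated hazard table for a frozen-exposure, time-fixed-covariate model
## in which the marginal counterfactual hazards under both baseline regimes
## AND the observed marginal hazard are constant across windows. With
## covariate-dependent hazards such constancy never holds for free
## (depletion of susceptibles), so the per-window levels are solved for:
## exposed-arm levels from the counterfactual-1 constraint (fixing the
## within-arm covariate ratio `rho`), unexposed-arm levels from the joint
## counterfactual-0 / observed-hazard constraints (2x2 solve).
calibrate_constant_hazard <- function(K, piL, e1, H1, H0, rho) {
  h <- array(NA_real_, c(K, 2, 2))          # [k, a+1, l-index]
  S1 <- c(1, 1); S0 <- c(1, 1)
  m <- rbind(piL * (1 - e1), piL * e1)      # observed at-risk mass [a+1, l]
  Hobs <- NA_real_
  for (k in seq_len(K)) {
    P1 <- piL * S1 / sum(piL * S1)
    x10 <- H1 / (P1[1] + rho * P1[2]); x11 <- rho * x10
    P0 <- piL * S0 / sum(piL * S0)
    if (k == 1) {
      x00 <- H0 / (P0[1] + rho * P0[2]); x01 <- rho * x00
      Hobs <- (m[2, 1] * x10 + m[2, 2] * x11 +
                 m[1, 1] * x00 + m[1, 2] * x01) / sum(m)
    } else {
      rhs <- c(H0, Hobs * sum(m) - m[2, 1] * x10 - m[2, 2] * x11)
      A <- rbind(P0, m[1, ])
      sol <- solve(A, rhs)
      x00 <- sol[1]; x01 <- sol[2]
    }
    x <- c(x00, x01, x10, x11)
    if (any(x <= 0) || any(x >= 1)) {
      cc_stop("cc_invalid_probability",
              "constant-hazard calibration left (0,1) at window %d", k - 1)
    }
    h[k, 1, ] <- c(x00, x01); h[k, 2, ] <- c(x10, x11)
    S1 <- S1 * (1 - c(x10, x11)); S0 <- S0 * (1 - c(x00, x01))
    m[2, ] <- m[2, ] * (1 - c(x10, x11))
    m[1, ] <- m[1, ] * (1 - c(x00, x01))
  }
  list(h = h, Hobs = Hobs)
}

## Shared scaffolding for the two-window time-varying-confounding presets:
## L_1 depends on A_0, and drives both A_1 (through the stay probability)
## and the window-1 hazard.
## cell masses kept away from zero so that saturated propensity fitting on
## sampled controls is stable at moderate cohort sizes
tv_scaffold <- local({
  Ls <- 0:2
  list(
    Ls = Ls,
    piL = c(0.35, 0.35, 0.30),
    e1 = 0.30 + 0.15 * Ls,                   # Pr(A_0=1 | L_0)
    covP = function(l0, a0) {                # L_1 | L_0, tilted up under
      p <- rbind(c(0.50, 0.30, 0.20),        # baseline exposure
                 c(0.30, 0.40, 0.30),
                 c(0.20, 0.30, 0.50))[l0 + 1, ]
      if (a0 == 1) p <- p * 1.9^(0:2)
      p / sum(p)
    },
    hdev = function(a1, l1) 0.10 * (1 + 0.5 * l1) * (1 + 0.6 * a1)
  )
})

## Calibrated two-window model with genuine time-varying confounding in
## which the marginal counterfactual hazard of each sustained regime is
## constant across windows (the hazard-constancy side condition of the
## per-protocol risk-set result); the selection side condition is supplied
## by the constant-fraction sampling device. A covariate space of size 3
## leaves room for covariate-dependent window-1 hazards, which a binary
## covariate would not (the two regime-mean constraints would force them
## flat and destroy the confounding).
build_tv_confounding <- function() {
  sc <- tv_scaffold
  Ls <- sc$Ls; piL <- sc$piL; e1 <- sc$e1; covP <- sc$covP
  H1 <- 0.15; H0 <- 0.08
  ## window-0 adherent hazards: covariate spread, regime means H1 / H0
  h0w0 <- (1 + 0.4 * Ls); h0w0 <- h0w0 * H0 / sum(piL * h0w0)
  h1w0 <- (1 + 0.5 * Ls); h1w0 <- h1w0 * H1 / sum(piL * h1w0)
  ## window-1: L_1 distribution among the at-risk under each regime pins
  ## the level of an increasing covariate shape
  Pbar <- function(a) {
    mass <- piL * (1 - (if (a == 1) h1w0 else h0w0))
    out <- numeric(3)
    for (l0 in Ls) out <- out + mass[l0 + 1] * covP(l0, a)
    out / sum(out)
  }
  shape <- c(1, 3, 6.5)
  h1w1 <- shape * H1 / sum(Pbar(1) * shape)
  h0w1 <- shape * H0 / sum(Pbar(0) * shape)
  ## stay probabilities Pr(A_1 = A_0 | L_1): covariate-dependent switching
  ## is the time-varying confounding; the selection condition is met by the
  ## constant-fraction sampling device, not by hazard constancy of a case
  ## process
  stay <- c(0.82, 0.68, 0.54)
  if (any(c(h0w1, h1w1) <= 0) || any(c(h0w1, h1w1) >= 1)) {
    cc_stop("cc_invalid_probability",
            "tv-confounding calibration left (0,1)")
  }
  dgp_spec(
    K = 2, L_space = Ls,
    init_L = piL,
    exposure_law = function(k, L, A, u) {
      if (k == 0) return(e1[L[1] + 1])
      st <- stay[L[2] + 1]
      if (A[1] == 1) st else 1 - st
    },
    covariate_law = function(k, L, A, u) covP(L[1], A[1]),
    hazard_law = function(k, L, A, u) {
      if (k == 0) {
        return(if (A[1] == 1) h1w0[L[1] + 1] else h0w0[L[1] + 1])
      }
      if (A[2] == A[1]) {
        if (A[2] == 1) h1w1[L[2] + 1] else h0w1[L[2] + 1]
      } else {
        sc$hdev(A[2], L[2])
      }
    },
    constant_hazard_enforced = TRUE,
    label = "tv-confounding"
  )
}

## Time-varying-confounding model with pointwise proportional adherent
## hazards (exposed = theta times unexposed in every covariate-history
## cell and window): the homogeneity condition of the history-matched
## per-protocol result. No hazard-constancy calibration is needed there,
## because the matched functional involves no sampling fractions.
build_tv_confounding_homogeneous <- function() {
  sc <- tv_scaffold
  theta <- 2
  h0 <- function(l, k) 0.05 * (1 + 0.6 * l) * (1 + 0.4 * k)
  dgp_spec(
    K = 2, L_space = sc$Ls,
    init_L = sc$piL,
    exposure_law = function(k, L, A, u) {
      if (k == 0) return(sc$e1[L[1] + 1])
      st <- c(0.9, 0.85, 0.8)[L[2] + 1]
      if (A[1] == 1) st else 1 - st
    },
    covariate_law = function(k, L, A, u) sc$covP(L[1], A[1]),
    hazard_law = function(k, L, A, u) {
      if (k >= 1 && A[2] != A[1]) return(sc$hdev(A[2], L[2]))
      h0(L[k + 1], k) * (if (A[k + 1] == 1) theta else 1)
    },
    homogeneity_scale = "hazard-ratio",
    label = "tv-confounding-homogeneous"
  )
}

#' Preset cohort models
#'
#' A catalogue of data-generating processes, each engineered around the
#' assumption set of one or more identification results:
#'
#' * `"null"`: hazard ignores exposure entirely (it depends on `L_0`, which
#'   also drives exposure); every causal contrast equals 1.
#' * `"confounded-binary"`: baseline confounding by binary `L_0`
#'   (exposure-affine and hazard-affine), K = 3, free exposure switching,
#'   window-trending hazards; satisfies consistency, baseline
#'   exchangeability given `L_0` and positivity (case-base and survivor
#'   identification), with survival strongly exposure-dependent and a
#'   covariate-heterogeneous risk ratio (used as the violation witness for
#'   survivor-controls-as-case-base and for matching under heterogeneity).
#' * `"confounded-homogeneous-RR"` / `"confounded-homogeneous-OR"`:
#'   frozen exposure, baseline confounding, with the factual risk
#'   (respectively odds) ratio exactly constant across `L_0` strata
#'   (matched case-base / matched survivor identification).
#' * `"hazard-homogeneous"`: frozen exposure with proportional discrete
#'   hazards (`h_1 = theta * h_0` in every stratum-window), so the
#'   conditional hazard ratio is constant across windows and strata
#'   (matched risk-set identification).
#' * `"constant-hazard"`: frozen exposure, baseline confounding, hazard
#'   levels calibrated so the marginal counterfactual hazards of both
#'   baseline regimes and the observed marginal hazard are constant across
#'   windows (unmatched risk-set intention-to-treat identification).
#' * `"nonconstant-hazard"`: as above but with hazards doubling after
#'   window 0 (risk-set constant-hazard violation witness).
#' * `"tv-confounding"`: two windows, covariate space {0,1,2}, `L_1`
#'   affected by `A_0` and driving both `A_1` and the window-1 hazard;
#'   each sustained regime's marginal counterfactual hazard is constant
#'   across windows (unmatched risk-set per-protocol identification, with
#'   the constant-fraction selection device).
#' * `"tv-confounding-homogeneous"`: same confounding structure with
#'   pointwise proportional adherent hazards (constant conditional hazard
#'   ratio across windows and covariate histories), for the history-matched
#'   per-protocol result.
#' * `"unmeasured-U"`: a binary unmeasured confounder in the exposure and
#'   hazard laws (exchangeability-violation witness).
#' * `"rare-outcome"`: unconfounded exposure with covariate-heterogeneous
#'   hazards scaled by `eps` (default `1e-4`, overall risk about 5e-4),
#'   isolating the rare-disease approximation of the marginal risk ratio
#'   by the (survivor-sampling) marginal exposure-odds ratio.
#'
#' @param name Preset name.
#' @param eps Hazard scale for `"rare-outcome"`.
#' @return A validated [dgp_spec()].
#' @export
preset_dgp <- function(name = c("null", "confounded-binary",
                                "confounded-homogeneous-RR",
                                "confounded-homogeneous-OR",
                                "hazard-homogeneous",
                                "constant-hazard", "nonconstant-hazard",
                                "tv-confounding",
                                "tv-confounding-homogeneous",
                                "unmeasured-U", "rare-outcome"),
                       eps = 1e-4) {
  name <- match.arg(name)
  spec <- switch(name,
    "null" = dgp_spec(
      K = 3, init_L = c(0.6, 0.4),
      exposure_law = function(k, L, A, u) {
        if (k == 0) 0.3 + 0.3 * L[1] else 0.2 + 0.5 * A[k] + 0.1 * L[1]
      },
      hazard_law = function(k, L, A, u) 0.06 + 0.06 * L[1],
      constant_hazard_enforced = TRUE,
      label = "null"),

    "confounded-binary" = dgp_spec(
      K = 3, init_L = c(0.5, 0.5),
      exposure_law = function(k, L, A, u) {
        if (k == 0) 0.10 + 0.6 * L[1] else 0.15 + 0.6 * A[k] + 0.15 * L[1]
      },
      hazard_law = function(k, L, A, u) {
        # sub-multiplicative exposure-covariate interaction: the risk ratio
        # is covariate-heterogeneous, which exact matching cannot absorb
        0.05 * (1 + 1.2 * A[k + 1]) * (1 + 0.8 * L[1]) * (1 + 0.3 * k) *
          (1 - 0.5 * A[k + 1] * L[1])
      },
      label = "confounded-binary"),

    "confounded-homogeneous-RR" = {
      R0 <- 0.08 * (1 + 0.9 * (0:1)); R1 <- 1.9 * R0
      h <- function(a, l) 1 - (1 - (if (a == 1) R1 else R0)[l + 1])^(1 / 2)
      dgp_spec(
        K = 2, init_L = c(0.55, 0.45),
        exposure_law = function(k, L, A, u) c(0.30, 0.65)[L[1] + 1],
        hazard_law = function(k, L, A, u) h(A[1], L[1]),
        freeze_exposure = TRUE, homogeneity_scale = "risk-ratio",
        label = "confounded-homogeneous-RR")
    },

    "confounded-homogeneous-OR" = {
      O0 <- 0.09 * (1 + 0.8 * (0:1)); O1 <- 2.2 * O0
      R0 <- O0 / (1 + O0); R1 <- O1 / (1 + O1)
      h <- function(a, l) 1 - (1 - (if (a == 1) R1 else R0)[l + 1])^(1 / 2)
      dgp_spec(
        K = 2, init_L = c(0.5, 0.5),
        exposure_law = function(k, L, A, u) c(0.35, 0.60)[L[1] + 1],
        hazard_law = function(k, L, A, u) h(A[1], L[1]),
        freeze_exposure = TRUE, homogeneity_scale = "odds-ratio",
        label = "confounded-homogeneous-OR")
    },

    "hazard-homogeneous" = dgp_spec(
      K = 2, init_L = c(0.55, 0.45),
      exposure_law = function(k, L, A, u) c(0.30, 0.70)[L[1] + 1],
      hazard_law = function(k, L, A, u) {
        0.06 * (1 + 0.8 * L[1]) * (1 + 0.5 * k) *
          (if (A[1] == 1) 1.8 else 1)
      },
      freeze_exposure = TRUE, homogeneity_scale = "hazard-ratio",
      label = "hazard-homogeneous"),

    "constant-hazard" = {
      piL <- c(0.6, 0.4); e1 <- c(0.25, 0.75)
      cal <- calibrate_constant_hazard(K = 3, piL = piL, e1 = e1,
                                       H1 = 0.18, H0 = 0.10, rho = 1.5)
      dgp_spec(
        K = 3, init_L = piL,
        exposure_law = function(k, L, A, u) e1[L[1] + 1],
        hazard_law = function(k, L, A, u) {
          cal$h[k + 1, A[1] + 1, L[1] + 1]
        },
        freeze_exposure = TRUE, constant_hazard_enforced = TRUE,
        label = "constant-hazard")
    },

    ## exposed-arm hazard doubles after window 0 while the unexposed arm
    ## stays flat: both the counterfactual hazards and their ratio vary
    ## across windows, so no single hazard ratio is recoverable
    "nonconstant-hazard" = dgp_spec(
      K = 3, init_L = c(0.6, 0.4),
      exposure_law = function(k, L, A, u) c(0.25, 0.75)[L[1] + 1],
      hazard_law = function(k, L, A, u) {
        if (A[1] == 1) {
          0.10 * (1 + 0.5 * L[1]) * (if (k >= 1) 2 else 1)
        } else {
          0.06 * (1 + 0.5 * L[1])
        }
      },
      freeze_exposure = TRUE,
      label = "nonconstant-hazard"),

    "tv-confounding" = build_tv_confounding(),

    "tv-confounding-homogeneous" = build_tv_confounding_homogeneous(),

    "unmeasured-U" = dgp_spec(
      K = 2, init_L = c(0.5, 0.5), include_U = TRUE, p_U = 0.5,
      exposure_law = function(k, L, A, u) 0.2 + 0.3 * u + 0.2 * L[1],
      hazard_law = function(k, L, A, u) {
        0.05 * (1 + 1.5 * A[1]) * (1 + 2 * u) * (1 + 0.5 * L[1])
      },
      freeze_exposure = TRUE,
      label = "unmeasured-U"),

    ## exposure unconfounded (covariate-heterogeneous hazards retained):
    ## this isolates the rare-event approximation itself, so the crude
    ## survivor exposure-odds ratio tracks the causal marginal odds ratio,
    ## which in turn approximates the marginal risk ratio as eps -> 0
    "rare-outcome" = dgp_spec(
      K = 2, init_L = c(0.5, 0.5),
      exposure_law = function(k, L, A, u) 0.45,
      hazard_law = function(k, L, A, u) {
        eps * (1 + 1.5 * A[1]) * (1 + 0.8 * L[1])
      },
      freeze_exposure = TRUE,
      label = sprintf("rare-outcome(eps=%g)", eps))
  )
  validate_spec(spec)
}
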