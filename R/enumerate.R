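#' Exactly enumerate all trajectories of a cohort model
#'
#' Walks the full discrete state space of a validated spec and returns every
#' possible trajectory (including the unmeasured confounder `U` when present)
#' together with its exact probability. This is the substrate for all
#' distribution-level computations: estimands, identifying functionals and
#' oracle checks.
#'
#' @param spec A [dgp_spec()] (validated automatically if needed).
#' @param cap Maximum number of atoms before an enumeration-too-large error.
#' @param regime `"natural"` for the observed-data law, or one of
#'   `"set-A0-1"`, `"set-A0-0"` (intervene on baseline exposure only;
#'   subsequent exposures follow the natural law given the intervened
#'   history), `"always"`, `"never"` (sustained regimes).
#' @return A data frame with columns `U`, `L0..L{K-1}`, `A0..A{K-1}`
#'   (`NA` after the event, per the at-risk convention), `T` (event window,
#'   `Inf` if event-free at `t_K`) and `prob`. Probabilities sum to 1.
#' @export
enumerate_trajectories <- function(spec, cap = 1e7, regime = "natural") {
  spec <- ensure_validated(spec, cap = cap)
  K <- spec$K
  nb <- atom_bound(spec)
  if (nb > cap) {
    cc_stop("cc_enumeration_too_large",
            "state space bound %g atoms exceeds cap %g", nb, cap)
  }
  regime <- match.arg(regime, c("natural", "set-A0-1", "set-A0-0",
                                "always", "never"))
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 2048L)
  acc$n <- 0L
  emit <- function(u, L, A, Tw, p) {
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$rows)) {
      acc$rows <- c(acc$rows, vector("list", length(acc$rows)))
    }
    acc$rows[[acc$n]] <- c(u, c(L, rep(NA_integer_, K - length(L))),
                           c(A, rep(NA_integer_, K - length(A))), Tw, p)
  }
  pexp_regime <- function(k, u, L, A) {
    switch(regime,
      "natural"  = law_pexp(spec, k, u, L, A),
      "set-A0-1" = if (k == 0L) 1 else law_pexp(spec, k, u, L, A),
      "set-A0-0" = if (k == 0L) 0 else law_pexp(spec, k, u, L, A),
      "always"   = 1,
      "never"    = 0)
  }
  walk <- function(k, u, L, A, p) {
    if (p <= 0) return(invisible(NULL))
    if (k == K) {
      emit(u, L, A, Inf, p)
      return(invisible(NULL))
    }
    lprobs <- law_lprobs(spec, k, u, L, A)
    for (li in seq_along(spec$L_space)) {
      if (lprobs[li] <= 0) next
      Lk <- c(L, spec$L_space[li])
      p1 <- pexp_regime(k, u, Lk, A)
      for (a in 0:1) {
        pa <- if (a == 1L) p1 else 1 - p1
        if (pa <= 0) next
        Ak <- c(A, a)
        h <- law_haz(spec, k, u, Lk, Ak)
        base <- p * lprobs[li] * pa
        if (h > 0) emit(u, Lk, Ak, k, base * h)
        walk(k + 1L, u, Lk, Ak, base * (1 - h))
      }
    }
  }
  init <- spec$tables$init
  for (u in u_values(spec)) {
    pu <- sum(init$prob[init$u == u])
    walk(0L, u, integer(0), integer(0), pu)
  }
  m <- do.call(rbind, acc$rows[seq_len(acc$n)])
  out <- as.data.frame(m)
  names(out) <- c("U", paste0("L", 0:(K - 1)), paste0("A", 0:(K - 1)),
                  "T", "prob")
  attr(out, "K") <- K
  attr(out, "L_space") <- spec$L_space
  out
}

## Observed-data law: marginalize U and aggregate identical observable rows.
observed_law <- function(spec, cap = 1e7) {
  atoms <- enumerate_trajectories(spec, cap = cap)
  K <- attr(atoms, "K")
  obs_cols <- c(paste0("L", 0:(K - 1)), paste0("A", 0:(K - 1)), "T")
  key <- do.call(paste, c(atoms[obs_cols], sep = "\r"))
  first <- !duplicated(key)
  out <- atoms[first, obs_cols, drop = FALSE]
  out$prob <- as.numeric(tapply(atoms$prob, key, sum)[key[first]])
  rownames(out) <- NULL
  attr(out, "K") <- K
  attr(out, "L_space") <- attr(atoms, "L_space")
  out
}

## Event-window helpers on enumerated atoms / cohort rows ------------------

## Y_k = I(T < t_k): event window T = w  =>  Y_k = 1 iff w <= k - 1.
y_at <- function(Tw, k) as.integer(Tw < k)

## at risk in window k (Y_k = 0): T >= k (including Inf)
at_risk_at <- function(Tw, k) Tw >= k

## exposure constant over at-risk windows 0..j (j given per row)
adherent_through <- function(df, j) {
  K <- attr(df, "K")
  A <- as.matrix(df[paste0("A", 0:(K - 1))])
  out <- rep(TRUE, nrow(df))
  for (kk in 1:max(1, K - 1)) {
    if (K == 1L) break
    idx <- !is.na(j) & j >= kk
    out[idx] <- out[idx] & (A[idx, kk + 1L] == A[idx, 1L])
  }
  out
}

#' Interventional outcome distribution of a cohort model
#'
#' Enumerates the intervened model (the exposure law replaced by the regime)
#' and returns the exact counterfactual event-probability curve
#' `Pr(Y_k(regime) = 1)` for `k = 1..K` and the per-window discrete-time
#' hazards `Pr(Y_{k+1}(regime) = 1 | Y_k(regime) = 0)`, marginally or within
#' strata of the baseline covariate (or of the full covariate history).
#'
#' @param spec A [dgp_spec()].
#' @param regime One of `"set-A0-1"`, `"set-A0-0"`, `"always"`, `"never"`.
#' @param conditioning `"marginal"`, `"L0"` (per baseline-covariate stratum)
#'   or `"history"` (per covariate-path stratum; hazards at window `k` are
#'   conditional on the path `L_0..L_k` under the regime).
#' @param cap Enumeration cap.
#' @return For `"marginal"`: list with `risk` (length `K`) and `hazard`
#'   (length `K`). Otherwise a list of such lists, one per stratum, named by
#'   the stratum value(s).
#' @export
interventional_distribution <- function(spec,
                                        regime = c("set-A0-1", "set-A0-0",
                                                   "always", "never"),
                                        conditioning = c("marginal", "L0",
                                                         "history"),
                                        cap = 1e7) {
  regime <- match.arg(regime)
  conditioning <- match.arg(conditioning)
  spec <- ensure_validated(spec, cap = cap)
  atoms <- enumerate_trajectories(spec, cap = cap, regime = regime)
  K <- spec$K

  risk_haz <- function(w, p) {
    # w: event windows, p: probabilities (sub-population, need not sum to 1)
    tot <- sum(p)
    if (tot <= 0) cc_stop("cc_undefined_stratum", "stratum has probability 0")
    risk <- vapply(1:K, function(k) sum(p[w < k]) / tot, numeric(1))
    hazard <- vapply(0:(K - 1), function(k) {
      atrisk <- sum(p[w >= k])
      if (atrisk <= 0) return(NA_real_)
      sum(p[w == k]) / atrisk
    }, numeric(1))
    list(risk = risk, hazard = hazard)
  }

  if (conditioning == "marginal") {
    return(risk_haz(atoms$T, atoms$prob))
  }
  if (conditioning == "L0") {
    out <- lapply(split(atoms, atoms$L0), function(d) risk_haz(d$T, d$prob))
    return(out)
  }
  # history: hazards per covariate path; hazard at window k uses the
  # distribution of (L_0..L_k) among those still at risk under the regime
  Lcols <- paste0("L", 0:(K - 1))
  out <- list()
  for (k in 0:(K - 1)) {
    sub <- atoms[at_risk_at(atoms$T, k), , drop = FALSE]
    pathkey <- do.call(paste, c(sub[Lcols[1:(k + 1)]], sep = ","))
    for (pk in unique(pathkey)) {
      d <- sub[pathkey == pk, , drop = FALSE]
      atrisk <- sum(d$prob)
      if (atrisk <= 0) next
      out[[paste0("k=", k, "|L=", pk)]] <-
        list(window = k, hazard = sum(d$prob[d$T == k]) / atrisk)
    }
  }
  out
}
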