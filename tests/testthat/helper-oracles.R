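## Independent oracles, written against the raw law functions of a spec
## (never its canonical tables or the package enumerator): a flat
## grid-based enumeration of the trajectory distribution, and a g-formula
## risk computed from it. Deliberately different in style and code path
## from the recursive tree walk inside the package.

oracle_enumerate <- function(spec, regime = "natural") {
  K <- spec$K
  Ls <- spec$L_space
  us <- if (spec$include_U) 0:1 else 0L
  pu <- if (spec$include_U) c(1 - spec$p_U, spec$p_U) else 1
  grid <- expand.grid(c(list(u = us),
                        rep(list(Ls), K),
                        rep(list(0:1), K),
                        list(Tw = c(0:(K - 1), Inf))),
                      KEEP.OUT.ATTRS = FALSE)
  Lcols <- 2:(K + 1)
  Acols <- (K + 2):(2 * K + 1)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    u <- grid$u[i]
    Lp <- as.integer(grid[i, Lcols])
    Ap <- as.integer(grid[i, Acols])
    Tw <- grid$Tw[i]
    last <- if (is.finite(Tw)) Tw else K - 1
    # canonicalise: post-event slots pinned to the first level (they carry
    # no probability; other combinations are duplicates)
    if (last < K - 1) {
      if (any(Lp[(last + 2):K] != Ls[1]) || any(Ap[(last + 2):K] != 0L)) next
    }
    p <- pu[match(u, us)]
    for (k in 0:last) {
      Aprev <- if (k > 0) Ap[1:k] else integer(0)
      pl <- if (k == 0) {
        v <- if (is.function(spec$init_L)) spec$init_L(u) else spec$init_L
        v[match(Lp[1], Ls)]
      } else if (is.null(spec$covariate_law)) {
        as.numeric(Lp[k + 1] == Lp[k])
      } else {
        spec$covariate_law(k, Lp[1:k], Aprev, u)[match(Lp[k + 1], Ls)]
      }
      pe1 <- if (regime == "always" || (regime == "set-A0-1" && k == 0)) 1
      else if (regime == "never" || (regime == "set-A0-0" && k == 0)) 0
      else if (spec$freeze_exposure && k >= 1) as.numeric(Ap[1] == 1L)
      else spec$exposure_law(k, Lp[1:(k + 1)], Aprev, u)
      pa <- if (Ap[k + 1] == 1L) pe1 else 1 - pe1
      h <- spec$hazard_law(k, Lp[1:(k + 1)], Ap[1:(k + 1)], u)
      p <- p * pl * pa * (if (k == last && is.finite(Tw)) h else 1 - h)
      if (p == 0) break
    }
    if (p <= 0) next
    Lo <- Lp; Ao <- Ap
    if (last < K - 1) {
      Lo[(last + 2):K] <- NA_integer_
      Ao[(last + 2):K] <- NA_integer_
    }
    rows[[length(rows) + 1L]] <- c(u, Lo, Ao, Tw, p)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("U", paste0("L", 0:(K - 1)), paste0("A", 0:(K - 1)),
                  "T", "prob")
  out
}

## exact Pr(Y_k(regime) = 1) for k = 1..K by direct summation
oracle_cf_risk <- function(spec, regime) {
  at <- oracle_enumerate(spec, regime)
  vapply(1:spec$K, function(k) sum(at$prob[at$T < k]), numeric(1))
}

## exact per-window counterfactual hazards from the oracle atoms
oracle_cf_hazard <- function(spec, regime) {
  at <- oracle_enumerate(spec, regime)
  vapply(0:(spec$K - 1), function(k) {
    sum(at$prob[at$T == k]) / sum(at$prob[at$T >= k])
  }, numeric(1))
}

## atom-table comparison key (NA-safe)
atom_key <- function(df) {
  cols <- setdiff(names(df), "prob")
  do.call(paste, c(lapply(df[cols], function(x) ifelse(is.na(x), "NA", x)),
                   sep = "|"))
}

expect_same_distribution <- function(a, b, tol = 1e-12) {
  ka <- atom_key(a); kb <- atom_key(b)
  expect_setequal(ka, kb)
  expect_lt(max(abs(a$prob[order(ka)] - b$prob[order(kb)])), tol)
}

## a tiny fully-custom spec used across unit tests (K = 2, time-varying
## covariate, free switching)
toy_spec <- function() {
  dgp_spec(
    K = 2,
    init_L = c(0.65, 0.35),
    exposure_law = function(k, L, A, u) {
      if (k == 0) 0.2 + 0.4 * L[1] else 0.25 + 0.4 * A[1] + 0.2 * L[2]
    },
    covariate_law = function(k, L, A, u) {
      p1 <- 0.3 + 0.3 * L[1] + 0.25 * A[1]
      c(1 - p1, p1)
    },
    hazard_law = function(k, L, A, u) {
      0.08 * (1 + A[k + 1]) * (1 + 0.6 * L[k + 1]) * (1 + 0.4 * k)
    },
    label = "toy"
  )
}
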