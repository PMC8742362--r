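#' Define a discrete-time structural cohort model
#'
#' A `cc_dgp_spec` describes a fixed cohort followed over `K` exposure windows
#' `k = 0, ..., K-1` (half-open intervals `[t_k, t_{k+1})`, administrative end
#' `t_K`). While at risk, a subject carries a discrete covariate `L_k`, a
#' binary exposure `A_k`, and a discrete-time hazard of sustaining the event
#' in window `k`. Event indicators are `Y_k = I(T < t_k)` for `k = 0, ..., K`
#' (so `Y_0 = 0` and "event in window k" means `Y_k = 0, Y_{k+1} = 1`).
#' An optional binary unmeasured confounder `U` can enter the exposure and
#' hazard laws to engineer violations of baseline exchangeability.
#'
#' All laws are supplied as R functions of the subject's history and are
#' tabulated over the (finite) history space by [validate_spec()], which gives
#' every spec a canonical table form used for enumeration, simulation and
#' serialization.
#'
#' @param K Number of exposure windows (integer, at least 1).
#' @param L_space Integer vector of covariate codes (default binary `0:1`).
#' @param init_L Distribution of `L_0`: either a probability vector over
#'   `L_space`, or a function `function(u)` returning one (per level of `U`).
#' @param exposure_law Function `function(k, L, A, u)` returning
#'   `Pr(A_k = 1 | L_0..L_k, A_0..A_{k-1}, U = u)` for an at-risk subject;
#'   `L` has length `k + 1`, `A` has length `k`.
#' @param covariate_law Function `function(k, L, A, u)` returning the
#'   probability vector of `L_k` over `L_space` given `L_0..L_{k-1}` and
#'   `A_0..A_{k-1}` (`k >= 1`). `NULL` keeps the covariate time-fixed
#'   (`L_k = L_{k-1}` with probability 1).
#' @param hazard_law Function `function(k, L, A, u)` returning
#'   `Pr(Y_{k+1} = 1 | Y_k = 0, L_0..L_k, A_0..A_k, U = u)`; `L` and `A` both
#'   have length `k + 1`.
#' @param include_U Include a binary unmeasured confounder `U`?
#' @param p_U `Pr(U = 1)` when `include_U` is set.
#' @param freeze_exposure If `TRUE`, `A_k = A_0` deterministically for
#'   `k >= 1` (the supplied `exposure_law` is only consulted at `k = 0`).
#' @param constant_hazard_enforced Marker that the spec was built so that the
#'   relevant marginal counterfactual hazards are constant across windows
#'   (checked, not assumed, by [check_constant_hazards()]).
#' @param homogeneity_scale One of `"none"`, `"risk-ratio"`, `"odds-ratio"`,
#'   `"hazard-ratio"`: scale on which the spec was built to satisfy effect
#'   homogeneity across covariate strata (checked by
#'   [check_effect_homogeneity()]).
#' @param label Optional preset name carried along in printouts.
#'
#' @return An object of class `cc_dgp_spec` (unvalidated; see
#'   [validate_spec()]).
#' @seealso [validate_spec()], [enumerate_trajectories()], [sample_cohort()],
#'   [preset_dgp()]
#' @export
dgp_spec <- function(K, L_space = 0:1, init_L, exposure_law,
                     covariate_law = NULL, hazard_law,
                     include_U = FALSE, p_U = 0.5,
                     freeze_exposure = FALSE,
                     constant_hazard_enforced = FALSE,
                     homogeneity_scale = c("none", "risk-ratio",
                                           "odds-ratio", "hazard-ratio"),
                     label = NULL) {
  homogeneity_scale <- match.arg(homogeneity_scale)
  if (length(K) != 1L || is.na(K) || K < 1 || K != as.integer(K)) {
    cc_stop("cc_invalid_grid", "K must be a single integer >= 1 (got %s)",
            paste(K, collapse = ","))
  }
  structure(list(
    K = as.integer(K),
    L_space = as.integer(L_space),
    init_L = init_L,
    exposure_law = exposure_law,
    covariate_law = covariate_law,
    hazard_law = hazard_law,
    include_U = isTRUE(include_U),
    p_U = p_U,
    freeze_exposure = isTRUE(freeze_exposure),
    constant_hazard_enforced = isTRUE(constant_hazard_enforced),
    homogeneity_scale = homogeneity_scale,
    label = label,
    validated = FALSE,
    tables = NULL,
    lookup = NULL
  ), class = "cc_dgp_spec")
}

#' @export
print.cc_dgp_spec <- function(x, ...) {
  cat("<cc_dgp_spec>", if (!is.null(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  K =", x$K, " L_space = {", paste(x$L_space, collapse = ","), "}\n")
  cat("  include_U =", x$include_U,
      " freeze_exposure =", x$freeze_exposure, "\n")
  cat("  validated =", isTRUE(x$validated), "\n")
  invisible(x)
}

u_values <- function(spec) if (spec$include_U) 0:1 else 0L

init_table <- function(spec) {
  us <- u_values(spec)
  pu <- if (spec$include_U) c(1 - spec$p_U, spec$p_U) else 1
  rows <- list()
  for (i in seq_along(us)) {
    pl <- if (is.function(spec$init_L)) spec$init_L(us[i]) else spec$init_L
    if (length(pl) != length(spec$L_space)) {
      cc_stop("cc_normalization_error",
              "init_L must give one probability per covariate code")
    }
    rows[[i]] <- data.frame(u = us[i], l = spec$L_space, prob = pu[i] * pl)
  }
  do.call(rbind, rows)
}

check_prob <- function(p, what, key) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    cc_stop("cc_invalid_probability",
            "%s returned a value outside [0,1] at history %s (got %s)",
            what, key, paste(signif(p, 4), collapse = ","))
  }
  p
}

check_dist <- function(p, what, key, tol = 1e-12) {
  check_prob(p, what, key)
  if (abs(sum(p) - 1) > tol) {
    cc_stop("cc_normalization_error",
            "%s does not sum to 1 at history %s (sum = %.15g)",
            what, key, sum(p))
  }
  p
}

## Upper bound on the number of enumeration atoms.
atom_bound <- function(spec) {
  (length(spec$L_space)^spec$K) * (2^spec$K) * (spec$K + 1) *
    length(u_values(spec))
}

#' Validate a cohort model and tabulate its laws
#'
#' Checks the spec invariants (grid, probability ranges, normalization of all
#' covariate distributions) by walking every positive-probability history, and
#' attaches the canonical table form of each law (a stratum-to-probability
#' table keyed by the history values). All enumeration, simulation and
#' serialization work off these tables.
#'
#' @param spec A [dgp_spec()].
#' @param cap Maximum number of trajectory atoms tolerated (guards the walk).
#' @return The spec, with `validated = TRUE` and `tables`/`lookup` filled in.
#' @export
validate_spec <- function(spec, cap = 1e7) {
  stopifnot(inherits(spec, "cc_dgp_spec"))
  if (atom_bound(spec) > cap) {
    cc_stop("cc_enumeration_too_large",
            "state space bound %g exceeds cap %g", atom_bound(spec), cap)
  }
  if (anyDuplicated(spec$L_space)) {
    cc_stop("cc_invalid_grid", "L_space codes must be distinct")
  }
  init <- init_table(spec)
  check_prob(init$prob, "init_L", "<baseline>")
  if (abs(sum(init$prob) - 1) > 1e-12) {
    cc_stop("cc_normalization_error", "init_L probabilities sum to %.15g",
            sum(init$prob))
  }

  K <- spec$K
  exp_rows <- list(); cov_rows <- list(); haz_rows <- list()

  walk <- function(k, u, L, A) {
    # subject at risk entering window k with L_0..L_{k-1}, A_0..A_{k-1}
    if (k == K) return(invisible(NULL))
    if (k == 0L) {
      lprobs <- init$prob[init$u == u] / sum(init$prob[init$u == u])
    } else if (is.null(spec$covariate_law)) {
      lprobs <- as.numeric(spec$L_space == L[k])
    } else {
      key <- hist_key(L, A)
      lprobs <- check_dist(spec$covariate_law(k, L, A, u),
                           "covariate_law", key)
      cov_rows[[length(cov_rows) + 1L]] <<- data.frame(
        k = k, u = u, key = key, l = spec$L_space, prob = lprobs)
    }
    for (li in seq_along(spec$L_space)) {
      if (lprobs[li] <= 0) next
      Lk <- c(L, spec$L_space[li])
      keyE <- hist_key(Lk, A)
      if (spec$freeze_exposure && k >= 1L) {
        p1 <- as.numeric(A[1] == 1L)
      } else {
        p1 <- check_prob(spec$exposure_law(k, Lk, A, u), "exposure_law", keyE)
      }
      exp_rows[[length(exp_rows) + 1L]] <<- data.frame(
        k = k, u = u, key = keyE, p = p1)
      # walk both exposure arms even when one has natural probability zero:
      # interventions can force either arm, and their laws must be tabulated
      for (a in 0:1) {
        Ak <- c(A, a)
        keyH <- hist_key(Lk, Ak)
        h <- check_prob(spec$hazard_law(k, Lk, Ak, u), "hazard_law", keyH)
        haz_rows[[length(haz_rows) + 1L]] <<- data.frame(
          k = k, u = u, key = keyH, p = h)
        walk(k + 1L, u, Lk, Ak)
      }
    }
  }
  for (u in u_values(spec)) {
    if (sum(init$prob[init$u == u]) > 0) walk(0L, u, integer(0), integer(0))
  }

  bindt <- function(rows) {
    if (!length(rows)) {
      return(data.frame(k = integer(0), u = integer(0), key = character(0),
                        p = numeric(0)))
    }
    tab <- do.call(rbind, rows)
    tab[!duplicated(tab[c("k", "u", "key", intersect("l", names(tab)))]), ,
        drop = FALSE]
  }
  tables <- list(
    init = init,
    exposure = bindt(exp_rows),
    covariate = bindt(cov_rows),
    hazard = bindt(haz_rows)
  )
  lookup <- list(
    exposure = stats::setNames(tables$exposure$p,
                               lk_name(tables$exposure$k, tables$exposure$u,
                                       tables$exposure$key)),
    hazard = stats::setNames(tables$hazard$p,
                             lk_name(tables$hazard$k, tables$hazard$u,
                                     tables$hazard$key)),
    covariate = if (nrow(tables$covariate)) {
      stats::setNames(tables$covariate$prob,
                      paste(lk_name(tables$covariate$k, tables$covariate$u,
                                    tables$covariate$key),
                            tables$covariate$l, sep = "|"))
    } else numeric(0)
  )
  spec$tables <- tables
  spec$lookup <- lookup
  spec$validated <- TRUE
  spec
}

ensure_validated <- function(spec, cap = 1e7) {
  if (!isTRUE(spec$validated)) validate_spec(spec, cap = cap) else spec
}

## Internal law accessors working off the canonical tables ----------------

law_lprobs <- function(spec, k, u, L, A) {
  if (k == 0L) {
    init <- spec$tables$init
    sel <- init$u == u
    init$prob[sel] / sum(init$prob[sel])
  } else if (is.null(spec$covariate_law)) {
    as.numeric(spec$L_space == L[k])
  } else {
    nm <- paste(lk_name(k, u, hist_key(L, A)), spec$L_space, sep = "|")
    p <- unname(spec$lookup$covariate[nm])
    p[is.na(p)] <- 0
    p
  }
}

law_pexp <- function(spec, k, u, L, A) {
  if (spec$freeze_exposure && k >= 1L) return(as.numeric(A[1] == 1L))
  unname(spec$lookup$exposure[lk_name(k, u, hist_key(L, A))])
}

law_haz <- function(spec, k, u, L, A) {
  unname(spec$lookup$hazard[lk_name(k, u, hist_key(L, A))])
}
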