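#' Simulate a cohort with counterfactual ground truth
#'
#' Draws `n` independent subjects from a validated cohort model. All
#' structural equations are driven by shared per-subject-per-window uniform
#' draws (one per equation), so that when `attach_counterfactuals = TRUE` the
#' four counterfactual regimes (`set-A0-1`, `set-A0-0`, `always`, `never`)
#' are jointly defined on every subject and consistency holds by
#' construction: a subject whose observed exposure path matches a regime has
#' exactly that regime's counterfactual outcome path.
#'
#' @param spec A [dgp_spec()].
#' @param n Cohort size (integer >= 1).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param attach_counterfactuals Attach counterfactual event windows
#'   `T_set1`, `T_set0`, `T_always`, `T_never`?
#' @return A `cc_cohort` data frame: `subject_id`, `T` (event window, `Inf`
#'   if event-free), `L0..L{K-1}` and `A0..A{K-1}` (present exactly for
#'   at-risk windows, `NA` afterwards), `Y1..YK`, plus counterfactual event
#'   windows when requested.
#' @export
sample_cohort <- function(spec, n, seed = NULL,
                          attach_counterfactuals = FALSE) {
  spec <- ensure_validated(spec)
  if (length(n) != 1L || is.na(n) || n < 1) {
    cc_stop("cc_argument_error", "n must be a single integer >= 1")
  }
  n <- as.integer(n)
  K <- spec$K
  Ls <- spec$L_space
  nL <- length(Ls)

  local_seed(seed, {
    uU <- stats::runif(n)
    UL <- matrix(stats::runif(n * K), n, K)
    UA <- matrix(stats::runif(n * K), n, K)
    UE <- matrix(stats::runif(n * K), n, K)

    init <- spec$tables$init
    us <- u_values(spec)
    pu <- vapply(us, function(u) sum(init$prob[init$u == u]), numeric(1))
    Uvec <- draw_categorical(matrix(pu, n, length(us), byrow = TRUE), uU, us)
    # L_0 given U (shared across regimes: its law does not involve A)
    P0 <- matrix(0, n, nL)
    for (i in seq_along(us)) {
      sel <- Uvec == us[i]
      pl <- init$prob[init$u == us[i]] / pu[i]
      P0[sel, ] <- matrix(pl, sum(sel), nL, byrow = TRUE)
    }
    L0 <- draw_categorical(P0, UL[, 1], Ls)

    regimes <- "natural"
    if (attach_counterfactuals) {
      regimes <- c(regimes, "set-A0-1", "set-A0-0", "always", "never")
    }
    res <- list()
    for (rg in regimes) {
      Lm <- matrix(NA_integer_, n, K)
      Am <- matrix(NA_integer_, n, K)
      Tw <- rep(Inf, n)
      Lm[, 1] <- L0
      keyL <- as.character(L0)          # running L-history string
      keyA <- rep("", n)                # running A-history string
      for (k in 0:(K - 1)) {
        active <- is.infinite(Tw)
        if (!any(active)) break
        if (k >= 1L) {
          # covariate draw (time-fixed if no covariate_law)
          if (is.null(spec$covariate_law)) {
            Lm[active, k + 1L] <- Lm[active, k]
          } else {
            keys <- lk_name(k, Uvec[active],
                            paste0(keyL[active], ";", keyA[active]))
            P <- vapply(Ls, function(l) {
              p <- unname(spec$lookup$covariate[paste(keys, l, sep = "|")])
              p[is.na(p)] <- 0
              p
            }, numeric(sum(active)))
            P <- matrix(P, ncol = nL)
            Lm[active, k + 1L] <- draw_categorical(P, UL[active, k + 1L], Ls)
          }
          keyL[active] <- paste0(keyL[active], ",", Lm[active, k + 1L])
        }
        # exposure
        keysE <- lk_name(k, Uvec[active],
                         paste0(keyL[active], ";", keyA[active]))
        a <- integer(sum(active))
        if (rg == "always" || (rg == "set-A0-1" && k == 0L)) {
          a[] <- 1L
        } else if (rg == "never" || (rg == "set-A0-0" && k == 0L)) {
          a[] <- 0L
        } else if (spec$freeze_exposure && k >= 1L) {
          a <- Am[active, 1L]
        } else {
          p1 <- unname(spec$lookup$exposure[keysE])
          a <- as.integer(UA[active, k + 1L] < p1)
        }
        Am[active, k + 1L] <- a
        keyA[active] <- if (k == 0L) as.character(a) else
          paste0(keyA[active], ",", a)
        # hazard
        keysH <- lk_name(k, Uvec[active],
                         paste0(keyL[active], ";", keyA[active]))
        h <- unname(spec$lookup$hazard[keysH])
        ev <- UE[active, k + 1L] < h
        Tw[which(active)[ev]] <- k
      }
      # at-risk convention: L_k, A_k absent after the event
      for (k in 1:K) {
        if (k >= 2L) {
          gone <- Tw < (k - 1L)
          Lm[gone, k] <- NA_integer_
          Am[gone, k] <- NA_integer_
        }
      }
      res[[rg]] <- list(L = Lm, A = Am, T = Tw)
    }

    out <- data.frame(subject_id = seq_len(n), T = res$natural$T)
    for (k in 0:(K - 1)) out[[paste0("L", k)]] <- res$natural$L[, k + 1L]
    for (k in 0:(K - 1)) out[[paste0("A", k)]] <- res$natural$A[, k + 1L]
    for (k in 1:K) out[[paste0("Y", k)]] <- y_at(out$T, k)
    if (attach_counterfactuals) {
      out$T_set1 <- res[["set-A0-1"]]$T
      out$T_set0 <- res[["set-A0-0"]]$T
      out$T_always <- res[["always"]]$T
      out$T_never <- res[["never"]]$T
    }
    if (spec$include_U) out$U <- Uvec
    attr(out, "K") <- K
    attr(out, "L_space") <- Ls
    class(out) <- c("cc_cohort", "data.frame")
    out
  })
}

#' Counterfactual outcome indicators for a simulated cohort
#'
#' Expands the stored counterfactual event windows of a cohort simulated with
#' `attach_counterfactuals = TRUE` into the indicator sequence
#' `Y_1(regime)..Y_K(regime)`.
#'
#' @param cohort A `cc_cohort` with counterfactuals attached.
#' @param regime One of `"set-A0-1"`, `"set-A0-0"`, `"always"`, `"never"`.
#' @return Integer matrix, `n` rows by `K` columns.
#' @export
counterfactual_Y <- function(cohort, regime = c("set-A0-1", "set-A0-0",
                                                "always", "never")) {
  regime <- match.arg(regime)
  col <- switch(regime, "set-A0-1" = "T_set1", "set-A0-0" = "T_set0",
                "always" = "T_always", "never" = "T_never")
  if (is.null(cohort[[col]])) {
    cc_stop("cc_argument_error",
            "cohort has no counterfactuals attached (column %s missing)", col)
  }
  K <- attr(cohort, "K")
  vapply(1:K, function(k) y_at(cohort[[col]], k), integer(nrow(cohort)))
}

#' Write / read a cohort table as delimited text
#'
#' One row per subject; `T` is written as `"inf"` for subjects event-free at
#' the administrative end; post-event cells are empty.
#'
#' @param cohort A `cc_cohort`.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$T <- ifelse(is.infinite(df$T), "inf", df$T)
  for (cc in grep("^T_", names(df), value = TRUE)) {
    df[[cc]] <- ifelse(is.infinite(df[[cc]]), "inf", df[[cc]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @param K Number of exposure windows encoded in the file (inferred from the
#'   column names when `NULL`).
#' @export
read_cohort <- function(path, K = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(K)) K <- sum(grepl("^L[0-9]+$", names(df)))
  for (cc in c("T", grep("^T_", names(df), value = TRUE))) {
    df[[cc]] <- suppressWarnings(
      ifelse(df[[cc]] == "inf", Inf, as.numeric(df[[cc]])))
  }
  attr(df, "K") <- K
  attr(df, "L_space") <- sort(unique(stats::na.omit(df$L0)))
  class(df) <- c("cc_cohort", "data.frame")
  df
}
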