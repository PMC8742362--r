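## Case qualification and control sampling: case-base, survivor and risk-set
## schemes, unmatched and exact pair-matched.

cohort_K <- function(cohort) {
  K <- attr(cohort, "K")
  if (is.null(K)) cc_stop("cc_argument_error", "cohort is missing its K attribute")
  K
}

#' Identify qualifying cases
#'
#' A subject qualifies as a case if it sustains the event by the
#' administrative study end (`Y_K = 1`) and, for per-protocol analyses,
#' additionally kept a constant exposure level over every at-risk window up
#' to and including the event window.
#'
#' @param cohort A `cc_cohort`.
#' @param mode `"ITT"` or `"PP"`.
#' @return Data frame with `subject_id` and `event_window`.
#' @export
qualify_cases <- function(cohort, mode = c("ITT", "PP")) {
  mode <- match.arg(mode)
  ev <- is.finite(cohort$T)
  if (mode == "PP") {
    ev <- ev & adherent_through(cohort, ifelse(is.finite(cohort$T),
                                               cohort$T, NA))
  }
  data.frame(subject_id = cohort$subject_id[ev],
             event_window = cohort$T[ev])
}

#' Control eligibility sets
#'
#' Risk-set sampling: all subjects event-free at `t_k` (`Y_k = 0`) are
#' eligible for window `k`; the index case itself is a member of its own
#' window's eligible set, and a subject may be eligible (and selected) in
#' several windows. Case-base sampling: every subject at risk at baseline,
#' irrespective of `k`. Survivor sampling: subjects event-free at `t_K`.
#' Eligibility does not depend on protocol adherence (per-protocol analyses
#' handle deviation by censoring, not by eligibility), so `mode` does not
#' alter the returned set; the per-case sampling pool is [control_pool()].
#'
#' @param cohort A `cc_cohort`.
#' @param k Window index (`0..K-1`); ignored for case-base and survivor.
#' @param scheme `"risk-set"`, `"case-base"` or `"survivor"`.
#' @param mode `"ITT"` or `"PP"` (kept for interface symmetry).
#' @return Vector of subject ids.
#' @export
eligible_controls <- function(cohort, k = NULL,
                              scheme = c("risk-set", "case-base", "survivor"),
                              mode = c("ITT", "PP")) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  K <- cohort_K(cohort)
  if (scheme == "case-base") return(cohort$subject_id)
  if (scheme == "survivor") return(cohort$subject_id[is.infinite(cohort$T)])
  if (is.null(k) || k < 0 || k > K - 1) {
    cc_stop("cc_argument_error", "risk-set eligibility needs 0 <= k <= K-1")
  }
  cohort$subject_id[at_risk_at(cohort$T, k)]
}

#' Per-case sampling pool
#'
#' The eligible set for the case's event window with the index case itself
#' removed (the default; a case is listed as eligible but is never paired
#' with itself unless `exclude_self = FALSE`).
#'
#' @inheritParams eligible_controls
#' @param case_id Subject id of the index case.
#' @param exclude_self Drop the case from its own pool?
#' @return Vector of subject ids.
#' @export
control_pool <- function(cohort, case_id, k = NULL,
                         scheme = c("risk-set", "case-base", "survivor"),
                         mode = c("ITT", "PP"), exclude_self = TRUE) {
  elig <- eligible_controls(cohort, k, scheme, mode)
  if (exclude_self) elig <- elig[elig != case_id]
  elig
}

new_selection <- function(scheme, mode, n, S, n_selected,
                          sampling_fractions, links = NULL,
                          m_per_case = NULL, n_controls = NULL,
                          times = NULL) {
  structure(list(scheme = scheme, mode = mode, n = n, S = S,
                 n_selected = n_selected,
                 sampling_fractions = sampling_fractions,
                 links = links, m_per_case = m_per_case,
                 n_controls = n_controls, times = times),
            class = "cc_selection")
}

#' @export
print.cc_selection <- function(x, ...) {
  cat("<cc_selection>", x$scheme, x$mode, "\n")
  cat("  subjects:", x$n, " selections:", sum(x$n_selected), "\n")
  invisible(x)
}

## Sequential uniform draw of m distinct indices from 1..npool.
## Coupon-collector equivalence makes the kept-first-occurrence set an exact
## uniform without-replacement sample; the fast path avoids the O(npool)
## allocation of sample.int's Fisher-Yates for small m on large pools.
draw_wor <- function(npool, m) {
  if (m > npool) cc_stop("cc_sampling_infeasible",
                         "cannot draw %d from pool of %d", m, npool)
  if (npool < 64L || m > npool / 4) return(sample.int(npool, m))
  idx <- unique(sample.int(npool, m, replace = TRUE))
  while (length(idx) < m) {
    idx <- unique(c(idx, sample.int(npool, m - length(idx), replace = TRUE)))
  }
  idx
}

## Map draws over 1..(npool-1) to positions of a pool with entry s removed.
skip_self <- function(j, s) ifelse(j >= s, j + 1L, j)

#' Case-base (case-cohort) control sampling
#'
#' Draws `n_controls` subjects uniformly without replacement from the entire
#' baseline cohort, ignoring covariates, exposure and survival.
#'
#' @param cohort A `cc_cohort`.
#' @param n_controls Number of controls.
#' @param seed Integer seed.
#' @return A `cc_selection` with per-subject indicator `S`.
#' @export
sample_case_base_controls <- function(cohort, n_controls, seed = NULL) {
  n <- nrow(cohort)
  if (n_controls > n) {
    cc_stop("cc_argument_error",
            "n_controls (%d) exceeds cohort size (%d)", n_controls, n)
  }
  local_seed(seed, {
    sel <- sort(sample.int(n, n_controls))
    S <- integer(n); S[sel] <- 1L
    new_selection("case-base", "ITT", n, S, S,
                  sampling_fractions = n_controls / n,
                  n_controls = n_controls)
  })
}

#' Survivor (cumulative-incidence) control sampling
#'
#' Draws `n_controls` uniformly without replacement from the subjects that
#' reach the administrative study end event-free (`Y_K = 0`).
#'
#' @inheritParams sample_case_base_controls
#' @export
sample_survivor_controls <- function(cohort, n_controls, seed = NULL) {
  surv <- which(is.infinite(cohort$T))
  if (length(surv) < n_controls) {
    cc_stop("cc_sampling_infeasible",
            "only %d survivors available, %d controls requested",
            length(surv), n_controls)
  }
  local_seed(seed, {
    sel <- sort(surv[sample.int(length(surv), n_controls)])
    S <- integer(nrow(cohort)); S[sel] <- 1L
    new_selection("survivor", "ITT", nrow(cohort), S, S,
                  sampling_fractions = n_controls / length(surv),
                  n_controls = n_controls)
  })
}

#' Risk-set (incidence-density) control sampling
#'
#' Two selection devices are provided, both with eligibility "event-free at
#' `t_k`":
#'
#' * `sampling = "per-case"` (default): for every qualifying case with
#'   incident event in window `k`, `m_per_case` controls are drawn
#'   uniformly without replacement from the eligible set (the index case's
#'   own draw excludes itself by default). The per-eligible selection
#'   probability is then proportional to the case hazard, so it is constant
#'   across windows exactly when that hazard is.
#' * `sampling = "fraction"`: every eligible subject-window is selected
#'   independently with the same probability `fraction`, which satisfies
#'   the constant-sampling-probability selection condition by construction.
#'
#' A subject may be selected in several windows, and (per-case device) may
#' serve several cases within one window; the per-window indicator `S_k`
#' stays binary while the `times` matrix and `n_selected` count selections
#' with multiplicity, so their expectation matches the expected selection
#' count used in distribution-level evaluation.
#'
#' @param cohort A `cc_cohort`.
#' @param m_per_case Controls drawn per case (per-case device).
#' @param mode `"ITT"` or `"PP"` case qualification.
#' @param seed Integer seed.
#' @param exclude_self May a case be drawn as its own control? Default no.
#' @param sampling Selection device (see above).
#' @param fraction Per-eligible selection probability (fraction device).
#' @return A `cc_selection` with `S` an `n` by `K` 0/1 matrix, the `times`
#'   count matrix, per-subject selection counts `n_selected`, per-window
#'   realized sampling fractions, and (per-case device) the
#'   per-(case, control, window) `links` table.
#' @export
sample_risk_set_controls <- function(cohort, m_per_case = 1,
                                     mode = c("ITT", "PP"), seed = NULL,
                                     exclude_self = TRUE,
                                     sampling = c("per-case", "fraction"),
                                     fraction = NULL) {
  mode <- match.arg(mode)
  sampling <- match.arg(sampling)
  K <- cohort_K(cohort)
  n <- nrow(cohort)

  if (sampling == "fraction") {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1) {
      cc_stop("cc_argument_error",
              "fraction sampling needs 0 < fraction < 1")
    }
    return(local_seed(seed, {
      S <- matrix(0L, n, K)
      frac <- rep(NA_real_, K)
      for (k in 0:(K - 1)) {
        elig <- which(at_risk_at(cohort$T, k))
        S[elig, k + 1L] <- as.integer(stats::runif(length(elig)) < fraction)
        frac[k + 1L] <- sum(S[elig, k + 1L]) / length(elig)
      }
      new_selection("risk-set", mode, n, S, rowSums(S), frac,
                    times = S, m_per_case = NULL)
    }))
  }

  cases <- qualify_cases(cohort, mode)
  local_seed(seed, {
    S <- matrix(0L, n, K)
    times <- matrix(0L, n, K)
    link_case <- list(); link_ctl <- list(); link_k <- list()
    frac <- rep(NA_real_, K)
    for (k in sort(unique(cases$event_window))) {
      elig <- which(at_risk_at(cohort$T, k))
      ck <- sort(cases$subject_id[cases$event_window == k])
      pos <- match(match(ck, cohort$subject_id), elig)
      npool <- length(elig) - as.integer(exclude_self)
      if (npool < m_per_case) {
        cc_stop("cc_sampling_infeasible",
                "window %d: eligible pool of %d is smaller than m = %d",
                k, npool, m_per_case)
      }
      picked <- vector("list", length(ck))
      for (ci in seq_along(ck)) {
        if (exclude_self && !is.na(pos[ci])) {
          j <- skip_self(draw_wor(length(elig) - 1L, m_per_case), pos[ci])
        } else {
          j <- draw_wor(length(elig), m_per_case)
        }
        picked[[ci]] <- elig[j]
      }
      pk <- unlist(picked)
      S[unique(pk), k + 1L] <- 1L
      times[, k + 1L] <- tabulate(pk, nbins = n)
      link_case[[length(link_case) + 1L]] <- rep(ck, each = m_per_case)
      link_ctl[[length(link_ctl) + 1L]] <- cohort$subject_id[pk]
      link_k[[length(link_k) + 1L]] <- rep(k, length(pk))
      frac[k + 1L] <- (m_per_case * length(ck)) / length(elig)
    }
    links <- data.frame(case_id = unlist(link_case),
                        control_id = unlist(link_ctl),
                        window = unlist(link_k))
    new_selection("risk-set", mode, n, S, rowSums(times), frac,
                  links = links, m_per_case = m_per_case, times = times)
  })
}

#' Exact pair-matched control-exposure sampling
#'
#' Assigns to every qualifying case a single matched control exposure `A'`,
#' drawn as the baseline exposure of one subject sampled uniformly from the
#' scheme's pool: case-base, all subjects sharing the case's `L_0`
#' (irrespective of exposure and survival); survivor, survivors sharing
#' `L_0`; risk-set ITT, subjects event-free at the case's event window
#' sharing `L_0`; risk-set PP, subjects event-free at `t_k`, protocol
#' adherent through `k`, sharing the case's full covariate history
#' `L_0..L_k`. Cases with an empty pool are dropped with a warning and
#' recorded in the `dropped` attribute.
#'
#' @param cohort A `cc_cohort`.
#' @param scheme `"case-base"`, `"survivor"` or `"risk-set"`.
#' @param mode `"ITT"` or `"PP"` (`"PP"` only meaningful for risk-set).
#' @param seed Integer seed.
#' @param allow_self May a case act as its own matched control? Default no.
#' @return A `cc_matched` data frame: `case_id`, `case_window`,
#'   `case_exposure`, `control_id`, `control_exposure`, `match_key`.
#' @export
sample_matched_controls <- function(cohort,
                                    scheme = c("case-base", "survivor",
                                               "risk-set"),
                                    mode = c("ITT", "PP"), seed = NULL,
                                    allow_self = FALSE) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (scheme != "risk-set") mode <- "ITT"
  K <- cohort_K(cohort)
  cases <- qualify_cases(cohort, mode)
  cases <- cases[order(cases$subject_id), , drop = FALSE]
  crow <- match(cases$subject_id, cohort$subject_id)

  # group key per case: pools are identical within a (window, match_key)
  # group, so each pool is materialised once
  case_key <- character(nrow(cases))
  if (scheme %in% c("case-base", "survivor")) {
    case_key <- paste0("L0=", cohort$L0[crow])
  } else if (mode == "ITT") {
    case_key <- paste0("k=", cases$event_window, ";L0=", cohort$L0[crow])
  } else {
    for (k in unique(cases$event_window)) {
      sel <- cases$event_window == k
      Lh <- do.call(paste, c(cohort[crow[sel], paste0("L", 0:k),
                                    drop = FALSE], sep = ","))
      case_key[sel] <- paste0("k=", k, ";L=", Lh)
    }
  }

  local_seed(seed, {
    rows <- list(); dropped <- list()
    for (g in sort(unique(case_key))) {
      in_g <- which(case_key == g)
      k <- if (scheme == "risk-set") cases$event_window[in_g[1]] else NULL
      ref <- crow[in_g[1]]
      pool <- switch(scheme,
        "case-base" = which(cohort$L0 == cohort$L0[ref]),
        "survivor" = which(is.infinite(cohort$T) &
                             cohort$L0 == cohort$L0[ref]),
        "risk-set" = {
          sel <- at_risk_at(cohort$T, k)
          if (mode == "PP") {
            sel <- sel & adherent_through(cohort, rep(k, nrow(cohort)))
            for (kk in 0:k) {
              sel <- sel & !is.na(cohort[[paste0("L", kk)]]) &
                cohort[[paste0("L", kk)]] == cohort[[paste0("L", kk)]][ref]
            }
          } else {
            sel <- sel & cohort$L0 == cohort$L0[ref]
          }
          which(sel)
        })
      npool <- length(pool)
      spos <- match(crow[in_g], pool)     # case's own position in its pool
      self_in <- !allow_self & !is.na(spos)
      eff <- npool - as.integer(self_in)
      ok <- eff >= 1L
      if (any(!ok)) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(case_id = cases$subject_id[in_g[!ok]], match_key = g)
      }
      if (!any(ok)) next
      d <- integer(length(in_g))
      if (any(self_in & ok)) {
        d[self_in & ok] <- skip_self(
          sample.int(npool - 1L, sum(self_in & ok), replace = TRUE),
          spos[self_in & ok])
      }
      if (any(!self_in & ok)) {
        d[!self_in & ok] <- sample.int(npool, sum(!self_in & ok),
                                       replace = TRUE)
      }
      src <- pool[d[ok]]
      i <- in_g[ok]
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cases$subject_id[i],
        case_window = if (scheme == "risk-set") k else NA_integer_,
        case_exposure = cohort$A0[crow[i]],
        control_id = cohort$subject_id[src],
        control_exposure = cohort$A0[src],
        match_key = g)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(case_id = integer(0), case_window = integer(0),
                 case_exposure = integer(0), control_id = integer(0),
                 control_exposure = integer(0), match_key = character(0))
    out <- out[order(out$case_id), , drop = FALSE]
    rownames(out) <- NULL
    drp <- if (length(dropped)) do.call(rbind, dropped) else NULL
    if (!is.null(drp)) {
      cc_warn("cc_empty_pool_warning",
              "%d case(s) dropped for empty matched pools (%s)",
              nrow(drp), paste(unique(drp$match_key), collapse = "; "))
    }
    attr(out, "dropped") <- drp
    attr(out, "scheme") <- scheme
    attr(out, "mode") <- mode
    class(out) <- c("cc_matched", "data.frame")
    out
  })
}

#' Write a control selection or matched set to CSV
#'
#' Selections are written long: one row per subject (single-draw schemes,
#' `window = -1`) or per subject-window (risk-set), with the selected flag
#' and the selection count.
#'
#' @param selection A `cc_selection` or `cc_matched`.
#' @param path Output file.
#' @export
write_selection <- function(selection, path) {
  if (inherits(selection, "cc_matched")) {
    utils::write.csv(as.data.frame(selection), path, row.names = FALSE)
    return(invisible(path))
  }
  if (is.matrix(selection$S)) {
    K <- ncol(selection$S)
    cnt <- matrix(0L, selection$n, K)
    if (!is.null(selection$links)) {
      tb <- table(selection$links$control_id, selection$links$window)
      cnt[cbind(as.integer(rownames(tb))[row(tb)],
                as.integer(colnames(tb))[col(tb)] + 1L)] <- as.integer(tb)
    }
    df <- data.frame(
      subject_id = rep(seq_len(selection$n), K),
      scheme = selection$scheme, mode = selection$mode,
      window = rep(0:(K - 1), each = selection$n),
      selected = as.integer(selection$S),
      times = as.integer(cnt))
    df <- df[df$selected > 0, , drop = FALSE]
  } else {
    df <- data.frame(subject_id = seq_len(selection$n),
                     scheme = selection$scheme, mode = selection$mode,
                     window = -1L, selected = selection$S,
                     times = selection$S)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
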