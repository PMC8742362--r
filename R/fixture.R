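#' Worked-example cohort of nine follow-up courses over twelve windows
#'
#' A fixed cohort of nine subjects on a twelve-window grid reconstructing
#' the textbook walk-through of possible courses of follow-up: rows 4, 5, 7
#' and 9 reach the administrative end event-free; incident events occur in
#' rows 2 (window 3), 3 (window 4), 1 and 6 (window 5) and 8 (window 7);
#' rows 2, 3 and 8 keep a constant exposure level until their events
#' (per-protocol cases), while rows 1 (baseline-exposed) and 6 switch
#' exposure before their events and so qualify as cases only for
#' intention-to-treat contrasts. The five incident events, the per-protocol
#' case set {2, 3, 8}, and the risk-set eligibility walks (all nine rows at
#' the first per-protocol case's window; rows {1, 4..9} at row 1's window;
#' the event-free {4, 5, 7, 8, 9} at row 8's window, of which {4, 5, 7, 9}
#' form row 8's own sampling pool) are pinned by tests.
#'
#' Values not pinned by those properties (the covariate values and the
#' exposure levels of the event-free rows) are fixed arbitrary constants:
#' a time-fixed binary covariate alternating 1, 0, ... across rows, and
#' constant exposure 0/1 alternating across the event-free rows. This
#' reconstruction is synthetic: only the properties listed above are
#' normative.
#'
#' @return A `cc_cohort` of 9 subjects with `K = 12`.
#' @export
figure1_fixture <- function() {
  K <- 12L
  Tw <- c(5, 3, 4, Inf, Inf, 5, Inf, 7, Inf)
  L <- c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  A_full <- list(
    c(1, 1, 1, 0, 0, 0, NA, NA, NA, NA, NA, NA),  # deviates at k=3, event k=5
    c(1, 1, 1, 1, NA, NA, NA, NA, NA, NA, NA, NA),# constant, event k=3
    c(0, 0, 0, 0, 0, NA, NA, NA, NA, NA, NA, NA), # constant, event k=4
    rep(0, 12),
    rep(1, 12),
    c(0, 0, 1, 1, 1, 1, NA, NA, NA, NA, NA, NA),  # deviates at k=2, event k=5
    rep(0, 12),
    c(1, 1, 1, 1, 1, 1, 1, 1, NA, NA, NA, NA),    # constant, event k=7
    rep(1, 12)
  )
  out <- data.frame(subject_id = 1:9, T = Tw)
  for (k in 0:(K - 1)) {
    out[[paste0("L", k)]] <- ifelse(at_risk_at(Tw, k), L, NA_integer_)
  }
  for (k in 0:(K - 1)) {
    out[[paste0("A", k)]] <- vapply(A_full, `[`, numeric(1), k + 1)
  }
  for (k in 1:K) out[[paste0("Y", k)]] <- y_at(Tw, k)
  attr(out, "K") <- K
  attr(out, "L_space") <- 0:1
  class(out) <- c("cc_cohort", "data.frame")
  out
}
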