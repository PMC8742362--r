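## Exposure-propensity estimation from control data and the inverse
## probability weights built from it: time-fixed weights for baseline
## contrasts and telescoping time-varying weights (with censoring at protocol
## deviation) for sustained contrasts.

pkey <- function(df, cols) {
  if (!length(cols)) return(rep("<all>", nrow(df)))
  do.call(paste, c(df[cols], sep = "|"))
}

#' Fit a saturated exposure propensity from control records
#'
#' Stratum-wise empirical exposure frequencies among control records:
#' the sample analogue of the control-conditional propensity (for baseline
#' weights, `Pr(A_0 = 1 | L_0, S = 1)`; for per-protocol window-`j` weights,
#' `Pr(A_j = 1 | L_0..L_j, A_0..A_{j-1}, Y_j = 0, S_j = 1)`). Records may
#' carry a frequency/mass column `wt` (selection multiplicity, or exact
#' probability mass when fitting on an enumerated law). Strata with
#' estimated propensity 0 or 1 are kept but flagged; touching them when
#' computing a weight raises a positivity-violation error.
#'
#' @param records Data frame with a binary `exposure` column, the
#'   conditioning columns and optionally `wt`.
#' @param conditioning Character vector of conditioning column names (may be
#'   empty for the overall exposure prevalence).
#' @param method Only `"saturated"` is implemented; the output contract (a
#'   stratum-to-probability map) is what downstream weighting consumes, so a
#'   parametric fitter can be slotted in by producing the same shape.
#' @return A `cc_propensity`: list with `conditioning`, the stratum table
#'   (`key`, `n`, `wt`, `p`, `flagged`) and a fast lookup vector.
#' @export
fit_propensity <- function(records, conditioning, method = "saturated") {
  method <- match.arg(method, "saturated")
  if (!nrow(records)) {
    cc_stop("cc_argument_error", "no control records to fit propensity on")
  }
  if (!is_binary01(stats::na.omit(records$exposure))) {
    cc_stop("cc_argument_error", "records$exposure must be 0/1")
  }
  wt <- if (is.null(records$wt)) rep(1, nrow(records)) else records$wt
  key <- pkey(records, conditioning)
  num <- tapply(wt * records$exposure, key, sum)
  den <- tapply(wt, key, sum)
  n <- tapply(rep(1, nrow(records)), key, sum)
  p <- as.numeric(num / den)
  strata <- data.frame(key = names(den), n = as.integer(n),
                       wt = as.numeric(den), p = p,
                       flagged = p <= 0 | p >= 1,
                       stringsAsFactors = FALSE)
  structure(list(conditioning = conditioning, strata = strata,
                 lookup = stats::setNames(p, strata$key)),
            class = "cc_propensity")
}

#' @export
print.cc_propensity <- function(x, ...) {
  cat("<cc_propensity> Pr(exposure = 1 |",
      paste(x$conditioning, collapse = ", "), ")\n")
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' Look up fitted propensities for new records
#'
#' @param map A `cc_propensity`.
#' @param newdata Data frame containing the conditioning columns.
#' @return Numeric vector of propensities, strictly inside (0, 1).
#' @export
propensity_value <- function(map, newdata) {
  key <- pkey(newdata, map$conditioning)
  p <- unname(map$lookup[key])
  bad <- is.na(p) | p <= 0 | p >= 1
  if (any(bad)) {
    cc_stop("cc_positivity_violation",
            "propensity missing or degenerate for stratum %s",
            paste(unique(key[bad]), collapse = "; "))
  }
  p
}

#' Time-fixed inverse probability weight
#'
#' `W = a0 / p + (1 - a0) / (1 - p)` with `p` the control-derived baseline
#' exposure propensity. Vectorised over subjects.
#'
#' @param a0 Baseline exposure (0/1).
#' @param p Propensity `Pr(A_0 = 1 | L_0, S = 1)` for the subject's stratum.
#' @return Numeric weights, all positive.
#' @export
time_fixed_weight <- function(a0, p) {
  if (any(is.na(p) | p <= 0 | p >= 1)) {
    cc_stop("cc_positivity_violation",
            "time-fixed weight needs 0 < p < 1 (got %s)",
            paste(unique(p[is.na(p) | p <= 0 | p >= 1]), collapse = ","))
  }
  a0 / p + (1 - a0) / (1 - p)
}

#' Time-varying inverse probability weights along one exposure path
#'
#' `W_k = prod_{j=0..k} [A_j / p_j + (1 - A_j) / (1 - p_j)]`, the telescoping
#' product of per-window inverse propensity factors along a subject's
#' history, with `p_j` the (control-fitted) propensity of the subject's
#' window-`j` stratum.
#'
#' @param A Exposure path `A_0..A_k` (0/1).
#' @param p Per-window propensities `p_0..p_k`.
#' @return Numeric vector `W_0..W_k`.
#' @export
time_varying_weights <- function(A, p) {
  if (length(A) != length(p)) {
    cc_stop("cc_argument_error", "A and p must have equal length")
  }
  if (any(is.na(p) | p <= 0 | p >= 1)) {
    cc_stop("cc_positivity_violation",
            "time-varying weight needs 0 < p_j < 1 at every window")
  }
  cumprod(A / p + (1 - A) / (1 - p))
}

#' Censor subjects at their first protocol deviation
#'
#' Adds a `censor_time` column: the first window `k >= 1` whose exposure
#' differs from the baseline exposure over the subject's at-risk windows
#' (`NA` when the exposure path is constant while at risk). Downstream
#' per-protocol computation ignores windows at or after `censor_time`, so
#' uncensored exposure levels are constant over time.
#'
#' @param cohort A `cc_cohort`.
#' @return The cohort with a `censor_time` column.
#' @export
censor_at_deviation <- function(cohort) {
  K <- cohort_K(cohort)
  cens <- rep(NA_integer_, nrow(cohort))
  if (K > 1) {
    for (k in 1:(K - 1)) {
      Ak <- cohort[[paste0("A", k)]]
      hit <- is.na(cens) & !is.na(Ak) & Ak != cohort$A0
      cens[hit] <- k
    }
  }
  cohort$censor_time <- cens
  cohort
}
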