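#' @keywords internal
"_PACKAGE"

## Classed error helper: every structured failure mode raises a condition whose
## class downstream code and tests can catch explicitly.
cc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

cc_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "cc_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

## Canonical history key. L and A are integer vectors (possibly length 0).
## Used both when tabulating laws and when looking them up, so the two can
## never drift apart.
hist_key <- function(L, A) {
  paste0(paste(L, collapse = ","), ";", paste(A, collapse = ","))
}

## Vectorised running keys for cohort simulation: `acc` is the key so far.
lk_name <- function(k, u, key) paste(k, u, key, sep = "|")

## Run code under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## Draw categorical values by inverse CDF from a matrix of probabilities
## (rows = draws, cols = categories); u is a uniform vector.
draw_categorical <- function(P, u, values) {
  stopifnot(nrow(P) == length(u))
  cum <- P
  if (ncol(P) > 1L) {
    for (j in 2:ncol(P)) cum[, j] <- cum[, j - 1L] + P[, j]
  }
  idx <- rep(1L, length(u))
  if (ncol(P) > 1L) {
    idx <- idx + rowSums(u > cum[, -ncol(cum), drop = FALSE])
  }
  values[idx]
}

is_binary01 <- function(x) all(x %in% c(0L, 1L))
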