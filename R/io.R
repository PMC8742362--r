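## Serialization: cohort models as JSON/YAML law tables, estimand and
## propensity reports as JSON.

#' Write / read a cohort model as law tables
#'
#' A validated spec is serialized through its canonical table form (stratum
#' to probability maps keyed by history values), as JSON or YAML depending
#' on the file extension. Reading rebuilds table-backed law functions and
#' re-validates, so a round trip reproduces the model exactly.
#'
#' @param spec A validated [dgp_spec()].
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @export
write_dgp_spec <- function(spec, path) {
  spec <- ensure_validated(spec)
  payload <- list(
    K = spec$K, L_space = spec$L_space,
    include_U = spec$include_U, p_U = spec$p_U,
    freeze_exposure = spec$freeze_exposure,
    constant_hazard_enforced = spec$constant_hazard_enforced,
    homogeneity_scale = spec$homogeneity_scale,
    label = spec$label,
    tables = lapply(spec$tables, function(tb) as.list(as.data.frame(tb)))
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_dgp_spec
#' @export
read_dgp_spec <- function(path) {
  payload <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  tabs <- lapply(payload$tables, as.data.frame)
  Ls <- as.integer(payload$L_space)
  exp_lk <- stats::setNames(tabs$exposure$p,
                            lk_name(tabs$exposure$k, tabs$exposure$u,
                                    tabs$exposure$key))
  haz_lk <- stats::setNames(tabs$hazard$p,
                            lk_name(tabs$hazard$k, tabs$hazard$u,
                                    tabs$hazard$key))
  has_cov <- !is.null(tabs$covariate) && nrow(tabs$covariate) > 0
  cov_lk <- if (has_cov) {
    stats::setNames(tabs$covariate$prob,
                    paste(lk_name(tabs$covariate$k, tabs$covariate$u,
                                  tabs$covariate$key),
                          tabs$covariate$l, sep = "|"))
  } else numeric(0)
  need <- function(v, what, key) {
    if (any(is.na(v))) {
      cc_stop("cc_argument_error",
              "serialized spec has no %s entry for history %s", what, key)
    }
    v
  }
  init <- tabs$init
  spec <- dgp_spec(
    K = payload$K, L_space = Ls,
    init_L = function(u) {
      sel <- init$u == u
      init$prob[sel][match(Ls, init$l[sel])] / sum(init$prob[sel])
    },
    exposure_law = function(k, L, A, u) {
      need(unname(exp_lk[lk_name(k, u, hist_key(L, A))]), "exposure",
           hist_key(L, A))
    },
    covariate_law = if (has_cov) function(k, L, A, u) {
      p <- unname(cov_lk[paste(lk_name(k, u, hist_key(L, A)), Ls,
                               sep = "|")])
      p[is.na(p)] <- 0
      p
    } else NULL,
    hazard_law = function(k, L, A, u) {
      need(unname(haz_lk[lk_name(k, u, hist_key(L, A))]), "hazard",
           hist_key(L, A))
    },
    include_U = isTRUE(payload$include_U), p_U = payload$p_U,
    freeze_exposure = isTRUE(payload$freeze_exposure),
    constant_hazard_enforced = isTRUE(payload$constant_hazard_enforced),
    homogeneity_scale = payload$homogeneity_scale %||% "none",
    label = payload$label
  )
  validate_spec(spec)
}

#' Write an estimand report as JSON records
#'
#' @param estimand A `cc_estimand` (or list of them).
#' @param path Output path.
#' @export
write_estimand_report <- function(estimand, path) {
  if (inherits(estimand, "cc_estimand")) estimand <- list(estimand)
  recs <- lapply(estimand, function(e) {
    v <- e$value
    if (is.data.frame(v)) {
      lapply(seq_len(nrow(v)), function(i)
        list(kind = e$kind, window = v$window[i], stratum = v$history[i],
             value = v$ratio[i]))
    } else if (is.matrix(v)) {
      out <- list()
      for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
        out[[length(out) + 1L]] <- list(kind = e$kind,
                                        window = j - 1L,
                                        stratum = rownames(v)[i],
                                        value = v[i, j])
      out
    } else {
      lapply(seq_along(v), function(i)
        list(kind = e$kind,
             window = if (!is.null(e$window)) e$window[i],
             stratum = names(v)[i], value = unname(v[i])))
    }
  })
  jsonlite::write_json(do.call(c, recs), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write a fitted propensity map as JSON
#'
#' @param map A `cc_propensity`.
#' @param path Output path.
#' @export
write_propensity <- function(map, path) {
  jsonlite::write_json(
    list(conditioning = map$conditioning,
         strata = lapply(seq_len(nrow(map$strata)), function(i)
           list(key = map$strata$key[i], n = map$strata$n[i],
                p = map$strata$p[i]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
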