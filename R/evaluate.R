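# Model comparison and accuracy reporting.

# Pearson correlation with a defined answer for degenerate input: zero
# variance in either series yields NA (with a warning) rather than an error.
.safe_cor <- function(a, b, method = "pearson") {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("need at least 3 pairs for a correlation")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a series; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}

#' Compare fitted genomic prediction models
#'
#' Builds one row per fit with the AIC, variance components, range parameter,
#' the Pearson correlation between GEBVs and the phenotypes (stage-1 fitted
#' values) of the phenotyped individuals, and — when true breeding values are
#' supplied — the Pearson correlation between GEBVs and TBVs, computed over
#' the unphenotyped (validation) individuals by default.
#'
#' @param fits Named list of [gsblup()] fits on the same phenotyped set.
#' @param tbv Optional true breeding values: named numeric vector or a data
#'   frame with columns `individual` and `tbv`.
#' @param validation `"unphenotyped"` (default) or `"all"`: which individuals
#'   enter the GEBV-TBV correlation.
#' @return Data frame of class `gs_comparison`: columns `model`, `kernel`,
#'   `residual`, `aic`, `delta_aic`, `rank_aic`, `sigma2_g`, `sigma2_iid`
#'   (residual or polygenic variance), `theta`, `cor_fitted`, `cor_tbv`.
#' @export
compare_models <- function(fits, tbv = NULL,
                           validation = c("unphenotyped", "all")) {
  validation <- match.arg(validation)
  if (inherits(fits, "gsblup")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "gsblup")))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f) {
      paste0(f$kernel,
             if (f$residual == "fixed") "+fixed_resid" else "",
             if (f$pedigree_mode) "+pedigree" else "")
    }, "")

  obs_sets <- lapply(fits, function(f) sort(f$obs_ids))
  if (!all(vapply(obs_sets, identical, TRUE, obs_sets[[1L]])))
    stop("fits were not made on the same phenotyped individuals")

  if (is.data.frame(tbv)) {
    stopifnot(all(c("individual", "tbv") %in% names(tbv)))
    tbv <- setNames(tbv$tbv, as.character(tbv$individual))
  }

  row_of <- function(f) {
    fv <- fitted(f)
    cf <- tryCatch(suppressWarnings(.safe_cor(fv, f$y[f$obs_ids])),
                   error = function(e) NA_real_)
    ct <- NA_real_
    if (!is.null(tbv)) {
      g <- f$gebv
      keep <- if (validation == "unphenotyped") !g$phenotyped else rep(TRUE, nrow(g))
      ids <- intersect(g$individual[keep], names(tbv))
      if (length(ids) >= 3L) {
        gv <- setNames(g$gebv, g$individual)[ids]
        ct <- tryCatch(suppressWarnings(.safe_cor(gv, tbv[ids])),
                       error = function(e) NA_real_)
      }
    }
    vc <- f$vc
    data.frame(kernel = f$kernel, residual = f$residual,
               aic = f$aic,
               sigma2_g = if ("g" %in% names(vc)) vc[["g"]] else NA_real_,
               sigma2_iid = vc[[if (f$residual == "fixed") "v" else "e"]],
               theta = f$theta, cor_fitted = cf, cor_tbv = ct,
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(fits, row_of))
  out <- cbind(model = names(fits), out, row.names = NULL)
  out$delta_aic <- out$aic - min(out$aic)
  out$rank_aic <- rank(out$aic, ties.method = "min")
  out <- out[, c("model", "kernel", "residual", "aic", "delta_aic", "rank_aic",
                 "sigma2_g", "sigma2_iid", "theta", "cor_fitted", "cor_tbv")]
  class(out) <- c("gs_comparison", "data.frame")
  out
}

#' @export
print.gs_comparison <- function(x, digits = 4, ...) {
  cat("Genomic prediction model comparison (smaller AIC preferred)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], function(v) signif(v, digits))
  print(y, row.names = FALSE)
  invisible(x)
}
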