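# Stage 1: per-individual logistic growth curves and extrapolation.
#
# Each phenotyped individual i has a short series y_it observed at a handful
# of times.  The mean curve is the 3-parameter logistic
#
#   E(y_it) = alpha_i / (1 + beta_i exp(-gamma_i t))
#
# (asymptote / shape / rate), fitted separately per individual by nonlinear
# least squares.  With 5 time points this leaves 2 error degrees of freedom
# per individual; the residual variance is pooled across individuals as
# sigma2 = sum(RSS_i) / sum(df_i).  The curve is then extrapolated to a target
# time with a delta-method standard error computed from the pooled variance
# ("re-fit with the residual variance fixed": the least-squares optimum is
# unchanged, only the parameter covariance is rescaled), and the squared
# standard error is carried forward as a known within-individual error
# variance.

.logistic_mean <- function(t, alpha, beta, gamma) alpha / (1 + beta * exp(-gamma * t))

# Jacobian of the logistic mean wrt (alpha, beta, gamma), rows = times
.logistic_jac <- function(t, alpha, beta, gamma) {
  E <- exp(-gamma * t)
  den <- 1 + beta * E
  cbind(alpha = 1 / den,
        beta  = -alpha * E / den^2,
        gamma = alpha * beta * t * E / den^2)
}

#' Fit a three-parameter logistic growth curve to one individual
#'
#' Nonlinear least squares for E(y) = alpha / (1 + beta exp(-gamma t)).
#' Starting values are derived deterministically from the data (asymptote from
#' the series maximum, rate from the log-slope between the first and last
#' observations, shape from the first observation), backed by a fixed fallback
#' grid of rates, so the fit is reproducible without any random numbers.
#'
#' @param time,y Numeric vectors of observation times (strictly increasing)
#'   and trait values; at least 4 points (3 parameters + 1 error df).
#' @return Object of class `logistic_fit`: list with `par` (named vector
#'   alpha, beta, gamma), `rss`, `df` (residual degrees of freedom, n - 3),
#'   `fitted`, `converged`, and the data.
#' @export
fit_logistic <- function(time, y) {
  stopifnot(length(time) == length(y))
  if (length(time) < 4L) stop("need >= 4 observations for a 3-parameter logistic fit")
  if (is.unsorted(time, strictly = TRUE)) stop("times must be strictly increasing")
  if (!all(is.finite(time)) || !all(is.finite(y))) stop("non-finite observations")

  dat <- data.frame(t = time, y = y)
  n <- length(y)

  degenerate <- stats::sd(y) == 0
  ymax <- max(y)
  alpha0 <- if (ymax > 0) 1.05 * ymax else 1
  tspan <- diff(range(time))
  # log-slope heuristic: y rises from y1 toward alpha; crude rate scale
  g0 <- {
    y1 <- y[1L]; yn <- y[n]
    r <- abs(yn - y1) / max(abs(alpha0), 1)
    max(min(-log(max(1 - r, 0.05)) / tspan * 3, 10 / tspan), 0.2 / tspan)
  }
  b0 <- {
    b <- alpha0 / max(y[1L], alpha0 / 100) - 1
    if (!is.finite(b) || b <= 0) 9 else b
  }
  starts <- rbind(c(alpha0, b0, g0),
                  cbind(alpha0, b0, c(0.5, 1, 2, 5, 10) / tspan),
                  c(alpha0, 1, 2 / tspan))

  best <- NULL
  if (!degenerate) {
    for (s in seq_len(nrow(starts))) {
      st <- list(alpha = unname(starts[s, 1]), beta = unname(starts[s, 2]),
                 gamma = unname(starts[s, 3]))
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nlsLM(
          y ~ alpha / (1 + beta * exp(-gamma * t)), data = dat, start = st,
          lower = c(-Inf, 1e-10, 1e-10),
          control = minpack.lm::nls.lm.control(maxiter = 200))),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
        if (rss <= 1e-12 * max(1, sum(y^2))) break
      }
    }
  }

  if (is.null(best)) {
    # degenerate or unfittable series: boundary fit at a flat curve
    par <- c(alpha = mean(y), beta = 1e-10, gamma = 1e-10)
    out <- list(par = par, rss = sum((y - mean(y))^2), df = n - 3L,
                fitted = rep(mean(y), n), converged = FALSE,
                time = time, y = y)
  } else {
    par <- coef(best$fit)[c("alpha", "beta", "gamma")]
    out <- list(par = par, rss = best$rss, df = n - 3L,
                fitted = .logistic_mean(time, par[1L], par[2L], par[3L]),
                converged = TRUE, time = time, y = y)
  }
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic growth fit: alpha =", format(x$par[1L], digits = 5),
      " beta =", format(x$par[2L], digits = 5),
      " gamma =", format(x$par[3L], digits = 5), "\n")
  cat(sprintf("RSS = %.6g on %d error df%s\n", x$rss, x$df,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Pooled residual variance across individual growth fits
#'
#' Returns sum(RSS_i) / sum(df_i).  With 5 observations per individual each
#' fit contributes 2 error degrees of freedom, so this equals RSS / (2 n).
#'
#' @param fits List of [fit_logistic()] results.
#' @return Pooled residual variance (scalar).
#' @export
pooled_variance <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied")
  rss <- vapply(fits, function(f) f$rss, 0)
  df <- vapply(fits, function(f) as.numeric(f$df), 0)
  if (any(df <= 0)) stop("fits with no error degrees of freedom")
  sum(rss) / sum(df)
}

#' Extrapolate a fitted growth curve with a delta-method standard error
#'
#' Predicts the trait at `target_time` from a logistic fit and attaches the
#' standard error of the predicted mean, se^2 = grad' Cov grad with
#' Cov = pooled_var * (J'J)^-1 (J the Jacobian at the least-squares optimum,
#' grad the gradient of the mean curve at the target time).  Fixing the
#' residual variance at the pooled estimate leaves the point estimate
#' untouched; it only scales the parameter covariance.
#'
#' @param fit A `logistic_fit`.
#' @param target_time Time at which to predict (extrapolation allowed).
#' @param pooled_var Pooled residual variance from [pooled_variance()].
#' @return List with `prediction`, `se`, and `var` (= se^2; `Inf` when J'J is
#'   singular, in which case the individual should be excluded downstream).
#' @export
predict_growth <- function(fit, target_time, pooled_var) {
  stopifnot(inherits(fit, "logistic_fit"), pooled_var >= 0)
  p <- fit$par
  pred <- .logistic_mean(target_time, p[1L], p[2L], p[3L])
  J <- .logistic_jac(fit$time, p[1L], p[2L], p[3L])
  g <- drop(.logistic_jac(target_time, p[1L], p[2L], p[3L]))
  JtJ <- crossprod(J)
  v <- tryCatch(pooled_var * drop(crossprod(g, solve(JtJ, g))),
                error = function(e) Inf)
  if (!is.finite(v) || v < 0) v <- Inf
  if (pooled_var == 0) v <- 0
  list(prediction = unname(pred), se = sqrt(v), var = v)
}

#' Stage-1 growth-curve extrapolation for a whole population
#'
#' Runs the two-pass procedure: fit a logistic curve to every individual,
#' pool the residual variance across individuals, then predict every
#' individual's trait at the target time with a standard error based on the
#' pooled variance.  The squared standard errors are the known
#' within-individual error variances used by [gsblup()]'s fixed-residual mode.
#'
#' @param data Long-format data frame of repeated measures.
#' @param target_time Prediction time (typically beyond the last measurement).
#' @param id,time,value Column names in `data` (defaults `"individual"`,
#'   `"time"`, `"value"`).
#' @return Object of class `growth_extrapolation`: list with `table`
#'   (data frame: individual, prediction, se, var), `pooled_variance`,
#'   `pooled_df`, `n`, `target_time`, `fits` (named list of `logistic_fit`s)
#'   and `flagged` (ids of non-converged or variance-degenerate fits).
#' @export
growth_extrapolate <- function(data, target_time,
                               id = "individual", time = "time", value = "value") {
  stopifnot(is.data.frame(data), all(c(id, time, value) %in% names(data)))
  ids <- unique(as.character(data[[id]]))
  if (length(ids) == 0L) stop("no individuals in data")

  fits <- vector("list", length(ids)); names(fits) <- ids
  for (i in ids) {
    d <- data[as.character(data[[id]]) == i, , drop = FALSE]
    d <- d[order(d[[time]]), , drop = FALSE]
    fits[[i]] <- fit_logistic(d[[time]], d[[value]])
  }
  pv <- pooled_variance(fits)
  preds <- lapply(fits, predict_growth, target_time = target_time, pooled_var = pv)

  tab <- data.frame(individual = ids,
                    prediction = vapply(preds, `[[`, 0, "prediction"),
                    se = vapply(preds, `[[`, 0, "se"),
                    var = vapply(preds, `[[`, 0, "var"),
                    row.names = NULL, stringsAsFactors = FALSE)
  flagged <- ids[!vapply(fits, `[[`, TRUE, "converged") | !is.finite(tab$var)]
  out <- list(table = tab, pooled_variance = pv,
              pooled_df = sum(vapply(fits, function(f) as.numeric(f$df), 0)),
              n = length(ids), target_time = target_time,
              fits = fits, flagged = flagged)
  class(out) <- "growth_extrapolation"
  out
}

#' @export
print.growth_extrapolation <- function(x, ...) {
  cat(sprintf("Stage-1 logistic extrapolation to time %s\n", format(x$target_time)))
  cat(sprintf("  %d individuals, pooled residual variance %.6g on %d df\n",
              x$n, x$pooled_variance, x$pooled_df))
  if (length(x$flagged))
    cat("  flagged individuals:", paste(x$flagged, collapse = ", "), "\n")
  cat("  predictions: "); print(summary(x$table$prediction))
  invisible(x)
}

#' @export
summary.growth_extrapolation <- function(object, ...) {
  structure(list(n = object$n, pooled_variance = object$pooled_variance,
                 pooled_df = object$pooled_df, target_time = object$target_time,
                 flagged = object$flagged,
                 prediction = summary(object$table$prediction),
                 se = summary(object$table$se)),
            class = "summary.growth_extrapolation")
}

#' @export
print.summary.growth_extrapolation <- function(x, ...) {
  cat(sprintf("Stage 1: %d individuals extrapolated to time %s\n",
              x$n, format(x$target_time)))
  cat(sprintf("Pooled residual variance: %.6g (%d df)\n", x$pooled_variance, x$pooled_df))
  cat("Predictions:\n"); print(x$prediction)
  cat("Standard errors:\n"); print(x$se)
  if (length(x$flagged)) cat("Flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.growth_extrapolation <- function(x, ...) x$table
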