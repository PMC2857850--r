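# The main fitting function and its methods.

#' Control parameters for [gsblup()]
#'
#' @param theta_grid_n Number of log-spaced points in the outer range-parameter
#'   grid (default 13).
#' @param golden_iter Maximum golden-section refinement iterations for the
#'   range parameter (default 25).
#' @param boundary_tol Log-likelihood tolerance for declaring a variance
#'   component to be at the zero boundary (default 1e-6): a component is set to
#'   exactly 0 when dropping it costs less than this much likelihood.
#' @param maxit Maximum iterations for the inner variance optimizer.
#' @return Named list of control values.
#' @export
gs_control <- function(theta_grid_n = 13L, golden_iter = 25L,
                       boundary_tol = 1e-6, maxit = 200L) {
  list(theta_grid_n = as.integer(theta_grid_n),
       golden_iter = as.integer(golden_iter),
       boundary_tol = boundary_tol, maxit = as.integer(maxit))
}

#' Genomic BLUP with ridge-regression or geostatistical kernels
#'
#' Fits the mixed model y_i = mu + g_i + v_i + e_i by REML, where g is the
#' marker-explained genetic effect with var(g) = sigma2_g * Gamma, Gamma
#' either ZZ' (`kernel = "rr"`), a distance-decay correlation matrix f(D)
#' (spatial kernels), or omitted (`"independent"`).  Two residual modes:
#' *pooled* (default) fits a single iid variance absorbing both the polygenic
#' effect and the residual error; *fixed* takes known heterogeneous
#' within-individual error variances (e.g. squared stage-1 standard errors
#' from [growth_extrapolate()]) and fits a free iid polygenic variance
#' sigma2_v on top.  A pedigree adds father, mother and cross variance
#' components.  The kernel range parameter theta is estimated by profiling the
#' REML likelihood unless supplied.  Breeding values (GEBVs, the BLUPs of
#' mu + h_i) are returned for every genotyped individual; unphenotyped
#' individuals are predicted through the cross-covariance block (and through
#' predicted parent effects when pedigree components are fitted).
#'
#' @param y Named numeric vector of phenotypes (names = individual ids), or a
#'   [growth_extrapolate()] result, in which case the stage-1 predictions are
#'   used (and their squared standard errors when `residual = "fixed"`).
#' @param genotypes Numeric marker matrix in -1/0/1 coding with individual ids
#'   as row names, covering phenotyped and to-be-predicted individuals.  May
#'   be `NULL` for `kernel = "independent"` with a pedigree.
#' @param kernel One of `"rr"`, `"independent"`, `"linear"`, `"quadratic"`,
#'   `"power"`, `"exponential"`, `"gaussian"`, `"spherical"`.
#' @param theta Fixed range parameter; `NULL` (default) profiles it.
#' @param residual `"pooled"` or `"fixed"` (see above).
#' @param residual_var Named vector of known within-individual error variances
#'   for `residual = "fixed"`; taken from `y` when `y` is a stage-1 object.
#' @param pedigree Optional data frame (`individual`, `father`, `mother`)
#'   switching on the extended father/mother/cross model.
#' @param stabilize Policy for repairing an indefinite Gamma, see
#'   [stabilize_gamma()].
#' @param control See [gs_control()].
#' @return Object of class `gsblup`; see [print.gsblup()], [summary.gsblup()],
#'   [predict.gsblup()].  Key fields: `vc` (named variance components, exact
#'   zeros at the boundary), `theta`, `loglik`, `aic`, `mu`, `gebv`
#'   (data frame: individual, gebv, phenotyped), `lambda2`
#'   (= sigma2_e / sigma2_g, the ridge penalty, for pooled RR fits).
#' @export
gsblup <- function(y, genotypes = NULL,
                   kernel = c("rr", "independent", "linear", "quadratic",
                              "power", "exponential", "gaussian", "spherical"),
                   theta = NULL, residual = c("pooled", "fixed"),
                   residual_var = NULL, pedigree = NULL,
                   stabilize = c("clip", "jitter"), control = gs_control()) {
  kernel <- match.arg(kernel)
  residual <- match.arg(residual)
  stabilize <- match.arg(stabilize)
  cl <- match.call()

  if (inherits(y, "growth_extrapolation")) {
    stage1 <- y
    ok <- is.finite(stage1$table$var)
    if (!all(ok))
      warning("excluding individuals with singular stage-1 fits: ",
              paste(stage1$table$individual[!ok], collapse = ", "))
    tab <- stage1$table[ok, , drop = FALSE]
    if (residual == "fixed" && is.null(residual_var))
      residual_var <- setNames(tab$var, tab$individual)
    y <- setNames(tab$prediction, tab$individual)
  }
  if (is.null(names(y))) stop("y must carry individual ids as names")
  if (anyDuplicated(names(y))) stop("duplicated ids in y")
  if (!all(is.finite(y))) stop("non-finite phenotypes")
  if (residual == "fixed") {
    if (is.null(residual_var)) stop("residual = 'fixed' needs residual_var (or a stage-1 object)")
    if (!all(names(y) %in% names(residual_var)))
      stop("residual_var missing for some phenotyped individuals")
    r_fixed <- unname(residual_var[names(y)])
    if (any(!is.finite(r_fixed) | r_fixed < 0)) stop("invalid residual_var values")
  } else r_fixed <- NULL

  uses_markers <- kernel != "independent"
  if (uses_markers) {
    if (is.null(genotypes)) stop(sprintf("kernel '%s' needs genotypes", kernel))
    if (is.null(rownames(genotypes))) stop("genotypes must carry individual ids as row names")
    miss <- setdiff(names(y), rownames(genotypes))
    if (length(miss)) stop("phenotyped individuals without genotypes: ",
                           paste(utils::head(miss, 5L), collapse = ", "))
  }

  all_ids <- unique(c(if (!is.null(genotypes)) rownames(genotypes),
                      if (!is.null(pedigree)) as.character(pedigree$individual),
                      names(y)))
  if (uses_markers) {
    no_geno <- setdiff(all_ids, rownames(genotypes))
    if (length(no_geno)) {
      warning("excluding individuals without genotypes from prediction: ",
              paste(utils::head(no_geno, 5L), collapse = ", "))
      all_ids <- setdiff(all_ids, no_geno)
    }
  }
  obs <- names(y)
  n <- length(obs)
  if (n < 3L) stop("need at least 3 phenotyped individuals")

  # ---- training covariance components -------------------------------------
  Z_obs <- if (uses_markers) genotypes[obs, , drop = FALSE]
  stab_report <- NULL
  theta_trace <- NULL
  theta_estimated <- FALSE

  extra <- NULL
  ped_design <- NULL
  if (!is.null(pedigree)) {
    ped_design <- omega_design(pedigree, obs)
    extra <- list(f = ped_design$V_f, m = ped_design$V_m, c = ped_design$V_c)
  }

  if (kernel == "independent") {
    fit <- .fit_inner(y, NULL, extra, r_fixed, control)
    theta_hat <- NA_real_
    Gamma_obs <- NULL
  } else if (kernel == "rr") {
    Gamma_obs <- rr_gamma(Z_obs)
    fit <- .fit_inner(y, Gamma_obs, extra, r_fixed, control)
    theta_hat <- NA_real_
  } else {
    D_obs <- genotype_dist(Z_obs)
    if (is.null(theta)) {
      theta_estimated <- TRUE
      prof <- .profile_theta(y, D_obs, kernel, extra, r_fixed,
                             stabilize_policy = stabilize, control)
      theta_hat <- prof$theta
      fit <- prof$fit
      stab_report <- prof$stab
      theta_trace <- prof$trace
      Gamma_obs <- suppressWarnings(
        stabilize_gamma(build_gamma(D_obs, kernel, theta_hat), policy = stabilize))
    } else {
      .check_theta(kernel, theta)
      theta_hat <- theta
      Gamma_obs <- stabilize_gamma(build_gamma(D_obs, kernel, theta_hat),
                                   policy = stabilize)
      stab_report <- attr(Gamma_obs, "stabilization")
      fit <- .fit_inner(y, Gamma_obs, extra, r_fixed, control)
    }
  }

  # ---- assemble estimates --------------------------------------------------
  iid_name <- if (residual == "fixed") "v" else "e"
  s2get <- function(k) if (k %in% names(fit$s2)) unname(fit$s2[[k]]) else 0
  vc <- setNames(numeric(0), character(0))
  if (kernel != "independent") vc["g"] <- s2get("g")
  if (!is.null(extra)) for (k in c("f", "m", "c")) vc[k] <- s2get(k)
  vc[iid_name] <- s2get(iid_name)
  boundary <- intersect(names(vc), fit$boundary)

  q <- length(vc) + theta_estimated
  loglik <- fit$loglik
  aic <- -2 * loglik + 2 * q

  # ---- BLUPs ---------------------------------------------------------------
  V <- matrix(0, n, n)
  if (kernel != "independent") V <- V + vc[["g"]] * Gamma_obs
  if (!is.null(extra)) V <- V + omega_matrix(ped_design, vc[["f"]], vc[["m"]], vc[["c"]])
  V <- V + diag(vc[[iid_name]], n)
  if (!is.null(r_fixed)) V <- V + diag(r_fixed, n)
  cV <- chol(V)
  Vi1 <- backsolve(cV, backsolve(cV, rep(1, n), transpose = TRUE))
  mu <- sum(Vi1 * y) / sum(Vi1)
  r <- y - mu
  Vinv_r <- backsolve(cV, backsolve(cV, r, transpose = TRUE))

  gebv <- setNames(rep(mu, length(all_ids)), all_ids)
  ghat <- setNames(rep(0, length(all_ids)), all_ids)
  if (kernel != "independent" && vc[["g"]] > 0) {
    K_all <- .gamma_cross(genotypes[all_ids, , drop = FALSE], Z_obs,
                          kernel, theta_hat)
    ghat[] <- vc[["g"]] * drop(K_all %*% Vinv_r)
    gebv <- gebv + ghat
  }
  vhat <- setNames(rep(0, n), obs)
  if (residual == "fixed" && vc[["v"]] > 0) {
    vhat[] <- vc[["v"]] * Vinv_r
    gebv[obs] <- gebv[obs] + vhat
  }
  if (!is.null(extra)) {
    full_design <- omega_design(pedigree,
                                intersect(all_ids, as.character(pedigree$individual)))
    for (k in c("f", "m", "c")) {
      if (vc[[k]] <= 0) next
      lab_all <- switch(k, f = full_design$father, m = full_design$mother,
                        c = full_design$cross)
      lab_obs <- switch(k, f = ped_design$father, m = ped_design$mother,
                        c = ped_design$cross)
      S <- outer(lab_all, lab_obs, "==") * 1
      gebv[names(lab_all)] <- gebv[names(lab_all)] + vc[[k]] * drop(S %*% Vinv_r)
    }
  }

  lambda2 <- if (kernel == "rr" && residual == "pooled" && vc[["g"]] > 0)
    vc[["e"]] / vc[["g"]] else NA_real_

  out <- list(call = cl, kernel = kernel, residual = residual,
              pedigree_mode = !is.null(pedigree),
              vc = vc, boundary = boundary,
              theta = theta_hat, theta_estimated = theta_estimated,
              mu = mu, loglik = loglik, q = q, aic = aic, lambda2 = lambda2,
              n_obs = n, y = y,
              gebv = data.frame(individual = all_ids,
                                gebv = unname(gebv[all_ids]),
                                phenotyped = all_ids %in% obs,
                                row.names = NULL, stringsAsFactors = FALSE),
              ghat = ghat, vhat = vhat,
              stabilization = stab_report, theta_trace = theta_trace,
              convergence = fit$convergence,
              Z_obs = Z_obs, Vinv_r = Vinv_r, obs_ids = obs)
  class(out) <- "gsblup"
  out
}

# cross-covariance block between a set of individuals and the training set
.gamma_cross <- function(Z_new, Z_obs, kernel, theta) {
  if (kernel == "rr") return(tcrossprod(Z_new, Z_obs))
  kernel_value(kernel, cross_dist(Z_new, Z_obs), theta)
}

.vc_labels <- c(g = "sigma2_g (markers)", f = "sigma2_f (father)",
                m = "sigma2_m (mother)", c = "sigma2_c (cross)",
                v = "sigma2_v (polygenic)", e = "sigma2_e (residual)")

#' @export
print.gsblup <- function(x, digits = 5, ...) {
  cat(sprintf("Genomic BLUP fit (kernel = %s, residual = %s%s)\n",
              x$kernel, x$residual,
              if (x$pedigree_mode) ", father/mother/cross effects" else ""))
  cat(sprintf("  n phenotyped = %d, individuals predicted = %d\n",
              x$n_obs, nrow(x$gebv)))
  vc <- x$vc
  lab <- .vc_labels[names(vc)]
  for (i in seq_along(vc))
    cat(sprintf("  %-22s %s%s\n", lab[i], format(vc[i], digits = digits),
                if (names(vc)[i] %in% x$boundary) "  (boundary)" else ""))
  if (!is.na(x$theta))
    cat(sprintf("  theta                  %s%s\n", format(x$theta, digits = digits),
                if (x$theta_estimated) "  (profiled REML)" else "  (fixed)"))
  cat(sprintf("  mu = %s, REML logLik = %s, AIC = %s (q = %d)\n",
              format(x$mu, digits = digits), format(x$loglik, digits = 8),
              format(x$aic, digits = 8), x$q))
  if (!is.na(x$lambda2))
    cat(sprintf("  ridge penalty lambda^2 = sigma2_e/sigma2_g = %s\n",
                format(x$lambda2, digits = digits)))
  invisible(x)
}

#' @export
summary.gsblup <- function(object, ...) {
  obs <- object$obs_ids
  fv <- fitted(object)
  structure(list(fit = object,
                 cor_fitted = .safe_cor(fv, object$y[obs]),
                 n_unphenotyped = sum(!object$gebv$phenotyped)),
            class = "summary.gsblup")
}

#' @export
print.summary.gsblup <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  GEBV vs phenotype correlation (phenotyped): %s\n",
              format(x$cor_fitted, digits = 4)))
  cat(sprintf("  unphenotyped individuals predicted: %d\n", x$n_unphenotyped))
  if (!is.null(x$fit$stabilization) && isTRUE(x$fit$stabilization$applied))
    cat(sprintf("  note: Gamma stabilized (%s; min eigenvalue %.3g)\n",
                x$fit$stabilization$policy, x$fit$stabilization$min_eigenvalue))
  invisible(x)
}

#' @export
coef.gsblup <- function(object, ...) c(mu = object$mu)

#' Variance component estimates of a `gsblup` fit
#'
#' @param object A `gsblup` fit.
#' @return Named numeric vector of REML variance component estimates
#'   (boundary estimates are exact zeros); the profiled `theta` is appended
#'   when it was estimated.
#' @export
varcomp <- function(object) {
  stopifnot(inherits(object, "gsblup"))
  out <- object$vc
  if (object$theta_estimated) out <- c(out, theta = object$theta)
  out
}

#' @export
logLik.gsblup <- function(object, ...) {
  structure(object$loglik, df = object$q, nobs = object$n_obs,
            class = "logLik")
}

#' @export
fitted.gsblup <- function(object, ...) {
  g <- object$gebv
  setNames(g$gebv, g$individual)[object$obs_ids]
}

#' @export
residuals.gsblup <- function(object, ...) {
  object$y[object$obs_ids] - fitted(object)
}

#' Predict breeding values for new genotyped individuals
#'
#' Conditional-expectation BLUP for individuals not in the training set:
#' mu + sigma2_g * Gamma_new,obs V^-1 (y - mu), with the cross block from the
#' fitted kernel; predicted father/mother/cross effects are added for
#' individuals whose parents appear in the training data when those variance
#' components are positive.
#'
#' @param object A `gsblup` fit.
#' @param genotypes Marker matrix for the new individuals (same marker set as
#'   the training genotypes); `NULL` returns the in-fit GEBV table.
#' @param pedigree Optional pedigree covering the new individuals.
#' @param ... Unused.
#' @return Named vector of GEBVs (or the in-fit GEBV data frame when
#'   `genotypes` is `NULL`).
#' @export
predict.gsblup <- function(object, genotypes = NULL, pedigree = NULL, ...) {
  if (is.null(genotypes)) return(object$gebv)
  if (object$kernel == "independent" && is.null(pedigree))
    stop("the independent model predicts new individuals only through a pedigree")
  ids <- rownames(genotypes)
  out <- setNames(rep(object$mu, nrow(genotypes)), ids)
  if (object$kernel != "independent" && object$vc[["g"]] > 0) {
    K <- .gamma_cross(genotypes, object$Z_obs, object$kernel, object$theta)
    out <- out + object$vc[["g"]] * drop(K %*% object$Vinv_r)
  }
  if (object$pedigree_mode && !is.null(pedigree)) {
    des_new <- omega_design(pedigree, ids)
    des_obs <- omega_design(pedigree, object$obs_ids)
    for (k in c("f", "m", "c")) {
      if (object$vc[[k]] <= 0) next
      lab_new <- switch(k, f = des_new$father, m = des_new$mother, c = des_new$cross)
      lab_obs <- switch(k, f = des_obs$father, m = des_obs$mother, c = des_obs$cross)
      S <- outer(lab_new, lab_obs, "==") * 1
      out <- out + object$vc[[k]] * drop(S %*% object$Vinv_r)
    }
  }
  out
}

#' Plot a `gsblup` fit
#'
#' Scatter of GEBVs against the phenotypes of the training individuals with
#' the identity line.
#'
#' @param x A `gsblup` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gsblup <- function(x, ...) {
  fv <- fitted(x)
  graphics::plot(x$y[x$obs_ids], fv,
                 xlab = "phenotype (stage-1 prediction)", ylab = "GEBV", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
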