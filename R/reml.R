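# Restricted maximum likelihood machinery.
#
# Marginal model: y = 1 mu + sum_k u_k + e, with
#   var(y) = V = sum_k s2_k C_k + diag(r_fixed)
# where the C_k are known symmetric matrices (genotypic Gamma, father/mother/
# cross indicator matrices, the identity) and r_fixed is an optional vector of
# known heterogeneous residual variances.  The intercept is the only fixed
# effect.  The REML log-likelihood convention used throughout is
#
#   lR = -1/2 [ log|V| + log(1' V^-1 1) + y' P y + (n - 1) log(2 pi) ],
#   P  = V^-1 - V^-1 1 (1' V^-1 1)^-1 1' V^-1.
#
# Two fitting routes:
#  * eigen route for the common two-component case V = s2_g Gamma + s2_e I
#    (one eigendecomposition of Gamma, then the likelihood is profiled down to
#    a 1-D search over the variance ratio, with s2_e solved in closed form);
#  * dense route for models with fixed heterogeneous residuals or pedigree
#    components (Cholesky per evaluation, analytic gradients, log-variance
#    parameterization, explicit drop-to-zero boundary tests).
# The kernel range parameter theta is profiled by an outer 1-D search
# (log-spaced grid refined by golden section).

.REML_FAIL <- -1e12

#' REML log-likelihood of the intercept-only Gaussian model
#'
#' Direct evaluation of
#' `-0.5 * (log|V| + log(1'V^-1 1) + y'Py + (n-1) log(2 pi))` via the Cholesky
#' factor of the marginal covariance `V`.
#'
#' @param y Numeric response vector.
#' @param V Positive-definite marginal covariance matrix.
#' @return Scalar restricted log-likelihood.
#' @export
reml_loglik <- function(y, V) {
  n <- length(y)
  if (!is.matrix(V) || nrow(V) != n || ncol(V) != n)
    stop("V must be an n x n matrix matching length(y)")
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV))
    stop("marginal covariance V is not positive definite")
  logdet <- 2 * sum(log(diag(cV)))
  Viy <- backsolve(cV, backsolve(cV, y, transpose = TRUE))
  Vi1 <- backsolve(cV, backsolve(cV, rep(1, n), transpose = TRUE))
  sxx <- sum(Vi1)
  sxy <- sum(y * Vi1)
  yPy <- sum(y * Viy) - sxy^2 / sxx
  -0.5 * (logdet + log(sxx) + yPy + (n - 1) * log(2 * pi))
}

# closed-form REML for V = s2 I (intercept-only iid model): s2_hat = var(y)
.reml_iid <- function(y) {
  n <- length(y)
  s2 <- stats::var(y)
  ll <- -0.5 * ((n - 1) * log(s2) + log(n) + (n - 1) + (n - 1) * log(2 * pi))
  list(s2 = s2, loglik = ll)
}

# ---- eigen route: V = s2_g Gamma + s2_e I ---------------------------------

# Profiled REML over the ratio g = s2_g / s2_e, after rotating by the
# eigenvectors of Gamma.  Returns s2_e in closed form for each g.
.fit_two_comp_eigen <- function(y, Gamma, control) {
  n <- length(y)
  eg <- eigen(Gamma, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, n)))

  prof <- function(lg) {
    w <- 1 + exp(lg) * lam
    sxx <- sum(xt^2 / w)
    Q <- sum(yt^2 / w) - sum(xt * yt / w)^2 / sxx
    if (!is.finite(Q) || Q <= 0) return(list(ll = .REML_FAIL, s2e = NA_real_))
    s2e <- Q / (n - 1)
    ll <- -0.5 * ((n - 1) * log(s2e) + sum(log(w)) + log(sxx) +
                    (n - 1) + (n - 1) * log(2 * pi))
    list(ll = ll, s2e = s2e)
  }

  lam_scale <- mean(lam[lam > 0])
  if (!is.finite(lam_scale) || lam_scale <= 0) {   # Gamma numerically zero
    iid <- .reml_iid(y)
    return(list(s2 = c(g = 0, e = iid$s2), loglik = iid$loglik,
                boundary = "g", convergence = 0L))
  }
  grid <- seq(log(1e-10 / lam_scale), log(1e10 / lam_scale), length.out = 61L)
  vals <- vapply(grid, function(lg) prof(lg)$ll, 0)
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  op <- stats::optimize(function(lg) prof(lg)$ll, c(lo, hi),
                        maximum = TRUE, tol = 1e-8)
  best <- prof(op$maximum)
  iid <- .reml_iid(y)
  if (iid$loglik >= best$ll - control$boundary_tol) {
    list(s2 = c(g = 0, e = iid$s2), loglik = iid$loglik,
         boundary = "g", convergence = 0L)
  } else {
    list(s2 = c(g = exp(op$maximum) * best$s2e, e = best$s2e),
         loglik = best$ll, boundary = character(0), convergence = 0L)
  }
}

# ---- dense route -----------------------------------------------------------

# log-likelihood and gradient wrt the variance components, dense V
.reml_dense_eval <- function(y, comps, s2, r_fixed = NULL, grad = FALSE) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (k in seq_along(comps)) V <- V + s2[k] * comps[[k]]
  if (!is.null(r_fixed)) V <- V + diag(r_fixed, n)
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(list(ll = .REML_FAIL))
  logdet <- 2 * sum(log(diag(cV)))
  Viy <- backsolve(cV, backsolve(cV, y, transpose = TRUE))
  Vi1 <- backsolve(cV, backsolve(cV, rep(1, n), transpose = TRUE))
  sxx <- sum(Vi1)
  sxy <- sum(y * Vi1)
  yPy <- sum(y * Viy) - sxy^2 / sxx
  ll <- -0.5 * (logdet + log(sxx) + yPy + (n - 1) * log(2 * pi))
  if (!grad) return(list(ll = ll))
  Vi <- chol2inv(cV)
  P <- Vi - tcrossprod(Vi1) / sxx
  Py <- Viy - Vi1 * (sxy / sxx)
  gr <- vapply(comps, function(C) {
    -0.5 * (sum(P * C) - drop(crossprod(Py, C %*% Py)))
  }, 0)
  list(ll = ll, grad = gr)
}

# maximize over s2 >= 0 for a fixed component set; log-variance search with
# L-BFGS-B, then greedy drop-to-zero boundary tests
.fit_vc_dense <- function(y, comps, r_fixed = NULL, control) {
  n <- length(y)
  K <- length(comps)
  stopifnot(K >= 1L)
  vy <- stats::var(y)
  diag_scale <- vapply(comps, function(C) mean(diag(C)), 0)

  fit_subset <- function(active) {
    if (length(active) == 0L) {
      if (is.null(r_fixed)) return(NULL)
      ev <- .reml_dense_eval(y, comps[0], numeric(0), r_fixed)
      return(list(s2 = numeric(0), loglik = ev$ll, convergence = 0L))
    }
    cs <- comps[active]
    start <- log(vy / (length(cs) + !is.null(r_fixed)) / diag_scale[active])
    fn <- function(x) {
      ev <- .reml_dense_eval(y, cs, exp(x), r_fixed)
      if (ev$ll <= .REML_FAIL) return(1e10)
      -ev$ll
    }
    gr <- function(x) {
      ev <- .reml_dense_eval(y, cs, exp(x), r_fixed, grad = TRUE)
      if (is.null(ev$grad)) return(rep(0, length(x)))
      -ev$grad * exp(x)
    }
    op <- tryCatch(
      stats::optim(start, fn, gr, method = "L-BFGS-B",
                   lower = start - 25, upper = start + 25,
                   control = list(maxit = control$maxit, factr = 1e4)),
      error = function(e) NULL)
    # derivative-free polish (Brent in 1-D, Nelder-Mead otherwise); on large
    # problems the gradient-based fit is accurate and each evaluation costs a
    # dense Cholesky, so the polish is reserved for small n or L-BFGS failure
    p0 <- if (is.null(op)) start else op$par
    op2 <- if (n > 400L && !is.null(op)) NULL else tryCatch(
      if (length(p0) == 1L)
        stats::optim(p0, fn, method = "Brent", lower = p0 - 20, upper = p0 + 20)
      else
        stats::optim(p0, fn, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    cand <- Filter(Negate(is.null), list(op, op2))
    if (length(cand) == 0L) return(NULL)
    best <- cand[[which.min(vapply(cand, `[[`, 0, "value"))]]
    list(s2 = setNames(exp(best$par), names(cs)), loglik = -best$value,
         convergence = best$convergence)
  }

  active <- seq_len(K)
  cur <- fit_subset(active)
  if (is.null(cur)) stop("variance component optimization failed")

  # explicit boundary tests: drop each component in turn (smallest
  # contribution first); accept the reduced model when it loses essentially
  # no likelihood
  repeat {
    if (length(active) == 0L) break
    contrib <- cur$s2 * diag_scale[active]
    ord <- order(contrib)
    dropped <- FALSE
    for (j in ord) {
      reduced <- setdiff(active, active[j])
      if (length(reduced) == 0L && is.null(r_fixed)) next  # V must stay PD
      sub <- fit_subset(reduced)
      if (!is.null(sub) && sub$loglik >= cur$loglik - control$boundary_tol) {
        active <- reduced
        cur <- sub
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }

  s2 <- setNames(numeric(K), names(comps))
  s2[names(cur$s2)] <- cur$s2
  list(s2 = s2, loglik = cur$loglik,
       boundary = setdiff(names(comps), names(cur$s2)),
       convergence = cur$convergence)
}

# ---- dispatcher with optional theta profiling ------------------------------

# Inner fit at a fixed Gamma (or NULL for the independent model).
# extra = named list of additional covariance components (pedigree),
# r_fixed = known residual variances or NULL.
.fit_inner <- function(y, Gamma, extra = NULL, r_fixed = NULL, control) {
  if (is.null(Gamma) && length(extra) == 0L && is.null(r_fixed)) {
    iid <- .reml_iid(y)
    return(list(s2 = c(e = iid$s2), loglik = iid$loglik,
                boundary = character(0), convergence = 0L))
  }
  if (!is.null(Gamma) && length(extra) == 0L && is.null(r_fixed))
    return(.fit_two_comp_eigen(y, Gamma, control))
  comps <- c(if (!is.null(Gamma)) list(g = Gamma), extra,
             list(e = diag(length(y))))
  if (!is.null(r_fixed)) {
    # with a known residual floor the free iid component is the polygenic one
    names(comps)[names(comps) == "e"] <- "v"
  }
  .fit_vc_dense(y, comps, r_fixed, control)
}

# theta grid: effective-range grid in distance units, mapped to each kernel's
# native parameterization
.theta_from_range <- function(kernel, r) {
  switch(kernel,
         exponential = r, gaussian = r, spherical = r,
         power = exp(-1 / r),
         linear = 1 / r,
         quadratic = 1 / r^2)
}

.theta_grid <- function(D, kernel, n_grid) {
  d <- D[upper.tri(D)]
  d <- d[d > 0]
  if (length(d) == 0L) stop("degenerate distance matrix: no positive distances")
  r <- exp(seq(log(0.05 * stats::median(d)), log(30 * max(d)),
               length.out = n_grid))
  r
}

# Outer profile over theta for a spatial kernel; returns the best theta, its
# inner fit and the (theta, loglik) trace.
.profile_theta <- function(y, D, kernel, extra = NULL, r_fixed = NULL,
                           stabilize_policy = "clip", control) {
  ranges <- .theta_grid(D, kernel, control$theta_grid_n)
  stab <- NULL
  eval_range <- function(r) {
    theta <- .theta_from_range(kernel, r)
    G <- suppressWarnings(stabilize_gamma(build_gamma(D, kernel, theta),
                                          policy = stabilize_policy))
    st <- attr(G, "stabilization")
    fit <- .fit_inner(y, G, extra, r_fixed, control)
    list(theta = theta, fit = fit, stab = st)
  }
  evals <- lapply(ranges, eval_range)
  lls <- vapply(evals, function(e) e$fit$loglik, 0)
  i <- which.max(lls)

  # monotone profiles: the optimum may sit on a plateau beyond the grid
  # (large theta approaches the ridge/quadratic limit, small theta the
  # independent limit); extend geometrically while the likelihood improves
  d <- D[upper.tri(D)]; d <- d[d > 0]
  r_hi_cap <- 1e5 * max(d); r_lo_cap <- 1e-4 * stats::median(d)
  while (i == length(ranges) && ranges[i] * 10 <= r_hi_cap) {
    r_new <- ranges[i] * 10
    e_new <- eval_range(r_new)
    if (e_new$fit$loglik <= lls[i] + 1e-9) { ranges <- c(ranges, r_new)
      evals <- c(evals, list(e_new)); lls <- c(lls, e_new$fit$loglik); break }
    ranges <- c(ranges, r_new); evals <- c(evals, list(e_new))
    lls <- c(lls, e_new$fit$loglik); i <- length(ranges)
  }
  while (i == 1L && ranges[1L] / 10 >= r_lo_cap) {
    r_new <- ranges[1L] / 10
    e_new <- eval_range(r_new)
    ranges <- c(r_new, ranges); evals <- c(list(e_new), evals)
    lls <- c(e_new$fit$loglik, lls)
    if (e_new$fit$loglik <= lls[2L] + 1e-9) { i <- 2L; break }
    i <- 1L
  }

  # golden-section refinement on log(range) between the neighbours of the
  # best grid point
  lo <- log(ranges[max(i - 1L, 1L)])
  hi <- log(ranges[min(i + 1L, length(ranges))])
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  e1 <- eval_range(exp(x1)); e2 <- eval_range(exp(x2))
  for (it in seq_len(control$golden_iter)) {
    if (e1$fit$loglik >= e2$fit$loglik) {
      b <- x2; x2 <- x1; e2 <- e1
      x1 <- b - phi * (b - a); e1 <- eval_range(exp(x1))
    } else {
      a <- x1; x1 <- x2; e1 <- e2
      x2 <- a + phi * (b - a); e2 <- eval_range(exp(x2))
    }
    if (b - a < 1e-6) break
  }
  cand <- c(evals[i], list(e1, e2))
  best <- cand[[which.max(vapply(cand, function(e) e$fit$loglik, 0))]]
  best$trace <- data.frame(theta = vapply(evals, `[[`, 0, "theta"),
                           loglik = lls)
  best
}
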