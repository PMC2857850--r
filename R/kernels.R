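# Genotypic covariance structures Gamma.
#
# Ridge regression uses Gamma = ZZ'.  The geostatistical alternatives express
# the genetic correlation between two individuals as a monotonically
# decreasing function f(d) of the Euclidean distance d between their
# marker-code vectors, with a range/decay parameter theta:
#
#   linear       f(d) = (1 - theta d)   for theta d   <= 1, else 0
#   quadratic    f(d) = (1 - theta d^2) for theta d^2 <= 1, else 0
#   power        f(d) = theta^d,        theta in (0, 1)
#   exponential  f(d) = exp(-d / theta)
#   gaussian     f(d) = exp(-d^2 / theta^2)
#   spherical    f(d) = 1 - 1.5 (d/theta) + 0.5 (d/theta)^3 for d <= theta, else 0
#
# These are the standard spatial correlation structures of mixed-model
# software.  The quadratic model is equivalent to ridge regression: on
# heterozygote-free codes ZZ' = m 11' - D^2/2, so 1 - theta d^2 with
# theta = 1/(2m) reproduces ZZ'/m exactly.

.GS_SPATIAL_KERNELS <- c("linear", "quadratic", "power", "exponential",
                         "gaussian", "spherical")
.GS_KERNELS <- c("independent", "rr", .GS_SPATIAL_KERNELS)

.check_theta <- function(kernel, theta) {
  if (is.null(theta) || length(theta) != 1L || !is.finite(theta))
    stop(sprintf("kernel '%s' needs a single finite theta", kernel))
  if (kernel == "power") {
    if (theta <= 0 || theta >= 1) stop("power kernel needs theta in (0, 1)")
  } else if (theta <= 0) stop(sprintf("kernel '%s' needs theta > 0", kernel))
  invisible(theta)
}

#' Evaluate a geostatistical correlation function
#'
#' Returns f(d) for one of the distance-decay kernels (`linear`, `quadratic`,
#' `power`, `exponential`, `gaussian`, `spherical`).  All kernels satisfy
#' f(0) = 1 and are monotonically non-increasing in d.
#'
#' @param kernel Kernel name.
#' @param d Non-negative distance(s); vectorized.
#' @param theta Range/decay parameter (in distance units for the range-type
#'   kernels; a base in (0, 1) for `power`; inverse-distance(-squared) for
#'   `linear`/`quadratic`).
#' @return Numeric vector of correlation values.
#' @export
kernel_value <- function(kernel, d, theta) {
  kernel <- match.arg(kernel, .GS_SPATIAL_KERNELS)
  .check_theta(kernel, theta)
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  switch(kernel,
    linear      = ifelse(theta * d <= 1, 1 - theta * d, 0),
    quadratic   = ifelse(theta * d^2 <= 1, 1 - theta * d^2, 0),
    power       = theta^d,
    exponential = exp(-d / theta),
    gaussian    = exp(-d^2 / theta^2),
    spherical   = ifelse(d <= theta,
                         1 - 1.5 * (d / theta) + 0.5 * (d / theta)^3, 0))
}

#' Build the genotypic correlation matrix for a distance-decay kernel
#'
#' Applies [kernel_value()] elementwise to a distance matrix.  The
#' `independent` kernel gives the identity matrix of matching size.
#'
#' @param D Distance matrix from [genotype_dist()] or [cross_dist()].
#' @param kernel Kernel name (`"independent"` or a spatial kernel).
#' @param theta Range/decay parameter (ignored for `independent`).
#' @return Matrix Gamma of the same dimension as `D`.
#' @export
build_gamma <- function(D, kernel, theta = NULL) {
  kernel <- match.arg(kernel, c("independent", .GS_SPATIAL_KERNELS))
  if (kernel == "independent") {
    G <- diag(nrow(D))
    dimnames(G) <- dimnames(D)
    return(G)
  }
  G <- kernel_value(kernel, D, theta)
  dim(G) <- dim(D)
  dimnames(G) <- dimnames(D)
  G
}

#' Ridge-regression covariance Gamma = ZZ'
#'
#' Marker cross-product covariance; symmetric positive semidefinite, with the
#' squared row norms of Z on the diagonal.
#'
#' @param Z Numeric marker matrix.
#' @return `nrow(Z)` x `nrow(Z)` matrix ZZ'.
#' @export
rr_gamma <- function(Z) {
  if (!is.matrix(Z) || !is.numeric(Z) || !all(is.finite(Z)))
    stop("Z must be a finite numeric matrix")
  tcrossprod(Z)
}

#' Repair an indefinite genotypic covariance matrix
#'
#' The linear, quadratic and spherical kernels need not yield a positive
#' semidefinite Gamma.  This projects negative eigenvalues to zero (policy
#' `"clip"`, the default) or adds the smallest uniform diagonal shift making
#' the minimum eigenvalue non-negative (policy `"jitter"`).  A matrix whose
#' minimum eigenvalue is already >= -tol (relative) is returned unchanged.
#'
#' @param Gamma Symmetric matrix.
#' @param policy `"clip"` or `"jitter"`.
#' @param tol Relative eigenvalue tolerance.
#' @return `Gamma`, possibly corrected, with an attribute `"stabilization"`
#'   (list with `applied`, `policy`, `min_eigenvalue` before correction).
#' @export
stabilize_gamma <- function(Gamma, policy = c("clip", "jitter"), tol = 1e-8) {
  policy <- match.arg(policy)
  ev <- eigen(Gamma, symmetric = TRUE)
  scale <- max(abs(ev$values), 1)
  min_ev <- min(ev$values)
  if (min_ev >= -tol * scale) {
    attr(Gamma, "stabilization") <- list(applied = FALSE, policy = policy,
                                         min_eigenvalue = min_ev)
    return(Gamma)
  }
  if (policy == "clip") {
    lam <- pmax(ev$values, 0)
    G <- ev$vectors %*% (lam * t(ev$vectors))
    G <- (G + t(G)) / 2
  } else {
    G <- Gamma + diag(-min_ev + tol * scale, nrow(Gamma))
  }
  dimnames(G) <- dimnames(Gamma)
  warning(sprintf("Gamma was not positive semidefinite (min eigenvalue %.3g); %s applied",
                  min_ev, policy))
  attr(G, "stabilization") <- list(applied = TRUE, policy = policy,
                                   min_eigenvalue = min_ev)
  G
}
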