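# Shared fixtures and independent oracles used across the suite.
# Oracles deliberately use naive dense formulas (solve/determinant, double
# loops) so they share no code path with the package internals they check.

rand_Z <- function(n, m) {
  matrix(sample(c(-1, 0, 1), n * m, replace = TRUE), n, m,
         dimnames = list(sprintf("i%03d", seq_len(n)), sprintf("M%03d", seq_len(m))))
}

# brute-force pairwise Euclidean distances
loop_dist <- function(A, B = A) {
  D <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    D[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  D
}

# direct-formula REML log-likelihood (intercept only), via solve()/determinant()
naive_reml_ll <- function(y, V) {
  n <- length(y)
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  sxx <- drop(t(X) %*% Vi %*% X)
  P <- Vi - (Vi %*% X) %*% (t(X) %*% Vi) / sxx
  -0.5 * (ld + log(sxx) + drop(t(y) %*% P %*% y) + (n - 1) * log(2 * pi))
}

# draw y ~ N(mu 1, V)
sim_mvn <- function(V, mu = 0) {
  n <- nrow(V)
  L <- chol(V + diag(1e-10 * mean(diag(V)) + 1e-12, n))
  drop(mu + crossprod(L, rnorm(n)))
}

# small cross population used by several fitting tests
small_pop <- function(seed, n_markers = 150, n_qtl = 20, offspring = 24,
                      mothers = 5, error_sd = 1, qtl_effect_sd = 1.5,
                      phenotyped_fraction = 0.5) {
  sim_population(n_fathers = 2, n_mothers = mothers,
                 offspring_per_cross = offspring,
                 n_markers = n_markers, n_qtl = n_qtl,
                 qtl_effect_sd = qtl_effect_sd, error_sd = error_sd,
                 phenotyped_fraction = phenotyped_fraction, seed = seed)
}

# named phenotype vector y = mu + Z u + e with iid marker effects
sim_marker_trait <- function(Z, h_sd = 0.15, e_sd = 1, mu = 50) {
  u <- rnorm(ncol(Z), 0, h_sd)
  setNames(mu + drop(Z %*% u) + rnorm(nrow(Z), 0, e_sd), rownames(Z))
}
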