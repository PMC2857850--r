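spatial_kernels <- c("linear", "quadratic", "power", "exponential",
                     "gaussian", "spherical")

theta_for <- function(kernel, scale = 5) {
  switch(kernel, power = 0.8, linear = 1 / (2 * scale),
         quadratic = 1 / (2 * scale^2), scale)
}

test_that("kernel functions hit their closed-form anchor points", {
  expect_equal(kernel_value("gaussian", 0, 3), 1)
  expect_equal(kernel_value("gaussian", 3, 3), exp(-1))
  expect_equal(kernel_value("exponential", 2, 2), exp(-1))
  expect_equal(kernel_value("spherical", 5, 5), 0)
  expect_equal(kernel_value("spherical", 7, 5), 0)
  expect_equal(kernel_value("linear", 4, 0.25), 0)
  expect_equal(kernel_value("linear", 8, 0.25), 0)
  expect_equal(kernel_value("quadratic", 2, 0.25), 0)
  expect_equal(kernel_value("power", 3, 0.5), 0.125)
  expect_error(kernel_value("gaussian", 1, -1), "theta")
  expect_error(kernel_value("power", 1, 1.5), "\\(0, 1\\)")
  expect_error(kernel_value("nope", 1, 1))
})

test_that("all spatial kernels are unit at zero and monotone non-increasing", {
  d <- seq(0, 12, by = 0.25)
  for (k in spatial_kernels) {
    f <- kernel_value(k, d, theta_for(k))
    expect_equal(f[1], 1, info = k)
    expect_true(all(diff(f) <= 1e-12), info = k)
    expect_true(all(f <= 1 + 1e-12 & f >= -1e-12), info = k)
  }
})

test_that("build_gamma matches an elementwise scalar oracle", {
  set.seed(21)
  D <- genotype_dist(rand_Z(8, 10))
  for (k in spatial_kernels) {
    th <- theta_for(k, scale = median(D[upper.tri(D)]))
    G <- build_gamma(D, k, th)
    oracle <- matrix(0, nrow(D), ncol(D))
    for (i in seq_len(nrow(D))) for (j in seq_len(ncol(D)))
      oracle[i, j] <- kernel_value(k, D[i, j], th)
    expect_equal(G, oracle, ignore_attr = TRUE, tolerance = 1e-14, info = k)
  }
  expect_equal(build_gamma(D, "independent"), diag(nrow(D)), ignore_attr = TRUE)
  # distances far beyond the range: exponential correlation dies off
  G <- build_gamma(D * 1e6, "exponential", 1)
  expect_equal(G, diag(nrow(D)), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("ridge Gamma is the marker cross-product and is PSD", {
  Z1 <- matrix(c(1, -1, 0), 1, 3, dimnames = list("i1", NULL))
  expect_equal(rr_gamma(Z1), matrix(2, 1, 1), ignore_attr = TRUE)
  set.seed(22)
  Z <- rand_Z(12, 9)
  Z[2, ] <- Z[1, ]
  G <- rr_gamma(Z)
  expect_equal(G[1, 1], G[1, 2])
  expect_equal(G[1, 1], G[2, 2])
  expect_true(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8)
})

test_that("quadratic kernel reproduces ridge regression on heterozygote-free codes", {
  set.seed(23)
  m <- 40
  Z <- matrix(sample(c(-1, 1), 20 * m, replace = TRUE), 20, m)
  D <- genotype_dist(Z)
  # ZZ' = m 11' - D^2 / 2, exactly
  expect_equal(rr_gamma(Z), m - D^2 / 2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("gaussian kernel approaches the quadratic kernel at rate theta^-4", {
  set.seed(24)
  D <- genotype_dist(rand_Z(10, 15))
  sup_diff <- function(theta)
    max(abs(build_gamma(D, "gaussian", theta) - (1 - D^2 / theta^2)))
  thetas <- max(D) * c(4, 8, 16)
  diffs <- vapply(thetas, sup_diff, 0)
  expect_true(all(diff(diffs) < 0)) # vanishing difference
  # doubling theta divides the gap by ~2^4
  expect_equal(diffs[1] / diffs[2], 16, tolerance = 0.05)
  expect_equal(diffs[2] / diffs[3], 16, tolerance = 0.05)
})

test_that("stabilization repairs indefinite Gamma and leaves PSD input alone", {
  G_ok <- diag(3)
  expect_identical(unname(stabilize_gamma(G_ok)[, ]), unname(G_ok[, ]))
  expect_false(attr(stabilize_gamma(G_ok), "stabilization")$applied)

  G_bad <- matrix(c(1, 1.5, 1.5, 1), 2, 2)
  expect_warning(G_fix <- stabilize_gamma(G_bad), "not positive semidefinite")
  ev <- eigen(G_fix, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-10)
  expect_true(attr(G_fix, "stabilization")$applied)
  expect_equal(attr(G_fix, "stabilization")$min_eigenvalue, -0.5)

  expect_warning(G_j <- stabilize_gamma(G_bad, policy = "jitter"))
  expect_true(min(eigen(G_j, only.values = TRUE)$values) >= 0)
  # jitter only shifts the diagonal
  expect_equal(G_j[1, 2], G_bad[1, 2])
})
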