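test_that("RR breeding values satisfy the ridge normal equations", {
  set.seed(51)
  sim <- small_pop(51, offspring = 16, phenotyped_fraction = 1)
  ids <- sample(rownames(sim$genotypes), 60)
  Z <- sim$genotypes[ids, ]
  y <- sim_marker_trait(Z)
  fit <- gsblup(y, Z, kernel = "rr")
  lam2 <- fit$lambda2
  expect_equal(lam2, varcomp(fit)[["e"]] / varcomp(fit)[["g"]])
  r <- y - fit$mu
  u <- solve(crossprod(Z) + diag(lam2, ncol(Z)), crossprod(Z, r))
  expect_lt(max(abs(drop(Z %*% u) - fit$ghat[ids])), 1e-6)
})

test_that("an unphenotyped copy of a phenotyped genotype gets the same g-hat", {
  set.seed(52)
  sim <- small_pop(52, offspring = 10, phenotyped_fraction = 1)
  Z <- sim$genotypes[1:30, ]
  twin <- Z[7, , drop = FALSE]
  rownames(twin) <- "twin"
  Zall <- rbind(Z, twin)
  y <- sim_marker_trait(Z)
  for (kern in c("rr", "gaussian")) {
    fit <- gsblup(y, Zall, kernel = kern)
    g <- setNames(fit$gebv$gebv, fit$gebv$individual)
    expect_equal(g[["twin"]], g[[rownames(Z)[7]]], tolerance = 1e-6, info = kern)
  }
})

test_that("breeding values shrink to the mean as sigma2_g vanishes", {
  set.seed(53)
  Z <- rand_Z(25, 40)
  y <- setNames(rnorm(25, 30, 1), rownames(Z))
  # pure-noise trait: the marker variance hits the zero boundary and the
  # GEBVs collapse to the intercept
  fit <- gsblup(y, Z, kernel = "rr")
  if ("g" %in% fit$boundary) {
    expect_equal(fit$gebv$gebv, rep(fit$mu, nrow(fit$gebv)), tolerance = 1e-10)
    expect_identical(unname(varcomp(fit)[["g"]]), 0)
  } else {
    # if not at the boundary the ratio is still tiny; predictions huddle at mu
    expect_lt(varcomp(fit)[["g"]] * mean(diag(rr_gamma(Z))), 0.5 * var(y))
  }
})

test_that("predict() reproduces in-fit GEBVs and honours the kernel", {
  set.seed(54)
  sim <- small_pop(54, offspring = 12)
  s1 <- growth_extrapolate(sim$phenotypes, target_time = 600)
  fit <- gsblup(s1, sim$genotypes, kernel = "gaussian")
  new_ids <- setdiff(rownames(sim$genotypes), sim$phenotyped)[1:10]
  pr <- predict(fit, sim$genotypes[new_ids, ])
  g <- setNames(fit$gebv$gebv, fit$gebv$individual)
  expect_equal(pr, g[new_ids], tolerance = 1e-10)
})

test_that("fixed-residual mode uses the stage-1 error variances", {
  set.seed(55)
  sim <- small_pop(55, offspring = 16, error_sd = 0.5)
  s1 <- growth_extrapolate(sim$phenotypes, target_time = 600)
  fit <- gsblup(s1, sim$genotypes, kernel = "rr", residual = "fixed")
  expect_identical(fit$residual, "fixed")
  expect_true("v" %in% names(varcomp(fit)))
  # explicit residual_var vector gives the same fit
  y <- setNames(s1$table$prediction, s1$table$individual)
  rv <- setNames(s1$table$var, s1$table$individual)
  fit2 <- gsblup(y, sim$genotypes, kernel = "rr", residual = "fixed",
                 residual_var = rv)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-10)
  expect_error(gsblup(y, sim$genotypes, kernel = "rr", residual = "fixed"),
               "residual_var")
})

test_that("gsblup validates its inputs", {
  set.seed(56)
  Z <- rand_Z(10, 8)
  y <- setNames(rnorm(10), rownames(Z))
  expect_error(gsblup(unname(y), Z), "names")
  expect_error(gsblup(y, Z[1:5, ]), "without genotypes")
  expect_error(gsblup(y, Z, kernel = "gaussian", theta = -2), "theta")
  expect_error(gsblup(y[1:2], Z), "at least 3")
  # unphenotyped individuals lacking genotypes are dropped with a warning
  ped <- data.frame(individual = c(rownames(Z), "orphan"),
                    father = "F1", mother = "D1")
  expect_warning(fit <- gsblup(y, Z, kernel = "rr", pedigree = ped),
                 "without genotypes")
  expect_false("orphan" %in% fit$gebv$individual)
})

test_that("methods expose the fit in standard ways", {
  set.seed(57)
  sim <- small_pop(57, offspring = 10)
  s1 <- growth_extrapolate(sim$phenotypes, target_time = 600)
  fit <- gsblup(s1, sim$genotypes, kernel = "rr")
  expect_s3_class(fit, "gsblup")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), fit$q)
  expect_equal(length(fitted(fit)), fit$n_obs)
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(fit$y[fit$obs_ids]))
  expect_equal(coef(fit), c(mu = fit$mu))
  expect_output(print(fit), "Genomic BLUP fit")
  expect_output(print(summary(fit)), "correlation")
})
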