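test_that("sharing indicator matrices follow the family structure", {
  ped <- data.frame(individual = c("a", "b", "c", "d"),
                    father = c("F1", "F1", "F1", "F2"),
                    mother = c("D1", "D1", "D2", "D3"))
  des <- omega_design(ped, c("a", "b"))
  ones2 <- matrix(1, 2, 2)
  expect_equal(des$V_f, ones2, ignore_attr = TRUE)  # full sibs share everything
  expect_equal(des$V_m, ones2, ignore_attr = TRUE)
  expect_equal(des$V_c, ones2, ignore_attr = TRUE)

  des2 <- omega_design(ped, c("a", "d"))            # unrelated pair
  expect_equal(des2$V_f, diag(2), ignore_attr = TRUE)
  expect_equal(des2$V_m, diag(2), ignore_attr = TRUE)
  expect_equal(des2$V_c, diag(2), ignore_attr = TRUE)

  des3 <- omega_design(ped, c("a", "c"))            # paternal half sibs
  expect_equal(des3$V_f, ones2, ignore_attr = TRUE)
  expect_equal(des3$V_m, diag(2), ignore_attr = TRUE)
  expect_equal(des3$V_c, diag(2), ignore_attr = TRUE)

  expect_error(omega_design(ped, c("a", "zz")), "missing from pedigree")
})

test_that("unknown parents become singleton levels", {
  ped <- data.frame(individual = c("a", "b"), father = c(NA, NA),
                    mother = c("0", "0"))
  des <- omega_design(ped, c("a", "b"))
  expect_equal(des$V_f, diag(2), ignore_attr = TRUE)
  expect_equal(des$V_m, diag(2), ignore_attr = TRUE)
})

test_that("Omega matches the incidence-product representation and is PSD", {
  set.seed(61)
  sim <- small_pop(61, offspring = 6)
  ids <- sample(rownames(sim$genotypes), 25)
  des <- omega_design(sim$pedigree, ids)
  # independent construction: grouped random effects via 0/1 incidence
  inc <- function(lab) {
    T <- outer(lab, sort(unique(lab)), "==") * 1
    tcrossprod(T)
  }
  expect_equal(des$V_f, inc(des$father), ignore_attr = TRUE)
  expect_equal(des$V_m, inc(des$mother), ignore_attr = TRUE)
  expect_equal(des$V_c, inc(des$cross), ignore_attr = TRUE)
  # pairwise double-loop oracle for the combined covariance
  s2 <- c(f = 1.3, m = 0.4, c = 0.7)
  Om <- omega_matrix(des, s2[["f"]], s2[["m"]], s2[["c"]])
  oracle <- matrix(0, 25, 25)
  for (i in 1:25) for (j in 1:25)
    oracle[i, j] <- s2[["f"]] * (des$father[i] == des$father[j]) +
      s2[["m"]] * (des$mother[i] == des$mother[j]) +
      s2[["c"]] * (des$cross[i] == des$cross[j])
  expect_equal(Om, oracle, ignore_attr = TRUE)
  expect_true(min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10)
  # all variances zero: the extended model collapses to independent polygenics
  expect_equal(omega_matrix(des, 0, 0, 0), matrix(0, 25, 25), ignore_attr = TRUE)
  # cross sharing implies father and mother sharing
  expect_true(all(des$V_c <= des$V_f & des$V_c <= des$V_m))
})

test_that("the covariance-form fit matches an incidence-based REML oracle", {
  set.seed(62)
  sim <- small_pop(62, offspring = 6, phenotyped_fraction = 1)
  ids <- rownames(sim$genotypes)[1:60]
  des <- omega_design(sim$pedigree, ids)
  # simulate father variance + marker signal + noise
  fa_eff <- setNames(rnorm(length(unique(des$father)), 0, 1.5),
                     unique(des$father))
  Z <- sim$genotypes[ids, ]
  y <- sim_marker_trait(Z, h_sd = 0.1) + fa_eff[des$father]
  fit <- gsblup(y, Z, kernel = "rr", pedigree = sim$pedigree)

  # oracle: optimize the naive dense REML built from incidence products,
  # started at the package's own estimates plus neutral alternatives
  G <- rr_gamma(Z)
  comps <- list(G, tcrossprod(outer(des$father, unique(des$father), "==") * 1),
                tcrossprod(outer(des$mother, unique(des$mother), "==") * 1),
                tcrossprod(outer(des$cross, unique(des$cross), "==") * 1),
                diag(length(ids)))
  obj <- function(p) {
    V <- Reduce(`+`, Map(function(s, C) s * C, as.list(exp(p)), comps))
    -naive_reml_ll(y, V)
  }
  vc <- varcomp(fit)[c("g", "f", "m", "c", "e")]
  starts <- list(log(pmax(vc, 1e-8)),
                 log(rep(var(y) / 5, 5) / vapply(comps, function(C) mean(diag(C)), 0)))
  oracle <- min(vapply(starts, function(s)
    optim(s, obj, control = list(maxit = 5000, reltol = 1e-14))$value, 0))
  expect_lt(abs(fit$loglik - (-oracle)), 1e-6)
})
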