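# Synthetic cross populations with repeated growth measurements.
#
# The generator emulates the structure of a multi-family genomic selection
# study: a small set of fathers crossed to a set of mothers, a few hundred to
# a few thousand offspring genotyped at biallelic markers, an additive trait
# controlled by a subset of the markers (the QTL), and a phenotyped subset
# measured at a handful of times along a logistic growth curve whose asymptote
# carries the genetic signal.  Breeding values are to be predicted at a target
# time beyond the last measurement.  All randomness flows from the mandatory
# seed, so identical configurations give identical populations.

#' Simulate growth phenotypes from true breeding values
#'
#' Each individual grows along alpha_i / (1 + beta_i exp(-gamma_i t)) with
#' alpha_i = alpha + tbv_i (the breeding value shifts the asymptote) and
#' optional individual perturbations of beta and gamma; observations are the
#' curve values at `times` plus iid Gaussian measurement error.
#'
#' @param tbv Named numeric vector of true breeding values.
#' @param times Measurement times.
#' @param target_time Time at which the noiseless truth is recorded.
#' @param growth List with baseline `alpha`, `beta`, `gamma`.
#' @param error_sd Measurement error standard deviation.
#' @param beta_sd,gamma_sd Lognormal perturbation scales for beta and gamma
#'   (0 = identical shape and rate for everyone, the default).
#' @return List with `phenotypes` (long data frame: individual, time, value)
#'   and `truth` (data frame: individual, alpha, beta, gamma,
#'   value_at_target).
#' @export
sim_growth_phenotypes <- function(tbv, times, target_time,
                                  growth = list(alpha = 100, beta = 9, gamma = 0.01),
                                  error_sd = 1, beta_sd = 0, gamma_sd = 0) {
  ids <- names(tbv)
  stopifnot(!is.null(ids), error_sd >= 0)
  nid <- length(ids)
  alpha_i <- growth$alpha + unname(tbv)
  beta_i <- growth$beta * exp(stats::rnorm(nid, 0, beta_sd))
  gamma_i <- growth$gamma * exp(stats::rnorm(nid, 0, gamma_sd))

  mu <- outer(seq_len(nid), seq_along(times),
              function(i, j) .logistic_mean(times[j], alpha_i[i], beta_i[i], gamma_i[i]))
  obs <- mu + stats::rnorm(length(mu), 0, error_sd)
  phen <- data.frame(individual = rep(ids, times = length(times)),
                     time = rep(times, each = nid),
                     value = as.vector(obs),
                     stringsAsFactors = FALSE)
  phen <- phen[order(match(phen$individual, ids), phen$time), , drop = FALSE]
  rownames(phen) <- NULL
  truth <- data.frame(individual = ids, alpha = alpha_i, beta = beta_i,
                      gamma = gamma_i,
                      value_at_target = .logistic_mean(target_time, alpha_i,
                                                       beta_i, gamma_i),
                      stringsAsFactors = FALSE)
  list(phenotypes = phen, truth = truth)
}

# one gamete from a diploid parent: allele matrices A1/A2 are marker vectors
# in {0,1} (1 = allele "A1"); with a marker map, crossovers follow Haldane's
# model between adjacent markers, otherwise markers segregate independently
.gamete <- function(a1, a2, rec_prob) {
  m <- length(a1)
  if (is.null(rec_prob)) {
    pick <- stats::rbinom(m, 1L, 0.5)
  } else {
    pick <- integer(m)
    pick[1L] <- stats::rbinom(1L, 1L, 0.5)
    switches <- stats::rbinom(m - 1L, 1L, rec_prob)
    pick <- cumsum(c(pick[1L], switches)) %% 2L
  }
  ifelse(pick == 1L, a1, a2)
}

#' Simulate a multi-family cross population
#'
#' Founder parents receive marker alleles at frequencies drawn uniformly from
#' `allele_freq_range`; every father x mother pair forms a cross producing
#' `offspring_per_cross` offspring by Mendelian sampling (independent markers
#' by default, or Haldane recombination along a single chromosome when
#' `marker_spacing_cm` is given).  A random subset of `n_qtl` markers gets
#' additive effects drawn from N(0, `qtl_effect_sd`^2); the true breeding
#' value of an individual is the sum of its QTL codes times the effects.  A
#' fraction of offspring is phenotyped with repeated logistic growth
#' measurements via [sim_growth_phenotypes()].
#'
#' The defaults mirror a two-generation workshop-style design: 2 fathers x 10
#' mothers x 100 offspring (about 2000 individuals), 450 markers, 30 QTL,
#' five measurement times 0, 132, 265, 397, 530, prediction target time 600,
#' and roughly half of the offspring phenotyped.
#'
#' @param n_fathers,n_mothers,offspring_per_cross Cross design.
#' @param n_markers,n_qtl Marker panel size and number of causal markers
#'   (`n_qtl <= n_markers`).
#' @param qtl_effect_sd Standard deviation of the additive QTL effects.
#' @param allele_freq_range Range of founder allele frequencies.
#' @param marker_spacing_cm Spacing (centimorgan) between adjacent markers on
#'   a single chromosome; `NULL` (default) for independent markers.
#' @param growth,beta_sd,gamma_sd,error_sd,times,target_time Passed to
#'   [sim_growth_phenotypes()].
#' @param phenotyped_fraction Fraction of offspring with phenotype records.
#' @param seed Mandatory integer seed; the output is fully reproducible.
#' @return Object of class `gs_sim`: list with `calls` (character matrix of
#'   allele-pair labels), `genotypes` (coded -1/0/1 matrix), `pedigree`,
#'   `phenotypes` (long data frame for the phenotyped subset), `tbv` (named
#'   vector, all offspring), `phenotyped` (ids), `truth` (QTL indices,
#'   effects, founder alleles, per-individual curves and values at the target
#'   time) and `config`.
#' @export
sim_population <- function(n_fathers = 2, n_mothers = 10,
                           offspring_per_cross = 100,
                           n_markers = 450, n_qtl = 30, qtl_effect_sd = 1.5,
                           allele_freq_range = c(0.2, 0.8),
                           marker_spacing_cm = NULL,
                           growth = list(alpha = 100, beta = 9, gamma = 0.01),
                           beta_sd = 0, gamma_sd = 0, error_sd = 1,
                           times = c(0, 132, 265, 397, 530),
                           target_time = 600,
                           phenotyped_fraction = 0.5,
                           seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (n_qtl > n_markers) stop("n_qtl must not exceed n_markers")
  if (phenotyped_fraction <= 0 || phenotyped_fraction > 1)
    stop("phenotyped_fraction must be in (0, 1]")
  if (length(times) < 4L) stop("need >= 4 measurement times for the logistic fit")
  set.seed(as.integer(seed))

  marker_ids <- sprintf("M%03d", seq_len(n_markers))
  p <- stats::runif(n_markers, allele_freq_range[1L], allele_freq_range[2L])
  draw_parent <- function() {
    list(a1 = stats::rbinom(n_markers, 1L, p), a2 = stats::rbinom(n_markers, 1L, p))
  }
  fathers <- replicate(n_fathers, draw_parent(), simplify = FALSE)
  mothers <- replicate(n_mothers, draw_parent(), simplify = FALSE)
  names(fathers) <- sprintf("F%02d", seq_len(n_fathers))
  names(mothers) <- sprintf("D%02d", seq_len(n_mothers))

  rec_prob <- if (is.null(marker_spacing_cm)) NULL else
    0.5 * (1 - exp(-2 * marker_spacing_cm / 100))

  n_off <- n_fathers * n_mothers * offspring_per_cross
  ids <- sprintf("I%05d", seq_len(n_off))
  A_f <- matrix(0L, n_off, n_markers)  # paternal allele (1 = A1)
  A_m <- matrix(0L, n_off, n_markers)
  fa <- character(n_off); mo <- character(n_off)
  row <- 0L
  for (f in names(fathers)) for (m in names(mothers)) {
    for (k in seq_len(offspring_per_cross)) {
      row <- row + 1L
      A_f[row, ] <- .gamete(fathers[[f]]$a1, fathers[[f]]$a2, rec_prob)
      A_m[row, ] <- .gamete(mothers[[m]]$a1, mothers[[m]]$a2, rec_prob)
      fa[row] <- f; mo[row] <- m
    }
  }

  Z <- A_f + A_m - 1  # -1/0/1 coding: (# of A1 alleles) - 1
  dimnames(Z) <- list(ids, marker_ids)
  storage.mode(Z) <- "double"
  lab <- c("A2A2", "A1A2", "A1A1")  # indexed by (# of A1 alleles) + 1
  het_order <- matrix(stats::rbinom(n_off * n_markers, 1L, 0.5), n_off, n_markers)
  calls <- matrix(lab[A_f + A_m + 1L], n_off, n_markers, dimnames = dimnames(Z))
  calls[Z == 0 & het_order == 1L] <- "A2A1"  # record either heterozygote order

  qtl <- sort(sample.int(n_markers, n_qtl))
  effects <- stats::rnorm(n_qtl, 0, qtl_effect_sd)
  tbv <- setNames(drop(Z[, qtl, drop = FALSE] %*% effects), ids)
  if (n_qtl == 0L) tbv <- setNames(rep(0, n_off), ids)

  pedigree <- data.frame(individual = ids, father = fa, mother = mo,
                         stringsAsFactors = FALSE)
  n_phen <- max(1L, round(phenotyped_fraction * n_off))
  phenotyped <- sort(sample(ids, n_phen))

  gp <- sim_growth_phenotypes(tbv, times = times, target_time = target_time,
                              growth = growth, error_sd = error_sd,
                              beta_sd = beta_sd, gamma_sd = gamma_sd)
  out <- list(calls = calls, genotypes = Z, pedigree = pedigree,
              phenotypes = gp$phenotypes[gp$phenotypes$individual %in% phenotyped, ,
                                         drop = FALSE],
              tbv = tbv, phenotyped = phenotyped,
              truth = list(qtl = qtl, effects = effects,
                           allele_freq = p,
                           fathers = fathers, mothers = mothers,
                           paternal_allele = A_f, maternal_allele = A_m,
                           curves = gp$truth),
              config = list(n_fathers = n_fathers, n_mothers = n_mothers,
                            offspring_per_cross = offspring_per_cross,
                            n_markers = n_markers, n_qtl = n_qtl,
                            qtl_effect_sd = qtl_effect_sd,
                            allele_freq_range = allele_freq_range,
                            marker_spacing_cm = marker_spacing_cm,
                            growth = growth, beta_sd = beta_sd,
                            gamma_sd = gamma_sd, error_sd = error_sd,
                            times = times, target_time = target_time,
                            phenotyped_fraction = phenotyped_fraction,
                            seed = as.integer(seed)))
  rownames(out$phenotypes) <- NULL
  class(out) <- "gs_sim"
  out
}

#' @export
print.gs_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated cross population: %d fathers x %d mothers x %d offspring = %d individuals\n",
              cfg$n_fathers, cfg$n_mothers, cfg$offspring_per_cross, nrow(x$genotypes)))
  cat(sprintf("  %d markers (%d QTL), %d phenotyped at times %s, target time %s\n",
              cfg$n_markers, cfg$n_qtl, length(x$phenotyped),
              paste(cfg$times, collapse = ", "), format(cfg$target_time)))
  cat(sprintf("  var(TBV) = %.4g, measurement error sd = %.3g, seed = %d\n",
              stats::var(x$tbv), cfg$error_sd, cfg$seed))
  invisible(x)
}

#' Write a simulated population to delimited files
#'
#' Writes `genotypes.csv` (allele-pair calls), `pedigree.csv`,
#' `phenotypes.csv` (long format) and `tbv.csv` in the dialects read by
#' [read_genotypes()], [read_pedigree()] and [run_gs_pipeline()].
#'
#' @param sim A `gs_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "gs_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genotypes.csv", "pedigree.csv",
                            "phenotypes.csv", "tbv.csv"))
  geno <- data.frame(individual = rownames(sim$calls), sim$calls,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(geno, paths[1L], sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$pedigree, paths[2L], sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$phenotypes, paths[3L], sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(individual = names(sim$tbv), tbv = unname(sim$tbv)),
                     paths[4L], sep = ",", row.names = FALSE, quote = FALSE)
  invisible(paths)
}
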