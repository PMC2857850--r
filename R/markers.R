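# Marker coding and genotype distance matrices.
#
# Markers are biallelic; the covariate for individual i at marker k is
#   1 for A1A1, -1 for A2A2 and 0 for either heterozygote order,
# collected in the matrix Z = {z_ik}.  Genetic distance between individuals is
# the Euclidean distance between rows of Z.

#' Default allele-pair coding map
#'
#' Named integer vector mapping biallelic genotype call labels to marker
#' codes: homozygote `A1A1` to 1, homozygote `A2A2` to -1 and both
#' heterozygote orders to 0.
#'
#' @return Named integer vector.
#' @export
default_coding_map <- function() {
  c(A1A1 = 1L, A2A2 = -1L, A1A2 = 0L, A2A1 = 0L)
}

#' Read a genotype table from delimited text
#'
#' Reads a table with one row per individual: the first column holds the
#' individual identifier, the remaining columns one marker each (header row of
#' marker ids).  Cells are either integer codes in \{-1, 0, 1\} or genotype
#' call labels such as `"A1A2"`.  Row order of the file is preserved.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator (default `","`).
#' @return A matrix (numeric if the file holds codes, character if it holds
#'   call labels) with individual ids as row names and marker ids as column
#'   names.  Pass character matrices through [code_markers()] to obtain the
#'   coded matrix Z.
#' @export
read_genotypes <- function(file, sep = ",") {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("genotype file needs an id column plus >= 1 marker column")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) stop("duplicated individual ids in genotype file")
  x <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(x) <- ids
  num <- suppressWarnings(matrix(as.numeric(x), nrow(x), ncol(x),
                                 dimnames = dimnames(x)))
  if (!anyNA(num[!is.na(x)])) return(num)
  x
}

#' Code a genotype call table into the marker matrix Z
#'
#' Applies the biallelic scoring rule (see [default_coding_map()]) to a table
#' of genotype calls.  Already-coded numeric input is validated and returned
#' unchanged.  Heterozygotes in either allele order receive the same code.
#'
#' @param calls Character matrix of call labels (rows = individuals, columns =
#'   markers, dimnames required) or a numeric matrix of codes in \{-1, 0, 1\}.
#' @param map Named vector mapping call labels to codes; defaults to
#'   [default_coding_map()].
#' @param missing How to treat `NA` calls: `"error"` (default) or `"impute"`,
#'   which replaces missing codes by the marker's mean code (an extension;
#'   imputed entries are then generally not integers).
#' @return Numeric matrix Z with entries in \{-1, 0, 1\} (exactly, unless
#'   imputation was requested), same dimnames as the input.
#' @export
code_markers <- function(calls, map = default_coding_map(),
                         missing = c("error", "impute")) {
  missing <- match.arg(missing)
  if (is.data.frame(calls)) calls <- as.matrix(calls)
  if (is.numeric(calls)) {
    Z <- calls
  } else {
    storage.mode(calls) <- "character"
    bad <- !is.na(calls) & !(calls %in% names(map))
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("unknown genotype call '%s' for individual '%s', marker '%s'",
                   calls[bad][1L],
                   rownames(calls)[idx[1L]] %||% idx[1L],
                   colnames(calls)[idx[2L]] %||% idx[2L]))
    }
    Z <- matrix(unname(map[calls]), nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  }
  if (is.numeric(calls) && !all(Z[!is.na(Z)] %in% c(-1, 0, 1)))
    stop("numeric genotype codes must lie in {-1, 0, 1}")
  if (anyNA(Z)) {
    if (missing == "error") {
      idx <- which(is.na(Z), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing genotype call for individual '%s', marker '%s'",
                   rownames(Z)[idx[1L]] %||% idx[1L],
                   colnames(Z)[idx[2L]] %||% idx[2L]))
    }
    for (k in which(colSums(is.na(Z)) > 0L)) {
      mk <- mean(Z[, k], na.rm = TRUE)
      if (is.nan(mk)) mk <- 0
      Z[is.na(Z[, k]), k] <- mk
    }
  }
  storage.mode(Z) <- "double"
  Z
}

#' Euclidean distance matrix between genotype vectors
#'
#' Computes d_ii' = ||z_i - z_i'|| between all rows of the marker matrix Z.
#'
#' @param Z Numeric marker matrix (individuals x markers), no missing values.
#' @return Symmetric matrix of pairwise Euclidean distances with a zero
#'   diagonal and the row ids of `Z` as dimnames.
#' @export
genotype_dist <- function(Z) {
  if (!is.matrix(Z) || !is.numeric(Z)) stop("Z must be a numeric matrix")
  if (!all(is.finite(Z))) stop("Z contains non-finite entries")
  D <- as.matrix(stats::dist(Z, method = "euclidean"))
  dimnames(D) <- list(rownames(Z), rownames(Z))
  diag(D) <- 0
  D
}

#' Rectangular distance matrix between two genotype sets
#'
#' Pairwise Euclidean distances between the rows of two marker matrices sharing
#' the same marker set and order; used to build the covariance block between
#' prediction candidates and the training set.  `cross_dist(Z, Z)` reproduces
#' [genotype_dist()].
#'
#' @param Z_a,Z_b Numeric marker matrices with identical marker columns.
#' @return `nrow(Z_a)` x `nrow(Z_b)` matrix of distances.
#' @export
cross_dist <- function(Z_a, Z_b) {
  if (ncol(Z_a) != ncol(Z_b)) stop("marker sets differ between the two genotype matrices")
  if (!is.null(colnames(Z_a)) && !is.null(colnames(Z_b)) &&
      !identical(colnames(Z_a), colnames(Z_b)))
    stop("marker sets differ between the two genotype matrices")
  if (!all(is.finite(Z_a)) || !all(is.finite(Z_b))) stop("non-finite genotype codes")
  d2 <- outer(rowSums(Z_a^2), rowSums(Z_b^2), "+") - 2 * tcrossprod(Z_a, Z_b)
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  dimnames(D) <- list(rownames(Z_a), rownames(Z_b))
  D
}

`%||%` <- function(a, b) if (is.null(a)) b else a
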