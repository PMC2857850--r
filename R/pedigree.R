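# Father/mother/cross variance components.
#
# The extended model adds Omega = s2_f V_f + s2_m V_m + s2_c V_c to the
# marginal covariance, where V_f[i,i'] = 1 iff individuals i and i' share the
# father (likewise mother, cross = the unique father x mother pair) and the
# diagonals are 1: an individual shares its own parents with itself, so the
# construction coincides with grouped random effects via 0/1 incidence
# matrices (V = T T' with T the individual-by-level incidence).  Omega = 0
# recovers the model with independent polygenic effects.

#' Read a pedigree table from delimited text
#'
#' Expects columns `individual`, `father`, `mother` (header required; extra
#' columns ignored).  The cross identifier is derived internally as the
#' father x mother pair.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator (default `","`).
#' @return Data frame with character columns `individual`, `father`, `mother`.
#' @export
read_pedigree <- function(file, sep = ",") {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("individual", "father", "mother")
  if (!all(need %in% names(tab)))
    stop("pedigree file needs columns: individual, father, mother")
  out <- tab[need]
  out[] <- lapply(out, as.character)
  if (anyDuplicated(out$individual)) stop("duplicated individual ids in pedigree")
  out
}

# parent labels resolved to factor levels; unknown parents (NA, "", "0",
# "NA", ".") become unique singleton levels so they share with nobody
.ped_levels <- function(x, prefix) {
  x <- as.character(x)
  unknown <- is.na(x) | x %in% c("", "0", "NA", ".")
  x[unknown] <- paste0(".", prefix, "_unknown_", seq_len(sum(unknown)))
  x
}

#' Build the father/mother/cross indicator matrices
#'
#' For an ordered id vector, returns the symmetric 0/1 matrices `V_f`, `V_m`,
#' `V_c` whose (i, i') entry is 1 iff the two individuals share the father /
#' mother / cross (father x mother pair); diagonals are 1.  Unknown parent ids
#' are treated as unique singleton levels.
#'
#' @param pedigree Data frame with columns `individual`, `father`, `mother`.
#' @param ids Character vector of individual ids, in the order the matrices
#'   should follow; every id must appear in the pedigree.
#' @return List with matrices `V_f`, `V_m`, `V_c` (dimnames = `ids`) and the
#'   per-individual `father`, `mother`, `cross` label vectors.
#' @export
omega_design <- function(pedigree, ids) {
  stopifnot(is.data.frame(pedigree),
            all(c("individual", "father", "mother") %in% names(pedigree)))
  idx <- match(ids, as.character(pedigree$individual))
  if (anyNA(idx))
    stop("individuals missing from pedigree: ",
         paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
  fa <- .ped_levels(pedigree$father[idx], "f")
  mo <- .ped_levels(pedigree$mother[idx], "m")
  cr <- paste(fa, mo, sep = " x ")
  share <- function(lab) {
    M <- outer(lab, lab, "==") * 1
    dimnames(M) <- list(ids, ids)
    M
  }
  list(V_f = share(fa), V_m = share(mo), V_c = share(cr),
       father = setNames(fa, ids), mother = setNames(mo, ids),
       cross = setNames(cr, ids))
}

#' Assemble the Omega covariance matrix
#'
#' Omega = s2_f V_f + s2_m V_m + s2_c V_c; the zero matrix when all three
#' variances are zero (the model then reduces to independent polygenic
#' effects).
#'
#' @param design Result of [omega_design()].
#' @param s2_f,s2_m,s2_c Non-negative variance components.
#' @return Symmetric positive semidefinite matrix.
#' @export
omega_matrix <- function(design, s2_f, s2_m, s2_c) {
  stopifnot(s2_f >= 0, s2_m >= 0, s2_c >= 0)
  s2_f * design$V_f + s2_m * design$V_m + s2_c * design$V_c
}
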