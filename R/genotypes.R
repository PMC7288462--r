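#' Diploid SNP genotype matrix
#'
#' The central container of the package: unphased diploid calls for a set of
#' individuals grouped into population samples.  Calls are stored as two
#' allele matrices with the pair sorted alphabetically within each cell, so
#' that no gametic phase is ever implied ("CA" and "AC" are the same call).
#'
#' @param a1,a2 character matrices (individuals x loci) holding the two
#'   alleles of each call, `NA` for missing.  Dimnames give individual and
#'   locus IDs; generated when absent.
#' @param pop character or factor of population codes, one per individual.
#' @param alleles optional named list of declared allele symbols per locus;
#'   defaults to the alleles observed.  At most 3 alleles per locus.
#' @return an object of class `genotype_matrix` with elements `ind`, `pop`
#'   (factor), `loci`, `a1`, `a2`, `alleles`.
#' @examples
#' gm <- genotype_matrix(
#'   a1 = matrix(c("A", "A"), 2, 1), a2 = matrix(c("A", "C"), 2, 1),
#'   pop = c("P1", "P1")
#' )
#' n_individuals(gm)
#' @export
genotype_matrix <- function(a1, a2, pop, alleles = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(a1) == dim(a2))) stop("a1 and a2 must have identical dimensions")
  if (nrow(a1) < 1L || ncol(a1) < 1L) stop("need at least one individual and one locus")
  if (length(pop) != nrow(a1)) stop("pop must name a population for every individual")
  if (is.null(rownames(a1))) rownames(a1) <- sprintf("ind%03d", seq_len(nrow(a1)))
  if (is.null(colnames(a1))) colnames(a1) <- sprintf("L%03d", seq_len(ncol(a1)))
  dimnames(a2) <- dimnames(a1)
  # normalize unordered pair and paired missingness
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_character_; a2[miss] <- NA_character_
  swap <- !miss & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  obs <- lapply(seq_len(ncol(a1)), function(j)
    sort(unique(stats::na.omit(c(a1[, j], a2[, j])))))
  names(obs) <- colnames(a1)
  if (is.null(alleles)) {
    alleles <- obs
  } else {
    alleles <- alleles[colnames(a1)]
    bad <- vapply(colnames(a1), function(l)
      length(setdiff(obs[[l]], alleles[[l]])) > 0, logical(1))
    if (any(bad))
      stop("calls use alleles not declared for locus: ",
           paste(colnames(a1)[bad], collapse = ", "))
  }
  over <- vapply(alleles, length, integer(1)) > 3L
  if (any(over))
    stop("more than 3 allele symbols at locus ",
         paste(names(alleles)[over], collapse = ", "), " (",
         paste(vapply(alleles[over], paste, "", collapse = ","), collapse = "; "), ")")
  structure(list(ind = rownames(a1), pop = factor(pop), loci = colnames(a1),
                 a1 = a1, a2 = a2, alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ind), "individuals,",
      length(x$loci), "loci,", nlevels(x$pop), "populations\n")
  cat("missing calls:",
      sprintf("%.1f%%", 100 * mean(is.na(x$a1))), "\n")
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  tab <- table(object$pop)
  cat("populations (n individuals):\n")
  print(tab)
  nall <- vapply(object$alleles, length, integer(1))
  cat("loci:", length(object$loci), "(", sum(nall == 2), "biallelic,",
      sum(nall == 3), "triallelic,", sum(nall < 2), "monomorphic )\n")
  invisible(object)
}

#' Numbers of individuals, loci and population codes
#' @param gm a [genotype_matrix()]
#' @return integer counts / character vector of codes.
#' @export
n_individuals <- function(gm) length(gm$ind)

#' @rdname n_individuals
#' @export
n_loci <- function(gm) length(gm$loci)

#' @rdname n_individuals
#' @export
populations <- function(gm) levels(gm$pop)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()]
#' @param i individual selector (index, logical, or IDs)
#' @param j locus selector (index, logical, or locus IDs)
#' @param ... ignored
#' @param drop ignored; the result is always a `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x$ind)
  if (missing(j)) j <- seq_along(x$loci)
  if (is.character(i)) i <- match(i, x$ind)
  if (is.character(j)) j <- match(j, x$loci)
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  pop = as.character(x$pop)[i],
                  alleles = x$alleles[j])
}

#' Extract one population sample
#' @param gm a [genotype_matrix()]
#' @param pop a population code
#' @export
pop_subset <- function(gm, pop) {
  if (!pop %in% levels(gm$pop)) stop("unknown population: ", pop)
  gm[gm$pop == pop, ]
}

#' Two-letter genotype strings ("AC", NA when missing)
#' @param gm a [genotype_matrix()]
#' @return character matrix individuals x loci.
#' @export
genotype_calls <- function(gm) {
  out <- matrix(NA_character_, nrow(gm$a1), ncol(gm$a1), dimnames = dimnames(gm$a1))
  ok <- !is.na(gm$a1)
  out[ok] <- paste0(gm$a1[ok], gm$a2[ok])
  out
}

# allele copy counts at one locus for a set of row indices
.copy_counts <- function(gm, locus, rows = seq_along(gm$ind)) {
  al <- gm$alleles[[locus]]
  x <- c(gm$a1[rows, locus], gm$a2[rows, locus])
  x <- x[!is.na(x)]
  tab <- table(factor(x, levels = al))
  n <- as.vector(tab, mode = "integer")
  names(n) <- al
  n
}

# genotype counts (unordered pairs) at one biallelic/triallelic locus
.geno_counts <- function(gm, locus, rows = seq_along(gm$ind)) {
  a1 <- gm$a1[rows, locus]; a2 <- gm$a2[rows, locus]
  ok <- !is.na(a1)
  tab <- table(paste0(a1[ok], a2[ok]))
  out <- as.vector(tab, mode = "integer")
  names(out) <- names(tab)
  out
}

# per-individual copy count of one focal allele (0/1/2, NA missing)
.allele_dosage <- function(gm, locus, allele, rows = seq_along(gm$ind)) {
  a1 <- gm$a1[rows, locus]; a2 <- gm$a2[rows, locus]
  (a1 == allele) + (a2 == allele)
}
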