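#' Weir-Cockerham FST (theta)
#'
#' Variance-component estimator of Weir & Cockerham (1984) for diploid,
#' possibly multiallelic loci.  For each locus the components `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals) are summed over alleles; the per-locus estimate is
#' `a / (a + b + c)` and the multilocus estimate is the ratio of the summed
#' components.  Loci monomorphic across all populations contribute zero to
#' every component (their per-locus estimate is `NA`).
#'
#' @param gm a [genotype_matrix()].
#' @param pops population codes to include (default all).
#' @param loci loci to include (default all).
#' @return list of class `wc_fst`: `theta` (named per-locus vector),
#'   `multilocus`, `components` (loci x 3 matrix of summed a, b, c).
#' @export
wc_fst <- function(gm, pops = populations(gm), loci = gm$loci) {
  if (length(pops) < 2L) stop("need at least 2 populations")
  comp <- matrix(0, length(loci), 3, dimnames = list(loci, c("a", "b", "c")))
  for (j in seq_along(loci)) {
    comp[j, ] <- .wc_components(gm, pops, loci[j])
  }
  denom <- rowSums(comp)
  theta <- ifelse(denom == 0, NA_real_, comp[, "a"] / denom)
  names(theta) <- loci
  structure(list(theta = theta,
                 multilocus = sum(comp[, "a"]) / sum(comp),
                 components = comp),
            class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat("Weir-Cockerham FST over", nrow(x$components), "loci: multilocus theta =",
      format(x$multilocus, digits = 4), "\n")
  invisible(x)
}

# summed (a, b, c) variance components over alleles for one locus
.wc_components <- function(gm, pops, locus) {
  ni <- integer(0); P <- list(); H <- list()
  al <- gm$alleles[[locus]]
  for (p in pops) {
    rows <- which(gm$pop == p)
    a1 <- gm$a1[rows, locus]; a2 <- gm$a2[rows, locus]
    ok <- !is.na(a1)
    if (sum(ok) == 0L) next
    a1 <- a1[ok]; a2 <- a2[ok]
    n <- length(a1)
    cnt <- table(factor(c(a1, a2), levels = al))
    het <- vapply(al, function(u) sum((a1 == u) != (a2 == u)) / n, 0)
    ni <- c(ni, n); P[[length(P) + 1L]] <- as.vector(cnt) / (2 * n)
    H[[length(H) + 1L]] <- het
  }
  r <- length(ni)
  if (r < 2L) return(c(0, 0, 0))
  P <- do.call(rbind, P); H <- do.call(rbind, H)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  out <- c(a = 0, b = 0, c = 0)
  for (u in seq_along(al)) {
    pbar <- sum(ni * P[, u]) / (r * nbar)
    if (pbar == 0 || pbar == 1) next
    s2 <- sum(ni * (P[, u] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * H[, u]) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    out <- out + c(a, b, cc)
  }
  out
}

#' Permutation test for pairwise FST
#'
#' Individuals are permuted between the two population samples; the p-value
#' is the smoothed proportion of permuted multilocus theta values at least
#' as large as the observed one.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB the two population codes.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param loci loci to use (default all).
#' @export
fst_permutation_test <- function(gm, popA, popB, n_perm = 1000, seed = 1,
                                 loci = gm$loci) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  rows <- which(gm$pop %in% c(popA, popB))
  if (sum(gm$pop == popA) < 2L || sum(gm$pop == popB) < 2L)
    stop("both populations must have at least 2 individuals")
  sub <- gm[rows, loci]
  obs <- wc_fst(sub, pops = c(popA, popB))$multilocus
  nA <- sum(sub$pop == popA)
  set.seed(seed)
  hit <- 0L
  lab <- as.character(sub$pop)
  for (b in seq_len(n_perm)) {
    perm <- sample(lab)
    g <- genotype_matrix(sub$a1, sub$a2, pop = perm, alleles = sub$alleles)
    if (wc_fst(g, pops = c(popA, popB))$multilocus >= obs - 1e-12) hit <- hit + 1L
  }
  (1 + hit) / (n_perm + 1)
}

#' Pairwise multilocus FST matrix with permutation p-values
#'
#' @inheritParams fst_permutation_test
#' @param n_perm permutations per pair (0 to skip testing).
#' @return list of class `fst_matrix`: `fst` (symmetric matrix, diagonal 0)
#'   and `p` (permutation p-values, `NA` when `n_perm = 0`).
#' @export
pairwise_fst <- function(gm, n_perm = 0, seed = 1, loci = gm$loci) {
  pops <- populations(gm)
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sub <- gm[gm$pop %in% pops[c(i, j)], loci]
    fst[i, j] <- fst[j, i] <- wc_fst(sub, pops = pops[c(i, j)])$multilocus
    if (n_perm > 0) {
      pmat[i, j] <- pmat[j, i] <-
        fst_permutation_test(gm, pops[i], pops[j], n_perm,
                             seed = seed + i * 131L + j, loci = loci)
    }
  }
  structure(list(fst = fst, p = pmat), class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise Weir-Cockerham FST (", nrow(x$fst), "populations )\n")
  print(round(x$fst, 4))
  invisible(x)
}

#' Island-model FST outlier scan
#'
#' Simulates the neutral FST distribution under a symmetric island model
#' calibrated to the observed multilocus FST: per simulated locus an
#' ancestral allele frequency is drawn uniformly, deme frequencies follow
#' the Balding-Nichols Beta distribution with that mean and the target FST,
#' and genotypes are sampled binomially at the observed sample sizes.
#' Simulated loci are binned by total (pooled) heterozygosity; each observed
#' locus is flagged when its FST falls outside the
#' `(alpha/2, 1 - alpha/2)` envelope of its heterozygosity bin.
#'
#' @param gm a [genotype_matrix()].
#' @param n_sim simulated neutral loci (>= 1000).
#' @param alpha envelope significance level.
#' @param seed integer seed.
#' @param n_demes island-model demes.
#' @param n_sampled demes sampled per simulated locus.
#' @param pops populations used for the observed estimates.
#' @return data.frame of class `outlier_scan`: per locus FST, pooled
#'   heterozygosity, envelope bounds and outlier flag; the target FST as
#'   attribute `target_fst`.
#' @export
fst_outlier_scan <- function(gm, n_sim = 30000, alpha = 0.05, seed = 1,
                             n_demes = 50, n_sampled = 2,
                             pops = populations(gm)) {
  if (n_sim < 1000L) stop("n_sim must be >= 1000")
  obs <- wc_fst(gm, pops = pops)
  target <- obs$multilocus
  if (is.na(target) || target <= 0) {
    warning("multilocus FST <= 0: outlier scan skipped")
    return(NULL)
  }
  # observed pooled heterozygosity per locus
  het_obs <- vapply(gm$loci, function(l) {
    cnt <- .copy_counts(gm, l)
    if (sum(cnt) == 0L) return(NA_real_)
    1 - sum((cnt / sum(cnt))^2)
  }, 0)
  nbar <- round(mean(table(gm$pop)))
  set.seed(seed)
  shape <- (1 - target) / target
  sim_theta <- sim_het <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    pa <- stats::runif(1, 0.02, 0.98)
    pd <- stats::rbeta(n_sampled, pa * shape, (1 - pa) * shape)
    ncop <- 2L * nbar
    cnt <- stats::rbinom(n_sampled, ncop, pd)
    p_i <- cnt / ncop
    # Weir-Cockerham from allele counts assuming HW within demes
    r <- n_sampled
    nv <- rep(nbar, r)
    nb <- nbar; nc <- (r * nb - sum(nv^2) / (r * nb)) / (r - 1)
    h_i <- 2 * p_i * (1 - p_i)  # HW heterozygote proportions
    acc <- c(0, 0, 0)
    for (pp in list(cbind(p_i, h_i), cbind(1 - p_i, h_i))) {
      pbar <- mean(pp[, 1]); hbar <- mean(pp[, 2])
      if (pbar <= 0 || pbar >= 1) next
      s2 <- sum((pp[, 1] - pbar)^2) / (r - 1)
      a <- (nb / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nb - 1))
      b <- (nb / (nb - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                (2 * nb - 1) / (4 * nb) * hbar)
      acc <- acc + c(a, b, hbar / 2)
    }
    sim_theta[s] <- if (sum(acc) == 0) NA_real_ else acc[1] / sum(acc)
    pbar <- mean(p_i)
    sim_het[s] <- 1 - pbar^2 - (1 - pbar)^2
  }
  ok <- !is.na(sim_theta)
  sim_theta <- sim_theta[ok]; sim_het <- sim_het[ok]
  lo <- hi <- rep(NA_real_, length(gm$loci))
  flag <- rep(FALSE, length(gm$loci))
  for (j in seq_along(gm$loci)) {
    if (is.na(het_obs[j]) || is.na(obs$theta[j])) next
    w <- 0.05
    repeat {
      sel <- abs(sim_het - het_obs[j]) <= w
      if (sum(sel) >= 200L || w > 1) break
      w <- w * 2
    }
    q <- stats::quantile(sim_theta[sel], c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo[j] <- q[1]; hi[j] <- q[2]
    flag[j] <- obs$theta[j] < q[1] || obs$theta[j] > q[2]
  }
  out <- data.frame(locus = gm$loci, fst = unname(obs$theta),
                    het = unname(het_obs), lower = lo, upper = hi,
                    outlier = flag, stringsAsFactors = FALSE)
  attr(out, "target_fst") <- target
  class(out) <- c("outlier_scan", "data.frame")
  out
}

#' Phase-free genotypic linkage disequilibrium test
#'
#' Association between the unphased genotypes at two loci within one
#' population sample, without any assumption about gametic phase in double
#' heterozygotes: the test statistic is the G statistic (likelihood-ratio
#' chi-square) on the two-locus genotype contingency table, and the null
#' distribution is obtained by permuting the single-locus genotypes of one
#' locus across individuals.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population code.
#' @param locusA,locusB locus IDs.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return smoothed permutation p-value (1 for a zero-variance table).
#' @export
ld_pair_test <- function(gm, pop, locusA, locusB, n_perm = 1000, seed = 1) {
  rows <- which(gm$pop == pop)
  gA <- paste0(gm$a1[rows, locusA], gm$a2[rows, locusA])
  gB <- paste0(gm$a1[rows, locusB], gm$a2[rows, locusB])
  ok <- !is.na(gm$a1[rows, locusA]) & !is.na(gm$a1[rows, locusB])
  gA <- gA[ok]; gB <- gB[ok]
  if (length(unique(gA)) < 2L || length(unique(gB)) < 2L) return(1)
  gstat <- function(a, b) {
    tab <- table(a, b)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sel <- tab > 0
    2 * sum(tab[sel] * log(tab[sel] / e[sel]))
  }
  obs <- gstat(gA, gB)
  set.seed(seed)
  hit <- 0L
  for (b in seq_len(n_perm)) {
    if (gstat(gA, sample(gB)) >= obs - 1e-12) hit <- hit + 1L
  }
  (1 + hit) / (n_perm + 1)
}

#' Scan all locus pairs for genotypic LD
#'
#' Runs [ld_pair_test()] for every unordered pair of the given loci
#' (`L(L-1)/2` pairs).
#'
#' @inheritParams ld_pair_test
#' @param loci loci to scan (default: loci polymorphic in `pop`).
#' @return data.frame with columns `locusA`, `locusB`, `p`.
#' @export
ld_scan <- function(gm, pop, loci = NULL, n_perm = 100, seed = 1) {
  rows <- which(gm$pop == pop)
  if (is.null(loci)) {
    loci <- gm$loci[vapply(gm$loci, function(l)
      sum(.copy_counts(gm, l, rows) > 0L) >= 2L, logical(1))]
  }
  L <- length(loci)
  if (L < 2L) stop("need at least 2 polymorphic loci")
  pairs <- utils::combn(L, 2)
  p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    p[k] <- ld_pair_test(gm, pop, loci[pairs[1, k]], loci[pairs[2, k]],
                         n_perm = n_perm, seed = seed + k)
  }
  data.frame(locusA = loci[pairs[1, ]], locusB = loci[pairs[2, ]], p = p,
             stringsAsFactors = FALSE)
}

#' Neighbour-joining tree from an FST matrix
#'
#' Saitou-Nei neighbour joining on the pairwise FST distance matrix
#' (negative entries clamped to 0), with population codes as leaf labels.
#'
#' @param fst a [pairwise_fst()] result or a symmetric numeric matrix.
#' @return list of class `nj_result`: `tree` (an [ape::phylo] object) and
#'   `newick` (Newick text).
#' @export
nj_tree <- function(fst) {
  d <- if (inherits(fst, "fst_matrix")) fst$fst else as.matrix(fst)
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 populations")
  d[d < 0] <- 0
  tr <- ape::nj(stats::as.dist(d))
  structure(list(tree = tr, newick = ape::write.tree(tr)), class = "nj_result")
}

#' @export
print.nj_result <- function(x, ...) {
  cat(x$newick, "\n")
  invisible(x)
}

#' Correspondence analysis of an allele-count table
#'
#' Chi-square-standardized SVD of the correspondence matrix.  Rows are
#' populations (allele counts) or individuals (allele dosages); columns are
#' locus-allele combinations.  Returns principal row coordinates and the
#' percentage of total inertia carried by each axis (summing to 100).
#'
#' @param x non-negative count matrix, or a [genotype_matrix()] (converted
#'   with [allele_count_matrix()]).
#' @param by when `x` is a genotype matrix: `"population"` or
#'   `"individual"` rows.
#' @return list of class `ca_result`: `row_coords`, `inertia_pct`,
#'   `singular_values`.
#' @export
correspondence_analysis <- function(x, by = c("population", "individual")) {
  if (inherits(x, "genotype_matrix")) x <- allele_count_matrix(x, match.arg(by))
  x <- as.matrix(x)
  keep_r <- rowSums(x) > 0; keep_c <- colSums(x) > 0
  x <- x[keep_r, keep_c, drop = FALSE]
  if (!nrow(x) || !ncol(x)) stop("rank-0 matrix: no non-zero rows/columns")
  P <- x / sum(x)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  pos <- sv$d > 1e-12
  if (!any(pos)) stop("rank-0 correspondence matrix (all rows identical)")
  d <- sv$d[pos]
  coords <- sweep(sv$u[, pos, drop = FALSE], 1, sqrt(r), "/") %*% diag(d, length(d))
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("Axis", seq_along(d))
  structure(list(row_coords = coords,
                 inertia_pct = 100 * d^2 / sum(d^2),
                 singular_values = d),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("correspondence analysis:", nrow(x$row_coords), "rows,",
      length(x$inertia_pct), "axes\n")
  cat("inertia (%):", paste(sprintf("%.1f", x$inertia_pct[seq_len(min(5, length(x$inertia_pct)))]),
                            collapse = ", "), "...\n")
  invisible(x)
}

#' Allele-count matrix for ordination
#'
#' @param gm a [genotype_matrix()].
#' @param by `"population"` (copy counts per population) or `"individual"`
#'   (allele dosages 0/1/2, missing as 0).
#' @return numeric matrix, one column per locus-allele combination.
#' @export
allele_count_matrix <- function(gm, by = c("population", "individual")) {
  by <- match.arg(by)
  cols <- list()
  for (l in gm$loci) for (al in gm$alleles[[l]]) {
    d <- .allele_dosage(gm, l, al)
    d[is.na(d)] <- 0L
    cols[[paste0(l, ".", al)]] <- d
  }
  m <- do.call(cbind, cols)
  rownames(m) <- gm$ind
  if (by == "individual") return(m)
  rowsum(m, group = gm$pop)
}
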