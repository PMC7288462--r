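#' Allele frequencies at one locus in one population
#'
#' Frequencies over observed gene copies; missing calls are excluded.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population code.
#' @param locus locus ID.
#' @return named numeric vector over the declared alleles, summing to 1.
#' @export
allele_frequencies <- function(gm, pop, locus) {
  rows <- which(gm$pop == pop)
  n <- .copy_counts(gm, locus, rows)
  if (sum(n) == 0L) stop("no data: all calls missing at ", locus, " in ", pop)
  n / sum(n)
}

#' Observed and unbiased expected heterozygosity
#'
#' `HO` is the fraction of heterozygous individuals among non-missing calls;
#' `HE` is Nei's unbiased gene diversity
#' \eqn{\frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)} with `n` the number of
#' genotyped individuals.
#'
#' @inheritParams allele_frequencies
#' @return named numeric vector `c(HO =, HE =, n =)`.
#' @export
heterozygosities <- function(gm, pop, locus) {
  rows <- which(gm$pop == pop)
  a1 <- gm$a1[rows, locus]; a2 <- gm$a2[rows, locus]
  ok <- !is.na(a1)
  n <- sum(ok)
  if (n < 2L) return(c(HO = NA_real_, HE = NA_real_, n = n))
  ho <- mean(a1[ok] != a2[ok])
  cnt <- .copy_counts(gm, locus, rows)
  p <- cnt / sum(cnt)
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  c(HO = ho, HE = he, n = n)
}

#' Inbreeding coefficient from heterozygosities
#'
#' `FIS = 1 - HO / HE`.  A sample holding the two alternative homozygote
#' classes and no heterozygotes yields `FIS = 1`; `HO = HE` yields 0.
#' Undefined (`NA`) when `HE = 0`.
#'
#' @param HO,HE observed and expected heterozygosity.
#' @export
fis <- function(HO, HE) ifelse(HE > 0, 1 - HO / HE, NA_real_)

#' One-sided permutation test for heterozygote deficit (FIS > 0)
#'
#' Alleles are shuffled between individuals at the locus (random re-pairing
#' of the 2n observed gene copies), FIS recomputed each time, and the
#' p-value is the smoothed proportion of replicates with FIS at least the
#' observed one: `(1 + #\{FIS* >= FIS\}) / (n_perm + 1)`.
#'
#' @inheritParams allele_frequencies
#' @param n_perm number of permutations (> 0).
#' @param seed integer seed.
#' @export
fis_permutation_test <- function(gm, pop, locus, n_perm = 10000, seed = 1) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  rows <- which(gm$pop == pop)
  a1 <- gm$a1[rows, locus]; a2 <- gm$a2[rows, locus]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2L) stop("need at least 2 genotyped individuals")
  copies <- c(a1, a2)
  p <- table(copies) / (2 * n)
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  if (he <= 0) stop("monomorphic locus: FIS undefined")
  obs <- 1 - mean(a1 != a2) / he
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(copies)
    ho_b <- mean(perm[1:n] != perm[(n + 1):(2 * n)])
    if (1 - ho_b / he >= obs - 1e-12) cnt <- cnt + 1L
  }
  (1 + cnt) / (n_perm + 1)
}

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' The exact conditional test: given the observed allele counts, every
#' possible heterozygote count of the same parity is enumerated, its
#' conditional probability
#' \deqn{P(n_{Aa} \mid n, n_A) = \frac{n!\, n_A!\, n_a!\, 2^{n_{Aa}}}
#'   {n_{AA}!\, n_{Aa}!\, n_{aa}!\, (2n)!}}
#' computed, and the p-value is the total probability of configurations no
#' more probable than the observed one.  Monomorphic samples return 1.
#'
#' @param counts integer vector `c(n_AA, n_Aa, n_aa)` of genotype counts.
#' @export
hwe_exact_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    stop("counts must be 3 non-negative genotype counts (n_AA, n_Aa, n_aa)")
  n <- sum(counts)
  nA <- 2L * counts[1L] + counts[2L]
  na <- 2L * counts[3L] + counts[2L]
  if (nA == 0L || na == 0L) return(1)
  hets <- seq(nA %% 2L, min(nA, na), by = 2L)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- (na - h) / 2
    lgamma(n + 1) + lgamma(nA + 1) + lgamma(na + 1) + h * log(2) -
      lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) - lgamma(2 * n + 1)
  }, 0)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(counts[2L], hets)]
  sum(pr[pr <= obs + 1e-12])
}

#' Monte Carlo exact Hardy-Weinberg test (any number of alleles)
#'
#' Estimates the exact conditional p-value by direct sampling from the null:
#' the observed gene copies are randomly re-paired into diploid genotypes
#' `n_steps` times (each draw is an independent sample from the conditional
#' distribution given allele counts), and the p-value is the smoothed
#' fraction of tables with conditional probability no larger than the
#' observed table's.  Agrees with [hwe_exact_test()] within Monte Carlo
#' error on biallelic input.
#'
#' @param counts named integer vector of genotype counts, names like
#'   `"AC"` (unordered pairs), or a 3-vector as in [hwe_exact_test()].
#' @param n_steps number of Monte Carlo draws (>= 100).
#' @param seed integer seed.
#' @export
hwe_mc_test <- function(counts, n_steps = 10000, seed = 1) {
  if (n_steps < 100L) stop("n_steps must be >= 100")
  if (is.null(names(counts))) {
    if (length(counts) != 3L) stop("unnamed counts must be (n_AA, n_Aa, n_aa)")
    names(counts) <- c("AA", "Aa", "aa")
  }
  if (any(counts < 0)) stop("negative genotype counts")
  g1 <- substr(names(counts), 1L, 1L)
  g2 <- substr(names(counts), 2L, 2L)
  copies <- c(rep(g1, counts), rep(g2, counts))
  n <- sum(counts)
  if (length(unique(copies)) < 2L) return(1)
  tab_logp <- function(a, b) {
    het <- a != b
    key <- paste0(pmin(a, b), pmax(a, b))
    tb <- table(key)
    sum(het) * log(2) - sum(lgamma(tb + 1))  # shared factors drop out
  }
  obs <- tab_logp(c(rep(g1, counts)), c(rep(g2, counts)))
  set.seed(seed)
  hit <- 0L
  for (b in seq_len(n_steps)) {
    perm <- sample(copies)
    lp <- tab_logp(perm[1:n], perm[(n + 1):(2 * n)])
    if (lp <= obs + 1e-9) hit <- hit + 1L
  }
  (1 + hit) / (n_steps + 1)
}

#' Benjamini-Yekutieli FDR control
#'
#' Step-up rejection at level `alpha` with the Benjamini-Yekutieli
#' correction valid under arbitrary dependence: reject the ordered
#' p-values up to the largest `i` with
#' `p_(i) <= i * alpha / (m * c(m))`, `c(m) = sum(1/j)`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha significance threshold.
#' @return logical rejection flags in the input order.
#' @export
fdr_by <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(logical(0))
  stats::p.adjust(pvalues, method = "BY") <= alpha
}

#' Per-population diversity summary
#'
#' One row per population mirroring the standard diversity-table layout:
#' proportion of polymorphic loci (`Po`, per cent of loci with at least two
#' observed alleles), mean observed and unbiased expected heterozygosity
#' (over polymorphic loci; `*_all` variants average over all loci), mean
#' minor allele frequency, multilocus FIS as a ratio of averages
#' (`1 - sum(HO) / sum(HE)` over polymorphic loci), the number of loci out
#' of Hardy-Weinberg equilibrium after Benjamini-Yekutieli correction at
#' `alpha`, average gene diversity per locus (over all loci, monomorphic
#' contributing 0), and the average number of pairwise differences between
#' individuals (per-locus allele mismatches summed over loci, averaged over
#' individual pairs).
#'
#' @param gm a [genotype_matrix()].
#' @param pop population code (default: all, one row each).
#' @param alpha HWE significance threshold before FDR correction.
#' @return data.frame with one row per population.
#' @export
population_summary <- function(gm, pop = populations(gm), alpha = 0.05) {
  out <- lapply(pop, function(p) .pop_summary_one(gm, p, alpha))
  do.call(rbind, out)
}

.pop_summary_one <- function(gm, pop, alpha) {
  rows <- which(gm$pop == pop)
  L <- length(gm$loci)
  ho <- he <- maf <- rep(NA_real_, L)
  poly <- logical(L)
  hwe_p <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    loc <- gm$loci[j]
    cnt <- .copy_counts(gm, loc, rows)
    if (sum(cnt) == 0L) next
    poly[j] <- sum(cnt > 0L) >= 2L
    p <- cnt / sum(cnt)
    maf[j] <- if (poly[j]) min(p[p > 0]) else 0
    h <- heterozygosities(gm, pop, loc)
    ho[j] <- h["HO"]; he[j] <- h["HE"]
    if (poly[j]) {
      if (length(cnt) == 2L || sum(cnt > 0L) == 2L) {
        al <- names(cnt)[cnt > 0L]
        d <- .allele_dosage(gm, loc, al[1L], rows)
        d <- d[!is.na(d)]
        hwe_p[j] <- hwe_exact_test(c(sum(d == 2L), sum(d == 1L), sum(d == 0L)))
      } else {
        gc <- .geno_counts(gm, loc, rows)
        hwe_p[j] <- hwe_mc_test(gc, n_steps = 10000, seed = 1)
      }
    }
  }
  pv <- hwe_p[!is.na(hwe_p)]
  n_hwe_fail <- sum(fdr_by(pv, alpha))
  gene_div <- mean(ifelse(is.na(he), 0, he))
  data.frame(
    population = pop,
    n = length(rows),
    Po = 100 * mean(poly, na.rm = TRUE),
    FIS = 1 - sum(ho[poly], na.rm = TRUE) / sum(he[poly], na.rm = TRUE),
    n_HWE_dev = n_hwe_fail,
    HO = mean(ho[poly], na.rm = TRUE),
    HE = mean(he[poly], na.rm = TRUE),
    HO_all = mean(ho, na.rm = TRUE),
    HE_all = mean(he, na.rm = TRUE),
    MAF = mean(maf[poly], na.rm = TRUE),
    gene_diversity = gene_div,
    mean_pairwise_diff = .mean_pairwise_diff(gm, rows),
    stringsAsFactors = FALSE)
}

# mean over individual pairs of summed per-locus allele mismatches;
# a locus pair (i,k) contributes the number of allele copies not matchable
# between the two unordered genotypes (0, 1 or 2)
.mean_pairwise_diff <- function(gm, rows) {
  n <- length(rows)
  if (n < 2L) return(0)
  d1 <- gm$a1[rows, , drop = FALSE]; d2 <- gm$a2[rows, , drop = FALSE]
  tot <- 0; np <- 0L
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    ok <- !is.na(d1[i, ]) & !is.na(d1[k, ])
    if (!any(ok)) next
    same2 <- d1[i, ok] == d1[k, ok] & d2[i, ok] == d2[k, ok]
    share1 <- !same2 & (d1[i, ok] == d1[k, ok] | d1[i, ok] == d2[k, ok] |
                          d2[i, ok] == d1[k, ok] | d2[i, ok] == d2[k, ok])
    tot <- tot + sum(2L * (!same2 & !share1) + 1L * share1)
    np <- np + 1L
  }
  tot / np
}
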