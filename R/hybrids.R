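#' Select a diagnostic SNP panel from reference samples
#'
#' Picks loci whose characteristic allele is near-fixed in the target
#' taxon's reference populations (frequency at least `d_high`) and rare in
#' each other taxon's references (at most `d_low`).
#'
#' @param gm a [genotype_matrix()].
#' @param refs named list mapping taxon label to a character vector of its
#'   reference population codes; must contain the target taxon.
#' @param target taxon the panel should be diagnostic for.
#' @param d_high minimum characteristic-allele frequency in the target.
#' @param d_low maximum frequency in every other reference taxon.
#' @return data.frame of class `diagnostic_panel`: `locus`,
#'   `characteristic_allele`, `freq_target`; target as attribute.
#' @export
select_diagnostic_panel <- function(gm, refs, target, d_high = 0.9,
                                    d_low = 0.2) {
  if (!target %in% names(refs)) stop("refs must contain the target taxon")
  others <- setdiff(names(refs), target)
  loc <- character(0); ch <- character(0); fr <- numeric(0)
  ref_rows <- lapply(refs, function(p) which(gm$pop %in% p))
  for (l in gm$loci) {
    cnt <- .copy_counts(gm, l, ref_rows[[target]])
    if (sum(cnt) == 0L) next
    p_t <- cnt / sum(cnt)
    for (al in names(p_t)[p_t >= d_high]) {
      ok <- TRUE
      for (o in others) {
        co <- .copy_counts(gm, l, ref_rows[[o]])
        if (sum(co) == 0L || co[al] / sum(co) > d_low) { ok <- FALSE; break }
      }
      if (ok) {
        loc <- c(loc, l); ch <- c(ch, al); fr <- c(fr, p_t[al])
        break
      }
    }
  }
  if (!length(loc))
    stop("no loci satisfy the diagnostic thresholds (d_high = ", d_high,
         ", d_low = ", d_low, "); consider relaxing them")
  out <- data.frame(locus = loc, characteristic_allele = ch,
                    freq_target = fr, stringsAsFactors = FALSE)
  attr(out, "target") <- target
  class(out) <- c("diagnostic_panel", "data.frame")
  out
}

#' Hybrid index over a diagnostic panel
#'
#' Per individual, the fraction of characteristic-allele copies over the
#' scored panel loci: `HI = copies / (2 x loci scored)`.  A score of 1 is a
#' pure target-taxon individual (e.g. M. trossulus), 0 a pure individual of
#' the other taxon.  Missing panel loci shrink the denominator; individuals
#' with no scored panel loci get `NA` and are excluded from the population
#' aggregates.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a [select_diagnostic_panel()] result, or a data.frame with
#'   columns `locus` and `characteristic_allele`.
#' @return list of class `hybrid_index`: `individuals` (data.frame with
#'   `individual`, `population`, `HI`, `n_loci`), `populations` (data.frame
#'   with `population`, `mean_HI`, `V_HI`, `n`).
#' @export
hybrid_index <- function(gm, panel) {
  if (!nrow(panel)) stop("empty diagnostic panel")
  loci <- panel$locus
  if (!all(loci %in% gm$loci)) stop("panel loci absent from genotype matrix")
  dos <- sapply(seq_along(loci), function(k)
    .allele_dosage(gm, loci[k], panel$characteristic_allele[k]))
  dos <- matrix(dos, nrow = length(gm$ind))
  n_loc <- rowSums(!is.na(dos))
  hi <- rowSums(dos, na.rm = TRUE) / (2 * n_loc)
  hi[n_loc == 0L] <- NA_real_
  ind <- data.frame(individual = gm$ind, population = as.character(gm$pop),
                    HI = hi, n_loci = n_loc, stringsAsFactors = FALSE)
  pops <- do.call(rbind, lapply(populations(gm), function(p) {
    h <- hi[gm$pop == p]; h <- h[!is.na(h)]
    data.frame(population = p, mean_HI = mean(h),
               V_HI = if (length(h) > 1) stats::var(h) else NA_real_,
               n = length(h), stringsAsFactors = FALSE)
  }))
  structure(list(individuals = ind, populations = pops),
            class = "hybrid_index")
}

#' @export
print.hybrid_index <- function(x, ...) {
  print(x$populations, digits = 3)
  invisible(x)
}

#' Six hybrid genotype classes
#'
#' Labels of the six genotypic categories of a two-taxon hybrid-zone model:
#' the two pure parentals, F1 and F2 hybrids, and the two first-generation
#' backcrosses.
#' @export
hybrid_classes <- c("pure_A", "pure_B", "F1", "F2", "BC_A", "BC_B")

#' Expected genotype frequency under a hybrid class
#'
#' Closed-form genotype distribution at one locus for each of the six
#' classes, given the parental frequencies `piA` and `piB` of a chosen
#' reference allele.  Pure classes are Hardy-Weinberg at the parental
#' frequency; F1 takes one gamete from each parent; F2 is Hardy-Weinberg at
#' the pooled mean `(piA + piB) / 2`; backcrosses take one parental gamete
#' and one pooled (F1) gamete.
#'
#' @param class one of [hybrid_classes].
#' @param piA,piB reference-allele frequency in parental taxa A and B.
#' @param genotype reference-allele copy number 0, 1 or 2 (omit for the
#'   full length-3 distribution).
#' @return probability (or the named length-3 vector over copies 2, 1, 0).
#' @export
class_genotype_frequency <- function(class, piA, piB, genotype = NULL) {
  hw <- function(p) c(`2` = p^2, `1` = 2 * p * (1 - p), `0` = (1 - p)^2)
  two_gam <- function(p, q) c(`2` = p * q,
                              `1` = p * (1 - q) + q * (1 - p),
                              `0` = (1 - p) * (1 - q))
  mid <- (piA + piB) / 2
  dist <- switch(match.arg(class, hybrid_classes),
                 pure_A = hw(piA),
                 pure_B = hw(piB),
                 F1 = two_gam(piA, piB),
                 F2 = hw(mid),
                 BC_A = two_gam(piA, mid),
                 BC_B = two_gam(piB, mid))
  if (is.null(genotype)) dist else unname(dist[as.character(genotype)])
}

#' Posterior over the six hybrid classes
#'
#' A plug-in (empirical-Bayes) analogue of the NewHybrids categorical model:
#' parental allele frequencies are estimated from the declared reference
#' samples (with add-one Dirichlet smoothing), individual likelihoods are
#' products of [class_genotype_frequency()] over the panel loci (assumed
#' independent), and the per-individual posterior is the normalized product
#' of likelihood and prior (uniform over the six classes by default).
#'
#' @param gm a [genotype_matrix()].
#' @param panel loci to use: a [select_diagnostic_panel()] result or a
#'   character vector of locus IDs (all loci if `NULL`).
#' @param refA,refB character vectors of reference population codes for
#'   parental taxa A and B.
#' @param prior prior over the six classes.
#' @return list of class `class_posterior`: `posterior` (individuals x 6),
#'   `map` (factor of MAP classes), `map_prob`, `population_table`
#'   (per-population percentage of individuals per MAP class).
#' @export
assign_hybrid_classes <- function(gm, panel = NULL, refA, refB,
                                  prior = rep(1 / 6, 6)) {
  loci <- if (is.null(panel)) gm$loci
          else if (is.data.frame(panel)) panel$locus else panel
  rowsA <- which(gm$pop %in% refA); rowsB <- which(gm$pop %in% refB)
  if (!length(rowsA) || !length(rowsB)) stop("empty reference samples")
  prior <- prior / sum(prior)
  logpost <- matrix(0, length(gm$ind), 6,
                    dimnames = list(gm$ind, hybrid_classes))
  for (l in loci) {
    # reference allele: first declared allele of the locus
    al <- gm$alleles[[l]][1L]
    cA <- .copy_counts(gm, l, rowsA); cB <- .copy_counts(gm, l, rowsB)
    piA <- (cA[al] + 1) / (sum(cA) + 2)
    piB <- (cB[al] + 1) / (sum(cB) + 2)
    dist <- vapply(hybrid_classes, class_genotype_frequency, numeric(3),
                   piA = piA, piB = piB)  # 3 x 6, rows copies 2,1,0
    d <- .allele_dosage(gm, l, al)
    ok <- !is.na(d)
    logpost[ok, ] <- logpost[ok, ] + log(dist)[match(d[ok], c(2, 1, 0)), ]
  }
  logpost <- sweep(logpost, 2, log(prior), "+")
  post <- exp(logpost - apply(logpost, 1, max))
  post <- post / rowSums(post)
  map <- factor(hybrid_classes[max.col(post, ties.method = "first")],
                levels = hybrid_classes)
  tab <- 100 * prop.table(table(gm$pop, map), margin = 1)
  structure(list(posterior = post, map = map,
                 map_prob = post[cbind(seq_len(nrow(post)), max.col(post, ties.method = "first"))],
                 population_table = tab),
            class = "class_posterior")
}

#' @export
print.class_posterior <- function(x, ...) {
  cat("six-class hybrid assignment (% of individuals per MAP class):\n")
  print(round(x$population_table, 2))
  invisible(x)
}

#' Supervised ancestry fractions by EM
#'
#' Per-individual admixture proportions over K clusters with known
#' (reference-estimated) cluster allele frequencies.  The likelihood of
#' each of an individual's gene copies is a q-mixture of the cluster
#' frequencies of the observed allele; q is maximized on the simplex by EM,
#' converged when `max |dq| < 1e-8` or after 5000 iterations (warning on
#' non-convergence).
#'
#' @param gm a [genotype_matrix()].
#' @param ref_freqs list per cluster of per-locus named allele-frequency
#'   vectors (as built by [cluster_frequencies()]), or `NULL` to estimate
#'   from `refs`.
#' @param refs named list mapping cluster label to reference population
#'   codes (used when `ref_freqs` is `NULL`).
#' @param focal cluster whose q is used for the resident/admixed/migrant
#'   call (default: first cluster).
#' @return list of class `ancestry_result`: `q` (individuals x K),
#'   `classification` (factor resident/admixed/migrant by [classify_q()]).
#' @export
supervised_ancestry <- function(gm, ref_freqs = NULL, refs = NULL,
                                focal = NULL) {
  if (is.null(ref_freqs)) {
    if (is.null(refs)) stop("supply ref_freqs or refs")
    ref_freqs <- lapply(refs, function(p) cluster_frequencies(gm, p))
  }
  K <- length(ref_freqs)
  if (K < 1L) stop("need at least one cluster")
  clusters <- names(ref_freqs)
  if (is.null(focal)) focal <- clusters[1L]
  n <- length(gm$ind)
  # per individual: matrix copies x K of cluster likelihoods of each copy
  q <- matrix(1 / K, n, K, dimnames = list(gm$ind, clusters))
  if (K == 1L) {
    cls <- classify_q(q[, 1L])
    return(structure(list(q = q, classification = cls, focal = focal),
                     class = "ancestry_result"))
  }
  for (i in seq_len(n)) {
    lik <- list()
    for (l in gm$loci) {
      for (a in c(gm$a1[i, l], gm$a2[i, l])) {
        if (is.na(a)) next
        lik[[length(lik) + 1L]] <- vapply(clusters, function(k) {
          p <- ref_freqs[[k]][[l]]
          max(p[a], 1e-12)
        }, 0)
      }
    }
    if (!length(lik)) next
    M <- do.call(rbind, lik)
    qi <- rep(1 / K, K)
    conv <- FALSE
    for (it in seq_len(5000L)) {
      w <- sweep(M, 2, qi, "*")
      w <- w / rowSums(w)
      qnew <- colMeans(w)
      if (max(abs(qnew - qi)) < 1e-8) { qi <- qnew; conv <- TRUE; break }
      qi <- qnew
    }
    if (!conv) warning("EM did not converge for individual ", gm$ind[i])
    q[i, ] <- qi
  }
  cls <- classify_q(q[, focal])
  structure(list(q = q, classification = cls, focal = focal),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat("supervised ancestry over", ncol(x$q), "clusters; focal:", x$focal, "\n")
  print(table(x$classification))
  invisible(x)
}

#' Cluster allele frequencies from reference populations
#'
#' Add-one-smoothed allele frequencies per locus from the pooled reference
#' samples of one cluster.
#'
#' @param gm a [genotype_matrix()].
#' @param pops reference population codes.
#' @export
cluster_frequencies <- function(gm, pops) {
  rows <- which(gm$pop %in% pops)
  if (!length(rows)) stop("no individuals in reference populations")
  out <- lapply(gm$loci, function(l) {
    cnt <- .copy_counts(gm, l, rows)
    (cnt + 1) / (sum(cnt) + length(cnt))
  })
  names(out) <- gm$loci
  out
}

#' Resident / admixed / migrant call from an ancestry fraction
#'
#' Residents have `q > 0.8` for their sampling area, migrants `q < 0.2`,
#' and individuals with q between 0.2 and 0.8 (inclusive) are potentially
#' admixed.
#'
#' @param q ancestry fraction(s) toward the focal cluster.
#' @return factor with levels resident, admixed, migrant.
#' @export
classify_q <- function(q) {
  if (any(q < -1e-9 | q > 1 + 1e-9)) stop("q must lie in [0, 1]")
  factor(ifelse(q > 0.8, "resident", ifelse(q < 0.2, "migrant", "admixed")),
         levels = c("resident", "admixed", "migrant"))
}
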