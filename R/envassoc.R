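#' Collinearity screen of the environmental predictors
#'
#' Pairwise Pearson correlations over populations.  Pairs with `|r|` at or
#' above the cutoff are flagged; by default they are retained with a
#' warning rather than excluded (strongly coupled variable pairs, such as
#' water temperature and ice cover, need not distort tree-based models),
#' with hard exclusion available by flag.
#'
#' @param env an [env_table()] (or data.frame with the [env_variables]).
#' @param cutoff absolute correlation flag threshold.
#' @param exclude when `TRUE`, drop the second variable of each flagged
#'   pair from the returned `keep` set.
#' @return list of class `collinearity_report`: `r` (correlation matrix),
#'   `flagged` (data.frame of pairs), `keep` (variable names retained).
#' @export
collinearity_screen <- function(env, cutoff = 0.9, exclude = FALSE) {
  X <- as.data.frame(env)[, intersect(env_variables, colnames(env)), drop = FALSE]
  if (nrow(X) < 3L) stop("need at least 3 populations")
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  diag(r) <- 1
  idx <- which(abs(r) >= cutoff & upper.tri(r), arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(r)[idx[, 1]],
                        var2 = colnames(r)[idx[, 2]],
                        r = r[idx], stringsAsFactors = FALSE)
  keep <- colnames(X)
  if (exclude && nrow(flagged)) keep <- setdiff(keep, flagged$var2)
  if (!exclude && nrow(flagged))
    warning("highly correlated predictor pairs retained: ",
            paste(sprintf("%s~%s (r=%.2f)", flagged$var1, flagged$var2,
                          flagged$r), collapse = ", "))
  structure(list(r = r, flagged = flagged, keep = keep),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("collinearity screen:", nrow(x$flagged), "flagged pair(s);",
      length(x$keep), "predictors kept\n")
  if (nrow(x$flagged)) print(x$flagged)
  invisible(x)
}

# copy-level model frame for one locus: 2 rows per genotyped individual,
# response = allele symbol, predictors = site environment + region
.locus_model_frame <- function(gm, env, locus) {
  a1 <- gm$a1[, locus]; a2 <- gm$a2[, locus]
  ok <- !is.na(a1)
  allele <- c(a1[ok], a2[ok])
  pops <- rep(as.character(gm$pop)[ok], 2L)
  erow <- match(pops, env$population)
  X <- as.data.frame(env)[erow, c(env_variables, "region")]
  rownames(X) <- NULL
  X$region <- factor(X$region, levels = region_levels)
  list(X = X, y = factor(allele), population = pops)
}

#' Per-locus BRT models of allele frequencies on the environment
#'
#' Fits one cross-validated boosted-trees model per locus: the response is
#' the allele carried by each gene copy (two Bernoulli/multinomial
#' observations per genotyped individual, loss chosen by the observed
#' allele count), the predictors are the twelve site-level environmental
#' variables plus the categorical region, and fold assignment is stratified
#' by population.  Each locus gets its adjusted count pseudo-R-squared,
#' relative-influence profile and (for the requested variables) an
#' abrupt-transition interval from the partial-dependence curve.
#'
#' @param gm a [genotype_matrix()].
#' @param env an [env_table()] covering every population of `gm`.
#' @param config a [brt_config()].
#' @param loci loci to model (default all polymorphic; monomorphic loci are
#'   skipped with a message).
#' @param transition_vars continuous predictors for which transition
#'   intervals are extracted (default `"salinity"`).
#' @param coverage coverage fraction passed to [detect_transition()].
#' @return list of class `locus_models`: `summary` (data.frame per locus),
#'   `influence` (loci x predictors matrix, rows sum to 100),
#'   `transitions` (named list of intervals), `models` (the `brt` fits).
#' @export
per_locus_models <- function(gm, env, config = brt_config(), loci = gm$loci,
                             transition_vars = "salinity", coverage = 0.8) {
  if (!all(levels(gm$pop) %in% env$population))
    stop("environment table must cover every population")
  models <- list(); keep <- character(0)
  for (l in loci) {
    cnt <- .copy_counts(gm, l)
    if (sum(cnt > 0L) < 2L) {
      message("skipping monomorphic locus ", l)
      next
    }
    mf <- .locus_model_frame(gm, env, l)
    loss <- if (nlevels(mf$y) <= 2L) "bernoulli" else "multinomial"
    models[[l]] <- brt_cv(mf$X, mf$y, loss = loss, config = config,
                          strata = mf$population)
    keep <- c(keep, l)
  }
  if (!length(keep)) stop("no polymorphic loci to model")
  feats <- models[[1L]]$features
  infl <- t(vapply(models[keep], relative_influence, numeric(length(feats))))
  r2 <- vapply(models[keep], function(m) m$pseudo_r2, 0)
  trans <- list()
  for (l in keep) for (v in transition_vars) {
    mf <- .locus_model_frame(gm, env, l)
    pd <- partial_dependence(models[[l]], mf$X, v)
    trans[[paste(l, v, sep = ".")]] <-
      detect_transition(pd$value, pd[[2L]], coverage = coverage)
  }
  summ <- data.frame(locus = keep, pseudo_r2 = unname(r2),
                     n_trees = vapply(models[keep], function(m) m$best_n_trees, 0L),
                     top_influence = feats[apply(infl, 1, which.max)],
                     region_influence = infl[, "region"],
                     stringsAsFactors = FALSE)
  structure(list(summary = summ, influence = infl, transitions = trans,
                 models = models[keep],
                 frac_r2_gt_0.4 = mean(r2 > 0.4),
                 frac_r2_lt_0.1 = mean(r2 < 0.1),
                 max_region_influence = max(infl[, "region"])),
            class = "locus_models")
}

#' @export
print.locus_models <- function(x, ...) {
  cat("per-locus BRT models:", nrow(x$summary), "loci\n")
  cat(sprintf("  pseudo-R2 > 0.4: %.0f%%   < 0.1: %.0f%%   max region influence: %.1f%%\n",
              100 * x$frac_r2_gt_0.4, 100 * x$frac_r2_lt_0.1,
              x$max_region_influence))
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Abrupt-transition interval of a response curve
#'
#' Operationalizes "abrupt change along a gradient" as the shortest grid
#' interval containing at least `coverage` of the curve's total variation.
#' A linear ramp therefore yields an interval spanning about `coverage` of
#' the domain, while a step function collapses to the step's grid
#' neighbourhood.  Flat curves return `NULL`.
#'
#' @param x grid values (>= 10 points, increasing).
#' @param y curve values (e.g. partial-dependence probabilities).
#' @param coverage fraction of total variation the interval must contain.
#' @return numeric `c(low, high)` or `NULL` for a flat curve.
#' @export
detect_transition <- function(x, y, coverage = 0.8) {
  if (length(x) < 10L) stop("need a grid of at least 10 points")
  if (is.unsorted(x)) stop("grid must be increasing")
  steps <- abs(diff(y))
  tv <- sum(steps)
  if (tv <= 1e-10) return(NULL)
  target <- coverage * tv
  best <- c(NA_integer_, NA_integer_); best_len <- Inf
  i <- 1L; acc <- 0; j <- 0L
  # two-pointer shortest window over the step sequence
  for (i in seq_along(steps)) {
    if (j < i) { j <- i - 1L; acc <- 0 }
    while (acc < target - 1e-12 && j < length(steps)) {
      j <- j + 1L; acc <- acc + steps[j]
    }
    if (acc >= target - 1e-12) {
      len <- x[j + 1L] - x[i]
      if (len < best_len) { best_len <- len; best <- c(i, j + 1L) }
      acc <- acc - steps[i]
    } else break
  }
  c(low = x[best[1L]], high = x[best[2L]])
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|u - v|) / sum(u + v)` for equal-length non-negative profiles.
#'
#' @param u,v non-negative numeric vectors.
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("profiles must have equal length")
  if (any(u < 0) || any(v < 0)) stop("profiles must be non-negative")
  tot <- sum(u) + sum(v)
  if (tot == 0) stop("both profiles are all-zero: dissimilarity undefined")
  sum(abs(u - v)) / tot
}

#' Bray-Curtis dissimilarity matrix of profile rows
#' @param m non-negative matrix, one profile per row.
#' @export
bray_curtis_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
  d
}

# ANOSIM R from a rank matrix of dissimilarities
.anosim_R <- function(rk, grp) {
  n <- length(grp)
  within <- outer(grp, grp, "==")[upper.tri(rk)]
  r <- rk[upper.tri(rk)]
  M <- n * (n - 1) / 2
  (mean(r[!within]) - mean(r[within])) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based comparison of between-group versus within-group
#' dissimilarities: `R = (mean between-rank - mean within-rank) / (M / 2)`
#' with `M` the number of object pairs.  The p-value is obtained by
#' permuting group labels (smoothed), or by full enumeration of all
#' distinct label arrangements when `exact = TRUE` (p is then the exact
#' proportion of arrangements with `R* >= R`, the observed one included).
#'
#' @param d dissimilarity matrix (or `dist`).
#' @param groups group labels, at least 2 groups of size >= 2.
#' @param n_perm random label permutations when `exact = FALSE`.
#' @param seed integer seed.
#' @param exact enumerate all distinct label arrangements (feasible for
#'   small n).
#' @return list of class `anosim_result`: `R`, `p`, `n_perm`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1, exact = FALSE) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("singleton group: ANOSIM undefined")
  rk <- d
  rk[] <- 0
  ut <- upper.tri(d)
  rk[ut] <- rank(d[ut])
  rk <- rk + t(rk)
  obs <- .anosim_R(rk, groups)
  if (exact) {
    perms <- .distinct_label_perms(groups)
    stat <- vapply(perms, function(g) .anosim_R(rk, g), 0)
    p <- mean(stat >= obs - 1e-12)
    n_used <- length(perms)
  } else {
    set.seed(seed)
    hit <- 0L
    for (b in seq_len(n_perm))
      if (.anosim_R(rk, sample(groups)) >= obs - 1e-12) hit <- hit + 1L
    p <- (1 + hit) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(R = obs, p = p, n_perm = n_used, exact = exact),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%s)\n", x$R, x$p,
              if (x$exact) "exact enumeration" else paste(x$n_perm, "permutations")))
  invisible(x)
}

# all distinct arrangements of a label multiset (small n only)
.distinct_label_perms <- function(groups) {
  n <- length(groups)
  if (n > 10L) stop("exact enumeration limited to n <= 10")
  out <- list()
  rec <- function(prefix, remaining) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (u in unique(remaining)) {
      k <- match(u, remaining)
      rec(c(prefix, u), remaining[-k])
    }
  }
  rec(character(0), sort(groups))
  out
}

#' SIMPER decomposition of between-group Bray-Curtis dissimilarity
#'
#' Per variable, the mean over all between-group profile pairs of
#' `|u_i - v_i| / sum(u + v)`.  The contributions sum exactly to the mean
#' between-group Bray-Curtis dissimilarity.
#'
#' @param m non-negative profile matrix (rows = objects).
#' @param groups group labels as in [anosim()].
#' @return data.frame of class `simper_table`, ranked by contribution, with
#'   attribute `mean_dissimilarity`.
#' @export
simper <- function(m, groups) {
  m <- as.matrix(m)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("singleton group")
  contrib <- numeric(ncol(m))
  npair <- 0L
  n <- nrow(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (groups[i] == groups[j]) next
    tot <- sum(m[i, ]) + sum(m[j, ])
    contrib <- contrib + abs(m[i, ] - m[j, ]) / tot
    npair <- npair + 1L
  }
  contrib <- contrib / npair
  out <- data.frame(variable = colnames(m) %||% paste0("V", seq_len(ncol(m))),
                    contribution = contrib,
                    pct = 100 * contrib / sum(contrib),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution), ]
  rownames(out) <- NULL
  attr(out, "mean_dissimilarity") <- sum(contrib)
  class(out) <- c("simper_table", "data.frame")
  out
}

#' Compare BRT environment profiles between coding and non-coding loci
#'
#' Builds the matrix of per-locus relative-influence profiles from
#' [per_locus_models()], computes its Bray-Curtis dissimilarities, and runs
#' [anosim()] and [simper()] between the `region_class` groups of the locus
#' annotation.
#'
#' @param lm_res a [per_locus_models()] result.
#' @param ann a [locus_annotation()].
#' @param n_perm,seed passed to [anosim()].
#' @return list of class `group_comparison`: `anosim`, `simper`, `groups`.
#' @export
compare_region_class <- function(lm_res, ann, n_perm = 999, seed = 1) {
  loci <- lm_res$summary$locus
  grp <- ann$region_class[match(loci, ann$locus)]
  if (anyNA(grp)) stop("annotation missing for modelled loci")
  m <- lm_res$influence
  d <- bray_curtis_matrix(m)
  structure(list(anosim = anosim(d, grp, n_perm = n_perm, seed = seed),
                 simper = simper(m, grp),
                 groups = table(grp)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$anosim)
  cat("top SIMPER contributions:\n")
  print(utils::head(x$simper, 5))
  invisible(x)
}
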