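test_that("Weir-Cockerham theta matches the ANOVA oracle exhaustively", {
  # all 2-population single-locus dosage configurations with n = 3..4 each
  set.seed(1)
  checked <- 0L
  for (n in 3:4) {
    combos <- expand.grid(rep(list(0:2), n))
    keep <- sample(nrow(combos), 12)
    for (i in keep) for (j in keep) {
      d1 <- as.integer(combos[i, ]); d2 <- as.integer(combos[j, ])
      if (length(unique(c(d1, d2))) < 2) next
      gm <- gm_from_calls(list(P1 = dosage_to_calls(d1),
                               P2 = dosage_to_calls(d2)))
      got <- wc_fst(gm)$theta[[1]]
      want <- wc_theta_oracle(list(d1, d2))
      if (is.na(want) || !is.finite(want)) next
      expect_equal(got, want, tolerance = 1e-10,
                   label = paste(paste(d1, collapse = ""),
                                 paste(d2, collapse = "")))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 100)
})

test_that("theta limits: fixed difference gives 1, identical pops near 0", {
  gm <- gm_from_calls(list(P1 = rep("AA", 10), P2 = rep("CC", 10)))
  expect_equal(unname(wc_fst(gm)$theta[1]), 1)
  set.seed(5)
  d <- rbinom(600, 2, 0.5)
  gm2 <- gm_from_calls(list(P1 = dosage_to_calls(d[1:300]),
                            P2 = dosage_to_calls(d[301:600])))
  expect_lt(abs(wc_fst(gm2)$multilocus), 0.02)
})

test_that("FST permutation test: minimal p at fixed difference, calibrated null", {
  gm <- gm_from_calls(list(P1 = rep("AA", 10), P2 = rep("CC", 10)))
  p <- fst_permutation_test(gm, "P1", "P2", n_perm = 99, seed = 2)
  expect_equal(p, 1 / 100)
  expect_identical(p, fst_permutation_test(gm, "P1", "P2", n_perm = 99, seed = 2))
  set.seed(31)
  pv <- replicate(40, {
    d <- rbinom(24, 2, 0.5)
    g <- gm_from_calls(list(A = dosage_to_calls(d[1:12]),
                            B = dosage_to_calls(d[13:24])))
    tryCatch(fst_permutation_test(g, "A", "B", n_perm = 99,
                                  seed = sample.int(1e6, 1)),
             error = function(e) NA_real_)
  })
  pv <- pv[!is.na(pv)]
  expect_lt(mean(pv <= 0.05), 0.15)
  expect_gt(mean(pv), 0.3)
  g1 <- gm_from_calls(list(A = "AC", B = c("AC", "AA")))
  expect_error(fst_permutation_test(g1, "A", "B", 10), "at least 2")
})

test_that("per-locus theta spans the expected range on the default study", {
  st <- get_default_study(1)$study
  th <- wc_fst(st$gm)$theta
  th <- th[!is.na(th)]
  expect_gt(max(th), 0.7)   # diagnostic loci: strong fixation contrast
  expect_lt(min(th), 0.05)  # shared-polymorphism loci near 0
  # within-taxon replicate sites are far less differentiated than taxa
  pf <- pairwise_fst(st$gm)
  within <- pf$fst["EDU1", "EDU3"]
  between <- pf$fst["EDU1", "TRO1"]
  expect_lt(within, 0.05)
  expect_gt(between, 0.3)
  expect_gt(between, 20 * max(within, 0.001))
})

test_that("outlier scan flags an extreme locus and self-calibrates", {
  set.seed(77)
  # null data drawn from the scan's own island model at FST ~ 0.05
  Fst <- 0.05; shape <- (1 - Fst) / Fst
  n_loci <- 150; n <- 30
  mk <- function() {
    calls <- matrix(NA_character_, 2 * n, n_loci)
    for (j in seq_len(n_loci)) {
      pa <- runif(1, 0.1, 0.9)
      pd <- rbeta(2, pa * shape, (1 - pa) * shape)
      for (dem in 1:2) {
        d <- rbinom(n, 2, pd[dem])
        calls[(dem - 1) * n + 1:n, j] <- dosage_to_calls(d)
      }
    }
    gm_from_calls(list(D1 = calls[1:n, ], D2 = calls[n + 1:n, ]))
  }
  gm <- mk()
  scan <- fst_outlier_scan(gm, n_sim = 3000, alpha = 0.05, seed = 3,
                           n_sampled = 2)
  rate <- mean(scan$outlier, na.rm = TRUE)
  expect_gte(rate, 0)
  expect_lte(rate, 0.15)
  expect_true(all(scan$lower <= scan$upper, na.rm = TRUE))
  # an engineered fixed-difference locus amid that background is flagged high
  calls2 <- cbind(genotype_calls(gm), fixed = c(rep("AA", n), rep("CC", n)))
  gm2 <- gm_from_calls(list(D1 = calls2[1:n, ], D2 = calls2[n + 1:n, ]),
                       loci = colnames(calls2))
  scan2 <- fst_outlier_scan(gm2, n_sim = 3000, alpha = 0.05, seed = 3,
                            n_sampled = 2)
  expect_true(scan2$outlier[scan2$locus == "fixed"])
  expect_error(fst_outlier_scan(gm, n_sim = 10), "n_sim")
})

test_that("LD test: duplicated locus detected, independent loci calibrated", {
  set.seed(12)
  d <- rbinom(30, 2, 0.5)
  calls <- cbind(dosage_to_calls(d), dosage_to_calls(d))
  gm <- gm_from_calls(list(P = calls))
  expect_equal(ld_pair_test(gm, "P", "L1", "L2", n_perm = 199, seed = 1),
               1 / 200)
  rej <- replicate(150, {
    g <- gm_from_calls(list(P = cbind(dosage_to_calls(rbinom(25, 2, 0.5)),
                                      dosage_to_calls(rbinom(25, 2, 0.4)))))
    ld_pair_test(g, "P", "L1", "L2", n_perm = 99, seed = sample.int(1e6, 1)) <= 0.05
  })
  expect_lt(mean(rej), 0.11)
})

test_that("neighbour joining recovers additive matrices exactly", {
  set.seed(3)
  for (k in 1:5) {
    n_tip <- sample(4:6, 1)
    tr <- ape::rtree(n_tip, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- cophenetic(tr)
    res <- nj_tree(D)
    expect_equal(unname(cophenetic(res$tree)[rownames(D), colnames(D)]),
                 unname(D), tolerance = 1e-8)
    expect_match(res$newick, "^\\(.*\\);$")
  }
  # 3 taxa: branch lengths solve the three-point equations
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  res3 <- nj_tree(D3)
  el <- setNames(res3$tree$edge.length,
                 res3$tree$tip.label[res3$tree$edge[, 2]])
  expect_equal(unname(el["a"]), 1)  # (3 + 4 - 5) / 2
  expect_equal(unname(el["b"]), 2)
  expect_equal(unname(el["c"]), 3)
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("taxa form three major clades in the default-study NJ tree", {
  st <- get_default_study(1)$study
  pf <- pairwise_fst(st$gm)
  tre <- nj_tree(pf)$tree
  # the four pure edulis sites form a clade against trossulus-side sites
  edus <- c("EDU1", "EDU2", "EDU3", "EDU4")
  mrca_sub <- ape::keep.tip(tre, c(edus, "TRO1", "BAL1", "GAL1"))
  expect_true(ape::is.monophyletic(ape::unroot(mrca_sub), edus))
})

test_that("correspondence analysis matches an independent eigendecomposition", {
  st <- get_default_study(1)$study
  X <- allele_count_matrix(st$gm, by = "population")
  ca <- correspondence_analysis(X)
  expect_equal(sum(ca$inertia_pct), 100, tolerance = 1e-9)
  # oracle: MASS::corresp canonical correlations equal the singular values
  or <- MASS::corresp(as.matrix(X), nf = 3)
  expect_equal(ca$singular_values[1:3], unname(or$cor[1:3]), tolerance = 1e-6)
  # two identical rows get identical coordinates
  X2 <- rbind(X, dup = X[1, ])
  ca2 <- correspondence_analysis(X2)
  expect_equal(unname(ca2$row_coords["dup", ]),
               unname(ca2$row_coords[rownames(X)[1], ]), tolerance = 1e-8)
  # axis 1 separates the trossulus-side sites from the edulis side
  ax1 <- ca$row_coords[, 1]
  expect_true(sign(mean(ax1[c("TRO1", "BAL1", "BAL2")])) !=
                sign(mean(ax1[c("EDU1", "EDU2", "EDU3")])))
  expect_error(correspondence_analysis(matrix(0, 2, 2)), "rank-0")
})
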