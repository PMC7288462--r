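test_that("collinearity screen recovers the built-in temperature-ice coupling", {
  st <- get_default_study(1)$study
  rep_ <- suppressWarnings(collinearity_screen(st$env, cutoff = 0.8))
  expect_equal(unname(diag(rep_$r)), rep(1, length(env_variables)))
  expect_equal(rep_$r, t(rep_$r))
  expect_lt(abs(rep_$r["temperature", "ice_conc"] + 0.87), 0.05)
  flagged <- paste(rep_$flagged$var1, rep_$flagged$var2)
  expect_true("ice_conc temperature" %in% flagged ||
                "temperature ice_conc" %in% flagged)
  # duplicated column flagged at r = 1, excluded on request
  env2 <- st$env; env2$cloud <- env2$wind
  rep2 <- collinearity_screen(env2, cutoff = 0.99, exclude = TRUE)
  expect_true(any(abs(rep2$flagged$r - 1) < 1e-12))
  expect_lt(length(rep2$keep), length(env_variables))
})

test_that("transition detection: step, ramp, and flat curves", {
  x <- seq(0, 35, length.out = 71)
  step <- ifelse(x < 9.5, 1, 0)
  iv <- detect_transition(x, step)
  expect_lt(iv["high"] - iv["low"], 2 * diff(x)[1] + 1e-9)
  expect_true(iv["low"] <= 9.5 && iv["high"] >= 9)
  ramp <- x / 35
  ivr <- detect_transition(x, ramp, coverage = 0.8)
  expect_equal(unname(ivr["high"] - ivr["low"]), 0.8 * 35, tolerance = 0.05)
  expect_null(detect_transition(x, rep(0.3, 71)))
  expect_error(detect_transition(x[1:5], step[1:5]), "at least 10")
})

test_that("Bray-Curtis dissimilarity matches hand arithmetic", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  # matrix agrees with vegan
  set.seed(13)
  m <- matrix(runif(24), 6)
  expect_equal(unname(bray_curtis_matrix(m)),
               unname(as.matrix(vegan::vegdist(m, "bray"))),
               tolerance = 1e-12)
})

test_that("ANOSIM matches limits and the exact enumeration oracle", {
  # perfectly separated groups give R = 1
  m <- rbind(matrix(0.01 * 1:6, 3), 10 + matrix(0.01 * 1:6, 3))
  d <- bray_curtis_matrix(m)
  grp <- c("a", "a", "a", "b", "b", "b")
  expect_equal(anosim(d, grp, n_perm = 99, seed = 1)$R, 1)
  # exact p equals an independent enumeration using vegan's statistic
  set.seed(14)
  m2 <- matrix(runif(28), 7)
  d2 <- bray_curtis_matrix(m2)
  g2 <- c("a", "a", "a", "b", "b", "b", "b")
  res <- anosim(d2, g2, exact = TRUE)
  combs <- combn(7, 3)
  stats_or <- apply(combs, 2, function(ix) {
    g <- rep("b", 7); g[ix] <- "a"
    vegan::anosim(as.dist(d2), factor(g), permutations = 0)$statistic
  })
  n_a_arrangements <- factorial(3) * factorial(4)
  p_or <- sum(stats_or >= res$R - 1e-12) / length(stats_or)
  expect_equal(res$p, p_or, tolerance = 1e-12)
  expect_equal(res$R,
               vegan::anosim(as.dist(d2), factor(g2), permutations = 0)$statistic,
               tolerance = 1e-12)
  # null calibration with random labels
  set.seed(15)
  rej <- replicate(150, {
    mm <- matrix(runif(32), 8)
    anosim(bray_curtis_matrix(mm), sample(rep(c("a", "b"), 4)),
           n_perm = 99, seed = sample.int(1e6, 1))$p <= 0.05
  })
  expect_lt(mean(rej), 0.11)
  expect_error(anosim(d2, c("a", rep("b", 6)), 9), "singleton")
})

test_that("SIMPER decomposition identity and hand-computed 2x2 case", {
  set.seed(16)
  m <- matrix(runif(40), 8)
  grp <- rep(c("u", "v"), each = 4)
  s <- simper(m, grp)
  expect_equal(attr(s, "mean_dissimilarity"),
               mean(bray_curtis_matrix(m)[1:4, 5:8]), tolerance = 1e-12)
  expect_equal(sum(s$contribution), attr(s, "mean_dissimilarity"),
               tolerance = 1e-12)
  # groups differing in one variable only: that variable carries 100%
  m2 <- rbind(c(1, 5), c(1, 5), c(3, 5), c(3, 5))
  s2 <- simper(m2, c("u", "u", "v", "v"))
  expect_equal(s2$pct[s2$variable == "V1"], 100)
  # 2x2 toy equals the hand decomposition
  m3 <- rbind(c(2, 1), c(1, 1))
  s3 <- simper(rbind(m3, m3[2:1, ]), c("u", "u", "v", "v"))
  # between pairs: (2,1)v(1,1): contribs 1/5, 0/5 ; (2,1)v(2,1): 0,0 ;
  # (1,1)v(1,1): 0,0 ; (1,1)v(2,1): 1/5, 0 -> mean (0.1, 0)
  expect_equal(s3$contribution[s3$variable == "V1"], 0.1, tolerance = 1e-12)
  expect_equal(s3$contribution[s3$variable == "V2"], 0, tolerance = 1e-12)
})

test_that("per-locus BRT models separate cline-driven from neutral loci", {
  st <- get_default_study(1)$study
  ann <- st$annotation
  diag_loci <- ann$locus[!is.na(ann$diagnostic_for)][1:3]
  tri <- st$gm$loci[vapply(st$gm$alleles, length, 1L) == 3][1]
  neut <- setdiff(ann$locus[is.na(ann$diagnostic_for)], tri)[1:3]
  cfg <- brt_config(max_trees = 1500, cv_folds = 10, seed = 1)
  lm_res <- suppressWarnings(
    per_locus_models(st$gm, st$env, cfg, loci = c(diag_loci, neut, tri)))
  s <- lm_res$summary
  expect_true(all(s$pseudo_r2[s$locus %in% diag_loci] > 0.4))
  expect_true(all(s$pseudo_r2[s$locus %in% c(neut, tri)] < 0.1))
  # salinity dominates the influence profile of every cline-driven locus
  expect_true(all(s$top_influence[s$locus %in% diag_loci] == "salinity"))
  expect_equal(unname(rowSums(lm_res$influence)), rep(100, nrow(s)),
               tolerance = 1e-6)
  # partial-dependence transition inside the 8-11 psu window
  for (l in diag_loci) {
    iv <- lm_res$transitions[[paste0(l, ".salinity")]]
    expect_gte(iv["low"], 8)
    expect_lte(iv["high"], 11)
  }
  # triallelic locus was fitted with the multinomial loss
  expect_equal(lm_res$models[[tri]]$loss, "multinomial")
  expect_equal(lm_res$models[[diag_loci[1]]]$loss, "bernoulli")
  # ANOSIM/SIMPER comparison across coding / non-coding profiles runs end-to-end
  grp <- ann$region_class[match(s$locus, ann$locus)]
  if (length(unique(grp)) > 1 && min(table(grp)) >= 2) {
    gc <- compare_region_class(lm_res, ann, n_perm = 99, seed = 1)
    expect_true(gc$anosim$R >= -1 && gc$anosim$R <= 1)
    expect_equal(sum(gc$simper$contribution),
                 attr(gc$simper, "mean_dissimilarity"), tolerance = 1e-12)
  }
})

test_that("run_pipeline writes a coherent artifact bundle", {
  out <- withr::local_tempdir()
  cfg <- list(seed = 2, output_dir = out,
              simulate = list(n_per_site = 12),
              stages = c("validate", "diversity", "differentiation", "hybrids"),
              differentiation = list(n_perm = 0))
  res <- run_pipeline(cfg)
  for (f in c("diversity.tsv", "fst.tsv", "tree.nwk", "hybrid_index.tsv",
              "hybrid_classes.tsv", "run_log.tsv", "genotypes.csv"))
    expect_true(file.exists(file.path(out, f)), label = f)
  # idempotent under the seed
  out2 <- withr::local_tempdir()
  cfg$output_dir <- out2
  run_pipeline(cfg)
  expect_identical(readLines(file.path(out, "diversity.tsv")),
                   readLines(file.path(out2, "diversity.tsv")))
  expect_identical(readLines(file.path(out, "tree.nwk")),
                   readLines(file.path(out2, "tree.nwk")))
  # envassoc without an environment table is a config error naming the field
  f <- file.path(out, "genotypes.csv")
  expect_error(run_pipeline(list(inputs = list(genotypes_csv = f),
                                 stages = "envassoc")),
               "inputs\\$env")
})
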