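test_that("diagnostic panel selection respects the frequency thresholds", {
  st <- get_default_study(1)$study
  pan <- select_diagnostic_panel(st$gm, default_refs, "trossulus",
                                 d_high = 0.9, d_low = 0.2)
  expect_equal(nrow(pan), 16L)
  expect_setequal(pan$locus, get_default_study(1)$scenario$profiles$diagnostic)
  # boundary behaviour on a constructed trio of reference pops
  gm <- gm_from_calls(list(
    T1 = rbind(c("AA", "AA"), c("AA", "AA")),   # L1 0.95-like, L2 fixed
    E1 = rbind(c("CC", "AC"), c("CC", "CC")),   # L1 at 0.125, L2 at 0.25
    G1 = rbind(c("CC", "CC"), c("CC", "CC"))))
  p1 <- select_diagnostic_panel(gm, list(t = "T1", e = "E1", g = "G1"), "t",
                                d_high = 0.9, d_low = 0.2)
  expect_equal(p1$locus, "L1")   # L2 excluded: freq 0.25 in e exceeds d_low
  expect_error(select_diagnostic_panel(gm, list(t = "E1", e = "T1", g = "G1"),
                                       "t", d_high = 1, d_low = 0),
               "relaxing")
})

test_that("hybrid index hits its closed-form anchors", {
  st <- get_default_study(1)$study
  pan <- select_diagnostic_panel(st$gm, default_refs, "trossulus")
  n_pan <- nrow(pan)
  calls_hom <- matrix(paste0(pan$characteristic_allele,
                             pan$characteristic_allele), 1)
  other <- vapply(seq_len(n_pan), function(k) {
    al <- st$gm$alleles[[pan$locus[k]]]
    setdiff(al, pan$characteristic_allele[k])[1]
  }, "")
  calls_alt <- matrix(paste0(other, other), 1)
  calls_het <- matrix(paste0(pmin(pan$characteristic_allele, other),
                             pmax(pan$characteristic_allele, other)), 1)
  gm <- gm_from_calls(list(P = rbind(calls_hom, calls_alt, calls_het)),
                      loci = pan$locus)
  hi <- hybrid_index(gm, pan)
  expect_equal(hi$individuals$HI, c(1, 0, 0.5))
  # missing loci shrink the denominator
  calls_miss <- calls_hom; calls_miss[1, 1:4] <- "--"
  gm2 <- gm_from_calls(list(P = calls_miss), loci = pan$locus)
  hi2 <- hybrid_index(gm2, pan)
  expect_equal(hi2$individuals$HI, 1)
  expect_equal(hi2$individuals$n_loci, n_pan - 4L)
})

test_that("class genotype frequencies are exact and normalized", {
  # F2 with fixed parents: gamete pool (1/2, 1/2) -> (1/4, 1/2, 1/4)
  expect_equal(unname(class_genotype_frequency("F2", 1, 0)),
               c(0.25, 0.5, 0.25))
  # BC toward A with fixed parents: (1/2 hom, 1/2 het, 0)
  expect_equal(unname(class_genotype_frequency("BC_A", 1, 0)),
               c(0.5, 0.5, 0))
  expect_equal(unname(class_genotype_frequency("F1", 1, 0)), c(0, 1, 0))
  expect_equal(class_genotype_frequency("F1", 1, 0, genotype = 1), 1)
  # normalization over a grid of parental frequencies, all six classes
  for (piA in seq(0, 1, by = 0.25)) for (piB in seq(0, 1, by = 0.25)) {
    for (cl in hybrid_classes) {
      expect_equal(sum(class_genotype_frequency(cl, piA, piB)), 1,
                   tolerance = 1e-12, label = paste(cl, piA, piB))
    }
  }
})

test_that("fully heterozygous individual is assigned F1 with the closed-form posterior", {
  # likelihood ratio at 16 fixed diagnostic loci: F1 = 1 per locus,
  # F2/BC = 0.5 each, pures = 0 -> posterior(F1) = 1 / (1 + 3 * 0.5^16)
  lik <- vapply(hybrid_classes, function(cl)
    prod(rep(class_genotype_frequency(cl, 1, 0, genotype = 1), 16)), 0)
  post <- lik / sum(lik)
  expect_equal(unname(post["F1"]), 1 / (1 + 3 * 0.5^16), tolerance = 1e-12)
  expect_gt(post["F1"], 0.9999)
})

test_that("six-class assignment recovers the truth on the default scenario", {
  st <- get_default_study(1)$study
  pan <- select_diagnostic_panel(st$gm, default_refs, "trossulus")
  cp <- assign_hybrid_classes(st$gm, pan, refA = default_refs$trossulus,
                              refB = default_refs$edulis)
  expect_equal(colnames(cp$posterior), hybrid_classes)
  expect_equal(unname(rowSums(cp$posterior)), rep(1, nrow(cp$posterior)),
               tolerance = 1e-9)
  sel <- st$truth$class %in% names(lut_truth_class) &
    st$truth$population != "GAL1"
  acc <- mean(as.character(cp$map)[sel] ==
                lut_truth_class[st$truth$class[sel]])
  expect_gte(acc, 0.95)
})

test_that("bimodal zones show high V_HI, unimodal swarms low, at matched mean", {
  st <- get_default_study(1)$study
  pan <- select_diagnostic_panel(st$gm, default_refs, "trossulus")
  hp <- hybrid_index(st$gm, pan)$populations
  v <- setNames(hp$V_HI, hp$population)
  m <- setNames(hp$mean_HI, hp$population)
  expect_gt(v["BIMO"], 0.2)
  expect_lt(v["SWRM"], 0.1)
  expect_lt(abs(m["SWRM"] - 0.5), 0.1)
})

test_that("supervised ancestry EM matches symmetric and degenerate anchors", {
  st <- get_default_study(1)$study
  pan <- select_diagnostic_panel(st$gm, default_refs, "trossulus")
  gm <- st$gm[, pan$locus]
  anc <- supervised_ancestry(gm, refs = list(trossulus = "TRO1",
                                             edulis = default_refs$edulis))
  q <- anc$q[, "trossulus"]
  tro <- st$truth$population == "TRO1"
  edu <- st$truth$population %in% default_refs$edulis
  f1 <- st$truth$class == "F1"
  expect_gt(min(q[tro]), 0.9)
  expect_lt(max(q[edu]), 0.1)
  expect_lt(max(abs(q[f1] - 0.5)), 0.1)
  # grid-search oracle for one F1-type individual
  i <- which(f1)[1]
  grid <- seq(0.01, 0.99, by = 0.01)
  ref_freqs <- list(trossulus = cluster_frequencies(gm, "TRO1"),
                    edulis = cluster_frequencies(gm, default_refs$edulis))
  ll <- vapply(grid, function(qq) {
    s <- 0
    for (l in gm$loci) for (a in c(gm$a1[i, l], gm$a2[i, l])) {
      if (is.na(a)) next
      s <- s + log(qq * ref_freqs$trossulus[[l]][a] +
                     (1 - qq) * ref_freqs$edulis[[l]][a])
    }
    s
  }, 0)
  expect_lt(abs(grid[which.max(ll)] - q[i]), 0.02)
  # K = 1 collapses to q = 1
  anc1 <- supervised_ancestry(gm, refs = list(trossulus = "TRO1"))
  expect_true(all(anc1$q[, 1] == 1))
})

test_that("q-threshold classification follows the 0.2 / 0.8 rule", {
  expect_equal(as.character(classify_q(c(0.81, 0.8, 0.5, 0.2, 0.19))),
               c("resident", "admixed", "admixed", "admixed", "migrant"))
  expect_error(classify_q(1.2), "q must lie")
})
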