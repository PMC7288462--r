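# shared fixtures and independent oracles

# genotype matrix from two-letter call strings; pops = named list of
# character matrices/vectors, loci named L1..Lk
gm_from_calls <- function(pops, loci = NULL) {
  calls <- do.call(rbind, lapply(pops, function(x) {
    m <- if (is.matrix(x)) x else matrix(x, nrow = length(x))
    m
  }))
  popv <- rep(names(pops), vapply(pops, function(x)
    if (is.matrix(x)) nrow(x) else length(x), 0L))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(calls)))
  a1 <- substr(calls, 1, 1); a2 <- substr(calls, 2, 2)
  a1[calls == "--"] <- NA; a2[calls == "--"] <- NA
  dim(a1) <- dim(a2) <- dim(calls)
  colnames(a1) <- colnames(a2) <- loci
  rownames(a1) <- rownames(a2) <- sprintf("i%03d", seq_len(nrow(calls)))
  genotype_matrix(a1, a2, pop = popv)
}

# memoized default synthetic study (the standard scenario, one per seed)
.study_cache <- new.env()
get_default_study <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]])) {
    scen <- default_scenario(seed = seed)
    .study_cache[[key]] <- list(
      study = generate_study(scen$sites, scen$profiles, scen$clines,
                             seed = seed),
      scenario = scen)
  }
  .study_cache[[key]]
}

default_refs <- list(trossulus = "TRO1",
                     edulis = c("EDU1", "EDU2", "EDU3", "EDU4"),
                     galloprovincialis = "GAL1")

# independent Weir-Cockerham oracle via the ANOVA sums-of-squares route:
# variance components from mean squares of the allele-indicator ANOVA,
# sigma_a = (MSP - MSI) / (2 nc), sigma_b = (MSI - MSG) / 2, sigma_c = MSG
wc_theta_oracle <- function(dosage_by_pop) {
  # dosage_by_pop: list per population of 0/1/2 counts of the focal allele
  r <- length(dosage_by_pop)
  ni <- lengths(dosage_by_pop)
  n_tot <- sum(ni)
  nc <- (n_tot - sum(ni^2) / n_tot) / (r - 1)
  acc <- c(a = 0, b = 0, c = 0)
  for (allele in 1:2) {
    d <- lapply(dosage_by_pop, function(x) if (allele == 1) x else 2 - x)
    p_i <- vapply(d, function(x) mean(x) / 2, 0)
    pbar <- sum(ni * p_i) / n_tot
    ssp <- 2 * sum(ni * (p_i - pbar)^2)
    ssi <- sum(unlist(lapply(seq_len(r), function(i)
      2 * (d[[i]] / 2 - p_i[i])^2)))
    ssg <- sum(unlist(lapply(d, function(x) ifelse(x == 1, 0.5, 0))))
    msp <- ssp / (r - 1)
    msi <- ssi / (n_tot - r)
    msg <- ssg / n_tot
    acc <- acc + c(a = (msp - msi) / (2 * nc), b = (msi - msg) / 2, c = msg)
  }
  unname(acc["a"] / sum(acc))
}

# dosage vectors -> two-letter call strings for one biallelic locus
dosage_to_calls <- function(d) c("CC", "AC", "AA")[d + 1L]

lut_truth_class <- c(pure_trossulus = "pure_A", pure_edulis = "pure_B",
                     F1 = "F1", F2 = "F2",
                     BC_trossulus = "BC_A", BC_edulis = "BC_B")
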