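#' Taxon allele-frequency profiles for a three-taxon SNP panel
#'
#' Builds per-taxon allele frequencies for a simulated SNP panel in which a
#' chosen number of loci are diagnostic for the target taxon: their
#' characteristic allele has frequency at least `d_high` in the target taxon
#' and at most `d_low` in each of the other two.  Non-diagnostic loci share
#' an ancestral frequency drawn from a Beta distribution (shared trans-taxon
#' polymorphism) with small independent per-taxon drift; a configurable
#' number of them carry three alleles.
#'
#' @param n_loci total number of loci.
#' @param n_diagnostic loci diagnostic for the target taxon.
#' @param d_high minimum characteristic-allele frequency in the target taxon.
#' @param d_low maximum characteristic-allele frequency in the other taxa.
#' @param seed integer seed; the same seed always yields the same profiles.
#' @param n_triallelic number of (non-diagnostic) triallelic loci.
#' @param drift_sd standard deviation of per-taxon frequency drift around the
#'   shared ancestral frequency at non-diagnostic loci.
#' @param target taxon the diagnostic panel points to.
#' @param shared_beta shape parameters of the shared-polymorphism Beta.
#' @return an object of class `taxon_profiles`: list with `taxa`, `loci`,
#'   `alleles` (list per locus), `freq` (list taxon -> locus -> named
#'   frequency vector), `diagnostic` (locus names), `characteristic`
#'   (named allele symbols for the diagnostic loci), `target`.
#' @export
make_taxon_profiles <- function(n_loci = 54, n_diagnostic = 16,
                                d_high = 0.9, d_low = 0.1, seed = 1,
                                n_triallelic = 0, drift_sd = 0.02,
                                target = "trossulus",
                                shared_beta = c(1.5, 1.5)) {
  if (n_diagnostic + n_triallelic > n_loci)
    stop("n_diagnostic + n_triallelic exceeds n_loci")
  if (!(d_low >= 0 && d_low < d_high && d_high <= 1))
    stop("need 0 <= d_low < d_high <= 1")
  taxa <- c("trossulus", "edulis", "galloprovincialis")
  if (!target %in% taxa) stop("unknown target taxon: ", target)
  set.seed(seed)
  loci <- sprintf("BM%03d", seq_len(n_loci))
  kind <- rep("shared", n_loci)
  kind[seq_len(n_diagnostic)] <- "diag"
  if (n_triallelic > 0)
    kind[n_diagnostic + seq_len(n_triallelic)] <- "tri"
  alleles <- vector("list", n_loci); names(alleles) <- loci
  freq <- lapply(taxa, function(t) stats::setNames(vector("list", n_loci), loci))
  names(freq) <- taxa
  characteristic <- character(0)
  nuc <- c("A", "C", "G", "T")
  clamp01 <- function(x) pmin(pmax(x, 0.001), 0.999)
  for (j in seq_len(n_loci)) {
    if (kind[j] == "tri") {
      al <- sort(sample(nuc, 3))
      g <- stats::rgamma(3, 2); p0 <- g / sum(g)
      for (t in taxa) {
        d <- clamp01(p0 + stats::rnorm(3, 0, drift_sd))
        freq[[t]][[j]] <- stats::setNames(d / sum(d), al)
      }
    } else {
      al <- sort(sample(nuc, 2))
      if (kind[j] == "diag") {
        # characteristic allele = first of the sorted pair, by convention
        p_t <- if (d_high >= 1) 1 else stats::runif(1, d_high, 1)
        for (t in taxa) {
          p <- if (t == target) p_t
               else if (d_low <= 0) 0 else stats::runif(1, 0, d_low)
          freq[[t]][[j]] <- stats::setNames(c(p, 1 - p), al)
        }
        characteristic[loci[j]] <- al[1]
      } else {
        p0 <- stats::rbeta(1, shared_beta[1], shared_beta[2])
        for (t in taxa) {
          p <- clamp01(p0 + stats::rnorm(1, 0, drift_sd))
          freq[[t]][[j]] <- stats::setNames(c(p, 1 - p), al)
        }
      }
    }
    alleles[[j]] <- al
  }
  structure(list(taxa = taxa, loci = loci, alleles = alleles, freq = freq,
                 diagnostic = loci[kind == "diag"],
                 characteristic = characteristic, target = target,
                 d_high = d_high, d_low = d_low),
            class = "taxon_profiles")
}

#' @export
print.taxon_profiles <- function(x, ...) {
  cat("taxon_profiles:", length(x$loci), "loci,",
      length(x$diagnostic), "diagnostic for", x$target, "\n")
  invisible(x)
}

#' Site and cline specifications for the study simulator
#'
#' `site_spec()` describes one sampled population: its genotypic composition
#' (a pure taxon, a bimodal hybrid-zone mixture of the six genotype classes,
#' or a unimodal hybrid swarm of admixed individuals), an inbreeding level
#' `f`, the site environment and the sample size.  `cline_spec()` describes
#' a logistic cline: the weight of the first taxon of `taxa` at a site is
#' `1 / (1 + exp((x - midpoint) / steepness))` of the driving variable `x`.
#'
#' @param code population code.
#' @param composition one of [comp_pure()], [comp_bimodal()],
#'   [comp_unimodal()].
#' @param n number of diploid individuals.
#' @param env named list/vector with the [env_variables] for this site.
#' @param region one of [region_levels].
#' @param f within-population inbreeding coefficient in `[0, 1)`.
#' @param latitude,longitude decimal degrees (kept as metadata only).
#' @export
site_spec <- function(code, composition, n, env, region, f = 0,
                      latitude = NA_real_, longitude = NA_real_) {
  if (f < 0 || f >= 1) stop("f must lie in [0, 1)")
  if (n < 1) stop("n_individuals must be >= 1")
  if (!region %in% region_levels)
    stop("region must be one of: ", paste(region_levels, collapse = "; "))
  miss <- setdiff(env_variables, names(env))
  if (length(miss)) stop("site env lacks: ", paste(miss, collapse = ", "))
  structure(list(code = code, composition = composition, n = as.integer(n),
                 env = unlist(env[env_variables]), region = region, f = f,
                 latitude = latitude, longitude = longitude),
            class = "site_spec")
}

#' @rdname site_spec
#' @param taxon taxon label of a pure site.
#' @export
comp_pure <- function(taxon)
  structure(list(type = "pure", taxon = taxon), class = "site_composition")

#' @rdname site_spec
#' @param p_A,p_B,p_F1,p_bc mixture weights of the two parental classes, F1
#'   hybrids and backcrosses (split equally between the two directions);
#'   must sum to 1.
#' @export
comp_bimodal <- function(p_A, p_B, p_F1, p_bc) {
  p <- c(p_A, p_B, p_F1, p_bc)
  if (abs(sum(p) - 1) > 1e-8) stop("composition probabilities must sum to 1")
  structure(list(type = "bimodal", p = p), class = "site_composition")
}

#' @rdname site_spec
#' @param mean_hi,sd_hi mean and s.d. of the individual ancestry fraction in
#'   a unimodal swarm.
#' @export
comp_unimodal <- function(mean_hi, sd_hi) {
  if (mean_hi < 0 || mean_hi > 1) stop("mean_hi must lie in [0, 1]")
  structure(list(type = "unimodal", mean = mean_hi, sd = sd_hi),
            class = "site_composition")
}

#' @rdname site_spec
#' @param variable driving environmental variable name.
#' @param midpoint cline midpoint on the variable's scale.
#' @param steepness logistic scale parameter (> 0); smaller is steeper.
#' @param taxa length-2 taxon pair; the first taxon has weight -> 1 below
#'   the midpoint.
#' @export
cline_spec <- function(variable = "salinity", midpoint = 9.5,
                       steepness = 0.68,
                       taxa = c("trossulus", "edulis")) {
  if (steepness <= 0) stop("steepness must be > 0")
  structure(list(variable = variable, midpoint = midpoint,
                 steepness = steepness, taxa = taxa), class = "cline_spec")
}

#' @rdname site_spec
#' @param cline a `cline_spec`.
#' @param x value(s) of the driving variable.
#' @return weight of the first taxon of `cline$taxa` at `x`.
#' @export
cline_weight <- function(cline, x)
  1 / (1 + exp((x - cline$midpoint) / cline$steepness))

# draw one allele per row from a frequency vector
.draw_alleles <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)

#' Draw one individual's multilocus genotype from a genotype class
#'
#' Samples a genotype row per locus from the expected genotype distribution
#' of a hybrid-zone class.  Pure-class individuals get a homozygote excess
#' through locus-wise autozygosity: with probability `f` the two gene copies
#' are identical by descent, giving P(homozygote for allele a) =
#' p(a)^2 + f p(a)(1 - p(a)).  F1 individuals take one gamete from each
#' parental frequency profile; F2 take both gametes from the pooled mean
#' profile; backcrosses take one parental and one pooled gamete.  Admixed
#' individuals (`class = "admixed"`, ancestry `q`) draw each gamete from the
#' q-mixture of the two parental profiles.
#'
#' @param class one of `"pure_trossulus"`, `"pure_edulis"`,
#'   `"pure_galloprovincialis"`, `"F1"`, `"F2"`, `"BC_trossulus"`,
#'   `"BC_edulis"`, `"admixed"`.
#' @param profiles a [make_taxon_profiles()] object.
#' @param f inbreeding coefficient for pure/admixed classes.
#' @param q ancestry fraction of the first parental taxon, for
#'   `class = "admixed"`.
#' @param parents length-2 character vector naming the hybridizing taxa.
#' @return list with character vectors `a1`, `a2` (one allele per locus).
#' @export
sample_individual <- function(class, profiles, f = 0, q = NA,
                              parents = c("trossulus", "edulis")) {
  if (f < 0 || f >= 1) stop("f must lie in [0, 1)")
  L <- length(profiles$loci)
  pA <- profiles$freq[[parents[1]]]
  pB <- profiles$freq[[parents[2]]]
  a1 <- a2 <- character(L)
  for (j in seq_len(L)) {
    mid <- (pA[[j]] + pB[[j]]) / 2
    if (class %in% c("pure_trossulus", "pure_edulis", "pure_galloprovincialis")) {
      taxon <- sub("^pure_", "", class)
      p <- profiles$freq[[taxon]][[j]]
      if (f > 0 && stats::runif(1) < f) {
        a1[j] <- a2[j] <- .draw_alleles(p, 1)
      } else {
        a1[j] <- .draw_alleles(p, 1); a2[j] <- .draw_alleles(p, 1)
      }
    } else if (class == "F1") {
      a1[j] <- .draw_alleles(pA[[j]], 1); a2[j] <- .draw_alleles(pB[[j]], 1)
    } else if (class == "F2") {
      a1[j] <- .draw_alleles(mid, 1); a2[j] <- .draw_alleles(mid, 1)
    } else if (class == "BC_trossulus") {
      a1[j] <- .draw_alleles(pA[[j]], 1); a2[j] <- .draw_alleles(mid, 1)
    } else if (class == "BC_edulis") {
      a1[j] <- .draw_alleles(pB[[j]], 1); a2[j] <- .draw_alleles(mid, 1)
    } else if (class == "admixed") {
      if (is.na(q)) stop("admixed class needs an ancestry fraction q")
      p <- q * pA[[j]] + (1 - q) * pB[[j]]
      if (f > 0 && stats::runif(1) < f) {
        a1[j] <- a2[j] <- .draw_alleles(p, 1)
      } else {
        a1[j] <- .draw_alleles(p, 1); a2[j] <- .draw_alleles(p, 1)
      }
    } else stop("unknown genotype class: ", class)
  }
  list(a1 = a1, a2 = a2)
}

#' Simulate a full multi-site study dataset
#'
#' Generates genotypes, locus annotation, environment table and a truth
#' record for a list of sites.  Each site gets its own derived random
#' substream, so adding a site does not perturb the others' draws under the
#' same master seed.
#'
#' @param sites list of [site_spec()] objects.
#' @param profiles a [make_taxon_profiles()] object.
#' @param clines list of [cline_spec()] objects (recorded in the truth
#'   record; site compositions are expected to have been built from them,
#'   see [default_scenario()]).
#' @param seed master seed.
#' @param missing_rate probability that any single call is missing.
#' @param parents the hybridizing taxon pair for mixture/swarm sites.
#' @return list of class `synthetic_study` with `gm` ([genotype_matrix()]),
#'   `annotation`, `env`, `sites`, and `truth` (data.frame with
#'   per-individual `class` and ancestry `q`, plus attributes `clines`,
#'   `profiles`, `site_weights`).
#' @export
generate_study <- function(sites, profiles, clines = list(), seed = 1,
                           missing_rate = 0.02,
                           parents = c("trossulus", "edulis")) {
  codes <- vapply(sites, `[[`, "", "code")
  if (anyDuplicated(codes)) stop("duplicate population codes: ",
                                 paste(codes[duplicated(codes)], collapse = ", "))
  set.seed(seed)
  site_seeds <- sample.int(2147483646L, length(sites))
  rows_a1 <- list(); rows_a2 <- list()
  ind <- character(0); popv <- character(0)
  cls <- character(0); qv <- numeric(0)
  bim_classes <- c("pure_A", "pure_B", "F1", "BC")
  for (s in seq_along(sites)) {
    st <- sites[[s]]
    set.seed(site_seeds[s])
    for (i in seq_len(st$n)) {
      comp <- st$composition
      if (comp$type == "pure") {
        cl <- paste0("pure_", comp$taxon); qq <- as.numeric(comp$taxon == parents[1])
        g <- sample_individual(cl, profiles, f = st$f, parents = parents)
      } else if (comp$type == "bimodal") {
        pick <- sample(bim_classes, 1, prob = comp$p)
        cl <- switch(pick,
                     pure_A = paste0("pure_", parents[1]),
                     pure_B = paste0("pure_", parents[2]),
                     F1 = "F1",
                     BC = sample(c(paste0("BC_", parents[1]),
                                   paste0("BC_", parents[2])), 1))
        qq <- if (cl %in% c("F1", "F2")) 0.5
              else if (cl == paste0("pure_", parents[1])) 1
              else if (cl == paste0("pure_", parents[2])) 0
              else if (cl == paste0("BC_", parents[1])) 0.75 else 0.25
        g <- sample_individual(cl, profiles, f = st$f, parents = parents)
      } else { # unimodal swarm
        m <- comp$mean; v <- comp$sd^2
        if (v > 0 && v < m * (1 - m)) {
          k <- m * (1 - m) / v - 1
          qq <- stats::rbeta(1, m * k, (1 - m) * k)
        } else qq <- min(max(stats::rnorm(1, m, comp$sd), 0), 1)
        cl <- "admixed"
        g <- sample_individual("admixed", profiles, f = st$f, q = qq,
                               parents = parents)
      }
      rows_a1[[length(rows_a1) + 1L]] <- g$a1
      rows_a2[[length(rows_a2) + 1L]] <- g$a2
      ind <- c(ind, sprintf("%s_%03d", st$code, i))
      popv <- c(popv, st$code)
      cls <- c(cls, cl); qv <- c(qv, qq)
    }
  }
  a1 <- do.call(rbind, rows_a1); a2 <- do.call(rbind, rows_a2)
  dimnames(a1) <- dimnames(a2) <- list(ind, profiles$loci)
  if (missing_rate > 0) {
    set.seed(site_seeds[1] %% 1000003L + 7L)
    m <- matrix(stats::runif(length(a1)) < missing_rate, nrow(a1))
    a1[m] <- NA_character_; a2[m] <- NA_character_
  }
  gm <- genotype_matrix(a1, a2, pop = popv, alleles = profiles$alleles)

  nall <- vapply(profiles$alleles, length, integer(1))
  set.seed(site_seeds[length(site_seeds)] %% 1000033L + 11L)
  coding <- stats::runif(length(profiles$loci)) < 0.9
  ann <- locus_annotation(
    locus = profiles$loci,
    alleles = vapply(profiles$alleles, paste, "", collapse = ","),
    region_class = ifelse(coding, "coding", "non-coding"),
    synonymy = ifelse(coding,
                      ifelse(stats::runif(length(coding)) < 0.08,
                             "non-synonymous", "synonymous"), "n.a."),
    diagnostic_for = ifelse(profiles$loci %in% profiles$diagnostic,
                            profiles$target, NA_character_),
    characteristic_allele = ifelse(profiles$loci %in% profiles$diagnostic,
                                   profiles$characteristic[profiles$loci],
                                   NA_character_))

  envm <- t(vapply(sites, `[[`, numeric(length(env_variables)), "env"))
  env <- do.call(env_table, c(list(population = codes),
                              as.list(as.data.frame(envm)),
                              list(region = vapply(sites, `[[`, "", "region"))))

  w <- if (length(clines))
    vapply(sites, function(st)
      cline_weight(clines[[1]], st$env[[clines[[1]]$variable]]), 0)
  else rep(NA_real_, length(sites))
  truth <- data.frame(individual = ind, population = popv, class = cls,
                      q = qv, stringsAsFactors = FALSE)
  attr(truth, "clines") <- clines
  attr(truth, "site_weights") <- stats::setNames(w, codes)
  attr(truth, "f") <- stats::setNames(vapply(sites, `[[`, 0, "f"), codes)
  structure(list(gm = gm, annotation = ann, env = env, sites = sites,
                 truth = truth, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", length(x$sites), "sites, seed", x$seed, "\n")
  print(x$gm)
  invisible(x)
}

#' The default hybrid-zone study scenario
#'
#' Twelve sites of 30 diploid individuals spanning salinity 5-35 psu, with a
#' trossulus/edulis logistic cline (midpoint 9.5 psu, scale 0.68, i.e. the
#' 10%-90% transition falls inside 8-11 psu) driving site composition:
#' low-salinity unimodal hybrid swarms (Baltic-like), two mid-salinity
#' hybrid-zone sites (one parental-dominated bimodal mixture, one matched
#' unimodal swarm), fully marine pure Mytilus edulis sites with inbreeding
#' levels up to 0.6, one pure M. trossulus and one pure
#' M. galloprovincialis site.  The site environment carries all twelve
#' variables; water temperature and sea-ice concentration are constructed
#' with a sample correlation of exactly -0.87, the remaining variables are
#' weak noise.  The SNP panel has 54 loci of which 16 are fixed diagnostic
#' for M. trossulus and 2 are triallelic.
#'
#' @param seed master seed.
#' @param n_per_site individuals per site.
#' @param d_high,d_low diagnostic-panel frequency thresholds used to build
#'   the taxon profiles (defaults give fixed diagnostic loci).
#' @return list with `sites`, `clines`, `profiles` ready for
#'   [generate_study()].
#' @export
default_scenario <- function(seed = 1, n_per_site = 30,
                             d_high = 1, d_low = 0) {
  profiles <- make_taxon_profiles(n_loci = 54, n_diagnostic = 16,
                                  d_high = d_high, d_low = d_low,
                                  seed = seed, n_triallelic = 2)
  cl <- cline_spec("salinity", midpoint = 9.5, steepness = 0.68,
                   taxa = c("trossulus", "edulis"))
  sal <- c(5, 6.5, 8, 9.5, 9.5, 11, 13, 18, 24, 30, 6, 35)
  codes <- c("BAL1", "BAL2", "BAL3", "SWRM", "BIMO", "TRNS",
             "EDU1", "EDU2", "EDU3", "EDU4", "TRO1", "GAL1")
  region <- c(rep("Baltic Sea", 4), rep("North Atlantic Ocean", 6),
              "Barents Sea", "Mediterranean and Black Seas")
  f <- c(0.05, 0.05, 0.05, 0.05, 0.5, 0.2, 0, 0.2, 0, 0.5, 0.6, 0)
  env <- .scenario_env(sal, seed)
  sites <- vector("list", length(sal))
  for (i in seq_along(sal)) {
    w <- cline_weight(cl, sal[i])
    comp <- switch(codes[i],
      SWRM = comp_unimodal(0.5, 0.08),
      BIMO = comp_bimodal(0.48, 0.44, 0.04, 0.04),
      TRNS = comp_bimodal(0.06, 0.82, 0.06, 0.06),
      EDU1 = , EDU2 = , EDU3 = , EDU4 = comp_pure("edulis"),
      TRO1 = comp_pure("trossulus"),
      GAL1 = comp_pure("galloprovincialis"),
      comp_unimodal(w, 0.08))
    sites[[i]] <- site_spec(codes[i], comp, n = n_per_site,
                            env = env[i, ], region = region[i], f = f[i])
  }
  list(sites = sites, clines = list(cl), profiles = profiles)
}

# site environments: salinity as given; temperature/ice built with sample
# correlation exactly -0.87 by Gram-Schmidt; other variables weak noise
.scenario_env <- function(salinity, seed) {
  n <- length(salinity)
  set.seed(seed + 104729L)
  temp <- stats::runif(n, 0, 20)
  z <- stats::rnorm(n)
  ts <- scale(temp)[, 1]
  e <- stats::residuals(stats::lm(z ~ ts)); e <- e / sqrt(mean(e^2))
  ice_z <- -0.87 * ts / sqrt(mean(ts^2)) + sqrt(1 - 0.87^2) * e
  ice <- 40 + 15 * ice_z
  ice <- (ice - min(ice)) / (max(ice) - min(ice)) * 90  # affine -> [0, 90]
  env <- cbind(ice_conc = ice,
               cloud = stats::runif(n, 40, 90),
               wind = stats::runif(n, 2, 12),
               solar = stats::runif(n, 5000, 20000),
               precip = stats::runif(n, 300, 1200),
               temperature = temp,
               salinity = salinity,
               swell = stats::runif(n, 0.2, 3),
               tide = stats::runif(n, 10, 300),
               chl_a = stats::runif(n, 0.5, 8),
               nitrates = stats::runif(n, 1, 12),
               phosphates = stats::runif(n, 0.1, 2))
  env
}
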