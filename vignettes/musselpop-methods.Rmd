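---
title: "Methods: population structure, hybrid detection and environmental association in musselpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure, hybrid detection and environmental association in musselpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`musselpop` analyses diploid SNP genotypes from population samples of the
blue mussel species complex — *Mytilus edulis*, *M. trossulus* and
*M. galloprovincialis* — three incompletely isolated taxa that hybridize
wherever they meet. The package covers the full chain from genotype tables
to (i) within-population diversity and Hardy–Weinberg testing, (ii)
between-population differentiation, (iii) hybrid detection and
classification, and (iv) association of allele frequencies with local
environmental gradients. This vignette records the statistical models, the
defaults and why they were chosen, and the places where a genuine design
choice had to be made.

## Data model

Genotypes are unordered allele pairs: the container normalizes every call
to a sorted pair, so `"CA"` and `"AC"` are the same genotype and no gametic
phase is ever implied. This matters downstream — the linkage test is
explicitly phase-free, and double heterozygotes are never resolved into
haplotypes. Loci carry 2 or 3 alleles (SNPs from assay panels are mostly
biallelic, occasionally triallelic); missing calls are first-class and
propagate through every statistic by shrinking the relevant denominator,
never by imputation.

Genepop files are read with a declared allele-code table (default
`01→A, 02→C, 03→G, 04→T`) because the numeric Genepop dialect has no
intrinsic nucleotide semantics; population codes come from the last
individual ID of each `POP` block, the common field convention.

## Diversity statistics

Per locus and population the package reports observed heterozygosity
$H_O$, Nei's unbiased expected heterozygosity
$H_E = \frac{2n}{2n-1}\bigl(1-\sum_i p_i^2\bigr)$, minor allele frequency,
and $F_{IS} = 1 - H_O/H_E$ (undefined at monomorphic loci). A population
consisting of the two alternative homozygote classes with no heterozygotes
gives $F_{IS} = 1$ exactly. Two aggregation choices are deliberate:

* **Polymorphism** means at least two alleles observed in the sample, with
  no MAF floor, so `Po` is the plain percentage of segregating loci.
* **Multilocus $F_{IS}$** is a ratio of averages,
  $1 - \sum_\ell H_O^{(\ell)} / \sum_\ell H_E^{(\ell)}$, over polymorphic
  loci. Averaging per-locus ratios would let near-monomorphic loci (tiny
  $H_E$ denominators) dominate; the ratio-of-averages form is stable.
* Mean $H_O$/$H_E$ are reported both over polymorphic loci (the default
  displayed columns) and over all loci (`*_all`), since diversity tables in
  the literature are ambiguous on this point; *average gene diversity* is
  always over all loci, monomorphic ones contributing zero, so the two
  columns answer different questions.

Significance of heterozygote deficits uses a one-sided permutation test:
the $2n$ observed gene copies are re-paired at random, which is exactly the
null of random union of gametes within the sample.

**Hardy–Weinberg testing.** Biallelic loci always use the exact conditional
test: given the allele counts, all heterozygote counts of matching parity
are enumerated with probability
$P(n_{Aa}\mid n, n_A) = \frac{n!\,n_A!\,n_a!\,2^{n_{Aa}}}{n_{AA}!\,n_{Aa}!\,n_{aa}!\,(2n)!}$
and the p-value sums configurations no more probable than the observed one.
Enumeration is cheap at any realistic sample size, so nothing is
approximated in the biallelic case. Triallelic loci use a Monte Carlo
version of the same conditional test: rather than running a Markov chain
over tables, the observed gene copies are re-paired into genotypes
repeatedly — each draw is an *independent* sample from the conditional null
— and the p-value is the smoothed fraction of tables with conditional
probability at most the observed one. This is unbiased, needs no burn-in
or mixing diagnostics, and agrees with the exact test within Monte Carlo
error on biallelic input (a property the test suite asserts).

Multiple testing uses Benjamini–Yekutieli, valid under arbitrary
dependence among loci; its rejections are always a subset of
Benjamini–Hochberg rejections at the same level. Note that because the
exact HWE test is discrete, its realized level is strictly below the
nominal $\alpha$; the calibration test therefore checks that the rejection
rate does not *exceed* nominal rather than that it equals it.

## Differentiation

$F_{ST}$ is the Weir–Cockerham (1984) variance-component estimator
$\hat\theta = a/(a+b+c)$, summed over alleles, with the multilocus value a
ratio of summed components. Loci monomorphic across all populations
contribute zero components (their per-locus value is `NA`); negative
estimates are reported as computed and clamped to zero only when the
matrix is used as a distance (neighbour joining). The test suite checks
$\hat\theta$ against an independent ANOVA sums-of-squares implementation on
exhaustive small cases. Pairwise p-values permute individuals between the
two samples.

The outlier scan simulates the neutral $F_{ST}$ distribution under a
symmetric island model calibrated to the observed multilocus value:
ancestral frequencies uniform, deme frequencies Balding–Nichols
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, binomial
genotype sampling at the observed sample sizes, 50 demes with 2 sampled by
default (configurable). Simulated loci are binned by pooled heterozygosity
(an adaptive window that widens until it holds at least 200 simulated
loci) and each observed locus is flagged outside its bin's
$(\alpha/2,\,1-\alpha/2)$ envelope.

Genotypic linkage disequilibrium is a G statistic on the two-locus
genotype contingency table with a permutation null (one locus's genotypes
shuffled across individuals). Scanning $L$ polymorphic loci tests
$L(L-1)/2$ pairs — 2145 for $L = 66$.

Neighbour joining is delegated to `ape::nj` (a standard, deterministic
implementation that recovers additive matrices exactly); correspondence
analysis is the chi-square-standardized SVD of the allele-count table, with
row principal coordinates and per-axis inertia percentages summing to 100.

## Hybrid detection

A diagnostic panel is selected from declared reference samples: loci where
some allele has frequency at least `d_high` (default 0.9) in the target
taxon and at most `d_low` in each other taxon. The usual field phrasing
("high frequency in pure *M. trossulus*, rare elsewhere") does not pin the
lower threshold, so `d_low = 0.2` is the package default and both
thresholds are exposed.

The hybrid index of an individual is the fraction of characteristic-allele
copies over its scored panel loci, $HI = \text{copies}/(2\,L_\text{scored})$:
1 is pure target taxon, 0 pure alternative, 0.5 a first-generation hybrid.
Missing panel loci shrink the denominator rather than being imputed — with
near-fixed panels the per-locus expectation is homogeneous, so shrinking is
unbiased and keeps every genotyped locus informative. Population summaries
report mean $HI$ and its variance $V_{HI}$ (denominator $n-1$): bimodal
hybrid zones (parental genotypes coexisting) show high $V_{HI}$ at
intermediate means, unimodal hybrid swarms low $V_{HI}$.

Six-category assignment (two pure parentals, F1, F2, two backcrosses) uses
a plug-in empirical-Bayes posterior: parental allele frequencies are
estimated from the reference samples with add-one Dirichlet smoothing, each
class has a closed-form per-locus genotype distribution (Hardy–Weinberg at
the parental frequency; one gamete from each parent for F1; Hardy–Weinberg
at the pooled mean for F2; one parental and one pooled gamete for
backcrosses), and the posterior is the normalized product over loci under a
uniform prior. This replaces a full Bayesian treatment that integrates
over latent parental frequencies; with a near-fixed 16-locus panel the
likelihood is so concentrated that the plug-in approximation is excellent
(the smoothing constant guards the zero-probability genotypes). The
assignment defaults to the diagnostic panel, matching how such panels are
used in practice; an all-loci option exists.

Supervised ancestry fractions maximize the mixture likelihood
$\prod_\text{copies} \sum_k q_k\, p_k(\text{allele})$ over the simplex by
EM (converged at $\max|\Delta q| < 10^{-8}$ or 5000 iterations). This is a
reference-conditioned analogue of admixture clustering: unsupervised runs,
$K$ selection and their q-matrices are treated as external inputs, not
recomputed. Classification follows the 0.2/0.8 convention: resident above
0.8, migrant below 0.2, potentially admixed between.

## Boosted regression trees

The environment–genetics link uses an in-package gradient-boosting
learner for Bernoulli (two alleles) and multinomial (three alleles)
responses. Design:

* **Response encoding.** Each allele *copy* is one observation (two per
  genotyped individual), since the object being modelled is an allele
  frequency; an individual-level encoding is possible by passing dosages
  directly to `fit_brt`.
* **Base learner.** Depth-limited least-squares regression trees on the
  negative gradient $y - p$ (per class with softmax parameterization for
  the multinomial loss), fitted on a random half of the rows
  (`bag_fraction = 0.5`) and shrunk by `learning_rate = 0.01`. Categorical
  predictors (the region factor) split by subset, found with the
  ordered-mean heuristic that is exact for a single split on squared error.
* **Defaults.** `tree_depth = 2` allows pairwise interactions without
  inviting deep, data-hungry trees on site-level predictors;
  `max_trees = 20000` with 10-fold cross-validated selection of the
  optimum by held-out deviance, warning below the 1000-tree rule of thumb
  or at the cap. Folds are stratified by population so each fold sees
  every site — predictors are population-level constants, and a fold
  holding out an entire site would confound site identity with the
  held-out error.
* **Assessment.** The adjusted count pseudo-$R^2$ is
  $1 - \mathrm{err}_M/\mathrm{err}_0$: cross-validated misclassification
  of the model against that of the intercept-only (majority-class)
  predictor, with class predictions by maximal class probability
  (lowest-index tie-break, so e.g. probabilities 0.3/0.36/0.34 over
  A/C/T predict C).
* **Interpretation.** Relative influence sums each predictor's
  squared-error split improvements (over classes for multinomial),
  normalized to 100%. Partial dependence forces one predictor to a grid
  value in every training row and averages the predicted probability.

The inner loops (split search, staged prediction, staged held-out
deviance) are in C++, as is usual for boosting implementations; all
randomness flows through R's RNG so `set.seed` makes every fit
reproducible.

**Abrupt transitions.** "Change concentrated in a narrow range" is
operationalized as the shortest grid interval containing at least 80% of a
partial-dependence curve's total variation. A step function collapses to
one grid cell; a linear ramp yields an interval spanning ~80% of the
domain, which is the correct "no abrupt transition" answer.

**Group comparison.** Per-locus influence profiles (the untransformed BRT
results) are compared between coding and non-coding loci via Bray–Curtis
dissimilarity, ANOSIM ($R$ scaled by $M/2$ with rank ties averaged;
permutation p, or exact enumeration of label arrangements for small
problems) and SIMPER (per-variable contributions that sum exactly to the
mean between-group dissimilarity).

## The synthetic-data generator

No genotype data ship with the package, so every downstream stage is
validated on a simulator whose defaults encode the study design the
package targets:

* 54 SNPs, 16 of them diagnostic for *M. trossulus* (characteristic-allele
  frequency at the fixation end of the 90–100% convention in the target
  taxon, absent elsewhere), 2 triallelic, the rest sharing ancestral
  polymorphism across taxa (Beta(1.5, 1.5) frequencies with s.d. 0.02
  per-taxon drift);
* 12 sites × 30 diploid individuals spanning salinity 5–35 psu with a
  trossulus/edulis logistic cline of midpoint 9.5 psu and scale 0.68 psu,
  placing the 10%→90% transition inside 8–11 psu — the brackish-to-marine
  transition zone where such clines are observed;
* site compositions along the cline: low-salinity unimodal hybrid swarms
  (Baltic-like), a parental-dominated bimodal mixture
  (0.48/0.44/0.04/0.04 over parental/parental/F1/backcross — bimodal
  zones consist mostly of parental-like genotypes) and a matched unimodal
  swarm at the cline centre, pure marine *M. edulis* sites with
  inbreeding $f$ from 0 to 0.5, one pure *M. trossulus* site ($f = 0.6$,
  the upper end of reported heterozygote deficits) and one
  *M. galloprovincialis* site;
* inbreeding by locus-wise autozygosity,
  $P(\text{hom }a) = p_a^2 + f\,p_a(1-p_a)$;
* twelve environmental variables in their field units, with water
  temperature and sea-ice concentration constructed (by Gram–Schmidt) to a
  sample correlation of exactly −0.87 so the collinearity screen has a
  known strong pair, and the remaining variables weak noise;
* 2% uniformly missing calls; per-site random substreams derived from one
  master seed.

What the generator does **not** emulate: linkage between loci, coalescent
ancestry and within-taxon isolation by distance, selection at individual
loci beyond the cline-driven taxon turnover, genotyping artefacts
(allele dropout, batch effects), and spatial autocorrelation of the noise
environmental variables. Passing parameter-recovery tests therefore shows
the estimators are correct under the stated sampling model, not that real
data meet that model.

## Problem sizes in the tests

The test-suite and acceptance runs use the 12×30×54 default scenario; the
per-locus boosting checks model a representative subset of loci
(cline-driven, neutral and triallelic) with the default 0.01 learning rate
and a 1500–2500 tree cap, sizes at which the cross-validation curves of
the simulated loci have already flattened. Permutation and Monte Carlo
checks use 99–2000 replicates with fixed seeds; exhaustive oracles
(Hardy–Weinberg enumeration, variance-component identity, ANOSIM
enumeration) run at the small sample sizes where enumeration is exact.

## Known limitations

* The six-class model assumes exactly two hybridizing parental taxa;
  three-way hybrids are outside its hypothesis space (the third taxon is
  handled by exclusion, as in practice).
* The plug-in class posterior understates uncertainty when reference
  samples are small; the Dirichlet smoothing constant is exposed but the
  full hierarchical treatment is out of scope.
* The island-model outlier scan is a calibration device, not a
  demographic fit: envelopes are honest under the symmetric model only.
* Influence percentages from boosted trees split credit between collinear
  predictors (the duplicated-column property test quantifies this); the
  collinearity screen exists precisely so users see which pairs share
  credit.
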