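#' Run the full analysis pipeline from a configuration
#'
#' Executes validate -> diversity -> differentiation -> hybrids ->
#' environment association on either a simulated scenario or files named in
#' the configuration, writing TSV/JSON/Newick artifacts and a run log to
#' the output directory.  Reruns with the same seed produce identical
#' outputs.
#'
#' @param config a YAML file path or an equivalent named list.  Recognized
#'   fields: `seed`; `output_dir`; `stages` (subset of `validate`,
#'   `diversity`, `differentiation`, `hybrids`, `envassoc`); `simulate`
#'   (list passed to [default_scenario()]: `n_per_site`, ...) or `inputs`
#'   (`genotypes_csv` or `genepop`, `annotation`, `env`); `differentiation`
#'   (`n_perm`, `outlier_n_sim`); `hybrids` (`ref_pops`: named list of
#'   reference populations per taxon); `envassoc` (`max_trees`,
#'   `learning_rate`, `cv_folds`, `loci`, `anosim_n_perm`).
#' @return invisible list with the stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir %||% "musselpop_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||%
    c("validate", "diversity", "differentiation", "hybrids", "envassoc")
  log <- data.frame(stage = character(0), seconds = numeric(0))
  tick <- function(stage, t0)
    rbind(log, data.frame(stage = stage, seconds = round(as.numeric(
      difftime(Sys.time(), t0, units = "secs")), 2)))
  res <- list(seed = seed)

  t0 <- Sys.time()
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    gm <- if (!is.null(inp$genotypes_csv)) read_csv_genotypes(inp$genotypes_csv)
          else if (!is.null(inp$genepop)) read_genepop(inp$genepop)
          else stop("config field 'inputs' needs 'genotypes_csv' or 'genepop'")
    ann <- if (!is.null(inp$annotation)) read_locus_annotation(inp$annotation) else NULL
    env <- if (!is.null(inp$env)) read_env_table(inp$env) else NULL
    truth <- NULL
    if ("envassoc" %in% stages && is.null(env))
      stop("config field 'inputs$env' is required when the envassoc stage is enabled")
  } else {
    sim_cfg <- config$simulate %||% list()
    scen <- default_scenario(seed = seed,
                             n_per_site = sim_cfg$n_per_site %||% 30)
    study <- generate_study(scen$sites, scen$profiles, scen$clines,
                            seed = seed)
    gm <- study$gm; ann <- study$annotation; env <- study$env
    truth <- study$truth
    write_csv_genotypes(gm, file.path(out_dir, "genotypes.csv"))
    write_locus_annotation(ann, file.path(out_dir, "annotation.tsv"))
    write_env_table(env, file.path(out_dir, "environment.tsv"))
  }
  res$gm <- gm; res$annotation <- ann; res$env <- env; res$truth <- truth
  log <- tick("load", t0)

  if ("validate" %in% stages) {
    t0 <- Sys.time()
    res$validation <- validate_dataset(gm, ann, env)
    if (!res$validation$pass)
      stop("validate stage failed:\n",
           paste(res$validation$issues$message, collapse = "\n"))
    log <- tick("validate", t0)
  }
  if ("diversity" %in% stages) {
    t0 <- Sys.time()
    res$diversity <- population_summary(gm)
    utils::write.table(res$diversity, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log <- tick("diversity", t0)
  }
  if ("differentiation" %in% stages) {
    t0 <- Sys.time()
    dcfg <- config$differentiation %||% list()
    res$fst <- pairwise_fst(gm, n_perm = dcfg$n_perm %||% 0, seed = seed)
    utils::write.table(res$fst$fst, file.path(out_dir, "fst.tsv"),
                       sep = "\t", quote = FALSE)
    res$tree <- nj_tree(res$fst)
    writeLines(res$tree$newick, file.path(out_dir, "tree.nwk"))
    res$ca <- correspondence_analysis(gm, by = "population")
    utils::write.table(cbind(res$ca$row_coords[, 1:2, drop = FALSE]),
                       file.path(out_dir, "ca_coords.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(dcfg$outlier_n_sim)) {
      res$outliers <- fst_outlier_scan(gm, n_sim = dcfg$outlier_n_sim,
                                       seed = seed)
      utils::write.table(res$outliers, file.path(out_dir, "outliers.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    log <- tick("differentiation", t0)
  }
  if ("hybrids" %in% stages) {
    t0 <- Sys.time()
    hcfg <- config$hybrids %||% list()
    refs <- hcfg$ref_pops %||% .default_refs(gm)
    res$panel <- select_diagnostic_panel(gm, refs, target = names(refs)[1])
    res$hi <- hybrid_index(gm, res$panel)
    utils::write.table(res$hi$populations, file.path(out_dir, "hybrid_index.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    res$classes <- assign_hybrid_classes(gm, res$panel,
                                         refA = refs[[1]], refB = refs[[2]])
    utils::write.table(res$classes$population_table,
                       file.path(out_dir, "hybrid_classes.tsv"),
                       sep = "\t", quote = FALSE)
    res$ancestry <- supervised_ancestry(gm, refs = refs[1:2])
    log <- tick("hybrids", t0)
  }
  if ("envassoc" %in% stages) {
    t0 <- Sys.time()
    ecfg <- config$envassoc %||% list()
    res$collinearity <- suppressWarnings(collinearity_screen(env))
    cfg <- brt_config(learning_rate = ecfg$learning_rate %||% 0.01,
                      max_trees = ecfg$max_trees %||% 2000,
                      cv_folds = ecfg$cv_folds %||% 10,
                      seed = seed)
    loci <- ecfg$loci %||% gm$loci
    res$locus_models <- suppressWarnings(
      per_locus_models(gm, env, config = cfg, loci = loci))
    utils::write.table(res$locus_models$summary,
                       file.path(out_dir, "locus_models.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(ann) && length(unique(
          ann$region_class[match(res$locus_models$summary$locus, ann$locus)])) > 1) {
      res$group_comparison <- compare_region_class(
        res$locus_models, ann, n_perm = ecfg$anosim_n_perm %||% 999,
        seed = seed)
    }
    jsonlite::write_json(
      list(seed = seed,
           pseudo_r2 = stats::setNames(as.list(res$locus_models$summary$pseudo_r2),
                                       res$locus_models$summary$locus),
           frac_r2_gt_0.4 = res$locus_models$frac_r2_gt_0.4,
           frac_r2_lt_0.1 = res$locus_models$frac_r2_lt_0.1,
           max_region_influence = res$locus_models$max_region_influence,
           anosim = if (!is.null(res$group_comparison))
             list(R = res$group_comparison$anosim$R,
                  p = res$group_comparison$anosim$p)),
      file.path(out_dir, "envassoc.json"), auto_unbox = TRUE, digits = NA)
    log <- tick("envassoc", t0)
  }
  log$seed <- seed
  utils::write.table(log, file.path(out_dir, "run_log.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(res)
}

# reference populations guessed from a simulated-study naming convention
.default_refs <- function(gm) {
  pops <- populations(gm)
  refs <- list(trossulus = grep("^TRO", pops, value = TRUE),
               edulis = grep("^EDU", pops, value = TRUE),
               galloprovincialis = grep("^GAL", pops, value = TRUE))
  refs <- refs[lengths(refs) > 0]
  if (length(refs) < 2L)
    stop("cannot infer reference populations; supply hybrids$ref_pops")
  refs
}
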