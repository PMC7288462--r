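#' @useDynLib musselpop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Environmental variable names and region levels
#'
#' The twelve site-level environmental variables carried by an environment
#' table, in fixed column order, and the fixed set of region levels.
#' Units: sea-ice concentration (%), cloud amount (%), wind speed (m/s),
#' solar radiation (kJ m-2 day-1), precipitation (mm), water temperature
#' (degrees C), salinity (psu), swell height (m), tide height (cm),
#' chlorophyll-a (mg m-3), nitrates (umol/L), phosphates (umol/L).
#' @export
env_variables <- c("ice_conc", "cloud", "wind", "solar", "precip",
                   "temperature", "salinity", "swell", "tide",
                   "chl_a", "nitrates", "phosphates")

#' @rdname env_variables
#' @export
region_levels <- c("North Atlantic Ocean", "Baltic Sea", "Barents Sea",
                   "Mediterranean and Black Seas")

# default Genepop allele code table
.default_code_table <- c("01" = "A", "02" = "C", "03" = "G", "04" = "T")

#' Read a Genepop genotype file
#'
#' Parses the classic Genepop dialect: a title line, locus names (one per
#' line or comma-separated on one line), `POP` separators, and individual
#' lines `id , 0101 0102 ...` with 2- or 3-digit allele codes where
#' `00`/`000` means missing.  Numeric allele codes are mapped to nucleotide
#' symbols through `code_table`; population codes are taken from the last
#' individual ID of each POP block unless `pop_codes` supplies one code per
#' block.
#'
#' @param path file path.
#' @param code_table named character vector mapping 2-digit codes to allele
#'   symbols (3-digit codes are matched through their last two digits).
#' @param pop_codes optional character vector, one population code per POP
#'   block, overriding the last-individual convention.
#' @return a [genotype_matrix()].
#' @export
read_genepop <- function(path, code_table = .default_code_table,
                         pop_codes = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a Genepop file: fewer than 3 lines")
  lines <- trimws(lines)
  body <- lines[-1L]
  is_pop <- toupper(body) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("not a Genepop file: no POP separator")
  loc_lines <- body[seq_len(first_pop - 1L)]
  loc_lines <- loc_lines[nzchar(loc_lines)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) < 1L) stop("no locus names before first POP")

  blocks <- cumsum(is_pop)
  ind_lines <- which(!is_pop & nzchar(body) & blocks > 0L)
  ids <- character(0); pops <- integer(0)
  a1 <- a2 <- NULL
  rows_a1 <- list(); rows_a2 <- list()
  for (k in ind_lines) {
    ln <- body[k]
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L)
      stop("malformed individual line (no comma) at line ", k + 1L, ": ", ln)
    id <- trimws(parts[1L])
    geno <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "[[:space:]]+")[[1L]]
    geno <- geno[nzchar(geno)]
    if (length(geno) != length(loci))
      stop("line ", k + 1L, " ('", id, "'): ", length(geno),
           " genotype fields for ", length(loci), " declared loci")
    w <- nchar(geno)
    if (!all(w %in% c(4L, 6L)))
      stop("line ", k + 1L, ": allele fields must be 4 or 6 digits")
    half <- w %/% 2L
    c1 <- substr(geno, 1L, half)
    c2 <- substr(geno, half + 1L, w)
    dec <- function(code) {
      out <- rep(NA_character_, length(code))
      zero <- code %in% c("00", "000")
      code2 <- sprintf("%02d", suppressWarnings(as.integer(code)))
      hit <- code_table[code2]
      bad <- !zero & is.na(hit)
      if (any(bad))
        stop("unknown allele code '", code[bad][1L], "' at line ", k + 1L)
      out[!zero] <- hit[!zero]
      out
    }
    rows_a1[[length(rows_a1) + 1L]] <- dec(c1)
    rows_a2[[length(rows_a2) + 1L]] <- dec(c2)
    ids <- c(ids, id)
    pops <- c(pops, blocks[k])
  }
  a1 <- do.call(rbind, rows_a1); a2 <- do.call(rbind, rows_a2)
  # half-missing calls treated as fully missing
  m <- is.na(a1) | is.na(a2)
  a1[m] <- NA_character_; a2[m] <- NA_character_
  n_blocks <- max(pops)
  if (is.null(pop_codes)) {
    pop_codes <- vapply(seq_len(n_blocks), function(b) ids[max(which(pops == b))], "")
  } else if (length(pop_codes) != n_blocks) {
    stop("pop_codes must have one entry per POP block (", n_blocks, ")")
  }
  ids <- make.unique(ids)
  dimnames(a1) <- list(ids, loci)
  genotype_matrix(a1, a2, pop = pop_codes[pops])
}

#' Write a genotype matrix in Genepop format
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param code_table symbol-to-code mapping (inverse of the read mapping).
#' @param title first line of the file.
#' @export
write_genepop <- function(gm, path, code_table = .default_code_table,
                          title = "musselpop export") {
  inv <- stats::setNames(names(code_table), code_table)
  enc <- function(x) ifelse(is.na(x), "00", inv[x])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(gm$loci, con)
  for (p in levels(gm$pop)) {
    writeLines("POP", con)
    rows <- which(gm$pop == p)
    # keep the population code recoverable: last individual carries the code
    ids <- gm$ind[rows]
    ids[length(ids)] <- p
    for (i in seq_along(rows)) {
      r <- rows[i]
      g <- paste0(enc(gm$a1[r, ]), enc(gm$a2[r, ]))
      writeLines(paste0(ids[i], " ,  ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read/write the wide-CSV genotype dialect
#'
#' A wide CSV with columns `individual`, `population`, then one column per
#' locus holding two-letter calls such as `"AC"`; `"--"` (or empty) marks a
#' missing call.  The pair is unordered: `"CA"` and `"AC"` are the same
#' genotype.  `write_csv_genotypes()` and `read_csv_genotypes()` round-trip
#' bit-exactly.
#'
#' @param path file path.
#' @return a [genotype_matrix()].
#' @export
read_csv_genotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3L || !all(c("individual", "population") %in% names(df)[1:2]))
    stop("expected columns: individual, population, then loci")
  loci <- names(df)[-(1:2)]
  calls <- as.matrix(df[, loci, drop = FALSE])
  calls[calls %in% c("--", "", "NA")] <- NA_character_
  bad_len <- !is.na(calls) & nchar(calls) != 2L
  if (any(bad_len))
    stop("calls must be two-letter strings; offending value: ",
         calls[bad_len][1L])
  a1 <- substr(calls, 1L, 1L); a2 <- substr(calls, 2L, 2L)
  dim(a1) <- dim(a2) <- dim(calls)
  dimnames(a1) <- list(df$individual, loci)
  for (j in seq_along(loci)) {
    sym <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(sym) > 3L)
      stop("locus ", loci[j], " has ", length(sym), " allele symbols: ",
           paste(sym, collapse = ", "))
  }
  genotype_matrix(a1, a2, pop = df$population)
}

#' @rdname read_csv_genotypes
#' @param gm a [genotype_matrix()].
#' @export
write_csv_genotypes <- function(gm, path) {
  calls <- genotype_calls(gm)
  calls[is.na(calls)] <- "--"
  df <- data.frame(individual = gm$ind, population = as.character(gm$pop),
                   calls, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Locus annotation table
#'
#' Per-locus metadata: declared alleles, coding/non-coding status, synonymy
#' and optional diagnostic flags (which taxon the locus is diagnostic for
#' and which allele is characteristic of that taxon).
#'
#' @param locus character locus IDs.
#' @param alleles list or comma-joined strings of allele symbols (2 or 3).
#' @param region_class `"coding"` or `"non-coding"`.
#' @param synonymy `"synonymous"`, `"non-synonymous"` or `"n.a."`.
#' @param diagnostic_for optional taxon label per locus (`NA` if none).
#' @param characteristic_allele allele symbol, required iff `diagnostic_for`
#'   is set.
#' @return a `data.frame` of class `locus_annotation`.
#' @export
locus_annotation <- function(locus, alleles, region_class, synonymy,
                             diagnostic_for = NA_character_,
                             characteristic_allele = NA_character_) {
  if (is.list(alleles)) alleles <- vapply(alleles, paste, "", collapse = ",")
  nall <- lengths(strsplit(alleles, ","))
  if (!all(nall %in% c(2L, 3L)))
    stop("each locus must declare 2 or 3 alleles")
  region_class <- match.arg(region_class, c("coding", "non-coding"),
                            several.ok = TRUE)
  synonymy <- match.arg(synonymy, c("synonymous", "non-synonymous", "n.a."),
                        several.ok = TRUE)
  df <- data.frame(locus = locus, alleles = alleles,
                   region_class = region_class, synonymy = synonymy,
                   diagnostic_for = diagnostic_for,
                   characteristic_allele = characteristic_allele,
                   stringsAsFactors = FALSE)
  bad <- is.na(df$diagnostic_for) != is.na(df$characteristic_allele)
  if (any(bad))
    stop("characteristic_allele must be present iff diagnostic_for is: ",
         paste(df$locus[bad], collapse = ", "))
  class(df) <- c("locus_annotation", "data.frame")
  df
}

#' @rdname locus_annotation
#' @param path file path (TSV with the fixed header).
#' @export
read_locus_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  do.call(locus_annotation, df[c("locus", "alleles", "region_class", "synonymy",
                                 "diagnostic_for", "characteristic_allele")])
}

#' @rdname locus_annotation
#' @param ann a `locus_annotation`.
#' @export
write_locus_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-population environment table
#'
#' One row per population with the twelve environmental variables listed in
#' [env_variables] plus a categorical `region` drawn from [region_levels].
#'
#' @param population population codes.
#' @param ... the twelve environmental variables, by name.
#' @param region region factor values.
#' @return a `data.frame` of class `env_table`.
#' @export
env_table <- function(population, ..., region) {
  vars <- list(...)
  missing_vars <- setdiff(env_variables, names(vars))
  if (length(missing_vars))
    stop("missing environmental variables: ", paste(missing_vars, collapse = ", "))
  if (!all(region %in% region_levels))
    stop("region values must be one of: ", paste(region_levels, collapse = "; "))
  df <- data.frame(population = population, vars[env_variables],
                   region = factor(region, levels = region_levels),
                   stringsAsFactors = FALSE)
  pct <- c("ice_conc", "cloud")
  for (v in pct)
    if (any(df[[v]] < 0 | df[[v]] > 100, na.rm = TRUE))
      stop(v, " is a percentage and must lie in [0, 100]")
  class(df) <- c("env_table", "data.frame")
  df
}

#' @rdname env_table
#' @param path file path (TSV).
#' @export
read_env_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  do.call(env_table, c(list(population = df$population),
                       as.list(df[env_variables]), list(region = df$region)))
}

#' @rdname env_table
#' @param env an `env_table`.
#' @export
write_env_table <- function(env, path) {
  utils::write.table(env, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate a genotype / annotation / environment trio
#'
#' Checks referential integrity between the three tables (locus IDs between
#' genotypes and annotation, population codes between genotypes and
#' environment), and summarizes per-locus missingness and per-population
#' sample sizes.  Annotation rows for loci absent from the genotype data are
#' tolerated with a warning-level issue; the reverse direction, and
#' populations lacking an environment row, are failures.
#'
#' @param gm a [genotype_matrix()].
#' @param ann a [locus_annotation()] or `NULL`.
#' @param env an [env_table()] or `NULL`.
#' @return a list of class `validation_report`: `pass` (logical), `issues`
#'   (data.frame with `level` and `message`), `locus_missingness`,
#'   `population_n`.
#' @export
validate_dataset <- function(gm, ann = NULL, env = NULL) {
  issues <- data.frame(level = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  add <- function(level, msg)
    rbind(issues, data.frame(level = level, message = msg))
  if (!is.null(ann)) {
    unann <- setdiff(gm$loci, ann$locus)
    for (l in unann) issues <- add("error", paste0("locus ", l, " lacks an annotation row"))
    extra <- setdiff(ann$locus, gm$loci)
    for (l in extra) issues <- add("warning", paste0("annotation for absent locus ", l))
  }
  if (!is.null(env)) {
    noenv <- setdiff(levels(gm$pop), env$population)
    for (p in noenv) issues <- add("error", paste0("population ", p, " lacks environment row"))
    extra <- setdiff(env$population, levels(gm$pop))
    for (p in extra) issues <- add("warning", paste0("environment row for absent population ", p))
  }
  miss <- colMeans(is.na(gm$a1))
  out <- list(pass = !any(issues$level == "error"), issues = issues,
              locus_missingness = miss, population_n = table(gm$pop))
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation:", if (x$pass) "PASS" else "FAIL", "\n")
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s\n", x$issues$level[i], x$issues$message[i]))
  } else cat("  no issues\n")
  invisible(x)
}
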