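# Delimited-text readers/writers for the pipeline's artifacts, plus the
# one-command pipeline driver with its reproducibility manifest. All formats
# are plain tab-separated text: the data volumes are small and diffability
# matters more than compactness.

#' Read / write a phenotype table
#'
#' Tab-separated text with columns line_id, family, year, location,
#' management, environment, tester, trial, rep, block, yield. Management must
#' be `WW` or `WS`; year is parsed as integer; records with missing yield are
#' dropped with a message reporting the count.
#'
#' @param path file path.
#' @return `read_phenotypes`: validated data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_phenotypes(d)
  d$year <- as.integer(d$year)
  yield <- suppressWarnings(as.numeric(d$yield))
  bad_num <- which(!is.na(d$yield) & is.na(yield) & d$yield != "NA")
  if (length(bad_num))
    sgs_stop(sprintf("non-numeric yield '%s' at data row %d", d$yield[bad_num[1]],
                     bad_num[1]), "sgs_schema_error")
  d$yield <- yield
  drop <- is.na(d$yield)
  if (any(drop)) {
    message(sprintf("dropping %d record(s) with missing yield", sum(drop)))
    d <- d[!drop, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' @rdname read_phenotypes
#' @param pheno phenotype data.frame.
#' @export
write_phenotypes <- function(pheno, path) {
  check_phenotypes(pheno)
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a marker matrix
#'
#' Tab-separated text: first two columns `line_id` and `family`, remaining
#' columns one marker each with values in {0, 2}. Missing genotypes are
#' imputed at load time to the column mean rounded to the nearer of 0 or 2.
#'
#' @param path file path.
#' @return `read_markers`: a [marker_matrix()].
#' @export
read_markers <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("line_id", "family") %in% names(d)))
    sgs_stop("marker file needs line_id and family as its first columns", "sgs_schema_error")
  m <- as.matrix(d[, setdiff(names(d), c("line_id", "family")), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d$line_id
  if (anyNA(m)) {
    fill <- ifelse(colMeans(m, na.rm = TRUE) >= 1, 2, 0)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- fill[idx[, 2]]
    message(sprintf("imputed %d missing genotype call(s) to the column-mean allele",
                    nrow(idx)))
  }
  marker_matrix(m, stats::setNames(d$family, d$line_id))
}

#' @rdname read_markers
#' @param markers a [marker_matrix()].
#' @export
write_markers <- function(markers, path) {
  d <- data.frame(line_id = rownames(markers),
                  family = unname(families(markers)[rownames(markers)]),
                  unclass(markers), check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a relationship matrix
#'
#' Square tab-separated matrix with line IDs in the header row and first
#' column. Symmetry is verified on read (tolerance 1e-8).
#'
#' @param path file path.
#' @return `read_grm`: symmetric numeric matrix with ID dimnames.
#' @export
read_grm <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!identical(colnames(m), as.character(ids)))
    sgs_stop("relationship matrix header and ID column disagree", "sgs_schema_error")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8)
    sgs_stop(sprintf("relationship matrix is not symmetric (max asymmetry %.3g)", asym),
             "sgs_schema_error")
  m
}

#' @rdname read_grm
#' @param G symmetric matrix with ID dimnames.
#' @export
write_grm <- function(G, path) {
  check_symmetric(unclass(G), name = "G")
  d <- data.frame(line_id = rownames(G), unclass(G), check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a simulation configuration
#'
#' Flat YAML mapping of the [sim_config()] fields; matrix-valued fields
#' (`true_Go`) are stored as nested lists.
#'
#' @param path file path.
#' @return `read_sim_config`: a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$envs_per_year)) raw$envs_per_year <- as.data.frame(raw$envs_per_year)
  if (!is.null(raw$true_Go))
    raw$true_Go <- do.call(rbind, lapply(raw$true_Go, unlist))
  for (f in c("nuisance_variances", "location_effects", "residual_variances",
              "h2", "n_families", "family_size", "n_testers_per_year", "n_trials"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$env_grid <- NULL
  x$envs_per_year <- as.list(x$envs_per_year)
  x$true_Go <- apply(unname(x$true_Go), 1, as.list)
  x$residual_variances <- as.list(x$residual_variances)
  x$nuisance_variances <- as.list(x$nuisance_variances)
  x$location_effects <- as.list(x$location_effects)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Run the full sparse-testing pipeline
#'
#' Executes simulate (optional) -> relationship matrix -> CDmean optimization
#' -> cross-validation, writing every artifact as delimited text under
#' `out_dir` together with a JSON run manifest (configuration echo, input
#' checksums, package version, per-stage timings, seeds and convergence
#' flags) sufficient to re-execute the run bit-identically.
#'
#' @param config list (or path to a YAML file) with elements: either
#'   `simulate` (a [sim_config()] or its fields) or `phenotypes`/`markers`
#'   file paths; plus optional `scheme`, `grouping`, `structure`,
#'   `n_repeats`, `maf`, `lambda`, `seed`.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  scheme <- match.arg(config$scheme %||% "CV2", c("CV1", "CV2"))
  grouping <- match.arg(config$grouping %||% "LM", c("LM", "M", "MY", "M_plus", "LMY"))
  structure_ <- match.arg(config$structure %||% "FA", c("FA", "US", "DIAG"))
  seed <- as.integer(config$seed %||% 1L)
  maf <- config$maf %||% 0.05
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "sparsegs",
                   version = as.character(utils::packageVersion("sparsegs")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   settings = list(scheme = scheme, grouping = grouping,
                                   structure = structure_, seed = seed, maf = maf),
                   stages = list(), inputs = list())
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[stage]] <<- list(status = "failed",
                                        error = conditionMessage(e))
      manifest$completed <<- FALSE
      write_manifest(manifest, out_dir)
      stop(e)
    })
    manifest$stages[[stage]] <<- list(status = "ok",
                                      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  if (!is.null(config$simulate)) {
    sc <- config$simulate
    if (!inherits(sc, "sim_config")) {
      sc$seed <- sc$seed %||% seed
      sc <- do.call(sim_config, sc)
    }
    dataset <- tick("simulate", simulate_trial_data(sc))
    write_phenotypes(dataset$phenotypes, file.path(out_dir, "phenotypes.tsv"))
    write_markers(dataset$markers, file.path(out_dir, "markers.tsv"))
    utils::write.table(data.frame(line_id = rownames(dataset$true_values),
                                  dataset$true_values, check.names = FALSE),
                       file.path(out_dir, "true_values.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_sim_config(sc, file.path(out_dir, "sim_config.yml"))
    pheno <- dataset$phenotypes; markers <- dataset$markers
  } else {
    pheno <- tick("read", read_phenotypes(config$phenotypes))
    markers <- read_markers(config$markers)
    manifest$inputs <- as.list(tools::md5sum(c(config$phenotypes, config$markers)))
  }

  G <- tick("grm", regularize_grm(compute_grm(filter_markers(markers, maf)), 1e-6))
  write_grm(G, file.path(out_dir, "grm.tsv"))

  cv <- tick("crossval", run_crossval(
    list(phenotypes = pheno, grm = G), scheme = scheme, grouping = grouping,
    structure = structure_, n_repeats = config$n_repeats %||% 10, seed = seed,
    lambda = config$lambda %||% 0.5))
  utils::write.table(cv$cells, file.path(out_dir, "cv_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cv$by_env, file.path(out_dir, "cv_by_env.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (scheme == "CV2") {
    utils::write.table(cv$plans[[1]], file.path(out_dir, "cv2_split.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest$convergence <- cv$converged
  manifest$completed <- TRUE
  manifest$outputs <- as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                                       pattern = "\\.tsv$")))
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(NULL)
}
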