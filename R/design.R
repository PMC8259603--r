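# Environment classification schemes and mixed-model design construction.

#' Environment grouping schemes
#'
#' Maps raw (location, management, year) triples onto analysis environment
#' labels. Available schemes: `"LM"` location-by-management (single year),
#' `"M"` management (single year), `"MY"` management-by-year, `"M_plus"`
#' management pooled across years, and `"LMY"` location-by-management-by-year.
#'
#' @param scheme one of `"LM"`, `"M"`, `"MY"`, `"M_plus"`, `"LMY"`.
#' @return List of class `env_grouping` with the scheme name, a labelling
#'   function `fun(location, management, year)` and a single-year flag.
#' @export
#' @examples
#' g <- env_grouping("M")
#' g$fun("Kiboko", c("WW", "WS"), 2017)
env_grouping <- function(scheme = c("LM", "M", "MY", "M_plus", "LMY")) {
  scheme <- match.arg(scheme)
  fun <- switch(scheme,
    LM = function(location, management, year) paste(location, management, sep = "_"),
    M = function(location, management, year) management,
    MY = function(location, management, year) paste(management, year, sep = "_"),
    M_plus = function(location, management, year) management,
    LMY = function(location, management, year) paste(location, management, year, sep = "_"))
  structure(list(scheme = scheme, fun = fun,
                 single_year = scheme %in% c("LM", "M")),
            class = "env_grouping")
}

required_pheno_cols <- c("line_id", "family", "year", "location", "management",
                         "environment", "tester", "trial", "rep", "block", "yield")

check_phenotypes <- function(pheno) {
  miss <- setdiff(required_pheno_cols, names(pheno))
  if (length(miss))
    sgs_stop(paste0("phenotype table is missing column(s): ",
                    paste(miss, collapse = ", ")), "sgs_schema_error")
  bad <- !(pheno$management %in% c("WW", "WS"))
  if (any(bad))
    sgs_stop(sprintf("unknown management value '%s' (must be WW or WS)",
                     pheno$management[which(bad)[1]]), "sgs_schema_error")
  invisible(TRUE)
}

#' Build mixed-model design matrices from a phenotype table
#'
#' Encodes the multi-environment GBLUP model: fixed intercept and location
#' effects, a line-by-environment genetic term, and iid nuisance terms for
#' tester, trial, replication nested within (environment, trial) and
#' incomplete block nested within (replication, trial, environment), with
#' nesting realized through compound factor keys. Environments are relabelled
#' according to the grouping scheme. Nuisance factors that collapse to a
#' single level are dropped with a message.
#'
#' @param pheno phenotype data.frame with the standard columns (see
#'   [read_phenotypes()]).
#' @param grouping an [env_grouping()] or scheme name.
#' @param random nuisance terms to include, a subset of
#'   `c("tester", "trial", "rep", "block")`.
#' @return List of class `me_design` holding the response, dense fixed/nuisance
#'   design, record-to-line and record-to-environment maps, and bookkeeping.
#' @export
build_design <- function(pheno, grouping = "LM",
                         random = c("tester", "trial", "rep", "block")) {
  check_phenotypes(pheno)
  if (is.character(grouping)) grouping <- env_grouping(grouping)
  if (length(random)) random <- match.arg(random, several.ok = TRUE)
  years <- sort(unique(pheno$year))
  if (grouping$single_year && length(years) > 1L)
    sgs_stop(sprintf("grouping '%s' is a single-year scheme but the data span years %s",
                     grouping$scheme, paste(years, collapse = ", ")), "sgs_config_error")
  env_label <- grouping$fun(pheno$location, pheno$management, pheno$year)
  env_levels <- sort(unique(env_label))
  rec_env <- match(env_label, env_levels)

  n <- nrow(pheno)
  # fixed part: intercept + location contrasts
  loc <- factor(pheno$location)
  X <- if (nlevels(loc) > 1L) {
    stats::model.matrix(~loc)
  } else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  colnames(X) <- sub("^loc", "location", colnames(X))

  keys <- list(
    tester = pheno$tester,
    trial = pheno$trial,
    rep = paste(pheno$environment, pheno$trial, pheno$rep, sep = ":"),
    block = paste(pheno$environment, pheno$trial, pheno$rep, pheno$block, sep = ":"))
  dropped <- character(0)
  Zs <- list(); s_blocks <- list(fixed = seq_len(ncol(X)))
  off <- ncol(X)
  for (term in random) {
    f <- factor(keys[[term]])
    if (nlevels(f) < 2L) {
      dropped <- c(dropped, term)
      message(sprintf("dropping degenerate random term '%s' (single level)", term))
      next
    }
    Z <- stats::model.matrix(~0 + f)
    colnames(Z) <- paste0(term, ":", levels(f))
    Zs[[term]] <- Z
    s_blocks[[term]] <- off + seq_len(ncol(Z))
    off <- off + ncol(Z)
  }
  Ws <- do.call(cbind, c(list(X), Zs))

  structure(list(
    y = as.numeric(pheno$yield), n = n, Ws = Ws, s_blocks = s_blocks,
    rec_line = as.character(pheno$line_id), rec_env = rec_env,
    env_levels = env_levels, grouping = grouping, dropped = dropped,
    meta = data.frame(line_id = pheno$line_id, family = pheno$family,
                      environment = pheno$environment, env = env_label,
                      stringsAsFactors = FALSE)), class = "me_design")
}

#' @export
print.me_design <- function(x, ...) {
  cat(sprintf("me_design: %d records, %d analysis environments (%s grouping)\n",
              x$n, length(x$env_levels), x$grouping$scheme))
  cat(sprintf("  environments: %s\n", paste(x$env_levels, collapse = ", ")))
  cat(sprintf("  fixed + nuisance columns: %d (%s)\n", ncol(x$Ws),
              paste(names(x$s_blocks), collapse = ", ")))
  invisible(x)
}
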