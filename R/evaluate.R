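# End-to-end evaluation of sparse-testing designs: per-environment BLUEs,
# CV1/CV2 masking, optional historical-data augmentation, model fitting and
# Pearson prediction accuracy averaged over families.

#' Per-environment BLUEs of line testcross means
#'
#' For every raw environment, fits genotype as a fixed effect with trial,
#' replication and incomplete block as random effects (the standard stage-one
#' trial analysis) and returns the fixed genotype solutions. In balanced
#' designs these equal ordinary per-line means regardless of the random
#' terms. Computed from the complete (unmasked) data; these are the
#' validation targets for prediction accuracy.
#'
#' @param pheno phenotype data.frame (complete data).
#' @param environments optional subset of raw environment labels.
#' @return data.frame with columns line_id, environment, blue.
#' @export
compute_blues <- function(pheno, environments = NULL) {
  check_phenotypes(pheno)
  envs <- environments %||% sort(unique(pheno$environment))
  out <- vector("list", length(envs))
  for (k in seq_along(envs)) {
    d <- pheno[pheno$environment == envs[k], , drop = FALSE]
    if (!nrow(d)) next
    d$line <- factor(d$line_id)
    d$trial_f <- factor(d$trial)
    d$rep_f <- factor(paste(d$trial, d$rep, sep = ":"))
    d$block_f <- factor(paste(d$trial, d$rep, d$block, sep = ":"))
    terms <- c(trial_f = "(1 | trial_f)", rep_f = "(1 | rep_f)",
               block_f = "(1 | block_f)")
    keep <- vapply(names(terms), function(f) nlevels(d[[f]]) > 1L, logical(1))
    est <- NULL
    if (any(keep)) {
      fml <- stats::as.formula(paste("yield ~ 0 + line +",
                                     paste(terms[keep], collapse = " + ")))
      fit <- tryCatch(
        suppressWarnings(suppressMessages(lme4::lmer(fml, data = d))),
        error = function(e) NULL)
      if (!is.null(fit)) est <- lme4::fixef(fit)
    }
    if (is.null(est)) est <- stats::coef(stats::lm(yield ~ 0 + line, data = d))
    names(est) <- sub("^line", "", names(est))
    out[[k]] <- data.frame(line_id = names(est), environment = envs[k],
                           blue = unname(est), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# the 2 WW + 1 WS raw environments of a target year
target_envs <- function(pheno, target_year) {
  d <- unique(pheno[pheno$year == target_year,
                    c("environment", "management"), drop = FALSE])
  ww <- sort(d$environment[d$management == "WW"])
  ws <- sort(d$environment[d$management == "WS"])
  if (length(ww) != 2L || length(ws) != 1L)
    sgs_stop(sprintf(
      "sparse-testing masks need exactly 2 WW and 1 WS environment in year %s (found %d WW, %d WS)",
      target_year, length(ww), length(ws)), "sgs_config_error")
  list(ww = ww, ws = ws)
}

#' Random family-level masks for the CV1 scheme
#'
#' CV1 predicts whole bi-parental families in environments where they were
#' never phenotyped: in each repeat, a random half of the families is masked
#' in the first WW environment (and observed in the second), the other half
#' vice versa; in the WS environment, `floor(k/2)` randomly chosen families
#' from each WW-observed group of size k are masked. With 12 families this is
#' the 6/6 WW split with 3 + 3 families masked in WS. Odd family counts put
#' the extra family in the first group.
#'
#' @param lines data.frame with columns line_id and family.
#' @param ww_envs two WW environment labels.
#' @param ws_env the WS environment label.
#' @param n_repeats number of random repeats (default 10).
#' @param seed integer seed; plans are deterministic given it.
#' @return List of mask plans: data.frames with line_id, family, environment,
#'   status ("observed"/"masked"), with scheme/repeat/seed attributes.
#' @export
make_cv1_masks <- function(lines, ww_envs, ws_env, n_repeats = 10, seed = 1) {
  fams <- sort(unique(lines$family))
  if (length(fams) < 2L) sgs_stop("CV1 needs at least 2 families", "sgs_input_error")
  if (length(ww_envs) != 2L || length(ws_env) != 1L)
    sgs_stop("CV1 needs two WW environments and one WS environment", "sgs_input_error")
  seeds <- derive_seeds(seed, n_repeats)
  lapply(seq_len(n_repeats), function(r) {
    with_seed(seeds[r], {
      shuffled <- sample(fams)
      gA <- sort(shuffled[seq_len(ceiling(length(fams) / 2))])
      gB <- sort(setdiff(fams, gA))
      wsA <- if (length(gA)) sort(sample(gA, floor(length(gA) / 2))) else character(0)
      wsB <- if (length(gB)) sort(sample(gB, floor(length(gB) / 2))) else character(0)
    })
    plan <- rbind(
      data.frame(line_id = lines$line_id, family = lines$family,
                 environment = ww_envs[1],
                 status = ifelse(lines$family %in% gA, "observed", "masked"),
                 stringsAsFactors = FALSE),
      data.frame(line_id = lines$line_id, family = lines$family,
                 environment = ww_envs[2],
                 status = ifelse(lines$family %in% gB, "observed", "masked"),
                 stringsAsFactors = FALSE),
      data.frame(line_id = lines$line_id, family = lines$family,
                 environment = ws_env,
                 status = ifelse(lines$family %in% c(wsA, wsB), "masked", "observed"),
                 stringsAsFactors = FALSE))
    structure(plan, scheme = "CV1", rep = r, seed = seeds[r],
              groups = list(A = gA, B = gB, ws_masked = c(wsA, wsB)))
  })
}

#' Deterministic CDmean-based mask for the CV2 scheme
#'
#' Translates per-family [split_family_cv2()] assignments into a mask plan:
#' every line is observed in exactly one WW environment (masked in the
#' other), and observed in WS only if its split flags it as a WS calibration
#' line.
#'
#' @param splits named list of calibration splits, one per family.
#' @param ws_env the WS environment label.
#' @return A single mask plan data.frame (line_id, family, environment,
#'   status).
#' @export
make_cv2_masks <- function(splits, ws_env) {
  if (!length(splits) || is.null(names(splits)))
    sgs_stop("splits must be a named list (family -> calibration_split)", "sgs_integrity_error")
  plans <- lapply(names(splits), function(fam) {
    sp <- splits[[fam]]
    if (!inherits(sp, "calibration_split"))
      sgs_stop(sprintf("family '%s' is missing its calibration split", fam),
               "sgs_integrity_error")
    ww <- attr(sp, "ww_envs")
    rbind(
      data.frame(line_id = sp$line_id, family = fam, environment = ww[1],
                 status = ifelse(sp$ww_observed == ww[1], "observed", "masked"),
                 stringsAsFactors = FALSE),
      data.frame(line_id = sp$line_id, family = fam, environment = ww[2],
                 status = ifelse(sp$ww_observed == ww[2], "observed", "masked"),
                 stringsAsFactors = FALSE),
      data.frame(line_id = sp$line_id, family = fam, environment = ws_env,
                 status = ifelse(sp$ws_observed, "observed", "masked"),
                 stringsAsFactors = FALSE))
  })
  structure(do.call(rbind, plans), scheme = "CV2", rep = 1L)
}

#' Apply a mask plan to a phenotype table
#'
#' Removes every plot record whose (line, environment) cell is masked in the
#' plan; cells not listed in the plan (e.g. historical records) stay
#' observed. The result is the training set — masked phenotypes never reach
#' any downstream computation.
#'
#' @param pheno phenotype data.frame.
#' @param plan mask plan from [make_cv1_masks()] or [make_cv2_masks()].
#' @return The training subset of `pheno`.
#' @export
apply_mask <- function(pheno, plan) {
  key <- paste(pheno$line_id, pheno$environment, sep = "\r")
  masked <- paste(plan$line_id, plan$environment, sep = "\r")[plan$status == "masked"]
  pheno[!(key %in% masked), , drop = FALSE]
}

#' Augment a current dataset with historical data
#'
#' Combines a current and a historical dataset (disjoint line IDs, shared
#' marker panel). `mode = "all"` appends every historical line;
#' `mode = "optimized"` appends, per current family, the `n_select`
#' historical lines with the highest average genomic relationship to the
#' family ([avg_grm_select()]), using a relationship matrix built jointly
#' from the combined markers; `mode = "none"` returns the current dataset
#' unchanged. Multi-year analyses of the combined data require a multi-year
#' grouping scheme (`LMY`, `MY` or `M_plus`).
#'
#' @param current,historical lists with elements `markers` (a
#'   [marker_matrix()]), `phenotypes` and `lines` (as produced by
#'   [simulate_trial_data()]).
#' @param mode `"none"`, `"all"` or `"optimized"`.
#' @param n_select historical lines per family for `"optimized"`.
#' @param grouping optional grouping scheme to validate against (single-year
#'   schemes are rejected when historical data are added).
#' @return A combined dataset list with elements markers, phenotypes, lines,
#'   grm (joint, regularized) and `historical_ids`.
#' @export
augment_with_historical <- function(current, historical,
                                    mode = c("none", "all", "optimized"),
                                    n_select = 300, grouping = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(current)
  if (!is.null(grouping)) {
    gr <- if (is.character(grouping)) env_grouping(grouping) else grouping
    if (gr$single_year)
      sgs_stop(sprintf("historical augmentation needs a multi-year grouping, not '%s'",
                       gr$scheme), "sgs_config_error")
  }
  common <- intersect(colnames(current$markers), colnames(historical$markers))
  if (!length(common))
    sgs_stop("current and historical marker panels do not intersect", "sgs_input_error")
  overlap <- intersect(rownames(current$markers), rownames(historical$markers))
  if (length(overlap))
    sgs_stop(paste0("line IDs must be disjoint across datasets: ",
                    paste(utils::head(overlap, 5), collapse = ", ")), "sgs_input_error")
  mk <- marker_matrix(
    rbind(unclass(current$markers)[, common, drop = FALSE],
          unclass(historical$markers)[, common, drop = FALSE]),
    c(families(current$markers), families(historical$markers)))
  G <- regularize_grm(compute_grm(filter_markers(mk, 0.05)), 1e-6)
  hist_ids <- rownames(historical$markers)
  if (mode == "optimized") {
    fams <- split(rownames(current$markers), families(current$markers)[rownames(current$markers)])
    picks <- unique(unlist(lapply(fams, function(members) {
      avg_grm_select(G[hist_ids, members, drop = FALSE], n_select)$line_id
    })))
    hist_ids <- picks
  }
  keep_hist <- historical$phenotypes$line_id %in% hist_ids
  list(markers = mk,
       phenotypes = rbind(current$phenotypes, historical$phenotypes[keep_hist, , drop = FALSE]),
       lines = rbind(current$lines,
                     historical$lines[historical$lines$line_id %in% hist_ids, , drop = FALSE]),
       grm = G, historical_ids = hist_ids, mode = mode)
}

#' Run a sparse-testing cross-validation experiment
#'
#' The full inference procedure: compute per-environment BLUEs from the
#' complete data, build CV1 (random family-level) or CV2 (CDmean-based) mask
#' plans for the target year, fit the multi-environment GBLUP on the observed
#' records of each plan, predict GEBVs, and score each (family, environment)
#' cell by the Pearson correlation between the masked lines' GEBVs and their
#' BLUEs. The unweighted mean across families is reported per environment.
#'
#' @param dataset list with `phenotypes` and either `grm` or `markers` (as
#'   from [simulate_trial_data()] or [augment_with_historical()]).
#' @param scheme `"CV1"` or `"CV2"`.
#' @param grouping environment classification scheme.
#' @param structure covariance structure (`"FA"`, `"US"`, `"DIAG"`).
#' @param n_repeats CV1 repeats (CV2 is deterministic: one plan).
#' @param seed master seed for mask randomization.
#' @param lambda CDmean variance ratio for CV2 splits.
#' @param min_masked minimum masked lines per (family, environment) cell for
#'   a correlation to be reported (default 3).
#' @param target_year year whose families are masked; default the earliest
#'   year (later years act as historical data and are never masked).
#' @param ... further arguments to [me_gblup()] (e.g. `m`, `tol`,
#'   `max_iter`).
#' @return Object of class `cv_result`: `cells` (per scheme, repeat, family,
#'   environment accuracy), `by_env` (mean over families and repeats),
#'   `plans`, convergence flags and settings.
#' @export
run_crossval <- function(dataset, scheme = c("CV1", "CV2"), grouping = "LM",
                         structure = c("FA", "US", "DIAG"), n_repeats = 10,
                         seed = 1, lambda = 0.5, min_masked = 3,
                         target_year = NULL, ...) {
  scheme <- match.arg(scheme); structure <- match.arg(structure)
  pheno <- dataset$phenotypes
  check_phenotypes(pheno)
  G <- dataset$grm %||%
    regularize_grm(compute_grm(filter_markers(dataset$markers, 0.05)), 1e-6)
  target_year <- target_year %||% min(pheno$year)
  te <- target_envs(pheno, target_year)
  tgt <- pheno$year == target_year
  lines <- unique(pheno[tgt, c("line_id", "family"), drop = FALSE])

  blues <- compute_blues(pheno, environments = c(te$ww, te$ws))

  plans <- if (scheme == "CV1") {
    make_cv1_masks(lines, te$ww, te$ws, n_repeats = n_repeats, seed = seed)
  } else {
    fams <- split(lines$line_id, lines$family)
    splits <- lapply(fams, function(members) {
      scores <- if (length(members) >= 3) {
        cdmean_per_individual(G[members, members, drop = FALSE], lambda = lambda)
      } else {  # families too small to score: fall back to the ID tie-break
        data.frame(line_id = sort(members), cdmean = 0, stringsAsFactors = FALSE)
      }
      split_family_cv2(scores, te$ww)
    })
    list(make_cv2_masks(splits, te$ws))
  }

  grp_fun <- env_grouping(grouping)$fun
  env_info <- unique(pheno[pheno$environment %in% c(te$ww, te$ws),
                           c("environment", "location", "management", "year")])
  env_info$analysis_env <- grp_fun(env_info$location, env_info$management, env_info$year)

  cells <- list(); conv <- logical(length(plans))
  for (r in seq_along(plans)) {
    plan <- plans[[r]]
    train <- apply_mask(pheno, plan)
    fit <- me_gblup(train, G, grouping = grouping, structure = structure, ...)
    conv[r] <- fit$converged
    gebv <- fit$gebv
    masked <- plan[plan$status == "masked", , drop = FALSE]
    for (env in c(te$ww, te$ws)) {
      aenv <- env_info$analysis_env[env_info$environment == env]
      benv <- blues[blues$environment == env, , drop = FALSE]
      menv <- masked[masked$environment == env, , drop = FALSE]
      for (fam in unique(menv$family)) {
        ids <- intersect(menv$line_id[menv$family == fam], benv$line_id)
        ids <- intersect(ids, rownames(gebv))
        if (length(ids) < min_masked) next
        bl <- benv$blue[match(ids, benv$line_id)]
        pr <- gebv[ids, aenv]
        if (stats::sd(bl) == 0 || stats::sd(pr) == 0) next
        cells[[length(cells) + 1L]] <- data.frame(
          scheme = scheme, grouping = grouping, structure = structure,
          rep = r, family = fam, environment = env, n_masked = length(ids),
          accuracy = stats::cor(pr, bl), converged = conv[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(scheme = character(0), rep = integer(0), family = character(0),
               environment = character(0), n_masked = integer(0),
               accuracy = numeric(0))
  by_env <- if (nrow(cells)) {
    agg <- stats::aggregate(accuracy ~ environment, data = cells, FUN = mean)
    agg$n_cells <- stats::aggregate(accuracy ~ environment, data = cells,
                                    FUN = length)$accuracy
    agg
  } else cells
  structure(list(cells = cells, by_env = by_env, plans = plans,
                 converged = conv,
                 settings = list(scheme = scheme, grouping = grouping,
                                 structure = structure, n_repeats = length(plans),
                                 seed = seed, lambda = lambda,
                                 target_year = target_year)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Sparse-testing cross-validation: %s, %s grouping, %s covariance (%d plan%s)\n",
              s$scheme, s$grouping, s$structure, s$n_repeats,
              if (s$n_repeats > 1) "s" else ""))
  if (nrow(x$by_env)) {
    cat("Mean prediction accuracy across families:\n")
    print(transform(x$by_env, accuracy = round(accuracy, 3)), row.names = FALSE)
  } else cat("No scoreable cells.\n")
  if (!all(x$converged))
    cat(sprintf("Note: %d of %d fits did not converge.\n",
                sum(!x$converged), length(x$converged)))
  invisible(x)
}

#' Overall mean accuracy of a cross-validation result
#' @param x a `cv_result`.
#' @return Mean accuracy over all (repeat, family, environment) cells.
#' @export
mean_accuracy <- function(x) {
  stopifnot(inherits(x, "cv_result"))
  if (!nrow(x$cells)) return(NA_real_)
  mean(x$cells$accuracy)
}
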