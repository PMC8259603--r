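# Seeded simulation of multi-environment testcross trials of bi-parental
# doubled-haploid (DH) families: founder genotypes, DH progeny via an
# interference-free (Haldane) crossover model, genetic values drawn from the
# Kronecker covariance the analysis assumes, and alpha-lattice style plot
# records with tester/trial/rep/block nuisance effects and per-environment
# residual variances.

#' Simulation configuration for a sparse-testing trial system
#'
#' The defaults emulate a preliminary-yield-trial system: 12 bi-parental DH
#' families of 70 sibs testcrossed to one of three testers, evaluated in two
#' well-watered (WW) and one water-stress (WS) environment in a single year,
#' two-replicate alpha-lattice trials, plot heritabilities around 0.25-0.35 and
#' between-environment genetic correlations from 0.2 to 0.6.
#'
#' @param n_families families per year (scalar or one value per year).
#' @param family_size DH lines per family (scalar or per year); at least 4.
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_morgans genome
#'   layout; marker positions are drawn uniformly along each chromosome.
#' @param n_years number of trial years (later years emulate historical data).
#' @param envs_per_year data.frame with columns `location` and `management`
#'   (`"WW"` or `"WS"`), one row per environment within a year.
#' @param n_testers_per_year testers per year (scalar or per year); each family
#'   is testcrossed to a single tester.
#' @param n_trials trials per year (`NULL`: one per family).
#' @param n_reps replications per trial (alpha-lattice default 2).
#' @param blocks_per_rep incomplete blocks per replication.
#' @param true_Go v x v genetic covariance between environments (v = total
#'   environments over all years). `NULL` builds a default from `h2`,
#'   residual variances of 1, correlation 0.6 within management, 0.3 across
#'   managements, damped by 0.8 across years.
#' @param h2 target plot heritability per environment used when `true_Go` is
#'   `NULL` (default 0.30 for WW, 0.35 for WS environments).
#' @param residual_variances per-environment residual variance (recycled).
#' @param nuisance_variances named numeric vector with elements `tester`,
#'   `trial`, `rep`, `block`.
#' @param mu overall mean (yield-scale arbitrary units).
#' @param location_effects named fixed location effects; `NULL` spaces
#'   locations 0.25 apart (first location at 0).
#' @param founder_reuse for multi-year configs, probability that a later-year
#'   family reuses founders from earlier years (creates historical
#'   relatedness); ignored when `n_years == 1`.
#' @param seed master seed; all stages derive their own seeds from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 12, family_size = 70,
                       n_chromosomes = 10, markers_per_chromosome = 50,
                       chromosome_length_morgans = 1.5,
                       n_years = 1,
                       envs_per_year = data.frame(
                         location = c("Kiboko", "Kakamega", "Kiboko"),
                         management = c("WW", "WW", "WS")),
                       n_testers_per_year = 3, n_trials = NULL,
                       n_reps = 2, blocks_per_rep = 5,
                       true_Go = NULL, h2 = NULL, residual_variances = 1,
                       nuisance_variances = c(tester = 0.05, trial = 0.05,
                                              rep = 0.02, block = 0.02),
                       mu = 5, location_effects = NULL,
                       founder_reuse = 0.5, seed = 1L) {
  envs_per_year <- as.data.frame(envs_per_year)
  if (!all(c("location", "management") %in% names(envs_per_year)))
    sgs_stop("envs_per_year needs columns location and management", "sgs_config_error")
  if (!all(envs_per_year$management %in% c("WW", "WS")))
    sgs_stop("management must be 'WW' or 'WS'", "sgs_config_error")
  n_years <- as.integer(n_years)
  rep_year <- function(x) {
    x <- as.integer(x)
    if (length(x) == 1L) rep(x, n_years) else if (length(x) == n_years) x else
      sgs_stop("per-year config fields must have length 1 or n_years", "sgs_config_error")
  }
  n_families <- rep_year(n_families); family_size <- rep_year(family_size)
  n_testers_per_year <- rep_year(n_testers_per_year)
  if (is.null(n_trials)) n_trials <- n_families else n_trials <- rep_year(n_trials)
  if (any(family_size < 4))
    sgs_stop("family_size must be at least 4", "sgs_config_error")
  if (any(c(n_families, n_chromosomes, markers_per_chromosome, n_reps,
            blocks_per_rep, n_testers_per_year, n_trials) < 1) ||
      chromosome_length_morgans <= 0)
    sgs_stop("counts must be positive", "sgs_config_error")

  n_env_year <- nrow(envs_per_year)
  v <- n_env_year * n_years
  env_grid <- do.call(rbind, lapply(seq_len(n_years), function(yr)
    cbind(envs_per_year, year = 2016L + yr)))
  env_grid$env <- paste(env_grid$location, env_grid$management, env_grid$year, sep = "_")

  residual_variances <- rep_len(as.numeric(residual_variances), v)
  if (any(residual_variances < 0)) sgs_stop("variances must be >= 0", "sgs_config_error")
  if (is.null(true_Go)) {
    if (is.null(h2)) h2 <- ifelse(env_grid$management == "WS", 0.35, 0.30)
    h2 <- rep_len(h2, v)
    if (any(h2 < 0 | h2 >= 1)) sgs_stop("h2 must lie in [0, 1)", "sgs_config_error")
    sg <- h2 / (1 - h2) * residual_variances
    true_Go <- diag(sg, v)
    for (i in seq_len(v)) for (j in seq_len(v)) if (i != j) {
      r <- if (env_grid$management[i] == env_grid$management[j]) 0.6 else 0.3
      if (env_grid$year[i] != env_grid$year[j]) r <- r * 0.8
      true_Go[i, j] <- r * sqrt(sg[i] * sg[j])
    }
  }
  true_Go <- as.matrix(true_Go)
  if (nrow(true_Go) != v)
    sgs_stop(sprintf("true_Go must be %d x %d (one row per environment)", v, v),
             "sgs_config_error")
  check_symmetric(true_Go, name = "true_Go")
  if (min(eigen(true_Go, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * max(1, max(abs(true_Go))))
    sgs_stop("true_Go must be positive semi-definite", "sgs_config_error")
  dimnames(true_Go) <- list(env_grid$env, env_grid$env)
  nv <- c(tester = 0.05, trial = 0.05, rep = 0.02, block = 0.02)
  nv[names(nuisance_variances)] <- nuisance_variances
  if (any(nv < 0)) sgs_stop("variances must be >= 0", "sgs_config_error")
  locs <- unique(env_grid$location)
  if (is.null(location_effects))
    location_effects <- stats::setNames(0.25 * (seq_along(locs) - 1), locs)
  if (!all(locs %in% names(location_effects)))
    sgs_stop("location_effects must name every location", "sgs_config_error")

  structure(list(
    n_families = n_families, family_size = family_size,
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    chromosome_length_morgans = chromosome_length_morgans,
    n_years = n_years, envs_per_year = envs_per_year, env_grid = env_grid,
    n_testers_per_year = n_testers_per_year, n_trials = n_trials,
    n_reps = as.integer(n_reps), blocks_per_rep = as.integer(blocks_per_rep),
    true_Go = true_Go, residual_variances = stats::setNames(residual_variances, env_grid$env),
    nuisance_variances = nv, mu = mu, location_effects = location_effects,
    founder_reuse = founder_reuse, seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Sparse-testing simulation configuration\n")
  cat(sprintf("  years: %d | families/year: %s | family size: %s\n", x$n_years,
              paste(x$n_families, collapse = "/"), paste(x$family_size, collapse = "/")))
  cat(sprintf("  genome: %d chromosomes x %d markers (%.2f Morgans each)\n",
              x$n_chromosomes, x$markers_per_chromosome, x$chromosome_length_morgans))
  cat(sprintf("  environments: %s\n", paste(x$env_grid$env, collapse = ", ")))
  cat(sprintf("  reps: %d | blocks/rep: %d | seed: %d\n", x$n_reps, x$blocks_per_rep, x$seed))
  invisible(x)
}

#' Simulate founder inbreds and a genetic map
#'
#' Founders are fully inbred (two identical haplotypes), with presence-allele
#' frequencies drawn per marker from U(0.02, 0.98) so that the realized MAF
#' spectrum of their DH progeny straddles the 0.05 filter threshold.
#'
#' @param config a [sim_config()].
#' @return List of class `founder_set` with elements `map` (per-chromosome
#'   strictly increasing positions in Morgans), `haplotypes` (founder x list of
#'   per-chromosome 0/1 vectors) and `founder_ids`.
#' @export
simulate_founders <- function(config) {
  if (!inherits(config, "sim_config")) sgs_stop("config must be a sim_config", "sgs_config_error")
  seeds <- derive_seeds(config$seed, 2L)
  n_fam_total <- sum(config$n_families)
  n_founders <- 2L * n_fam_total
  with_seed(seeds[1L], {
    map <- lapply(seq_len(config$n_chromosomes), function(ch) {
      pos <- sort(stats::runif(config$markers_per_chromosome, 0, config$chromosome_length_morgans))
      while (any(diff(pos) <= 0)) pos <- sort(pos + cumsum(c(0, diff(pos) <= 0)) * 1e-9)
      pos
    })
    freq <- lapply(seq_len(config$n_chromosomes), function(ch)
      stats::runif(config$markers_per_chromosome, 0.02, 0.98))
    haplotypes <- lapply(seq_len(n_founders), function(f)
      lapply(seq_len(config$n_chromosomes), function(ch)
        as.integer(stats::runif(config$markers_per_chromosome) < freq[[ch]])))
  })
  names(haplotypes) <- id_label("P", seq_len(n_founders), n_founders)
  structure(list(map = map, haplotypes = haplotypes,
                 founder_ids = names(haplotypes), n_markers = config$n_chromosomes *
                   config$markers_per_chromosome),
            class = "founder_set")
}

# one recombinant gamete from two parental haplotypes on one chromosome,
# interference-free: crossover count ~ Poisson(length), positions uniform
haldane_gamete <- function(hapA, hapB, pos) {
  L <- pos[length(pos)] - pos[1L]
  n_x <- stats::rpois(1L, max(L, 0))
  start <- stats::rbinom(1L, 1L, 0.5)
  if (n_x == 0L) return(if (start == 0L) hapA else hapB)
  xpos <- sort(stats::runif(n_x, pos[1L], pos[length(pos)]))
  strand <- (start + findInterval(pos, xpos)) %% 2L
  ifelse(strand == 0L, hapA, hapB)
}

#' Simulate a doubled-haploid family from two founders
#'
#' Each DH line is one recombinant gamete of the F1, doubled: crossovers are
#' placed by an interference-free model on genetic distance (Haldane mapping),
#' so adjacent markers d Morgans apart recombine with probability
#' `(1 - exp(-2d)) / 2`. Output uses the dominant 0/2 presence/absence coding
#' and is fully homozygous by construction.
#'
#' @param parent1,parent2 founder haplotypes: lists of per-chromosome 0/1
#'   vectors (one haplotype each; founders are inbred).
#' @param family_size number of DH lines to produce.
#' @param map per-chromosome marker positions (Morgans), as in
#'   [simulate_founders()].
#' @param seed integer seed.
#' @return `family_size` x markers matrix of 0/2 values (no dimnames).
#' @export
simulate_dh_family <- function(parent1, parent2, family_size, map, seed = NULL) {
  if (family_size < 1) sgs_stop("family_size must be >= 1", "sgs_config_error")
  if (length(parent1) != length(map) || length(parent2) != length(map) ||
      any(vapply(seq_along(map), function(ch)
        length(parent1[[ch]]) != length(map[[ch]]) ||
        length(parent2[[ch]]) != length(map[[ch]]), logical(1))))
    sgs_stop("parents must share the marker map", "sgs_config_error")
  with_seed(seed, {
    rows <- vapply(seq_len(family_size), function(i) {
      unlist(lapply(seq_along(map), function(ch)
        haldane_gamete(parent1[[ch]], parent2[[ch]], map[[ch]])))
    }, numeric(sum(lengths(map))))
  })
  t(rows) * 2
}

# symmetric PSD square root via eigendecomposition; errors name the matrix
psd_sqrt <- function(M, name) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  tol <- -1e-8 * max(1, max(abs(e$values)))
  if (min(e$values) < tol)
    sgs_stop(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                     name, min(e$values)), "sgs_numeric_error")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Draw genetic values with Kronecker covariance between environments
#'
#' Draws a lines x environments matrix `u` with
#' `cov(u[, i], u[, j]) = true_Go[i, j] * G`, i.e. `vec(u)` has covariance
#' `true_Go (x) G` under environment-major vectorization.
#'
#' @param G lines x lines relationship matrix (PSD; regularize first if near
#'   singular).
#' @param true_Go environments x environments genetic covariance (PSD).
#' @param seed integer seed.
#' @return Matrix with rownames from `G` and one column per environment.
#' @export
simulate_genetic_values <- function(G, true_Go, seed = NULL) {
  LG <- psd_sqrt(unclass(G), "G")
  Lo <- psd_sqrt(as.matrix(true_Go), "true_Go")
  with_seed(seed, {
    Z <- matrix(stats::rnorm(nrow(G) * nrow(true_Go)), nrow(G), nrow(true_Go))
  })
  u <- LG %*% Z %*% t(Lo)
  dimnames(u) <- list(rownames(G), colnames(true_Go))
  u
}

# pack families into trials in family-contiguous groups; returns per-line trial id
assign_trials <- function(family, n_trials, year_tag) {
  fams <- unique(family)
  fam_trial <- rep(seq_len(n_trials), length.out = length(fams))
  fam_trial <- sort(fam_trial)  # contiguous family groups per trial
  names(fam_trial) <- fams
  paste0(year_tag, "T", sprintf("%02d", fam_trial[family]))
}

#' Simulate plot-level trial phenotypes
#'
#' Builds replicated plot records for every (line, environment) pair flagged in
#' `observed`: `y = mu + location + tester + trial + rep + block + genetic
#' value + residual`, with tester/trial/rep/block effects drawn iid from the
#' configured nuisance variances, rep effects nested in (environment, trial)
#' and block effects nested in (rep, trial); residual variance is
#' per-environment. Lines are packed into trials in family-contiguous groups
#' and re-randomized into incomplete blocks within every replication.
#'
#' @param lines data.frame with columns `line_id`, `family`, `year`.
#' @param genetic_values lines x environments matrix (rownames = line IDs,
#'   colnames = environment labels of `config$env_grid$env`).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param observed optional logical matrix (lines x environments) marking which
#'   cells are phenotyped; default: every line in every environment of its
#'   year.
#' @return data.frame with columns line_id, family, year, location, management,
#'   environment, tester, trial, rep, block, yield.
#' @export
simulate_trial_phenotypes <- function(lines, genetic_values, config, seed = NULL,
                                      observed = NULL) {
  env_grid <- config$env_grid
  if (!all(lines$line_id %in% rownames(genetic_values)))
    sgs_stop("missing genetic value for a phenotyped line", "sgs_integrity_error")
  if (is.null(observed)) {
    observed <- outer(lines$year[match(rownames(genetic_values), lines$line_id)],
                      env_grid$year, "==")
    dimnames(observed) <- list(rownames(genetic_values), env_grid$env)
  }
  nv <- config$nuisance_variances
  with_seed(seed, {
    recs <- vector("list", 0L)
    for (yr_i in seq_len(config$n_years)) {
      yr <- 2016L + yr_i
      yl <- lines[lines$year == yr, , drop = FALSE]
      if (!nrow(yl)) next
      fams <- unique(yl$family)
      tester_of <- stats::setNames(
        paste0("Y", yr_i, "TST", rep(seq_len(config$n_testers_per_year[yr_i]),
                                     length.out = length(fams))), fams)
      tester_eff <- stats::setNames(stats::rnorm(length(unique(tester_of)),
                                                 0, sqrt(nv["tester"])),
                                    unique(tester_of))
      trial_of <- stats::setNames(
        assign_trials(yl$family, config$n_trials[yr_i], paste0("Y", yr_i)), yl$line_id)
      trial_eff <- stats::setNames(stats::rnorm(length(unique(trial_of)), 0,
                                                sqrt(nv["trial"])), unique(trial_of))
      yr_envs <- which(env_grid$year == yr)
      for (e in yr_envs) {
        env <- env_grid$env[e]
        obs_lines <- yl$line_id[observed[yl$line_id, env]]
        if (!length(obs_lines)) next
        for (tr in unique(trial_of[obs_lines])) {
          tl <- obs_lines[trial_of[obs_lines] == tr]
          for (r in seq_len(config$n_reps)) {
            rep_key <- paste(env, tr, paste0("R", r), sep = "_")
            rep_eff <- stats::rnorm(1, 0, sqrt(nv["rep"]))
            ord <- sample(tl)
            blk <- paste0("B", sprintf("%02d", rep(seq_len(config$blocks_per_rep),
                                                   length.out = length(ord),
                                                   each = ceiling(length(ord) / config$blocks_per_rep))[seq_along(ord)]))
            blk_eff <- stats::setNames(stats::rnorm(config$blocks_per_rep, 0,
                                                    sqrt(nv["block"])),
                                       paste0("B", sprintf("%02d", seq_len(config$blocks_per_rep))))
            yvals <- config$mu + config$location_effects[env_grid$location[e]] +
              tester_eff[tester_of[yl$family[match(ord, yl$line_id)]]] +
              trial_eff[tr] + rep_eff + blk_eff[blk] +
              genetic_values[ord, env] +
              stats::rnorm(length(ord), 0, sqrt(config$residual_variances[env]))
            recs[[length(recs) + 1L]] <- data.frame(
              line_id = ord,
              family = yl$family[match(ord, yl$line_id)],
              year = yr, location = env_grid$location[e],
              management = env_grid$management[e], environment = env,
              tester = unname(tester_of[yl$family[match(ord, yl$line_id)]]),
              trial = tr, rep = paste0("R", r), block = blk,
              yield = unname(yvals), stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic sparse-testing dataset
#'
#' Runs the full generator: founders, DH families, marker matrix, genomic
#' relationship matrix (after the MAF > 0.05 filter), genetic values from the
#' Kronecker covariance `true_Go (x) G`, and replicated plot phenotypes. All
#' randomness derives from `config$seed`, so identical configurations yield
#' identical datasets.
#'
#' @param config a [sim_config()].
#' @return List of class `synthetic_dataset`: `markers` (a [marker_matrix()]
#'   with all simulated markers), `phenotypes`, `true_values` (lines x
#'   environments), `grm` (the regularized kernel the values were drawn from),
#'   `lines` (line/family/year table) and the `config`.
#' @export
simulate_trial_data <- function(config) {
  if (!inherits(config, "sim_config")) sgs_stop("config must be a sim_config", "sgs_config_error")
  founders <- simulate_founders(config)
  seeds <- derive_seeds(config$seed, 4L + sum(config$n_families))
  fam_seed <- seeds[seq_len(sum(config$n_families)) + 4L]

  n_fam_total <- sum(config$n_families)
  fam_year <- rep(seq_len(config$n_years), config$n_families)
  # founder pairs: default pairing walks the founder list; later years may
  # reuse earlier founders to create historical relatedness
  pair <- matrix(rep(seq_len(2L * n_fam_total), length.out = 2L * n_fam_total),
                 ncol = 2L, byrow = TRUE)
  if (config$n_years > 1L) {
    with_seed(seeds[1L], {
      for (f in which(fam_year > 1L)) {
        prev <- seq_len(2L * sum(config$n_families[seq_len(fam_year[f] - 1L)]))
        if (stats::runif(1) < config$founder_reuse)
          pair[f, 1L] <- sample(prev, 1L)
        if (stats::runif(1) < config$founder_reuse)
          pair[f, 2L] <- sample(prev[prev != pair[f, 1L]], 1L)
      }
    })
  }

  mk <- vector("list", n_fam_total); fam_lab <- character(n_fam_total)
  lines_tab <- vector("list", n_fam_total)
  fam_in_year <- unlist(lapply(config$n_families, seq_len))
  for (f in seq_len(n_fam_total)) {
    yr_i <- fam_year[f]
    fam_lab[f] <- sprintf("Y%d_F%02d", yr_i, fam_in_year[f])
    fs <- config$family_size[yr_i]
    m <- simulate_dh_family(founders$haplotypes[[pair[f, 1L]]],
                            founders$haplotypes[[pair[f, 2L]]],
                            fs, founders$map, seed = fam_seed[f])
    rownames(m) <- paste0(fam_lab[f], "_", id_label("L", seq_len(fs), fs))
    mk[[f]] <- m
    lines_tab[[f]] <- data.frame(line_id = rownames(m), family = fam_lab[f],
                                 year = 2016L + yr_i, stringsAsFactors = FALSE)
  }
  markers_all <- do.call(rbind, mk)
  colnames(markers_all) <- id_label("M", seq_len(ncol(markers_all)), ncol(markers_all))
  lines <- do.call(rbind, lines_tab)
  markers <- marker_matrix(markers_all, rep(fam_lab, vapply(mk, nrow, integer(1))))

  G <- regularize_grm(compute_grm(filter_markers(markers, 0.05)), 1e-6)
  true_values <- simulate_genetic_values(G, config$true_Go, seed = seeds[2L])
  phenotypes <- simulate_trial_phenotypes(lines, true_values, config, seed = seeds[3L])
  structure(list(markers = markers, phenotypes = phenotypes,
                 true_values = true_values, grm = G, lines = lines,
                 config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic sparse-testing dataset: %d lines, %d markers, %d plot records\n",
              nrow(x$markers), ncol(x$markers), nrow(x$phenotypes)))
  cat(sprintf("  environments: %s\n", paste(colnames(x$true_values), collapse = ", ")))
  invisible(x)
}
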