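# Multi-environment GBLUP: user-facing fit and methods.

#' Fit a multi-environment GBLUP model by REML
#'
#' Fits the mixed model `y = mu + location + u_genetic + u_tester + u_trial +
#' u_rep + u_block + e` to plot-level records, where the genetic effect of
#' line g in environment v has covariance `Go (x) G` between (line,
#' environment) pairs: `G` is the genomic relationship matrix and `Go` the
#' environments' genetic covariance. `Go` may be unstructured (`"US"`),
#' factor-analytic (`"FA"`, `Go = Lambda Lambda' + Psi` with `m` latent
#' factors), or diagonal (`"DIAG"`, a no-borrowing baseline). Residual
#' variances are heterogeneous per analysis environment; tester, trial,
#' replication-within-(environment, trial) and block-within-replication
#' effects are iid.
#'
#' Estimation is EM-REML with average-information acceleration; EM steps
#' guarantee the restricted likelihood never decreases, AI steps speed up
#' convergence and fall back to EM when they would overshoot. Balanced designs
#' (every line the same number of plots in every environment) are detected and
#' solved through the eigendecomposition of `G`, which makes large
#' full-observation fits cheap; any missingness pattern is handled by a
#' general dense solver. Non-convergence within `max_iter` is reported via the
#' `converged` flag, never silently ignored.
#'
#' @param pheno phenotype data.frame with columns line_id, family, year,
#'   location, management, environment, tester, trial, rep, block, yield.
#' @param K genomic relationship matrix covering every phenotyped line
#'   (rownames = line IDs). Near-singular matrices are ridge-regularized
#'   automatically (see [regularize_grm()]).
#' @param grouping environment classification scheme (see [env_grouping()]).
#' @param structure covariance structure for `Go`: `"FA"`, `"US"` or `"DIAG"`.
#' @param m number of latent FA factors; default 1 for fewer than 4
#'   environments, 2 for 4-6.
#' @param random nuisance terms to include.
#' @param tol convergence tolerance on the change in REML log-likelihood.
#' @param max_iter maximum REML iterations.
#' @param method `"auto"` (AI with EM fallback; FA always uses EM), `"ai"`, or
#'   `"em"` (pure EM, monotone likelihood).
#' @param init optional list with elements `Go`, `sig_p`, `sig_e` to start
#'   from.
#' @param verbose print per-iteration log-likelihoods.
#' @return An object of class `me_gblup` with components `Go` (estimated
#'   genetic covariance), `Lambda`/`Psi` (FA only), `sigma2_nuisance`,
#'   `sigma2_resid`, `beta` (fixed effects), `gebv` (lines x environments
#'   BLUPs), `logLik`, `converged`, and bookkeeping. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `simulate`, `plot`,
#'   `logLik`; see also [heritability()] and [genetic_correlations()].
#' @export
#' @examples
#' cfg <- sim_config(n_families = 4, family_size = 12, n_chromosomes = 3,
#'                   markers_per_chromosome = 30, n_trials = 2, seed = 7)
#' dat <- simulate_trial_data(cfg)
#' fit <- me_gblup(dat$phenotypes, dat$grm, grouping = "LM", structure = "FA",
#'                 max_iter = 50)
#' heritability(fit)
me_gblup <- function(pheno, K, grouping = "LM",
                     structure = c("FA", "US", "DIAG"), m = NULL,
                     random = c("tester", "trial", "rep", "block"),
                     tol = 1e-6, max_iter = 200L,
                     method = c("auto", "ai", "em"), init = NULL,
                     verbose = FALSE) {
  structure <- match.arg(structure)
  method <- match.arg(method)
  cl <- match.call()
  design <- if (inherits(pheno, "me_design")) pheno else build_design(pheno, grouping, random)
  K <- as.matrix(K)
  if (is.null(rownames(K))) sgs_stop("K needs line IDs as rownames", "sgs_input_error")
  ok <- tryCatch({ chol(K); TRUE }, error = function(e) FALSE)
  if (!ok) {
    message("relationship matrix is singular; adding ridge 1e-6 to the diagonal")
    K <- regularize_grm(unclass(K), 1e-6)
  }
  fit <- reml_engine(design, K, structure = structure, m = m, tol = tol,
                     max_iter = max_iter, method = method, init = init,
                     verbose = verbose)
  fit$call <- cl
  fit$grouping <- design$grouping$scheme
  fit$env_levels <- design$env_levels
  fit$meta <- design$meta
  fit$K <- K
  fit$n <- design$n
  fit$dropped <- design$dropped
  if (!fit$converged) {
    dl <- if (length(fit$logLik_trace) >= 2)
      sprintf(" (last |dlogL| = %.3g)", abs(diff(utils::tail(fit$logLik_trace, 2))))
    else ""
    warning(sprintf("REML did not converge in %d iterations%s", fit$n_iter, dl))
  }
  class(fit) <- "me_gblup"
  fit
}

#' Per-environment plot heritability from a fitted model
#'
#' `h2_v = sigma2_g(v) / (sigma2_g(v) + sigma2_e(v))`, with the genetic
#' variance taken from the diagonal of the estimated `Go` and the residual
#' variance from the environment's residual component.
#'
#' @param fit an [me_gblup()] fit.
#' @return Named numeric vector of heritabilities; `NA` where the total
#'   variance is zero.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "me_gblup"))
  sg <- diag(fit$Go); se <- fit$sigma2_resid
  tot <- sg + se
  out <- ifelse(tot > 0, sg / tot, NA_real_)
  stats::setNames(out, fit$env_levels)
}

#' Genetic correlations between environments from a fitted model
#'
#' @param fit an [me_gblup()] fit.
#' @return v x v correlation matrix with unit diagonal; rows/columns of
#'   zero-variance environments are `NA`.
#' @export
genetic_correlations <- function(fit) {
  stopifnot(inherits(fit, "me_gblup"))
  sg <- diag(fit$Go)
  R <- fit$Go / sqrt(outer(sg, sg))
  R[!is.finite(R)] <- NA_real_
  diag(R) <- ifelse(sg > 0, 1, NA_real_)
  R
}

#' @export
print.me_gblup <- function(x, ...) {
  cat(sprintf("Multi-environment GBLUP (%s covariance%s, %s grouping)\n",
              x$structure, if (!is.null(x$m)) paste0(", m = ", x$m) else "",
              x$grouping))
  cat(sprintf("  %d records, %d lines, %d environments; %s in %d iterations (logL %.3f)\n",
              x$n, nrow(x$gebv), length(x$env_levels),
              if (x$converged) "converged" else "NOT converged", x$n_iter, x$logLik))
  cat("  heritability:", paste(sprintf("%s %.2f", x$env_levels, heritability(x)),
                               collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.me_gblup <- function(object, ...) {
  out <- list(
    structure = object$structure, m = object$m, grouping = object$grouping,
    Go = object$Go, h2 = heritability(object),
    correlations = genetic_correlations(object),
    sigma2_resid = object$sigma2_resid,
    sigma2_nuisance = object$sigma2_nuisance,
    beta = object$beta, logLik = object$logLik, converged = object$converged,
    n_iter = object$n_iter, n = object$n, pinned = object$pinned,
    Lambda = object$Lambda, Psi = object$Psi)
  class(out) <- "summary.me_gblup"
  out
}

#' @export
print.summary.me_gblup <- function(x, ...) {
  cat(sprintf("Multi-environment GBLUP, %s covariance, %s grouping\n",
              x$structure, x$grouping))
  cat(sprintf("REML logL %.4f after %d iterations (%s)\n", x$logLik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("\nGenetic covariance between environments (Go):\n")
  print(round(x$Go, 4))
  cat("\nGenetic correlations (off-diagonal) / plot heritability (diagonal):\n")
  M <- x$correlations; diag(M) <- x$h2
  print(round(M, 3))
  cat("\nResidual variances:\n"); print(round(x$sigma2_resid, 4))
  if (length(x$sigma2_nuisance)) {
    cat("\nNuisance variances:\n"); print(round(x$sigma2_nuisance, 4))
  }
  cat("\nFixed effects:\n"); print(round(x$beta, 4))
  if (length(x$pinned))
    cat("\nComponents pinned at the variance floor:", paste(x$pinned, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.me_gblup <- function(object, ...) object$beta

#' Predict genomic estimated breeding values
#'
#' Returns the BLUPs of the genetic effect for every line in every analysis
#' environment. For lines present in `K` but absent from the fitted
#' relationship matrix, predictions propagate through genomic relationship:
#' `u_new = K[new, fit] K[fit, fit]^-1 u_fit` per environment.
#'
#' @param object an [me_gblup()] fit.
#' @param K optional relationship matrix containing the fitted lines plus new
#'   lines to predict.
#' @param ... unused.
#' @return Matrix of GEBVs (lines x environments).
#' @export
predict.me_gblup <- function(object, K = NULL, ...) {
  if (is.null(K)) return(object$gebv)
  K <- as.matrix(K)
  fit_ids <- rownames(object$gebv)
  miss <- setdiff(fit_ids, rownames(K))
  if (length(miss))
    sgs_stop(paste0("K lacks fitted line(s): ", paste(utils::head(miss, 5), collapse = ", ")),
             "sgs_join_error")
  new_ids <- setdiff(rownames(K), fit_ids)
  out <- matrix(NA_real_, nrow(K), ncol(object$gebv),
                dimnames = list(rownames(K), colnames(object$gebv)))
  out[fit_ids, ] <- object$gebv
  if (length(new_ids)) {
    Kff <- object$K[fit_ids, fit_ids]
    out[new_ids, ] <- K[new_ids, fit_ids, drop = FALSE] %*%
      solve(Kff, object$gebv)
  }
  out
}

#' @export
fitted.me_gblup <- function(object, ...) object$fitted

#' @export
residuals.me_gblup <- function(object, ...) object$residuals

#' @export
logLik.me_gblup <- function(object, ...) {
  npar <- length(object$sigma2_resid) + length(object$sigma2_nuisance) +
    if (object$structure == "FA") {
      length(object$Psi) + sum(!upper.tri(object$Lambda))
    } else if (object$structure == "DIAG") ncol(object$Go) else
      ncol(object$Go) * (ncol(object$Go) + 1) / 2
  structure(object$logLik, df = npar, class = "logLik")
}

#' Simulate phenotype vectors from a fitted model
#'
#' Draws new response vectors at the fitted design and REML estimates:
#' genetic effects from `Go (x) K`, nuisance effects and residuals from their
#' estimated variances, fixed effects at their estimates.
#'
#' @param object an [me_gblup()] fit.
#' @param nsim number of replicate response vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns, one row per fitted record.
#' @export
simulate.me_gblup <- function(object, nsim = 1, seed = NULL, ...) {
  design_env <- match(object$meta$env, object$env_levels)
  line_idx <- match(object$meta$line_id, rownames(object$K))
  # non-genetic surface (fixed effects + nuisance BLUPs); genetic effects and
  # residuals are redrawn from their estimated covariances
  Xb <- object$fitted - object$gebv[cbind(line_idx, design_env)]
  with_seed(seed, {
    out <- matrix(NA_real_, object$n, nsim)
    for (s in seq_len(nsim)) {
      u <- simulate_genetic_values(object$K, object$Go,
                                   seed = sample.int(.Machine$integer.max - 1L, 1L))
      e <- stats::rnorm(object$n, 0, sqrt(object$sigma2_resid[design_env]))
      out[, s] <- Xb + u[cbind(line_idx, design_env)] + e
    }
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.me_gblup <- function(x, which = c("trace", "correlation"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if ("trace" %in% which) {
    graphics::plot(seq_along(x$logLik_trace), x$logLik_trace, type = "b",
                   xlab = "REML iteration", ylab = "log-likelihood",
                   main = "Convergence", pch = 20)
  }
  if ("correlation" %in% which) {
    R <- genetic_correlations(x)
    v <- ncol(R)
    graphics::image(seq_len(v), seq_len(v), t(R[v:1, , drop = FALSE]),
                    zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                    main = "Genetic correlations",
                    col = grDevices::hcl.colors(21, "Blue-Red 3", rev = TRUE))
    graphics::axis(1, seq_len(v), colnames(R), las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(v), rev(rownames(R)), las = 2, cex.axis = 0.7)
  }
  invisible(x)
}
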