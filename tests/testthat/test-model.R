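# Environment grouping, design construction and the REML engine.

test_that("grouping schemes reproduce the environment classifications", {
  g <- env_grouping("LM")
  expect_equal(g$fun(c("Kiboko", "Kakamega", "Kiboko"), c("WW", "WW", "WS"), 2017),
               c("Kiboko_WW", "Kakamega_WW", "Kiboko_WS"))
  expect_equal(env_grouping("M")$fun("Kiboko", c("WW", "WS"), 2017), c("WW", "WS"))
  expect_equal(env_grouping("MY")$fun("Kiboko", "WW", c(2017, 2018)),
               c("WW_2017", "WW_2018"))
  expect_equal(env_grouping("LMY")$fun("Kiboko", "WW", 2018), "Kiboko_WW_2018")
  expect_error(env_grouping("XY"))
})

test_that("design construction relabels environments and drops degenerate terms", {
  dat <- small_dataset(seed = 2)
  d <- build_design(dat$phenotypes, "LM")
  expect_equal(length(d$env_levels), 3L)
  expect_setequal(d$env_levels, c("Kiboko_WW", "Kakamega_WW", "Kiboko_WS"))
  # management grouping merges the two WW locations into one level
  dm <- build_design(dat$phenotypes, "M")
  expect_setequal(dm$env_levels, c("WW", "WS"))
  ww_recs <- dat$phenotypes$management == "WW"
  expect_true(all(dm$meta$env[ww_recs] == "WW"))
  # a single-tester dataset drops the tester term with a message
  ph1 <- dat$phenotypes
  ph1$tester <- "T1"
  expect_message(d1 <- build_design(ph1, "LM"), "tester")
  expect_false("tester" %in% names(d1$s_blocks))
  # multi-year data reject single-year schemes
  cfg2 <- sim_config(n_families = c(2, 2), family_size = 6, n_years = 2,
                     n_chromosomes = 2, markers_per_chromosome = 20, seed = 3)
  dat2 <- simulate_trial_data(cfg2)
  expect_error(build_design(dat2$phenotypes, "LM"), class = "sgs_config_error")
  expect_silent(build_design(dat2$phenotypes, "LMY"))
  # missing column is named
  expect_error(build_design(dat$phenotypes[, -10], "LM"), "block",
               class = "sgs_schema_error")
})

test_that("single-environment REML matches the eigen-decomposition oracle", {
  cfg <- sim_config(n_families = 6, family_size = 30, n_chromosomes = 5,
                    markers_per_chromosome = 40,
                    envs_per_year = data.frame(location = "Kiboko", management = "WW"),
                    n_trials = 1, n_reps = 1, blocks_per_rep = 1,
                    n_testers_per_year = 1, h2 = 0.4,
                    nuisance_variances = c(tester = 0, trial = 0, rep = 0, block = 0),
                    location_effects = c(Kiboko = 0), seed = 13)
  dat <- simulate_trial_data(cfg)
  y_line <- setNames(dat$phenotypes$yield, dat$phenotypes$line_id)[rownames(dat$grm)]
  oracle <- single_kernel_reml(y_line, dat$grm)
  fit <- me_gblup(dat$phenotypes, dat$grm, grouping = "LM", structure = "US",
                  random = character(0), tol = 1e-10, max_iter = 500)
  expect_lt(abs(fit$Go[1, 1] - oracle["sig_g"]), 1e-4)
  expect_lt(abs(fit$sigma2_resid[[1]] - oracle["sig_e"]), 1e-4)
  expect_lt(abs(fit$beta[[1]] - oracle["mu"]), 1e-4)
})

test_that("the balanced and general solvers agree to numerical precision", {
  dat <- small_dataset(seed = 6)
  design <- build_design(dat$phenotypes, "LM")
  prep <- sparsegs:::reml_prepare(design, dat$grm)
  expect_true(prep$balanced)
  theta <- sparsegs:::init_theta(design, prep)
  sf <- sparsegs:::fast_solve(sparsegs:::fast_backend(design, dat$grm, prep),
                              design, prep, theta)
  sd_ <- sparsegs:::dense_solve(sparsegs:::dense_backend(design, dat$grm, prep),
                                design, prep, theta)
  expect_equal(sf$logL, sd_$logL, tolerance = 1e-9)
  expect_equal(sf$u1, sd_$u1, tolerance = 1e-9)
  expect_equal(sf$T, sd_$T, tolerance = 1e-9)
  expect_equal(sf$lev, sd_$lev, tolerance = 1e-9)
  expect_equal(sf$trS, sd_$trS, tolerance = 1e-9)
})

test_that("EM iterations never decrease the restricted likelihood", {
  dat <- small_dataset(seed = 12)
  fit <- suppressWarnings(me_gblup(dat$phenotypes, dat$grm, grouping = "LM",
                                   structure = "US", method = "em",
                                   max_iter = 60, tol = 0))
  expect_true(all(diff(fit$logLik_trace) > -1e-8))
  # and on an unbalanced (sparse-tested) pattern through the general solver
  ph <- dat$phenotypes
  drop_lines <- unique(ph$line_id)[seq(1, 50, by = 2)]
  ph <- ph[!(ph$line_id %in% drop_lines & ph$environment == ph$environment[1]), ]
  fit2 <- suppressWarnings(me_gblup(ph, dat$grm, grouping = "LM", structure = "US",
                                    method = "em", max_iter = 60, tol = 0))
  expect_false(fit2$balanced)
  expect_true(all(diff(fit2$logLik_trace) > -1e-8))
})

test_that("estimates are invariant to record order", {
  dat <- small_dataset(seed = 15)
  fit1 <- me_gblup(dat$phenotypes, dat$grm, grouping = "LM", structure = "US",
                   tol = 1e-8, max_iter = 500)
  set.seed(1)
  shuf <- dat$phenotypes[sample(nrow(dat$phenotypes)), ]
  fit2 <- me_gblup(shuf, dat$grm, grouping = "LM", structure = "US", tol = 1e-8,
                   max_iter = 500)
  # the likelihood is flat near the optimum in weakly identified directions,
  # so parameters agree only to the scale implied by the logL tolerance
  expect_lt(max(abs(fit1$Go - fit2$Go)), 0.01)
  expect_lt(max(abs(heritability(fit1) - heritability(fit2))), 0.005)
  expect_lt(max(abs(fit1$sigma2_resid - fit2$sigma2_resid)), 0.01)
  expect_gt(min(diag(cor(fit1$gebv, fit2$gebv))), 0.9999)
})

test_that("a fully correlated model collapses to main-effect GBLUP", {
  dat <- small_dataset(seed = 18, n_families = 3, family_size = 10)
  ph <- dat$phenotypes[dat$phenotypes$management == "WW", ]
  G <- dat$grm
  s2 <- 0.4; se <- 0.9
  Go <- s2 * (matrix(1, 2, 2) + diag(1e-8, 2))
  suppressWarnings(fit <- me_gblup(
    ph, G, grouping = "LM", structure = "US", random = character(0),
    init = list(Go = Go, sig_p = numeric(0), sig_e = c(se, se)), max_iter = 0))
  # main-effect oracle: one genetic effect per line across both environments
  ids <- rownames(G)
  Z <- outer(ph$line_id, ids, "==") * 1
  X <- stats::model.matrix(~factor(ph$location))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + (se / s2) * solve(G)))
  sol <- solve(C, c(crossprod(X, ph$yield), crossprod(Z, ph$yield)))
  u_main <- sol[-seq_len(ncol(X))]
  expect_lt(max(abs(fit$gebv[, 1] - u_main)), 1e-4)
  expect_lt(max(abs(fit$gebv[, 2] - u_main)), 1e-4)
})

test_that("factor-analytic and unstructured fits coincide for two environments", {
  dat <- small_dataset(seed = 22, n_families = 5, family_size = 20)
  ph <- dat$phenotypes[dat$phenotypes$location == "Kiboko", ]
  fus <- me_gblup(ph, dat$grm, grouping = "LM", structure = "US", tol = 1e-8,
                  max_iter = 500)
  ffa <- me_gblup(ph, dat$grm, grouping = "LM", structure = "FA", m = 1,
                  tol = 1e-8, max_iter = 800)
  expect_lt(abs(fus$logLik - ffa$logLik), 1e-3)
  expect_lt(abs(genetic_correlations(fus)[1, 2] - genetic_correlations(ffa)[1, 2]),
            0.01)
  expect_equal(ffa$Go, tcrossprod(ffa$Lambda) + diag(ffa$Psi, 2),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("predictions propagate through relationships and respect duplicates", {
  dat <- small_dataset(seed = 25, n_families = 3, family_size = 10)
  G <- dat$grm
  # append an unrelated line and a duplicate of a fitted line, unphenotyped
  n <- nrow(G)
  K <- rbind(cbind(G, 0, G[, 7]), 0, c(G[7, ], 0, G[7, 7]))
  K[n + 1, n + 1] <- mean(diag(G))
  ids <- c(rownames(G), "UNREL", "DUP7")
  dimnames(K) <- list(ids, ids)
  fit <- me_gblup(dat$phenotypes, G, grouping = "LM", structure = "US", tol = 1e-7)
  pr <- predict(fit, K)
  expect_equal(pr[rownames(G), ], fit$gebv)
  expect_lt(max(abs(pr["UNREL", ])), 1e-8)   # shrunk to the prior mean
  expect_equal(pr["DUP7", ], fit$gebv[7, ], tolerance = 1e-6)
  expect_error(predict(fit, K[-3, -3]), class = "sgs_join_error")
})

test_that("heritability and genetic correlations follow their definitions", {
  fake <- structure(list(
    Go = matrix(c(1, 0.5, 0.5, 4), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B"))),
    sigma2_resid = c(A = 1, B = 0), env_levels = c("A", "B")),
    class = "me_gblup")
  expect_equal(unname(heritability(fake)), c(0.5, 1))
  expect_equal(genetic_correlations(fake)[1, 2], 0.25)
  fake$Go <- matrix(c(0.3, 0, 0, 0), 2, 2, dimnames = dimnames(fake$Go))
  fake$sigma2_resid <- c(A = 0.7, B = 1)
  expect_equal(unname(heritability(fake)), c(0.3, 0))
  expect_true(is.na(genetic_correlations(fake)[1, 2]))
  # rank-one genetic covariance means |correlation| 1 everywhere
  L <- c(0.6, -0.2, 0.9)
  fake2 <- structure(list(Go = tcrossprod(L), sigma2_resid = rep(1, 3),
                          env_levels = c("a", "b", "c")), class = "me_gblup")
  expect_equal(abs(genetic_correlations(fake2)[upper.tri(diag(3))]), rep(1, 3))
})

test_that("fit methods expose the expected quantities", {
  dat <- small_dataset(seed = 28, n_families = 3, family_size = 8)
  fit <- suppressWarnings(me_gblup(dat$phenotypes, dat$grm, grouping = "LM",
                                   structure = "FA", tol = 1e-6, max_iter = 200))
  expect_output(print(fit), "Multi-environment GBLUP")
  expect_output(print(summary(fit)), "Genetic covariance")
  expect_named(coef(fit))
  expect_equal(fitted(fit) + residuals(fit), dat$phenotypes$yield)
  expect_s3_class(logLik(fit), "logLik")
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(dim(sims), c(nrow(dat$phenotypes), 2L))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 9))
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  # non-convergence is reported, never silent
  expect_warning(me_gblup(dat$phenotypes, dat$grm, structure = "US",
                          max_iter = 2), "did not converge")
})
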