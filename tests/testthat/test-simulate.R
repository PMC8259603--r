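# Synthetic-data generator: founders, DH meiosis, genetic values, phenotypes.

test_that("founder simulation obeys the dimension contract and seeding", {
  cfg <- sim_config(n_families = 3, family_size = 10, n_chromosomes = 2,
                    markers_per_chromosome = 50, seed = 1)
  f1 <- simulate_founders(cfg)
  expect_length(f1$haplotypes, 6L)            # 2 founders per family
  expect_length(f1$haplotypes[[1]], 2L)       # per-chromosome haplotypes
  expect_equal(f1$n_markers, 100L)
  expect_true(all(vapply(f1$map, function(p) all(diff(p) > 0), logical(1))))
  expect_identical(f1, simulate_founders(cfg))  # determinism
  cfg2 <- sim_config(n_families = 3, family_size = 10, n_chromosomes = 2,
                     markers_per_chromosome = 50, seed = 2)
  expect_false(identical(simulate_founders(cfg2)$haplotypes, f1$haplotypes))
})

test_that("DH lines are homozygous recombinants with balanced segregation", {
  cfg <- sim_config(n_families = 2, family_size = 10, n_chromosomes = 1,
                    markers_per_chromosome = 50, seed = 5)
  f <- simulate_founders(cfg)
  # identical parents: no segregation
  same <- simulate_dh_family(f$haplotypes[[1]], f$haplotypes[[1]], 5, f$map, seed = 3)
  expect_true(all(same == rep(2 * unlist(f$haplotypes[[1]]), each = 5)))
  # fully informative cross: presence frequency near 0.5 at every marker
  p1 <- list(rep(0L, 50)); p2 <- list(rep(1L, 50))
  fam <- simulate_dh_family(p1, p2, 2000, f$map, seed = 7)
  expect_true(all(fam %in% c(0, 2)))
  freq <- colMeans(fam) / 2
  se3 <- 3 * 0.5 / sqrt(2000)
  expect_lt(abs(mean(freq) - 0.5), se3)
  expect_error(simulate_dh_family(p1, p2, 0, f$map), class = "sgs_config_error")
})

test_that("recombination between adjacent markers follows the Haldane map", {
  map <- list(c(0.50, 0.51))  # 0.01 Morgans apart
  p1 <- list(c(0L, 0L)); p2 <- list(c(1L, 1L))
  fam <- simulate_dh_family(p1, p2, 5000, map, seed = 11)
  rec <- mean(fam[, 1] != fam[, 2])
  c_expected <- (1 - exp(-0.02)) / 2
  se <- sqrt(c_expected * (1 - c_expected) / 5000)
  expect_lt(abs(rec - c_expected), 3.5 * se)
})

test_that("genetic values realize the requested Kronecker covariance", {
  G <- random_family_grm(40, seed = 3)
  zeroGo <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(all(simulate_genetic_values(G, zeroGo, seed = 1) == 0))
  # independent environments: near-zero cross-environment correlation
  I2 <- diag(2); dimnames(I2) <- list(c("a", "b"), c("a", "b"))
  In <- diag(40); rownames(In) <- colnames(In) <- rownames(G)
  set.seed(99)
  rs <- replicate(200, {
    u <- simulate_genetic_values(In, I2, seed = sample.int(1e6, 1))
    cor(u[, 1], u[, 2])
  })
  expect_lt(abs(mean(rs)), 0.05)
  # strong configured correlation is recovered empirically
  Go <- matrix(c(1, 0.9 * sqrt(2), 0.9 * sqrt(2), 2), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  u <- simulate_genetic_values(diag(5000), Go, seed = 12)
  expect_lt(abs(cor(u[, 1], u[, 2]) - 0.9), 0.03)
  bad <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = dimnames(Go))
  expect_error(simulate_genetic_values(G, bad, seed = 1), "true_Go",
               class = "sgs_numeric_error")
})

test_that("plot records decompose into the configured effects", {
  # all variance components zero: y = mu + genetic value exactly
  cfg <- sim_config(n_families = 2, family_size = 10, n_chromosomes = 2,
                    markers_per_chromosome = 30, n_trials = 1,
                    residual_variances = 0,
                    nuisance_variances = c(tester = 0, trial = 0, rep = 0, block = 0),
                    location_effects = c(Kiboko = 0, Kakamega = 0),
                    mu = 5, h2 = 0.3, seed = 8)
  dat <- simulate_trial_data(cfg)
  ph <- dat$phenotypes
  gv <- dat$true_values[cbind(ph$line_id, ph$environment)]
  expect_equal(ph$yield, 5 + gv, tolerance = 1e-12)
  # count contract: lines x environments x reps
  expect_equal(nrow(ph), 20 * 3 * 2)
})

test_that("realized residual variance matches the configured value", {
  cfg <- sim_config(n_families = 4, family_size = 170, n_chromosomes = 2,
                    markers_per_chromosome = 30, n_trials = 2,
                    residual_variances = c(0.8, 1.0, 1.2), h2 = 0.3, seed = 10)
  dat <- simulate_trial_data(cfg)
  ph <- dat$phenotypes
  # subtract every simulated effect except the residual by refitting the
  # record against its own generating components
  for (env in colnames(dat$true_values)) {
    d <- ph[ph$environment == env, ]
    keys <- interaction(d$tester, d$trial, d$rep, d$block, drop = TRUE)
    resid <- d$yield - dat$true_values[cbind(d$line_id, d$environment)]
    resid <- resid - ave(resid, keys)  # removes mu + location + all nuisance draws
    n_keys <- nlevels(keys)
    s2 <- sum(resid^2) / (length(resid) - n_keys)
    expect_lt(abs(s2 / cfg$residual_variances[env] - 1), 0.10)
  }
})

test_that("datasets are deterministic, strictly 0/2, and consistent with the config", {
  cfg <- sim_config(n_families = 3, family_size = 8, n_chromosomes = 2,
                    markers_per_chromosome = 25, seed = 21)
  d1 <- simulate_trial_data(cfg)
  d2 <- simulate_trial_data(cfg)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(unclass(d1$markers), unclass(d2$markers))
  expect_true(all(unclass(d1$markers) %in% c(0, 2)))
  expect_equal(ncol(d1$true_values), nrow(cfg$true_Go))
  expect_setequal(unique(d1$phenotypes$environment), colnames(cfg$true_Go))
  # every phenotyped line is genotyped
  expect_true(all(d1$phenotypes$line_id %in% rownames(d1$markers)))
})

test_that("multi-year configs produce year-specific lines with shared founders", {
  cfg <- sim_config(n_families = c(3, 4), family_size = c(8, 8), n_years = 2,
                    n_chromosomes = 2, markers_per_chromosome = 25,
                    founder_reuse = 1, seed = 33)
  dat <- simulate_trial_data(cfg)
  expect_equal(ncol(dat$true_values), 6L)
  expect_setequal(unique(dat$lines$year), c(2017L, 2018L))
  # lines are phenotyped only in their own year's environments
  ph <- dat$phenotypes
  yr <- dat$lines$year[match(ph$line_id, dat$lines$line_id)]
  expect_true(all(yr == ph$year))
})
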