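# BLUEs, masking schemes, historical augmentation and the CV driver.

test_that("BLUEs equal per-line means in balanced noise-free designs", {
  cfg <- sim_config(n_families = 2, family_size = 8, n_chromosomes = 2,
                    markers_per_chromosome = 25, n_trials = 1, blocks_per_rep = 1,
                    residual_variances = 0.2,
                    nuisance_variances = c(tester = 0, trial = 0, rep = 0, block = 0),
                    seed = 41)
  dat <- simulate_trial_data(cfg)
  bl <- compute_blues(dat$phenotypes)
  ph <- dat$phenotypes
  for (env in unique(ph$environment)) {
    d <- ph[ph$environment == env, ]
    mn <- tapply(d$yield, d$line_id, mean)
    b <- bl$blue[bl$environment == env][match(names(mn), bl$line_id[bl$environment == env])]
    expect_equal(unname(b), as.vector(mn), tolerance = 1e-8)
  }
  # environment subset is honored and lines without plots get no BLUE
  bl1 <- compute_blues(ph, environments = unique(ph$environment)[1])
  expect_equal(unique(bl1$environment), unique(ph$environment)[1])
})

test_that("CV1 masks reproduce the half-and-half family pattern", {
  lines <- data.frame(line_id = sprintf("L%03d", 1:120),
                      family = rep(sprintf("F%02d", 1:12), each = 10))
  plans <- make_cv1_masks(lines, c("WW_A", "WW_B"), "WS", n_repeats = 10, seed = 4)
  expect_length(plans, 10L)
  for (plan in plans) {
    gr <- attr(plan, "groups")
    expect_length(gr$A, 6L)               # 6/6 family split in WW
    expect_length(gr$B, 6L)
    expect_length(gr$ws_masked, 6L)       # 3 + 3 families masked in WS
    expect_length(intersect(gr$A, gr$B), 0L)
    # family-level masking: every line of a masked family is masked
    for (env in c("WW_A", "WW_B")) {
      sub <- plan[plan$environment == env, ]
      st <- tapply(sub$status, sub$family, function(x) length(unique(x)))
      expect_true(all(st == 1))
    }
    # every family observed in exactly one WW environment
    obs_ww <- plan[plan$environment %in% c("WW_A", "WW_B") & plan$status == "observed", ]
    expect_equal(sort(unique(obs_ww$family)), sprintf("F%02d", 1:12))
    expect_true(all(table(unique(obs_ww[c("family", "environment")])$family) == 1))
  }
  expect_identical(plans, make_cv1_masks(lines, c("WW_A", "WW_B"), "WS",
                                         n_repeats = 10, seed = 4))
  expect_false(identical(plans[[1]],
                         make_cv1_masks(lines, c("WW_A", "WW_B"), "WS", 1, seed = 5)[[1]]))
})

test_that("CV2 masks realize the calibration split exactly", {
  ww <- c("WW_A", "WW_B")
  splits <- list(
    F1 = split_family_cv2(data.frame(line_id = sprintf("a%02d", 1:9),
                                     cdmean = 9:1 / 10), ww),
    F2 = split_family_cv2(data.frame(line_id = sprintf("b%02d", 1:4),
                                     cdmean = c(.1, .4, .3, .2)), ww))
  plan <- make_cv2_masks(splits, "WS")
  # every line observed in exactly one WW environment
  obs <- plan[plan$status == "observed" & plan$environment %in% ww, ]
  expect_equal(sort(table(obs$line_id)), sort(setNames(rep(1L, 13),
                                                       c(sprintf("a%02d", 1:9),
                                                         sprintf("b%02d", 1:4)))),
               ignore_attr = TRUE)
  # WS-observed lines come from both WW groups per family
  ws_obs <- plan$line_id[plan$environment == "WS" & plan$status == "observed"]
  spA <- splits$F1
  expect_equal(sum(spA$line_id %in% ws_obs & spA$ww_observed == "WW_A"), 3)
  expect_equal(sum(spA$line_id %in% ws_obs & spA$ww_observed == "WW_B"), 2)
  expect_error(make_cv2_masks(list(F1 = data.frame(x = 1)), "WS"),
               class = "sgs_integrity_error")
})

test_that("masking removes exactly the masked plot records", {
  dat <- small_dataset(seed = 44)
  lines <- unique(dat$phenotypes[, c("line_id", "family")])
  envs <- sort(unique(dat$phenotypes$environment))
  plan <- make_cv1_masks(lines, envs[1:2], envs[3], n_repeats = 1, seed = 1)[[1]]
  train <- apply_mask(dat$phenotypes, plan)
  masked <- plan[plan$status == "masked", ]
  key_m <- paste(masked$line_id, masked$environment)
  expect_false(any(paste(train$line_id, train$environment) %in% key_m))
  expect_equal(nrow(dat$phenotypes) - nrow(train),
               sum(paste(dat$phenotypes$line_id, dat$phenotypes$environment) %in% key_m))
})

test_that("historical augmentation respects mode and grouping constraints", {
  cfg <- sim_config(n_families = c(3, 4), family_size = c(8, 10), n_years = 2,
                    n_chromosomes = 2, markers_per_chromosome = 30,
                    founder_reuse = 1, seed = 47)
  dat <- simulate_trial_data(cfg)
  cur_ids <- dat$lines$line_id[dat$lines$year == 2017]
  his_ids <- dat$lines$line_id[dat$lines$year == 2018]
  current <- list(markers = marker_matrix(unclass(dat$markers)[cur_ids, ],
                                          families(dat$markers)[cur_ids]),
                  phenotypes = dat$phenotypes[dat$phenotypes$line_id %in% cur_ids, ],
                  lines = dat$lines[dat$lines$line_id %in% cur_ids, ])
  historical <- list(markers = marker_matrix(unclass(dat$markers)[his_ids, ],
                                             families(dat$markers)[his_ids]),
                     phenotypes = dat$phenotypes[dat$phenotypes$line_id %in% his_ids, ],
                     lines = dat$lines[dat$lines$line_id %in% his_ids, ])
  expect_identical(augment_with_historical(current, historical, "none"), current)
  expect_error(augment_with_historical(current, historical, "all", grouping = "LM"),
               class = "sgs_config_error")
  all_cmb <- augment_with_historical(current, historical, "all", grouping = "LMY")
  expect_equal(length(unique(all_cmb$phenotypes$environment)), 6L)
  opt <- augment_with_historical(current, historical, "optimized", n_select = 5)
  expect_lte(length(opt$historical_ids), length(his_ids))
  expect_lte(length(opt$historical_ids), 5 * 3)   # union bound over families
  expect_true(all(opt$historical_ids %in% his_ids))
  # overlapping IDs are rejected
  expect_error(augment_with_historical(current, current, "all"),
               class = "sgs_input_error")
})

test_that("cross-validation results are reproducible and well-formed", {
  dat <- small_dataset(seed = 50, n_families = 4, family_size = 12)
  cv <- run_crossval(dat, scheme = "CV1", grouping = "LM", structure = "DIAG",
                     n_repeats = 2, seed = 3, max_iter = 80, tol = 1e-5)
  expect_s3_class(cv, "cv_result")
  expect_true(all(cv$cells$accuracy >= -1 & cv$cells$accuracy <= 1))
  expect_true(all(cv$cells$n_masked >= 3))
  cv_again <- run_crossval(dat, scheme = "CV1", grouping = "LM", structure = "DIAG",
                           n_repeats = 2, seed = 3, max_iter = 80, tol = 1e-5)
  expect_identical(cv$cells, cv_again$cells)
  expect_output(print(cv), "Sparse-testing cross-validation")
  expect_type(mean_accuracy(cv), "double")
})
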