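# Slope classifier: features, centroid assignment, resampling, null, KS.

test_that("per-magnitude proportions count self-attributions by level", {
  tr <- make_trials(n0 = 10, n_per = 10)
  tr$response_identical <- FALSE
  tr$response_identical[tr$magnitude_level == 0] <- TRUE
  tr$response_identical[tr$aspect == "temporal" & tr$magnitude_level == 1][1:8] <- TRUE
  tr$response_identical[tr$aspect == "temporal" & tr$magnitude_level == 2][1:4] <- TRUE
  tr$response_identical[tr$aspect == "temporal" & tr$magnitude_level == 3][1:2] <- TRUE
  expect_equal(per_magnitude_proportions(tr, "temporal"), c(1, 0.8, 0.4, 0.2))
  expect_equal(per_magnitude_proportions(tr, "spatial"), c(1, 0, 0, 0))
  # duplicating every trial leaves proportions unchanged
  tr2 <- rbind(tr, transform(tr, trial_index = trial_index + 1000))
  expect_equal(per_magnitude_proportions(tr2, "temporal"), c(1, 0.8, 0.4, 0.2))
  expect_error(per_magnitude_proportions(tr[tr$magnitude_level != 2, ], "temporal"),
               "level 2")
})

test_that("slope fitting matches the least-squares closed form", {
  f <- fit_slope(c(1.0, 0.8, 0.4, 0.2))
  expect_equal(f[["slope"]], -0.28)
  expect_equal(fit_slope(c(0.5, 0.5, 0.5, 0.5))[["slope"]], 0)
  f <- fit_slope(c(0.9, 0.7, 0.5, 0.3))
  expect_equal(f[["slope"]], -0.2)
  expect_equal(f[["intercept"]], 0.9)
  # exact line: zero residual
  expect_equal(f[["intercept"]] + f[["slope"]] * (0:3), c(0.9, 0.7, 0.5, 0.3))
  # agrees with lm() on a non-degenerate profile
  p <- c(0.95, 0.62, 0.41, 0.12)
  ref <- unname(coef(lm(p ~ I(0:3))))
  expect_equal(fit_slope(p)[["intercept"]], ref[1])
  expect_equal(fit_slope(p)[["slope"]], ref[2])
})

test_that("participants are assigned to the nearer centroid", {
  expect_equal(classify_participant(c(-0.27, -0.25), c(-0.30, -0.28),
                                    c(-0.10, -0.12)), "control")
  expect_equal(classify_participant(c(-0.10, -0.12), c(-0.30, -0.28),
                                    c(-0.10, -0.12)), "psychosis")
  expect_warning(
    lab <- classify_participant(c(0, 0), c(-1, 0), c(1, 0)),
    "tie")
  expect_equal(lab, "control")
  expect_error(classify_participant(c(NA, 0), c(0, 0), c(1, 1)), "finite")
})

test_that("widely separated groups classify perfectly, same-distribution groups at chance", {
  sep <- small_params(8, modify = function(cfg) {
    cfg$control$delta_increment_mean <- c(3, 3, 3)
    cfg$control$delta_increment_sd <- c(0, 0, 0)
    cfg$control$kappa_sd <- 0
    cfg$psychosis$delta_increment_mean <- c(0, 0, 0)
    cfg$psychosis$delta_increment_sd <- c(0, 0, 0)
    cfg$psychosis$kappa_sd <- 0
    cfg$control$missing_rate <- 0
    cfg$psychosis$missing_rate <- 0
    cfg
  })
  data <- apply_exclusions(build_cohort(sep, seed = 5))$data
  res <- run_classifier(data, n_iterations = 200, seed = 1)
  expect_equal(mean(res$accuracy), 1.0)

  same <- small_params(30, modify = function(cfg) {
    clin <- cfg$psychosis$clinical
    cfg$psychosis <- cfg$control
    cfg$psychosis$clinical <- clin # keep the PANSS marginals
    cfg
  })
  data <- apply_exclusions(build_cohort(same, seed = 6))$data
  res <- run_classifier(data, n_iterations = 2000, seed = 2)
  expect_equal(mean(res$accuracy), 0.5, tolerance = 0.06)
})

test_that("permuted labels are classified at chance and runs are reproducible", {
  data <- default_cohort(seed = 3)
  nul <- permutation_null(data, n_iterations = 500, seed = 9)
  se <- sd(nul$accuracy) / sqrt(length(nul$accuracy))
  expect_lt(abs(mean(nul$accuracy) - 0.5), 3 * se + 0.01)
  nul2 <- permutation_null(data, n_iterations = 500, seed = 9)
  expect_identical(nul$accuracy, nul2$accuracy)
  # true labels beat the null distribution decisively
  real <- run_classifier(data, n_iterations = 500, seed = 9)
  ks <- ks_two_sample(real$accuracy, nul$accuracy)
  expect_gt(ks$D, 0.8)
  expect_lt(ks$p, 1e-6)
})

test_that("accuracy is invariant to trial order and id relabeling", {
  data <- default_cohort(seed = 4)
  res <- run_classifier(data, n_iterations = 100, seed = 3)

  shuf <- data
  set.seed(1)
  shuf$trials <- shuf$trials[sample.int(nrow(shuf$trials)), ]
  res2 <- run_classifier(shuf, n_iterations = 100, seed = 3)
  expect_identical(res$accuracy, res2$accuracy)

  # order-preserving relabeling of participant ids
  relab <- data
  relab$trials$participant_id <- paste0("X", relab$trials$participant_id)
  relab$participants$participant_id <- paste0("X", relab$participants$participant_id)
  res3 <- run_classifier(relab, n_iterations = 100, seed = 3)
  expect_identical(res$accuracy, res3$accuracy)
})

test_that("trial subsampling works and degrades accuracy gracefully", {
  data <- default_cohort(seed = 5)
  full <- run_classifier(data, n_iterations = 300, seed = 4)
  sub24 <- run_classifier(data, n_iterations = 300, n_trials_sampled = 24,
                          seed = 4)
  expect_gte(mean(full$accuracy), mean(sub24$accuracy) - 0.02)
  # identical participant stream: leave-out draws match across configs
  expect_equal(full$per_participant$n_left_out, sub24$per_participant$n_left_out)

  fb <- run_classifier(data, n_iterations = 100, n_trials_sampled = 24,
                       trial_pool = "first_block", seed = 4)
  expect_true(all(fb$accuracy >= 0 & fb$accuracy <= 1))
  expect_error(run_classifier(data, n_trials_sampled = 100,
                              trial_pool = "first_block"), "caps")
  expect_error(run_classifier(data, leave_out_fraction = 0.99), "retained")
})

test_that("the robustness grid is ordered by information", {
  data <- default_cohort(seed = 5)
  grid <- classifier_grid(data, n_trials = c(240, 48), leave_out = c(0.2, 0.8),
                          n_iterations = 200, seed = 6)
  expect_s3_class(grid, "soa_classifier_grid")
  expect_equal(nrow(grid), 4)
  for (lo in c(0.2, 0.8)) {
    a240 <- grid$accuracy[grid$n_trials == 240 & grid$leave_out == lo]
    a48 <- grid$accuracy[grid$n_trials == 48 & grid$leave_out == lo]
    expect_gte(a240, a48 - 0.02)
  }
})

test_that("the two-sample KS statistic matches ECDF enumeration", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$D, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})
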