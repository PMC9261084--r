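# Mixed-model ladders and clinical correlations.

test_that("the SoA ladder recovers the group-by-magnitude structure", {
  data <- default_cohort(seed = 2)
  m <- fit_soa_ladder(data)
  expect_s3_class(m, "soa_model_comparison")
  expect_equal(m$winner, "magnitude_x_group")
  expect_true(all(m$table$delta_bic >= 0))
  expect_equal(m$table$delta_bic[1], 0)
  co <- m$coefficients
  expect_lt(co$Estimate[co$term == "mag_c"], 0)
  expect_lt(co$Estimate[co$term == "mag_c:group_c"], 0)
  # aspect terms never earn their BIC keep on aspect-symmetric data
  d_aspect <- m$table$BIC[m$table$model == "magnitude_x_group_aspect"] -
    m$table$BIC[m$table$model == "magnitude_x_group"]
  expect_gt(d_aspect, -2)
})

test_that("group-bearing models lose by BIC when groups are identical", {
  same <- small_params(10, modify = function(cfg) {
    clin <- cfg$psychosis$clinical
    cfg$psychosis <- cfg$control
    cfg$psychosis$clinical <- clin # keep the PANSS marginals
    cfg
  })
  losses <- vapply(1:6, function(s) {
    data <- apply_exclusions(build_cohort(same, seed = 600 + s))$data
    m <- fit_soa_ladder(data)
    m$winner == "magnitude"
  }, logical(1))
  expect_gte(mean(losses), 5 / 6)
})

test_that("BIC ordering is invariant to candidate enumeration order", {
  data <- default_cohort(seed = 2)
  m <- fit_soa_ladder(data)
  # refit after permuting rows of the input; same winner and BIC table
  perm <- data
  set.seed(3)
  perm$trials <- perm$trials[sample.int(nrow(perm$trials)), ]
  m2 <- fit_soa_ladder(perm)
  expect_equal(m2$winner, m$winner)
  expect_equal(m2$table$BIC[order(m2$table$model)],
               m$table$BIC[order(m$table$model)], tolerance = 1e-6)
})

test_that("the confidence ladder finds the three-way structure and null models win on noise", {
  data <- default_cohort(seed = 2)
  m <- fit_confidence_ladder(data)
  expect_equal(m$winner, "full_three_way")
  co <- m$coefficients
  three_way <- co$Estimate[co$term == "poly(magnitude, 2)1:accuracy:group_c"]
  expect_gt(three_way, 0)

  # confidence independent of everything -> intercept-only model wins
  noise <- data
  set.seed(11)
  keep <- !is.na(noise$trials$confidence)
  noise$trials$confidence[keep] <- rnorm(sum(keep))
  m0 <- fit_confidence_ladder(noise)
  expect_equal(m0$winner, "intercept_only")
})

test_that("an exactly quadratic confidence profile is captured with near-zero residual", {
  data <- apply_exclusions(build_cohort(small_params(4), seed = 9))$data
  tr <- data$trials
  keep <- !is.na(tr$response_identical)
  mag <- tr$magnitude_level[keep]
  set.seed(2)
  data$trials$confidence[keep] <- 0.5 - 0.8 * mag + 0.3 * mag^2 +
    rnorm(sum(keep), 0, 1e-4)
  m <- fit_confidence_ladder(data)
  fit <- m$winner_fit
  expect_lt(sigma(fit), 1e-3)
})

test_that("winner confidence intervals cover a known generative fixed effect", {
  # data generated directly from the logistic mixed model the ladder fits;
  # 24 clusters so the random-effect variances (hence the Wald SEs) are
  # well estimated -- with very few participants Wald intervals under-cover
  beta <- c(intercept = 0.4, mag = -1.1, group = -0.6, interaction = -0.9)
  covered <- vapply(1:20, function(rep) {
    set.seed(700 + rep)
    trials <- lapply(seq_len(24), function(i) {
      d <- generate_design()
      d$participant_id <- sprintf("S%02d", i)
      d$group <- if (i <= 12) "control" else "psychosis"
      g <- if (i <= 12) 0.5 else -0.5
      u0 <- rnorm(1, 0, 0.3); u1 <- rnorm(1, 0, 0.2)
      eta <- beta["intercept"] + u0 +
        (beta["mag"] + u1) * (d$magnitude_level - 1.5) +
        beta["group"] * g +
        beta["interaction"] * (d$magnitude_level - 1.5) * g
      d$response_identical <- runif(240) < plogis(eta)
      d$confidence <- 0
      d$excluded <- FALSE; d$exclusion_reason <- "none"
      d
    })
    data <- soa_dataset(do.call(rbind, trials)[soameta:::TRIAL_COLUMNS])
    m <- fit_soa_ladder(data)
    co <- m$coefficients
    row <- co[co$term == "mag_c:group_c", ]
    nrow(row) == 1 && row$ci_lo <= beta["interaction"] &&
      row$ci_hi >= beta["interaction"]
  }, logical(1))
  # nominal 95% coverage; allow Monte-Carlo slack at 20 replicates
  expect_gte(mean(covered), 0.8)
})

test_that("clinical correlations recover the shipped coupling and nothing else", {
  data <- default_cohort(seed = 2)
  ct <- clinical_correlations(data)
  expect_s3_class(ct, "soa_correlations")
  expect_equal(nrow(ct), 24) # 2 groups x 4 scales x 3 measures
  expect_true(all(abs(ct$r) <= 1, na.rm = TRUE))
  expect_true(all(ct$n[ct$group == "control"] == 30))

  # a perfectly linear measure-scale relation gives r = 1
  fake <- data
  ps <- participant_summary(data)
  psy_ids <- ps$participant_id[ps$group == "psychosis"]
  idx <- match(psy_ids, fake$participants$participant_id)
  fake$participants$panss_negative[idx] <-
    10 + 5 * ps$gamma[match(psy_ids, ps$participant_id)]
  ct2 <- clinical_correlations(fake)
  r <- ct2$r[ct2$group == "psychosis" & ct2$scale == "panss_negative" &
               ct2$measure == "gamma"]
  expect_equal(r, 1, tolerance = 1e-8)

  # zero coupling: gamma ~ PANSS Positive correlation collapses
  null_params <- small_params(30, modify = function(cfg) {
    cfg$psychosis$clinical$panss_pos_coupling <- 0
    cfg
  })
  nd <- apply_exclusions(build_cohort(null_params, seed = 13))$data
  ct3 <- clinical_correlations(nd)
  r0 <- ct3$r[ct3$group == "psychosis" & ct3$scale == "panss_positive" &
                ct3$measure == "gamma"]
  expect_lt(abs(r0), 0.45)
})

test_that("the realized gamma-PANSS coupling matches its analytic target", {
  # oracle: large-sample correlation between standardized metacognitive
  # efficiency and realized gamma, attenuated by the shipped coupling ratio
  cfg <- jsonlite::read_json(
    system.file("extdata", "default_generative_params.json",
                package = "soameta"), simplifyVector = TRUE)
  p <- cfg$psychosis
  set.seed(41)
  n <- 300
  gains <- rnorm(n, p$conf_gain_mean, p$conf_gain_sd)
  gam <- vapply(seq_len(n), function(i) {
    draw <- function() cumsum(pmax(rnorm(3, p$delta_increment_mean,
                                         p$delta_increment_sd), 0))
    d <- simulate_responses(generate_design(), list(
      delta = rbind(temporal = draw(), spatial = draw()),
      kappa = rnorm(1, p$kappa_mean, p$kappa_sd),
      gain = gains[i], offset = p$conf_offset, sigma_meta = p$sigma_meta))
    acc <- label_accuracy(transform(d, excluded = FALSE))
    tryCatch(gk_gamma(d$confidence, acc)$gamma, error = function(e) NA_real_)
  }, numeric(1))
  ok <- !is.na(gam)
  r_target <- -(p$clinical$panss_pos_coupling / p$clinical$panss_pos_sd) *
    cor(gains[ok], gam[ok])

  rs <- vapply(1:10, function(s) {
    d <- apply_exclusions(build_cohort(seed = 800 + s))$data
    ct <- clinical_correlations(d)
    ct$r[ct$group == "psychosis" & ct$scale == "panss_positive" &
           ct$measure == "gamma"]
  }, numeric(1))
  expect_lt(abs(mean(rs) - r_target), 0.15)
  expect_lt(r_target, -0.15) # the shipped coupling is substantively negative
})
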