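# Synthetic cohort generator: design structure, observer model, determinism.

test_that("the trial design has the study structure for any seed", {
  for (seed in c(1, 7, 123)) {
    d <- generate_design(seed)
    expect_equal(nrow(d), 240)
    expect_equal(sum(d$magnitude_level == 0), 60)
    expect_equal(as.integer(table(d$block)), rep(48L, 5))
    counts <- table(d$aspect, d$magnitude_level)
    for (a in c("temporal", "spatial")) {
      expect_equal(as.integer(counts[a, c("1", "2", "3")]), rep(30L, 3))
    }
  }
  # same seed reproduces the order, different seeds permute it
  expect_identical(generate_design(5), generate_design(5))
  expect_false(identical(generate_design(5)$aspect, generate_design(6)$aspect))
})

test_that("separated evidence distributions give near-perfect detection", {
  d <- simulate_responses(generate_design(1),
                          list(delta = c(10, 10, 10), kappa = 5,
                               gain = 1, offset = 0, sigma_meta = 0), seed = 1)
  r <- compute_rates(d)
  s <- dprime_criterion(r$H, r$FA)
  expect_gt(r$H, 0.98)
  expect_lt(r$FA, 0.02)
  expect_gt(s$d_prime, 4)
})

test_that("a null observer scores d-prime near zero over 240 trials", {
  dp <- vapply(1:20, function(s) {
    d <- simulate_responses(generate_design(s),
                            list(delta = c(0, 0, 0), kappa = 1,
                                 gain = 1, offset = 0, sigma_meta = 0), seed = s)
    r <- compute_rates(d)
    dprime_criterion(r$H, r$FA)$d_prime
  }, numeric(1))
  expect_lt(abs(mean(dp)), 0.15) # SE of the mean ~ 0.05
})

test_that("metacognitive noise spans the gamma continuum", {
  gamma_at <- function(sigma, n = 30) {
    g <- vapply(seq_len(n), function(s) {
      d <- simulate_responses(generate_design(s),
                              list(delta = c(1, 2, 3), kappa = 1.3, gain = 1,
                                   offset = 0, sigma_meta = sigma), seed = 100 + s)
      acc <- label_accuracy(transform(d, excluded = FALSE))
      gk_gamma(d$confidence, acc)$gamma
    }, numeric(1))
    mean(g)
  }
  g_clean <- gamma_at(0)
  g_noisy <- gamma_at(25)
  expect_gt(g_clean, 0.3)        # noiseless read-out: strong association
  expect_lt(abs(g_noisy), 0.08)  # read-out swamped by noise: none
  expect_gt(g_clean, g_noisy + 0.2)
})

test_that("identical seeds give bit-identical cohorts", {
  a <- build_cohort(small_params(3), seed = 99)
  b <- build_cohort(small_params(3), seed = 99)
  expect_identical(a$trials, b$trials)
  expect_identical(a$participants, b$participants)
  c <- build_cohort(small_params(3), seed = 100)
  expect_false(identical(a$trials$response_identical,
                         c$trials$response_identical))
})

test_that("realized rates converge to their analytic values at high trial counts", {
  kappa <- 1.2; delta <- c(0.5, 1.0, 1.5)
  big <- do.call(rbind, lapply(1:40, generate_design)) # 9600 trials
  big$trial_index <- seq_len(nrow(big))
  d <- simulate_responses(big, list(delta = delta, kappa = kappa, gain = 1,
                                    offset = 0, sigma_meta = 0), seed = 4)
  r <- compute_rates(d)
  expect_equal(r$H, pnorm(kappa), tolerance = 0.02)
  expect_equal(r$FA, mean(pnorm(kappa - delta)), tolerance = 0.02)
})

test_that("larger alterations are self-attributed less", {
  d <- generate_design(3)
  weak <- simulate_responses(d, list(delta = c(0.3, 0.6, 0.9), kappa = 1.2,
                                     gain = 1, offset = 0, sigma_meta = 0),
                             seed = 11)
  strong <- simulate_responses(d, list(delta = c(1.5, 2.5, 3.5), kappa = 1.2,
                                       gain = 1, offset = 0, sigma_meta = 0),
                               seed = 11)
  for (lvl in 1:3) {
    p_weak <- mean(weak$response_identical[weak$magnitude_level == lvl])
    p_strong <- mean(strong$response_identical[strong$magnitude_level == lvl])
    expect_gt(p_weak, p_strong)
  }
})

test_that("generative parameters are validated", {
  cfg <- jsonlite::read_json(
    system.file("extdata", "default_generative_params.json",
                package = "soameta"), simplifyVector = TRUE)
  bad <- cfg
  bad$control$missing_rate <- 1
  expect_error(gen_params(bad$control, cfg$psychosis))
  bad <- cfg
  bad$psychosis$kappa_sd <- -0.1
  expect_error(gen_params(cfg$control, bad$psychosis))
  bad <- cfg
  bad$control$sigma_meta <- NULL
  expect_error(gen_params(bad$control, cfg$psychosis), "missing")
  # non-monotone delta vectors are rejected by the observer
  expect_error(simulate_responses(generate_design(1),
                                  list(delta = c(2, 1, 3), kappa = 1,
                                       gain = 1, offset = 0, sigma_meta = 0)))
})

test_that("clinical scores follow the group-appropriate scales", {
  data <- build_cohort(small_params(6), seed = 21)
  p <- data$participants
  ctrl <- p[p$group == "control", ]
  psy <- p[p$group == "psychosis", ]
  expect_true(all(is.na(ctrl$panss_positive)))
  expect_true(all(is.na(psy$spqb_total)))
  expect_true(all(psy$panss_positive >= 7 & psy$panss_positive <= 49))
  expect_equal(psy$panss_total,
               psy$panss_positive + psy$panss_negative + psy$panss_general)
  expect_equal(ctrl$spqb_total,
               ctrl$spqb_cogper + ctrl$spqb_inter + ctrl$spqb_disorg)
})
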