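test_that("transforms round-trip for every model variant", {
  withr::with_seed(1, {
    for (m in model_space()) {
      pars <- random_params()
      # collapse shared slots so the draw is valid for the variant
      a <- unname(pars$alpha)
      if (!m$split_alpha_by_source) a[3:4] <- a[1:2]
      if (!m$split_alpha_by_volatility) {
        a[2] <- a[1]
        a[4] <- a[3]
      }
      p0 <- rw_params(a[1], a[2], a[3], a[4],
                      zeta = if (m$zeta_free) pars$zeta else 0.5,
                      beta = pars$beta, variant = m)
      back <- theta_to_params(params_to_theta(p0), m)
      expect_equal(unname(back$alpha), unname(p0$alpha), tolerance = 1e-12)
      expect_equal(back$zeta, p0$zeta, tolerance = 1e-12)
      expect_equal(back$beta, p0$beta, tolerance = 1e-12)
    }
  })
})

test_that("reduced variants reject inconsistent learning rates", {
  expect_error(rw_params(0.2, 0.3, 0.2, 0.3,
                         variant = model_variant(split_alpha_by_volatility = FALSE)),
               "volatility")
  expect_error(rw_params(0.2, 0.2, 0.4, 0.4,
                         variant = model_variant(split_alpha_by_source = FALSE)),
               "source")
  # a single-alpha model is exactly the full model with tied rates
  tr <- quick_trials()
  withr::with_seed(2, tr$y <- rbinom(120, 1, 0.5))
  tied <- rw_params(0.3, variant = model_variant(FALSE, FALSE, TRUE),
                    zeta = 0.4, beta = 3)
  full <- rw_params(0.3, zeta = 0.4, beta = 3)
  expect_equal(negative_log_likelihood(tied, tr),
               negative_log_likelihood(full, tr), tolerance = 1e-12)
})

test_that("MAP fitting is deterministic and beats the prior mean", {
  sched <- generate_schedule(schedule_config(seed = 31L))
  tr <- simulate_agent(rw_params(0.3, 0.45, 0.2, 0.3, zeta = 0.4, beta = 6),
                       sched, seed = 32L)
  f1 <- fit_map(tr, n_starts = 4L, seed = 5L)
  f2 <- fit_map(tr, n_starts = 4L, seed = 5L)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$nll, f2$nll)

  priors <- prior_config()
  lay_mean <- theta_to_params(
    c(rep(priors$alpha_mean, 4), priors$zeta_mean, priors$beta_mean),
    model_variant())
  expect_lte(f1$nll, negative_log_likelihood(lay_mean, tr))
})

test_that("too few choices or random choices are handled sensibly", {
  tr <- quick_trials()
  tr$y <- NA_integer_
  tr$y[1:20] <- 1L
  expect_error(fit_map(tr), "at least 30")

  tr$y <- withr::with_seed(6, rbinom(120, 1, 0.5))
  f <- fit_map(tr, n_starts = 4L, seed = 7L)
  est <- natural_estimates(f)
  expect_lt(est[["beta"]], 2)  # noisy choices imply a weak value-choice link
  # learning rates shrink toward the prior mode under an uninformative
  # likelihood
  expect_true(all(abs(qlogis(est[1:4]) - qlogis(0.3)) < 1.5))
})

test_that("the Laplace evidence penalises unused parameters", {
  # zero-parameter model: evidence equals the log-likelihood
  tr <- quick_trials()
  withr::with_seed(8, tr$y <- rbinom(120, 1, 0.5))
  pars <- rw_params(0.3, zeta = 0.4, beta = 2)
  f0 <- fit_map(tr, fixed = pars)
  expect_equal(log_model_evidence(f0, tr), -negative_log_likelihood(pars, tr))

  # data from a no-split agent: the simpler model wins on average
  simple <- model_variant(FALSE, FALSE, TRUE)
  gen <- rw_params(0.3, zeta = 0.4, beta = 5, variant = simple)
  diffs <- numeric(0)
  for (i in 1:50) {
    sched <- generate_schedule(schedule_config(seed = 100L + i))
    tr <- simulate_agent(gen, sched, seed = 200L + i)
    fs <- fit_map(tr, variant = simple, n_starts = 3L, seed = i)
    ff <- fit_map(tr, variant = model_variant(), n_starts = 3L, seed = i)
    diffs <- c(diffs, log_model_evidence(fs, tr) - log_model_evidence(ff, tr))
  }
  expect_gt(mean(diffs), 0)
})

test_that("recovery is reproducible and degrades at shorter sessions", {
  gen <- withr::with_seed(21, lapply(1:20, function(i)
    rw_params(runif(1, .1, .6), runif(1, .1, .6), runif(1, .1, .6),
              runif(1, .1, .6), zeta = runif(1, .25, .75), beta = 6)))
  cfg_long <- long_schedule_config(1200L)
  cfg_short <- schedule_config()
  rep_long <- run_recovery(gen, cfg_long, seed = 9L, n_starts = 3L)
  rep_short <- run_recovery(gen, cfg_short, seed = 9L, n_starts = 3L)
  expect_identical(run_recovery(gen[1:3], cfg_short, seed = 9L, n_starts = 3L)$draws,
                   run_recovery(gen[1:3], cfg_short, seed = 9L, n_starts = 3L)$draws)
  a_slots <- c("alpha_primary_stable", "alpha_primary_volatile",
               "alpha_secondary_stable", "alpha_secondary_volatile")
  for (s in a_slots) {
    rl <- rep_long$metrics$rmse[rep_long$metrics$parameter == s]
    rs <- rep_short$metrics$rmse[rep_short$metrics$parameter == s]
    expect_gt(rs, rl)
  }
})

test_that("agents that ignore the advice are recovered with zeta near zero", {
  gen <- withr::with_seed(22, lapply(1:8, function(i)
    rw_params(runif(1, .15, .5), runif(1, .15, .5), runif(1, .15, .5),
              runif(1, .15, .5), zeta = 0, beta = 6)))
  rep0 <- run_recovery(gen, long_schedule_config(1000L), seed = 10L,
                       n_starts = 3L)
  z <- rep0$draws[rep0$draws$parameter == "zeta", ]
  expect_lt(mean(z$recovered), 0.12)
})
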