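test_that("the value update follows the delta rule", {
  expect_equal(update_value(0.5, 1, 0.5), 0.75)
  expect_equal(update_value(0.2, 0, 0.1), 0.18)
  for (v in c(0.1, 0.5, 0.9)) for (r in 0:1)
    expect_equal(update_value(v, r, 0), v)
  expect_error(update_value(1.2, 1, 0.5), "v must")
  expect_error(update_value(0.5, 2, 0.5), "binary")
  expect_error(update_value(0.5, 1, 1.5), "alpha")
})

test_that("advice weighting converts source accuracy to an option probability", {
  expect_identical(advice_weighted_value(0, 0.8), 0.8)
  expect_equal(advice_weighted_value(1, 0.8), 0.2)
  expect_identical(advice_weighted_value(0, 0.5), 0.5)
  expect_error(advice_weighted_value(0.3, 0.8), "binary")
})

test_that("value combination is a convex mixture", {
  expect_equal(combine_values(0.6, 0.8, 0), 0.6)
  expect_equal(combine_values(0.6, 0.8, 1), 0.8)
  expect_equal(combine_values(0.6, 0.8, 0.5), 0.7)
  v <- combine_values(0.3, 0.9, 0.25)
  expect_true(v >= 0.3 && v <= 0.9)
  expect_error(combine_values(0.6, 0.8, 1.2), "zeta")
})

test_that("the unit-square sigmoid has its analytic identities", {
  for (b in c(0.3, 1, 2, 8)) expect_equal(choice_probability(0.5, b), 0.5)
  v <- seq(0.05, 0.95, by = 0.05)
  expect_equal(choice_probability(v, 1), v, tolerance = 1e-9)
  expect_equal(choice_probability(0.8, 2), 0.64 / 0.68)
  # monotone and antisymmetric
  p <- choice_probability(v, 3.7)
  expect_true(all(diff(p) > 0))
  expect_equal(p, 1 - choice_probability(1 - v, 3.7), tolerance = 1e-12)
  expect_error(choice_probability(0.5, 0), "beta")
})

test_that("run_model matches a step-by-step application of the primitives", {
  tr <- quick_trials()
  withr::with_seed(42, {
    for (i in 1:5) {
      pars <- random_params()
      traj <- run_model(pars, tr)
      ref <- reference_forward(pars, tr)
      for (col in colnames(ref))
        expect_equal(traj[[col]], unname(ref[, col]), tolerance = 1e-12,
                     info = col)
    }
  })
})

test_that("frozen learning rates leave beliefs at the initial value", {
  tr <- quick_trials()
  pars <- rw_params(0, zeta = 0.5, beta = 2)
  traj <- run_model(pars, tr)
  expect_true(all(traj$v_primary == 0.5))
  expect_true(all(traj$v_secondary == 0.5))
  expect_true(all(traj$v_advice_weighted == 0.5))
  expect_true(all(traj$p_choice == 0.5))
})

test_that("phase-specific rates are inert when their phase never occurs", {
  tr <- quick_trials()
  tr$phase_primary <- "stable"
  tr$phase_secondary <- "stable"
  a <- run_model(rw_params(0.3, 0.9, 0.2, 0.8, zeta = 0.4, beta = 3,
                           variant = model_variant()), tr)
  b <- run_model(rw_params(0.3, 0.3, 0.2, 0.2, zeta = 0.4, beta = 3), tr)
  expect_equal(a$p_choice, b$p_choice, tolerance = 1e-14)
})

test_that("the likelihood matches its closed forms and the trajectory", {
  tr <- quick_trials()
  tr$y <- rep(c(0L, 1L), 60)
  flat <- rw_params(0, zeta = 0.5, beta = 2)
  expect_equal(negative_log_likelihood(flat, tr), 120 * log(2))

  pars <- rw_params(0.35, 0.5, 0.2, 0.4, zeta = 0.6, beta = 4)
  traj <- run_model(pars, tr)
  byhand <- -sum(ifelse(tr$y == 1, log(traj$p_choice), log(1 - traj$p_choice)))
  expect_equal(negative_log_likelihood(pars, tr), byhand, tolerance = 1e-10)

  # greedy self-consistent choices at very high beta give a vanishing NLL
  # (trials with the combined value at the decision boundary are excluded,
  # since the sigmoid limit is only deterministic away from 0.5)
  greedy <- tr
  greedy$y <- as.integer(traj$v_combined > 0.5)
  greedy$y[abs(traj$v_combined - 0.5) < 0.02] <- NA_integer_
  sharp <- rw_params(0.35, 0.5, 0.2, 0.4, zeta = 0.6, beta = 400)
  expect_lt(negative_log_likelihood(sharp, greedy), 1e-3)
})

test_that("relabelling both options leaves the likelihood unchanged", {
  tr <- quick_trials()
  withr::with_seed(8, tr$y <- rbinom(120, 1, 0.5))
  flip <- tr
  flip$r <- 1L - tr$r
  flip$advice <- 1L - tr$advice
  flip$y <- 1L - tr$y
  withr::with_seed(9, {
    for (i in 1:5) {
      pars <- random_params()
      # floating-point noise only: computing log(1 - p) for p near the
      # boundary cancels, so exact equality is not attainable at high beta
      expect_equal(negative_log_likelihood(pars, tr),
                   negative_log_likelihood(pars, flip), tolerance = 1e-6)
    }
  })
})

test_that("missing choices update beliefs but are skipped by the likelihood", {
  tr <- quick_trials()
  withr::with_seed(10, tr$y <- rbinom(120, 1, 0.5))
  pars <- rw_params(0.3, zeta = 0.4, beta = 3)
  full <- negative_log_likelihood(pars, tr)
  tr2 <- tr
  tr2$y[41:60] <- NA_integer_
  traj <- run_model(pars, tr)
  dropped <- sum(ifelse(tr$y[41:60] == 1, log(traj$p_choice[41:60]),
                        log(1 - traj$p_choice[41:60])))
  expect_equal(negative_log_likelihood(pars, tr2), full + dropped,
               tolerance = 1e-10)
  tr$y <- NA_integer_
  expect_error(negative_log_likelihood(pars, tr), "missing")
})

test_that("belief trajectories stay inside the unit interval for any parameters", {
  withr::with_seed(77, {
    for (i in 1:20) {
      cfg <- schedule_variants()[[sample(4, 1)]]
      cfg$seed <- sample.int(1e6, 1)
      tr <- sample_trials(generate_schedule(cfg), seed = sample.int(1e6, 1))
      traj <- run_model(random_params(), tr)
      expect_true(all(traj$p_choice > 0 & traj$p_choice < 1))
      expect_true(all(traj$v_combined >= 0 & traj$v_combined <= 1))
      expect_true(all(abs(traj$pe_primary) <= 1))
      expect_equal(traj$pe_primary, tr$r - traj$v_primary, tolerance = 1e-12)
    }
  })
})
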