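test_that("a single stable block gives constant probabilities everywhere", {
  blk <- schedule_block("stable", 120L, 0.8)
  cfg <- schedule_config(blocks_primary = blk, blocks_secondary = blk,
                         seed = 1L)
  s <- generate_schedule(cfg)
  expect_equal(s$p_primary, rep(0.8, 120))
  expect_equal(s$p_secondary, rep(0.8, 120))
  expect_true(all(s$phase_primary == "stable"))
  expect_true(all(s$phase_secondary == "stable"))
})

test_that("invalid configurations are rejected", {
  blk <- schedule_block("stable", 120L, 0.8)
  short <- schedule_block("stable", 100L, 0.8)
  expect_error(schedule_config(blocks_primary = short, blocks_secondary = blk),
               "sum")
  bad_stable <- rbind(schedule_block("stable", 31L, 0.8),
                      schedule_block("volatile", 89L, 0.8))
  ok <- schedule_config(blocks_primary = bad_stable, blocks_secondary = blk)
  expect_s3_class(ok, "schedule_config")
  too_short <- data.frame(phase = c("stable", "volatile"),
                          length = c(30L, 90L), p_high = 0.8)
  expect_error(schedule_config(blocks_primary = too_short,
                               blocks_secondary = blk), "stable")
  expect_error(schedule_block("stable", 40, 0.5), "p_high")
  expect_error(schedule_block("stable", 40, 1), "p_high")
})

test_that("volatile runs respect the switch range and stable runs are constant", {
  for (seed in 1:6) {
    for (cfg in schedule_variants()) {
      cfg$seed <- seed
      s <- generate_schedule(cfg)
      for (side in c("primary", "secondary")) {
        p <- s[[paste0("p_", side)]]
        phase <- s[[paste0("phase_", side)]]
        expect_true(all(p > 0 & p < 1))
        # stable blocks: constant probability
        for (seg in split(seq_len(120), cumsum(c(TRUE, diff(phase == "stable") != 0)))) {
          if (phase[seg[1]] == "stable") expect_length(unique(p[seg]), 1)
          else {
            runs <- rle(p[seg])$lengths
            expect_true(all(runs >= 10 & runs <= 20),
                        info = paste(side, "seed", seed))
            # reversals alternate between q and 1 - q
            expect_true(all(abs(p[seg] - 0.8) < 1e-12 |
                              abs(p[seg] - 0.2) < 1e-12))
          }
        }
      }
    }
  }
})

test_that("schedule generation and trial sampling are reproducible", {
  cfg <- schedule_config(seed = 99L)
  expect_identical(generate_schedule(cfg), generate_schedule(cfg))
  s <- generate_schedule(cfg)
  expect_identical(sample_trials(s, seed = 3L), sample_trials(s, seed = 3L))
})

test_that("sampled trials follow the schedule probabilities", {
  # degenerate probabilities force the outcome and the advice accuracy
  blk <- schedule_block("stable", 120L, 0.999999)
  cfg <- schedule_config(blocks_primary = blk, blocks_secondary = blk,
                         seed = 2L)
  s <- generate_schedule(cfg)
  s$p_primary[] <- 1
  s$p_secondary[] <- 1
  tr <- sample_trials(s, seed = 4L)
  expect_true(all(tr$r == 1))
  # advice correct on every trial: advice endorses the rewarded option
  expect_true(all(tr$advice != tr$r))

  # binomial calibration and independence on a long constant schedule
  long <- schedule_config(n_trials = 10000L,
                          blocks_primary = schedule_block("stable", 10000L, 0.8),
                          blocks_secondary = schedule_block("stable", 10000L, 0.7),
                          seed = 5L)
  tl <- sample_trials(generate_schedule(long), seed = 6L)
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(mean(tl$r) - 0.8), 3 * se)
  correct <- as.integer(tl$advice != tl$r)
  se_c <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(mean(correct) - 0.7), 3 * se_c)
  expect_lt(abs(cor(tl$r, correct)), 3 / sqrt(10000))
})

test_that("trial sequences and configurations round-trip through text files", {
  tr <- quick_trials()
  tr$y[3] <- 1L
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$r, tr$r)
  expect_equal(back$advice, tr$advice)
  expect_identical(back$y[3], 1L)
  expect_true(all(is.na(back$y[-3])))
  expect_equal(back$phase_primary, tr$phase_primary)

  cfgp <- withr::local_tempfile(fileext = ".json")
  cfg <- schedule_config(seed = 7L)
  write_schedule_config(cfg, cfgp)
  cfg2 <- read_schedule_config(cfgp)
  expect_equal(cfg2$n_trials, cfg$n_trials)
  expect_equal(cfg2$blocks_primary$length, cfg$blocks_primary$length)
  expect_identical(generate_schedule(cfg2), generate_schedule(cfg))
})

test_that("split_trials recovers the per-session sequences of a cohort", {
  spec <- cohort_spec(n_subjects = c("individual-primary" = 2L,
                                     "social-primary" = 2L), seed = 11L)
  coh <- generate_cohort(spec)
  sess <- split_trials(coh$trials)
  expect_length(sess, 8)
  expect_true(all(vapply(sess, nrow, 1L) == 120L))
})
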