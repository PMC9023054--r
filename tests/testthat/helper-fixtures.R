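# Shared fixtures: everything is generated in code at test time.

# A realised default-variant session with outcomes and advice.
quick_trials <- function(schedule_seed = 5L, trial_seed = 6L) {
  cfg <- schedule_config(seed = schedule_seed)
  sample_trials(generate_schedule(cfg), seed = trial_seed)
}

# Long schedule for recovery studies: alternating 50-trial stable/volatile
# blocks; the secondary source is phase-shifted by one block.
long_schedule_config <- function(n_trials = 1000L, p_high = 0.8) {
  stopifnot(n_trials %% 100 == 0)
  unit <- rbind(schedule_block("stable", 50L, p_high),
                schedule_block("volatile", 50L, p_high))
  blocks <- do.call(rbind, rep(list(unit), n_trials / 100))
  schedule_config(n_trials = n_trials, blocks_primary = blocks,
                  blocks_secondary = blocks[c(2:nrow(blocks), 1L), ])
}

# Coarse grid for cheap structural checks of the Bayesian learner.
tiny_grid <- function() bayes_grid(n_p = 20L, n_v = 10L, n_k = 5L)

# Independently coded reference filter for the Bayesian learner: a plain
# loop re-deriving the stencil kernels and the filtering recursion from the
# model definition, kept free of the package's advance_post machinery.
reference_bayes_filter <- function(outcomes, n_p, n_v, n_k,
                                   v_range = c(-9, -0.5),
                                   k_range = log(c(0.05, 1.5))) {
  p <- (seq_len(n_p) - 0.5) / n_p
  v <- seq(v_range[1], v_range[2], length.out = n_v)
  k <- seq(k_range[1], k_range[2], length.out = n_k)
  one_kernel <- function(x, drift, vars) {
    n <- length(x); dx <- x[2] - x[1]
    m <- max(1, ceiling(max((vars + drift^2) / (0.45 * 2 * dx^2))),
             ceiling(max(abs(drift)) / (0.9 * dx)))
    M <- matrix(0, n, n)
    for (j in seq_len(n)) {
      wp <- (vars[j] / m + (drift[j] / m)^2 + drift[j] / m * dx) / (2 * dx^2)
      wm <- (vars[j] / m + (drift[j] / m)^2 - drift[j] / m * dx) / (2 * dx^2)
      jp <- min(n, j + 1); jm <- max(1, j - 1)
      M[jp, j] <- M[jp, j] + wp
      M[jm, j] <- M[jm, j] + wm
      M[j, j] <- M[j, j] + 1 - wp - wm
    }
    out <- diag(n)
    for (i in seq_len(m)) out <- M %*% out
    out
  }
  Tp <- lapply(v, function(vi) {
    conc <- exp(-vi)
    a <- 1 + p * conc; b <- 1 + (1 - p) * conc
    one_kernel(p, a / (a + b) - p, a * b / ((a + b)^2 * (a + b + 1)))
  })
  Tv <- lapply(k, function(ki) one_kernel(v, rep(0, n_v), rep(exp(2 * ki), n_v)))
  post <- array(1 / (n_p * n_v * n_k), dim = c(n_p, n_v, n_k))
  p_hat <- numeric(length(outcomes))
  for (t in seq_along(outcomes)) {
    pred <- post
    for (ik in seq_len(n_k)) pred[, , ik] <- pred[, , ik] %*% t(Tv[[ik]])
    for (iv in seq_len(n_v))
      for (ik in seq_len(n_k)) pred[, iv, ik] <- Tp[[iv]] %*% pred[, iv, ik]
    p_hat[t] <- sum(p * rowSums(pred))
    lik <- if (outcomes[t] == 1) p else 1 - p
    post <- pred * lik
    post <- post / sum(post)
  }
  p_hat
}

# Pure-R forward pass of the dual-source model, built from the exported
# scalar primitives; used as the independent oracle for run_model.
reference_forward <- function(params, trials) {
  n <- nrow(trials)
  vp <- vs <- params$v0
  out <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("v_primary", "v_secondary",
                                        "v_advice_weighted", "v_combined",
                                        "p_choice")))
  for (t in seq_len(n)) {
    aw <- advice_weighted_value(trials$advice[t], vs)
    vc <- combine_values(vp, aw, params$zeta)
    out[t, ] <- c(vp, vs, aw, vc, choice_probability(vc, params$beta))
    s <- as.integer(trials$advice[t] != trials$r[t])
    ap <- if (trials$phase_primary[t] == "volatile")
      params$alpha[["primary_volatile"]] else params$alpha[["primary_stable"]]
    as_ <- if (trials$phase_secondary[t] == "volatile")
      params$alpha[["secondary_volatile"]] else params$alpha[["secondary_stable"]]
    vp <- update_value(vp, trials$r[t], ap)
    vs <- update_value(vs, s, as_)
  }
  out
}

random_params <- function() {
  rw_params(runif(1, .02, .95), runif(1, .02, .95), runif(1, .02, .95),
            runif(1, .02, .95), zeta = runif(1, .05, .95),
            beta = exp(runif(1, log(0.5), log(20))))
}
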