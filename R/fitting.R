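#' Prior configuration for MAP fitting
#'
#' Parameters are estimated in unconstrained space: learning rates and zeta
#' through the logit transform, beta through the log transform, each with an
#' independent Gaussian prior. Defaults are weakly informative: learning
#' rates centred on 0.3, zeta on 0.5, beta on 4, all with unit variance in
#' transformed space.
#'
#' @param alpha_mean,alpha_var Prior mean and variance of logit(alpha).
#' @param zeta_mean,zeta_var Prior mean and variance of logit(zeta).
#' @param beta_mean,beta_var Prior mean and variance of log(beta).
#' @return An object of class `"prior_config"`.
#' @export
prior_config <- function(alpha_mean = qlogis(0.3), alpha_var = 1,
                         zeta_mean = 0, zeta_var = 1,
                         beta_mean = log(4), beta_var = 1) {
  if (any(c(alpha_var, zeta_var, beta_var) <= 0))
    stop("prior variances must be positive", call. = FALSE)
  structure(list(alpha_mean = alpha_mean, alpha_var = alpha_var,
                 zeta_mean = zeta_mean, zeta_var = zeta_var,
                 beta_mean = beta_mean, beta_var = beta_var),
            class = "prior_config")
}

# Free-parameter layout for a model variant: names, transforms, prior
# moments.  Learning-rate sharing across slots is resolved here.
param_layout <- function(variant, priors) {
  alpha_names <- if (variant$split_alpha_by_source &&
                     variant$split_alpha_by_volatility) {
    c("alpha_primary_stable", "alpha_primary_volatile",
      "alpha_secondary_stable", "alpha_secondary_volatile")
  } else if (variant$split_alpha_by_source) {
    c("alpha_primary", "alpha_secondary")
  } else if (variant$split_alpha_by_volatility) {
    c("alpha_stable", "alpha_volatile")
  } else "alpha"
  nm <- c(alpha_names, if (variant$zeta_free) "zeta", "beta")
  mu <- c(rep(priors$alpha_mean, length(alpha_names)),
          if (variant$zeta_free) priors$zeta_mean, priors$beta_mean)
  sigma2 <- c(rep(priors$alpha_var, length(alpha_names)),
              if (variant$zeta_free) priors$zeta_var, priors$beta_var)
  list(names = nm, mu = mu, sigma2 = sigma2, alpha_names = alpha_names)
}

# Map the four (primary/secondary x stable/volatile) slots onto the free
# alpha parameters of a variant.
alpha_slot_index <- function(variant) {
  if (variant$split_alpha_by_source && variant$split_alpha_by_volatility) {
    c(1L, 2L, 3L, 4L)
  } else if (variant$split_alpha_by_source) {
    c(1L, 1L, 2L, 2L)        # primary, secondary
  } else if (variant$split_alpha_by_volatility) {
    c(1L, 2L, 1L, 2L)        # stable, volatile
  } else rep(1L, 4L)
}

#' Transform free parameters between natural and unconstrained space
#'
#' `theta_to_params()` maps an unconstrained vector (logit learning rates
#' and zeta, log beta, in the layout of the given variant) to an
#' [rw_params()]; `params_to_theta()` is its inverse.
#'
#' @param theta Numeric vector in transformed space.
#' @param params An [rw_params()].
#' @param variant A [model_variant()].
#' @param v0 Initial value passed through to [rw_params()].
#' @return `theta_to_params()` an `rw_params`; `params_to_theta()` a named
#'   numeric vector.
#' @export
theta_to_params <- function(theta, variant = model_variant(), v0 = 0.5) {
  lay <- param_layout(variant, prior_config())
  stopifnot(length(theta) == length(lay$names))
  names(theta) <- lay$names
  n_alpha <- length(lay$alpha_names)
  alpha_free <- unname(plogis(theta[seq_len(n_alpha)]))
  a <- alpha_free[alpha_slot_index(variant)]
  zeta <- if (variant$zeta_free) plogis(theta[["zeta"]]) else 0.5
  beta <- exp(theta[["beta"]])
  rw_params(a[1], a[2], a[3], a[4], zeta = zeta, beta = beta, v0 = v0,
            variant = variant)
}

#' @rdname theta_to_params
#' @export
params_to_theta <- function(params) {
  variant <- params$variant
  lay <- param_layout(variant, prior_config())
  idx <- alpha_slot_index(variant)
  n_alpha <- length(lay$alpha_names)
  alpha_free <- numeric(n_alpha)
  for (j in seq_len(n_alpha)) alpha_free[j] <- params$alpha[match(j, idx)]
  theta <- c(qlogis(alpha_free),
             if (variant$zeta_free) qlogis(params$zeta),
             log(params$beta))
  names(theta) <- lay$names
  theta
}

neg_log_joint_fn <- function(trials, priors, variant, v0 = 0.5) {
  lay <- param_layout(variant, priors)
  r <- as.integer(trials$r)
  adv <- as.integer(trials$advice)
  php <- phase_code(trials$phase_primary)
  phs <- phase_code(trials$phase_secondary)
  y <- as.integer(trials$y)
  idx <- alpha_slot_index(variant)
  n_alpha <- length(lay$alpha_names)
  function(theta) {
    alpha_free <- plogis(theta[seq_len(n_alpha)])
    zeta <- if (variant$zeta_free) plogis(theta[n_alpha + 1]) else 0.5
    beta <- exp(theta[length(theta)])
    nll <- rw_nll_cpp(alpha_free[idx], zeta, beta, v0, r, adv, php, phs, y)
    nlp <- -sum(dnorm(theta, lay$mu, sqrt(lay$sigma2), log = TRUE))
    val <- nll + nlp
    if (!is.finite(val)) 1e10 else val
  }
}

#' MAP estimation of the dual-source model
#'
#' Maximises log-likelihood plus log-prior in transformed space by
#' multi-start quasi-Newton optimisation (BFGS, with a Nelder-Mead fallback
#' per start). Starts are the prior mean plus `n_starts` draws from the
#' prior; the best optimum is kept, ties broken by first occurrence.
#'
#' @param trials A `"trial_sequence"` with at least 30 non-missing choices.
#' @param priors A [prior_config()].
#' @param variant A [model_variant()].
#' @param n_starts Number of random starts in addition to the prior mean.
#' @param seed Integer seed for the random starts (the fit is deterministic
#'   given the seed).
#' @param fixed Optionally a full [rw_params()]: no optimisation is
#'   performed and the model is evaluated at these values (a zero-parameter
#'   model, whose log evidence is its log-likelihood).
#' @return An object of class `"fit_result"`: MAP estimates in natural
#'   (`$params`) and transformed (`$theta`) space, `$nll`,
#'   `$neg_log_joint`, optimiser diagnostics, and the inputs needed to
#'   compute [log_model_evidence()].
#' @export
fit_map <- function(trials, priors = prior_config(),
                    variant = model_variant(), n_starts = 10L, seed = 1L,
                    fixed = NULL) {
  check_trials_complete(trials)
  y <- as.integer(trials$y)
  n_choices <- sum(!is.na(y))

  if (!is.null(fixed)) {
    nll <- negative_log_likelihood(fixed, trials)
    return(structure(list(params = fixed, theta = numeric(0), nll = nll,
                          neg_log_joint = nll, variant = fixed$variant,
                          priors = priors, n_choices = n_choices,
                          diagnostics = list(n_starts = 0L, n_converged = 0L,
                                             convergence = integer(0)),
                          seed = as.integer(seed)),
                     class = "fit_result"))
  }

  if (n_choices < 30)
    stop("need at least 30 non-missing choices (have ", n_choices, ")",
         call. = FALSE)
  lay <- param_layout(variant, priors)
  obj <- neg_log_joint_fn(trials, priors, variant)
  d <- length(lay$names)

  starts <- withr::with_seed(as.integer(seed), {
    s <- matrix(rnorm(n_starts * d, rep(lay$mu, each = n_starts),
                      rep(sqrt(lay$sigma2), each = n_starts)),
                nrow = n_starts)
    rbind(lay$mu, s)
  })

  best <- NULL
  codes <- integer(0)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], obj, method = "BFGS",
            control = list(maxit = 500)),
      error = function(e)
        optim(starts[i, ], obj, method = "Nelder-Mead",
              control = list(maxit = 2000)))
    codes <- c(codes, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("no optimiser start converged to a finite optimum", call. = FALSE)

  theta <- best$par
  names(theta) <- lay$names
  params <- theta_to_params(theta, variant)
  structure(list(params = params, theta = theta,
                 nll = negative_log_likelihood(params, trials),
                 neg_log_joint = best$value, variant = variant,
                 priors = priors, n_choices = n_choices,
                 diagnostics = list(n_starts = nrow(starts),
                                    n_converged = sum(codes == 0),
                                    convergence = codes),
                 seed = as.integer(seed)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", variant_label(x$variant),
      sprintf("  nll=%.2f  n_choices=%d\n", x$nll, x$n_choices), sep = "")
  if (length(x$theta)) print(round(natural_estimates(x), 4))
  invisible(x)
}

#' Natural-space estimates from a fit
#'
#' @param fit A `"fit_result"`.
#' @param sqrt_alpha Also return square-root transformed learning rates
#'   (a common normalising transform at the reporting stage)?
#' @return Named numeric vector of estimates in natural space.
#' @export
natural_estimates <- function(fit, sqrt_alpha = FALSE) {
  p <- fit$params
  out <- c(alpha_primary_stable = unname(p$alpha[1]),
           alpha_primary_volatile = unname(p$alpha[2]),
           alpha_secondary_stable = unname(p$alpha[3]),
           alpha_secondary_volatile = unname(p$alpha[4]),
           zeta = p$zeta, beta = p$beta)
  if (sqrt_alpha) {
    sq <- sqrt(out[1:4])
    names(sq) <- paste0("sqrt_", names(sq))
    out <- c(out, sq)
  }
  out
}

# Central finite-difference Hessian of f at x.
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- numeric(d)
      ei[i] <- h
      ej[j] <- h
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

#' Approximate log model evidence
#'
#' Laplace approximation at the MAP in transformed space:
#' `log joint + (d/2) log(2 pi) - 0.5 log det(Hessian)`, with the Hessian of
#' the negative log joint obtained by central finite differences
#' (step 1e-4). When the Hessian is not positive definite the function
#' falls back to `-BIC/2 = log-likelihood - (d/2) log(n)` with a warning.
#' A zero-parameter fit returns its log-likelihood.
#'
#' @param fit A `"fit_result"` from [fit_map()].
#' @param trials The trial sequence the fit was obtained on.
#' @return Scalar approximate log evidence.
#' @export
log_model_evidence <- function(fit, trials) {
  stopifnot(inherits(fit, "fit_result"))
  d <- length(fit$theta)
  if (d == 0) return(-fit$nll)
  obj <- neg_log_joint_fn(trials, fit$priors, fit$variant, fit$params$v0)
  H <- fd_hessian(obj, fit$theta)
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    warning("Hessian not positive definite at the MAP; using -BIC/2",
            call. = FALSE)
    return(-fit$nll - d / 2 * log(fit$n_choices))
  }
  -fit$neg_log_joint + d / 2 * log(2 * pi) - sum(log(diag(ch)))
}

#' Parameter-recovery study
#'
#' Simulates choice data from each generating parameter set, refits the
#' model, and tabulates how well the generating values are recovered.
#'
#' @param generating_grid A list of [rw_params()] (one per simulated agent)
#'   or a single `rw_params` recycled `n_reps` times.
#' @param schedule_config A [schedule_config()]; a fresh schedule and trial
#'   realisation is drawn per simulated dataset.
#' @param n_reps Number of simulated datasets per generating set.
#' @param seed Integer seed controlling the whole study.
#' @param priors,variant,n_starts Passed to [fit_map()].
#' @return An object of class `"recovery_report"`: `$draws` (long table of
#'   generating and recovered values), `$metrics` (per-parameter
#'   correlation, bias, RMSE), `$n_failed`, and the simulation settings.
#' @export
run_recovery <- function(generating_grid, schedule_config = rwdual::schedule_config(),
                         n_reps = 1L, seed = 1L, priors = prior_config(),
                         variant = model_variant(), n_starts = 10L) {
  if (inherits(generating_grid, "rw_params"))
    generating_grid <- list(generating_grid)
  if (length(generating_grid) == 0) stop("empty generating grid", call. = FALSE)

  par_names <- c("alpha_primary_stable", "alpha_primary_volatile",
                 "alpha_secondary_stable", "alpha_secondary_volatile",
                 "zeta", "beta")
  rows <- list()
  n_failed <- 0L
  cell <- 0L
  for (g in seq_along(generating_grid)) {
    for (rep in seq_len(n_reps)) {
      cell <- cell + 1L
      cell_seed <- (as.integer(seed) + 7919L * cell) %% .Machine$integer.max
      pars <- generating_grid[[g]]
      res <- tryCatch({
        cfg <- schedule_config
        cfg$seed <- cell_seed
        sched <- generate_schedule(cfg)
        trials <- simulate_agent(pars, sched, seed = cell_seed + 1L)
        fit <- fit_map(trials, priors = priors, variant = variant,
                       n_starts = n_starts, seed = cell_seed + 2L)
        natural_estimates(fit)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        next
      }
      gen <- c(unname(pars$alpha), pars$zeta, pars$beta)
      rows[[length(rows) + 1L]] <-
        data.frame(set = g, rep = rep, parameter = par_names,
                   generating = gen, recovered = unname(res[par_names]))
    }
  }
  draws <- do.call(rbind, rows)
  metrics <- do.call(rbind, lapply(split(draws, draws$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               correlation = if (sd(d$generating) > 0 && sd(d$recovered) > 0)
                 cor(d$generating, d$recovered) else NA_real_,
               bias = mean(d$recovered - d$generating),
               rmse = sqrt(mean((d$recovered - d$generating)^2)))
  }))
  rownames(metrics) <- NULL
  structure(list(draws = draws, metrics = metrics, n_failed = n_failed,
                 settings = list(n_sets = length(generating_grid),
                                 n_reps = n_reps,
                                 n_trials = schedule_config$n_trials,
                                 seed = as.integer(seed))),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$settings$n_sets, " sets x ", x$settings$n_reps,
      " reps, ", x$settings$n_trials, " trials (", x$n_failed,
      " failed fits)\n", sep = "")
  print(transform(x$metrics, correlation = round(correlation, 3),
                  bias = round(bias, 3), rmse = round(rmse, 3)))
  invisible(x)
}
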