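#' Optimal-learner regression weights
#'
#' Quantifies how strongly a subject's choices follow each information
#' source by regressing the choices on the prediction series of the two
#' Bayesian optimal learners ([optimal_prediction_series()]): one filtering
#' only the primary outcomes, one filtering only the secondary source's
#' correctness (converted to the primary-congruent scale through the advice
#' weighting). Each predictor is standardised within the session and
#' entered in its own single-predictor binomial logistic regression; the
#' two slope coefficients are returned.
#'
#' Perfect separation (or a constant predictor) is handled by capping the
#' coefficient at `+/- cap` and flagging the result.
#'
#' @param trials A `"trial_sequence"` with non-missing choices `y`.
#' @param grid A [bayes_grid()] used for both learners.
#' @param cap Cap on the absolute coefficient under separation (default 10).
#' @return An object of class `"optimal_betas"`: `$beta_primary`,
#'   `$beta_secondary`, standard errors, separation flags, and the two
#'   predictor series.
#' @export
optimal_learner_betas <- function(trials, grid = bayes_grid(), cap = 10) {
  check_trials_complete(trials)
  y <- trials$y
  keep <- !is.na(y)
  if (sum(keep) < 10) stop("too few non-missing choices", call. = FALSE)

  pred_p <- optimal_prediction_series(trials, "primary", grid)$p_hat
  pred_s <- optimal_prediction_series(trials, "secondary", grid)$p_hat

  one_fit <- function(x) {
    x <- x[keep]
    yy <- y[keep]
    if (sd(x) == 0)
      return(list(beta = 0, se = NA_real_, flagged = TRUE))
    z <- (x - mean(x)) / sd(x)
    fit <- suppressWarnings(glm(yy ~ z, family = binomial()))
    b <- unname(coef(fit)[2])
    se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))[2])
    flagged <- !fit$converged || abs(b) > cap
    if (abs(b) > cap) b <- sign(b) * cap
    list(beta = b, se = se, flagged = flagged)
  }
  fp <- one_fit(pred_p)
  fs <- one_fit(pred_s)
  structure(list(beta_primary = fp$beta, beta_secondary = fs$beta,
                 se_primary = fp$se, se_secondary = fs$se,
                 flagged_primary = fp$flagged, flagged_secondary = fs$flagged,
                 pred_primary = pred_p, pred_secondary = pred_s),
            class = "optimal_betas")
}

#' @export
print.optimal_betas <- function(x, ...) {
  cat(sprintf("<optimal_betas> primary=%.3f (se %.3f)%s  secondary=%.3f (se %.3f)%s\n",
              x$beta_primary, x$se_primary,
              if (x$flagged_primary) " [flagged]" else "",
              x$beta_secondary, x$se_secondary,
              if (x$flagged_secondary) " [flagged]" else ""))
  invisible(x)
}

#' Optimal learning rates by simulation
#'
#' Derives the learning rates an optimal learner effectively exhibits on
#' this task: for each synthetic dataset a fresh schedule and trial
#' realisation is drawn, the Bayesian learner filters both sources, its two
#' prediction series are combined through the response model (advice
#' weighting, zeta mix, unit-square sigmoid with a high fixed beta) into
#' choices, and the full dual-source RW model is fitted to those choices.
#' The four fitted learning rates are averaged across datasets.
#'
#' @param schedule_config A single [schedule_config()] or a list of them
#'   (default the four counterbalanced [schedule_variants()]); datasets are
#'   assigned to the configurations round-robin, mirroring the task's
#'   random assignment of participants to counterbalanced schedules.
#' @param n_datasets Number of synthetic datasets (default 100).
#' @param seed Integer seed for the whole simulation.
#' @param zeta_sim,beta_sim Response-model parameters used to turn the
#'   optimal learner's combined prediction into choices: an even mix
#'   (`zeta = 0.5`) and near-deterministic responding (`beta = 10`).
#' @param grid A [bayes_grid()].
#' @param priors,n_starts Passed to [fit_map()] for the refits.
#' @param choices_mode If `"choices"` (default) the RW model is fitted to
#'   sampled binary choices; if `"probabilities"` choices are replaced by
#'   their expectation thresholded at 0.5 (a deterministic variant).
#' @return An object of class `"optimal_alphas"`: `$alpha` (the four
#'   averaged learning rates), `$se` (their Monte-Carlo standard errors),
#'   `$per_dataset`, `$n_failed`, and the settings.
#' @export
compute_optimal_alphas <- function(schedule_config = schedule_variants(),
                                   n_datasets = 100L, seed = 1L,
                                   zeta_sim = 0.5, beta_sim = 10,
                                   grid = bayes_grid(),
                                   priors = prior_config(), n_starts = 10L,
                                   choices_mode = c("choices", "probabilities")) {
  choices_mode <- match.arg(choices_mode)
  stopifnot(n_datasets >= 1)
  configs <- if (inherits(schedule_config, "schedule_config"))
    list(schedule_config) else schedule_config
  slot_names <- c("alpha_primary_stable", "alpha_primary_volatile",
                  "alpha_secondary_stable", "alpha_secondary_volatile")
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(n_datasets)) {
    ds_seed <- (as.integer(seed) + 6151L * i) %% .Machine$integer.max
    res <- tryCatch({
      cfg <- configs[[(i - 1L) %% length(configs) + 1L]]
      cfg$seed <- ds_seed
      sched <- generate_schedule(cfg)
      trials <- sample_trials(sched, seed = ds_seed + 1L)
      pred_p <- optimal_prediction_series(trials, "primary", grid)$p_hat
      pred_s <- optimal_prediction_series(trials, "secondary", grid)$p_hat
      v_comb <- combine_values(pred_p, pred_s, zeta_sim)
      pc <- choice_probability(v_comb, beta_sim)
      trials$y <- if (choices_mode == "choices")
        withr::with_seed(ds_seed + 2L, rbinom(length(pc), 1L, pc))
      else as.integer(pc > 0.5)
      fit <- fit_map(trials, priors = priors, n_starts = n_starts,
                     seed = ds_seed + 3L)
      natural_estimates(fit)[slot_names]
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("all optimal-alpha refits failed", call. = FALSE)
  per <- do.call(rbind, rows)
  alpha <- colMeans(per)
  se <- apply(per, 2, sd) / sqrt(nrow(per))
  structure(list(alpha = alpha, se = se,
                 per_dataset = as.data.frame(per), n_failed = n_failed,
                 settings = list(n_datasets = n_datasets, seed = as.integer(seed),
                                 zeta_sim = zeta_sim, beta_sim = beta_sim,
                                 n_trials = configs[[1]]$n_trials,
                                 n_schedule_variants = length(configs),
                                 choices_mode = choices_mode)),
            class = "optimal_alphas")
}

#' @export
print.optimal_alphas <- function(x, ...) {
  cat("<optimal_alphas> ", nrow(x$per_dataset), " datasets (",
      x$n_failed, " failed)\n", sep = "")
  print(round(rbind(mean = x$alpha, se = x$se), 4))
  invisible(x)
}

#' Learning-rate optimality scores
#'
#' `alpha_diff = alpha - alpha_optimal`, per learning-rate slot: how far a
#' fitted (untransformed) learning rate lies above or below the
#' simulation-derived optimal rate for the same source and phase.
#'
#' @param estimates A data.frame (or named vector) with the four columns
#'   `alpha_primary_stable`, `alpha_primary_volatile`,
#'   `alpha_secondary_stable`, `alpha_secondary_volatile`; any other
#'   columns (subject, drug, ...) are carried through.
#' @param optimal An `"optimal_alphas"` object or a named vector with the
#'   same four slots.
#' @return A data.frame of the same shape with the four alpha columns
#'   replaced by difference scores (all in (-1, 1)).
#' @export
alpha_diff <- function(estimates, optimal) {
  slots <- c("alpha_primary_stable", "alpha_primary_volatile",
             "alpha_secondary_stable", "alpha_secondary_volatile")
  opt <- if (inherits(optimal, "optimal_alphas")) optimal$alpha else optimal
  if (!all(slots %in% names(opt)))
    stop("optimal is missing learning-rate slot(s)", call. = FALSE)
  if (is.null(dim(estimates)))
    estimates <- as.data.frame(as.list(estimates))
  if (!all(slots %in% names(estimates)))
    stop("estimates is missing learning-rate slot(s)", call. = FALSE)
  out <- estimates
  for (s in slots) out[[s]] <- estimates[[s]] - opt[[s]]
  out
}
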