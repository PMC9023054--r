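#' The candidate model family
#'
#' The 2 x 2 x 2 factorial of [model_variant()] flags: learning rates split
#' by information source or not, split by environmental volatility or not,
#' and zeta free or fixed at 0.5 — eight models in total. Exactly one (the
#' last) has all splits on and zeta free; this is the full six-parameter
#' model. The family is plain configuration: supply your own list of
#' variants to the fitting and comparison functions to change it.
#'
#' @return A named list of eight `"model_variant"` objects.
#' @export
#' @examples
#' names(model_space())
model_space <- function() {
  grid <- expand.grid(src = c(FALSE, TRUE), vol = c(FALSE, TRUE),
                      zeta = c(FALSE, TRUE))
  out <- lapply(seq_len(nrow(grid)), function(i)
    model_variant(grid$src[i], grid$vol[i], grid$zeta[i]))
  names(out) <- vapply(out, variant_label, character(1))
  out
}

#' Fit a family of models to a set of subjects
#'
#' Fits every model variant to every subject's trial sequence by
#' [fit_map()] and assembles the subjects x models matrix of approximate
#' log model evidences ([log_model_evidence()]).
#'
#' @param trials_list A list of `"trial_sequence"` objects, one per subject
#'   (or subject-session).
#' @param models A list of [model_variant()]s, default [model_space()].
#' @param priors,n_starts Passed to [fit_map()].
#' @param seed Integer seed; each subject x model fit gets a derived seed.
#' @return A list with `$evidence` (subjects x models matrix) and `$fits`
#'   (nested list of `"fit_result"`).
#' @export
fit_model_space <- function(trials_list, models = model_space(),
                            priors = prior_config(), n_starts = 10L,
                            seed = 1L) {
  stopifnot(length(trials_list) >= 1, length(models) >= 1)
  ev <- matrix(NA_real_, length(trials_list), length(models),
               dimnames = list(names(trials_list), names(models)))
  fits <- vector("list", length(trials_list))
  for (s in seq_along(trials_list)) {
    fits[[s]] <- vector("list", length(models))
    for (m in seq_along(models)) {
      fit_seed <- (as.integer(seed) + 104729L * s + 1299709L * m) %%
        .Machine$integer.max
      fit <- fit_map(trials_list[[s]], priors = priors,
                     variant = models[[m]], n_starts = n_starts,
                     seed = fit_seed)
      ev[s, m] <- log_model_evidence(fit, trials_list[[s]])
      fits[[s]][[m]] <- fit
    }
  }
  list(evidence = ev, fits = fits)
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects and infers
#' the population frequencies of the candidate models from their
#' per-subject log evidences, by the variational Dirichlet scheme: starting
#' from a uniform Dirichlet(1) prior, model responsibilities and Dirichlet
#' counts are iterated to convergence. Exceedance probabilities — the
#' posterior probability that each model is the most frequent one in the
#' population — are estimated from Monte-Carlo draws of the fitted
#' Dirichlet.
#'
#' @param log_evidence Subjects x models matrix of (approximate) log model
#'   evidences; at least 2 subjects and 2 models, all finite.
#' @param seed Integer seed for the exceedance draws.
#' @param n_samples Number of Dirichlet draws (default 100,000).
#' @param tol Convergence tolerance on the Dirichlet parameters.
#' @param max_iter Iteration cap.
#' @return An object of class `"bms_result"`: `$alpha` (Dirichlet
#'   parameters), `$expected_freq` (posterior mean model frequencies,
#'   summing to 1), `$exceedance` (per-model exceedance probabilities),
#'   `$n_subjects`, `$n_models`, `$iterations`.
#' @export
bms <- function(log_evidence, seed = 1L, n_samples = 1e5, tol = 1e-6,
                max_iter = 10000L) {
  log_evidence <- as.matrix(log_evidence)
  if (!all(is.finite(log_evidence)))
    stop("log evidences must all be finite", call. = FALSE)
  n <- nrow(log_evidence)
  K <- ncol(log_evidence)
  if (n < 2 || K < 2)
    stop("need at least 2 subjects and 2 models", call. = FALSE)

  alpha0 <- rep(1, K)
  alpha <- alpha0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lu <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    g <- exp(lu)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol || iter >= max_iter) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  xp <- withr::with_seed(as.integer(seed), {
    draws <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                    nrow = n_samples)
    tabulate(max.col(draws, ties.method = "random"), K) / n_samples
  })

  r <- alpha / sum(alpha)
  names(alpha) <- names(r) <- names(xp) <- colnames(log_evidence)
  structure(list(alpha = alpha, expected_freq = r, exceedance = xp,
                 n_subjects = n, n_models = K, iterations = iter),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> ", x$n_subjects, " subjects, ", x$n_models,
      " models (", x$iterations, " iterations)\n", sep = "")
  print(round(rbind(expected_freq = x$expected_freq,
                    exceedance = x$exceedance), 4))
  invisible(x)
}
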