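#' Model variant flags
#'
#' The model family is the 2 x 2 x 2 factorial of whether learning rates are
#' split by information source, whether they are split by environmental
#' volatility, and whether the secondary-weighting parameter zeta is free or
#' fixed at 0.5. The full model (all three on) has six free parameters: four
#' learning rates, zeta, and the inverse decision temperature beta.
#'
#' @param split_alpha_by_source Separate learning rates for the primary and
#'   secondary source?
#' @param split_alpha_by_volatility Separate learning rates for stable and
#'   volatile phases?
#' @param zeta_free Is the secondary-weighting parameter estimated (otherwise
#'   fixed at 0.5)?
#' @return An object of class `"model_variant"`.
#' @export
#' @examples
#' model_variant()                      # the full six-parameter model
#' model_variant(FALSE, FALSE, FALSE)   # single-alpha model, zeta fixed
model_variant <- function(split_alpha_by_source = TRUE,
                          split_alpha_by_volatility = TRUE,
                          zeta_free = TRUE) {
  structure(list(split_alpha_by_source = isTRUE(split_alpha_by_source),
                 split_alpha_by_volatility = isTRUE(split_alpha_by_volatility),
                 zeta_free = isTRUE(zeta_free)),
            class = "model_variant")
}

variant_label <- function(variant) {
  paste0("src", as.integer(variant$split_alpha_by_source),
         "_vol", as.integer(variant$split_alpha_by_volatility),
         "_zeta", as.integer(variant$zeta_free))
}

#' Parameters of the dual-source Rescorla-Wagner model
#'
#' The four learning rates weight the prediction error in the value update,
#' one per information source (primary / secondary) and phase (stable /
#' volatile); `zeta` is the mixture weight of the advice-derived value
#' relative to the directly learned value; `beta` is the inverse decision
#' temperature of the unit-square sigmoid. `v0` is the shared initial value
#' of both traces and is fixed, not fitted.
#'
#' @param alpha_primary_stable,alpha_primary_volatile,alpha_secondary_stable,alpha_secondary_volatile
#'   Learning rates in (0, 1). Omitted rates default to their stable /
#'   primary counterparts, which is convenient for reduced variants.
#' @param zeta Secondary-weighting parameter in (0, 1).
#' @param beta Inverse decision temperature, > 0.
#' @param v0 Initial value in (0, 1), default 0.5.
#' @param variant A [model_variant()]; when a split flag is off the
#'   corresponding learning rates must be equal.
#' @return An object of class `"rw_params"`.
#' @export
#' @examples
#' rw_params(0.3, 0.4, 0.2, 0.25, zeta = 0.4, beta = 5)
rw_params <- function(alpha_primary_stable,
                      alpha_primary_volatile = alpha_primary_stable,
                      alpha_secondary_stable = alpha_primary_stable,
                      alpha_secondary_volatile = alpha_secondary_stable,
                      zeta = 0.5, beta = 4, v0 = 0.5,
                      variant = model_variant()) {
  p <- structure(list(alpha = c(primary_stable = unname(alpha_primary_stable),
                                primary_volatile = unname(alpha_primary_volatile),
                                secondary_stable = unname(alpha_secondary_stable),
                                secondary_volatile = unname(alpha_secondary_volatile)),
                      zeta = zeta, beta = beta, v0 = v0, variant = variant),
                 class = "rw_params")
  validate_rw_params(p)
  p
}

validate_rw_params <- function(p) {
  a <- p$alpha
  if (any(a < 0 | a > 1)) stop("learning rates must lie in [0, 1]", call. = FALSE)
  if (p$zeta < 0 || p$zeta > 1) stop("zeta must lie in [0, 1]", call. = FALSE)
  if (p$beta <= 0) stop("beta must be positive", call. = FALSE)
  if (p$v0 <= 0 || p$v0 >= 1) stop("v0 must lie in (0, 1)", call. = FALSE)
  v <- p$variant
  eq <- function(x, y) isTRUE(all.equal(x, y, tolerance = 1e-12))
  if (!v$split_alpha_by_source &&
      !(eq(a[["primary_stable"]], a[["secondary_stable"]]) &&
        eq(a[["primary_volatile"]], a[["secondary_volatile"]])))
    stop("variant has no source split but learning rates differ by source",
         call. = FALSE)
  if (!v$split_alpha_by_volatility &&
      !(eq(a[["primary_stable"]], a[["primary_volatile"]]) &&
        eq(a[["secondary_stable"]], a[["secondary_volatile"]])))
    stop("variant has no volatility split but learning rates differ by phase",
         call. = FALSE)
  invisible(p)
}

#' @export
print.rw_params <- function(x, ...) {
  cat("<rw_params> ", variant_label(x$variant), "\n", sep = "")
  cat(sprintf("  alpha: ps=%.3f pv=%.3f ss=%.3f sv=%.3f\n",
              x$alpha[1], x$alpha[2], x$alpha[3], x$alpha[4]))
  cat(sprintf("  zeta=%.3f beta=%.3f v0=%.2f\n", x$zeta, x$beta, x$v0))
  invisible(x)
}

#' Rescorla-Wagner value update
#'
#' `v + alpha * (r - v)`: the predicted value moves toward the observed
#' outcome by a fraction alpha of the prediction error.
#'
#' @param v Current value in \[0, 1\].
#' @param r Binary outcome (0 or 1).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value.
#' @export
#' @examples
#' update_value(0.5, 1, 0.5)  # 0.75
update_value <- function(v, r, alpha) {
  if (any(v < 0 | v > 1)) stop("v must lie in [0, 1]", call. = FALSE)
  if (!all(r %in% c(0, 1))) stop("r must be binary", call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]", call. = FALSE)
  v + alpha * (r - v)
}

#' Advice-weighted value
#'
#' Converts the belief that the secondary source is correct into the
#' probability, implied by its advice, that the primary-congruent option is
#' rewarded: `|advice - v_secondary|`. Advice is coded 0 when it endorses
#' the primary-congruent option.
#'
#' @param advice Binary advice code (0 or 1).
#' @param v_secondary Belief in the secondary source's accuracy, in \[0, 1\].
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' advice_weighted_value(0, 0.8)  # 0.8
#' advice_weighted_value(1, 0.8)  # 0.2
advice_weighted_value <- function(advice, v_secondary) {
  if (!all(advice %in% c(0, 1))) stop("advice must be binary", call. = FALSE)
  if (any(v_secondary < 0 | v_secondary > 1))
    stop("v_secondary must lie in [0, 1]", call. = FALSE)
  abs(advice - v_secondary)
}

#' Combine primary and advice-derived values
#'
#' Convex combination `zeta * v_advice_weighted + (1 - zeta) * v_primary`;
#' zeta is the weight given to the secondary source.
#'
#' @param v_primary,v_advice_weighted Probabilities in \[0, 1\].
#' @param zeta Weight in \[0, 1\].
#' @return Combined probability, between the two inputs.
#' @export
combine_values <- function(v_primary, v_advice_weighted, zeta) {
  if (any(zeta < 0 | zeta > 1)) stop("zeta must lie in [0, 1]", call. = FALSE)
  if (any(v_primary < 0 | v_primary > 1) ||
      any(v_advice_weighted < 0 | v_advice_weighted > 1))
    stop("values must lie in [0, 1]", call. = FALSE)
  zeta * v_advice_weighted + (1 - zeta) * v_primary
}

#' Unit-square sigmoid response rule
#'
#' Maps a belief value to a choice probability:
#' `p = v^beta / (v^beta + (1 - v)^beta)`. At `beta = 1` the map is the
#' identity; larger beta makes choices more deterministic around the belief.
#' Values are clipped to \[1e-6, 1 - 1e-6\] before exponentiation.
#'
#' @param v Belief value in \[0, 1\].
#' @param beta Inverse decision temperature, > 0.
#' @return Choice probability.
#' @export
#' @examples
#' choice_probability(0.8, 2)  # 0.64 / 0.68
choice_probability <- function(v, beta) {
  if (any(beta <= 0)) stop("beta must be positive", call. = FALSE)
  if (any(v < 0 | v > 1)) stop("v must lie in [0, 1]", call. = FALSE)
  v <- pmin(1 - 1e-6, pmax(1e-6, v))
  p <- v^beta / (v^beta + (1 - v)^beta)
  pmin(1 - 1e-12, pmax(1e-12, p))  # keep strictly inside (0, 1) at any beta
}

phase_code <- function(phase) {
  if (!all(phase %in% c("stable", "volatile")))
    stop("phase labels must be 'stable' or 'volatile'", call. = FALSE)
  as.integer(phase == "volatile")
}

check_trials_complete <- function(trials) {
  need <- c("r", "advice", "phase_primary", "phase_secondary")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(trials$r) || anyNA(trials$advice))
    stop("trials has missing outcomes or advice", call. = FALSE)
  if (!all(trials$r %in% 0:1) || !all(trials$advice %in% 0:1))
    stop("outcomes and advice must be binary", call. = FALSE)
  invisible(trials)
}

#' Run the dual-source model over a trial sequence
#'
#' Initialises both value traces at `v0` and, on each trial, computes the
#' advice-weighted secondary value, the zeta-combined value and the choice
#' probability, then updates the primary trace with the outcome (learning
#' rate selected by the primary source's phase label) and the secondary
#' trace with the inferred correctness of the advice (learning rate selected
#' by the secondary source's phase label).
#'
#' @param params An [rw_params()].
#' @param trials A `"trial_sequence"` with outcomes, advice and phase labels.
#' @return A `data.frame` of class `"belief_trajectory"` with per-trial
#'   columns `v_primary`, `v_secondary`, `v_advice_weighted`, `v_combined`,
#'   `p_choice`, `pe_primary`, `pe_secondary`. Values are those holding
#'   *before* the trial's outcome is observed.
#' @export
run_model <- function(params, trials) {
  validate_rw_params(params)
  check_trials_complete(trials)
  y <- if ("y" %in% names(trials)) as.integer(trials$y)
       else rep(NA_integer_, nrow(trials))
  out <- rw_filter_cpp(unname(params$alpha), params$zeta, params$beta,
                       params$v0,
                       as.integer(trials$r), as.integer(trials$advice),
                       phase_code(trials$phase_primary),
                       phase_code(trials$phase_secondary), y)
  traj <- data.frame(trial = seq_len(nrow(trials)),
                     v_primary = out$v_primary,
                     v_secondary = out$v_secondary,
                     v_advice_weighted = out$v_advice_weighted,
                     v_combined = out$v_combined,
                     p_choice = out$p_choice,
                     pe_primary = out$pe_primary,
                     pe_secondary = out$pe_secondary)
  attr(traj, "nll") <- out$nll
  attr(traj, "n_choices") <- out$n_choices
  class(traj) <- c("belief_trajectory", "data.frame")
  traj
}

#' Negative log-likelihood of observed choices
#'
#' Bernoulli negative log-likelihood of the non-missing choices `y` under
#' the model's per-trial choice probabilities. Trials with missing `y`
#' still drive belief updating (the feedback was shown) but contribute
#' nothing to the likelihood.
#'
#' @inheritParams run_model
#' @return Non-negative scalar.
#' @export
negative_log_likelihood <- function(params, trials) {
  validate_rw_params(params)
  check_trials_complete(trials)
  y <- as.integer(trials$y)
  if (all(is.na(y))) stop("all choices are missing", call. = FALSE)
  if (!all(y[!is.na(y)] %in% 0:1)) stop("choices must be binary", call. = FALSE)
  rw_nll_cpp(unname(params$alpha), params$zeta, params$beta, params$v0,
             as.integer(trials$r), as.integer(trials$advice),
             phase_code(trials$phase_primary),
             phase_code(trials$phase_secondary), y)
}
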