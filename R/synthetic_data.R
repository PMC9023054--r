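#' Forward-simulate an agent on a schedule
#'
#' Samples a trial realisation from the schedule, runs the dual-source
#' model forward, and draws choices `y(t) ~ Bernoulli(p_choice(t))`.
#' Belief updating depends only on the outcomes and advice (which are shown
#' regardless of choice), so the trajectory can be computed before choices
#' are sampled.
#'
#' @param params Generating [rw_params()].
#' @param schedule A `"task_schedule"`.
#' @param seed Integer seed (one seed governs outcomes, advice and choices).
#' @param subject,group,drug,session Metadata labels.
#' @return A `"trial_sequence"` with choices filled in, an extra
#'   `p_choice` column (the generating choice probabilities), and the
#'   generating parameters attached as `attr(, "params")`.
#' @export
simulate_agent <- function(params, schedule, seed = 1L, subject = "agent",
                           group = c("individual-primary", "social-primary"),
                           drug = c("PLA", "HAL"), session = 1L) {
  validate_rw_params(params)
  group <- match.arg(group)
  drug <- match.arg(drug)
  withr::with_seed(as.integer(seed), {
    trials <- sample_trials(schedule, subject = subject, group = group,
                            drug = drug, session = session)
    traj <- run_model(params, trials)
    trials$y <- rbinom(nrow(trials), 1L, traj$p_choice)
    trials$p_choice <- traj$p_choice
    attr(trials, "params") <- params
    trials
  })
}

default_alpha_means <- function() {
  list(PLA = c(alpha_primary_stable = 0.290, alpha_primary_volatile = 0.184,
               alpha_secondary_stable = 0.151, alpha_secondary_volatile = 0.187),
       HAL = c(alpha_primary_stable = 0.218, alpha_primary_volatile = 0.169,
               alpha_secondary_stable = 0.200, alpha_secondary_volatile = 0.202))
}

# Between-subject natural-space SDs: per-condition SEM x sqrt(n) at n = 31,
# pooled across the two drug conditions per slot.
default_alpha_sds <- function() {
  n <- 31
  se <- list(PLA = c(0.041, 0.018, 0.025, 0.028),
             HAL = c(0.033, 0.029, 0.026, 0.023))
  sds <- sqrt((se$PLA^2 + se$HAL^2) / 2 * n)
  names(sds) <- names(default_alpha_means()$PLA)
  sds
}

#' Specification of a synthetic cohort
#'
#' Defines the generative population for a two-group, two-session
#' (drug/placebo crossover) cohort. Per-subject parameters are sampled in
#' transformed space (logit for learning rates and zeta, log for beta):
#' each subject draws one offset per parameter, shared across sessions, and
#' the session's parameters are the drug-condition mean plus that offset —
#' so the drug effect is a within-subject shift of the condition means.
#' Sampling in transformed space keeps every draw inside the parameter
#' bounds. Transformed-space SDs are derived from the natural-space SDs by
#' the delta method at the slot's grand mean.
#'
#' The default condition means encode the effect this analysis pipeline is
#' designed to detect: a dopaminergic intervention (`HAL`) that lowers the
#' primary-source learning rates relative to placebo (`PLA`) and leaves
#' the secondary-source rates essentially unchanged, at learning-rate
#' magnitudes typical for this task family. Default SDs are per-subject
#' between-subject spreads consistent with a cohort of around 31
#' participants. The zeta and beta population values (zeta 0.3 +/- 0.15,
#' beta 4 with 30% log-scale spread, no drug effect on either) are
#' declared package choices.
#'
#' @param n_subjects Named integer vector: subjects per group.
#' @param alpha_means List with elements `PLA` and `HAL`, each a named
#'   vector over the four learning-rate slots.
#' @param alpha_sds Named vector of natural-space between-subject SDs per
#'   slot (shared across drug conditions).
#' @param zeta_mean,zeta_sd,beta_mean,beta_sd_log Population location and
#'   spread of zeta (natural space) and beta (log-normal).
#' @param schedule_config A single [schedule_config()] or a list of them
#'   (default the four counterbalanced [schedule_variants()]); subjects are
#'   assigned to the configurations round-robin, and each subject's
#'   schedule realisation is reused on both sessions (outcomes are redrawn
#'   per session).
#' @param seed Integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = c("individual-primary" = 15L,
                                       "social-primary" = 16L),
                        alpha_means = default_alpha_means(),
                        alpha_sds = default_alpha_sds(),
                        zeta_mean = 0.3, zeta_sd = 0.15,
                        beta_mean = 4, beta_sd_log = 0.3,
                        schedule_config = schedule_variants(),
                        seed = 1L) {
  stopifnot(all(n_subjects >= 1), !is.null(names(n_subjects)))
  slots <- names(default_alpha_means()$PLA)
  for (d in c("PLA", "HAL"))
    if (!all(slots %in% names(alpha_means[[d]])))
      stop("alpha_means$", d, " must name all four learning-rate slots",
           call. = FALSE)
  if (any(unlist(alpha_means) <= 0 | unlist(alpha_means) >= 1) ||
      zeta_mean <= 0 || zeta_mean >= 1 || beta_mean <= 0)
    stop("generative means must respect parameter bounds", call. = FALSE)
  structure(list(n_subjects = n_subjects, alpha_means = alpha_means,
                 alpha_sds = alpha_sds, zeta_mean = zeta_mean,
                 zeta_sd = zeta_sd, beta_mean = beta_mean,
                 beta_sd_log = beta_sd_log,
                 schedule_config = schedule_config,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# delta-method SD on the logit scale at mean m
logit_sd <- function(sd_nat, m) sd_nat / (m * (1 - m))

#' Generate a synthetic cohort
#'
#' Samples per-subject generative parameters from a [cohort_spec()],
#' simulates both sessions of every subject with [simulate_agent()]
#' (drug order counterbalanced by subject index, one schedule per subject
#' reused across sessions with fresh outcome draws), and returns the
#' trial data together with the ground-truth parameter table.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `"cohort"`: `$trials` (row-bound
#'   `"trial_sequence"` across all subject-sessions, including the
#'   generating `p_choice`), `$truth` (one row per subject-session with the
#'   generating parameters), `$spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  slots <- names(default_alpha_means()$PLA)
  groups <- names(spec$n_subjects)
  n_total <- sum(spec$n_subjects)

  grand_mean <- (spec$alpha_means$PLA[slots] + spec$alpha_means$HAL[slots]) / 2
  sd_t_alpha <- logit_sd(spec$alpha_sds[slots], grand_mean)
  sd_t_zeta <- logit_sd(spec$zeta_sd, spec$zeta_mean)

  offsets <- withr::with_seed(spec$seed, {
    m <- matrix(rnorm(n_total * 6), n_total, 6)
    m[, 1:4] <- sweep(m[, 1:4, drop = FALSE], 2, sd_t_alpha, "*")
    m[, 5] <- m[, 5] * sd_t_zeta
    m[, 6] <- m[, 6] * spec$beta_sd_log
    m
  })

  trials_all <- list()
  truth <- list()
  idx <- 0L
  for (g in groups) {
    for (i in seq_len(spec$n_subjects[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("%s_s%02d", substr(g, 1, 3), i)
      configs <- if (inherits(spec$schedule_config, "schedule_config"))
        list(spec$schedule_config) else spec$schedule_config
      cfg <- configs[[(idx - 1L) %% length(configs) + 1L]]
      cfg$seed <- (spec$seed + 271L * idx) %% .Machine$integer.max
      sched <- generate_schedule(cfg)
      drug_order <- if (idx %% 2L == 1L) c("PLA", "HAL") else c("HAL", "PLA")
      for (session in 1:2) {
        drug <- drug_order[session]
        theta_a <- qlogis(spec$alpha_means[[drug]][slots]) + offsets[idx, 1:4]
        theta_z <- qlogis(spec$zeta_mean) + offsets[idx, 5]
        theta_b <- log(spec$beta_mean) + offsets[idx, 6]
        a <- plogis(theta_a)
        pars <- rw_params(a[1], a[2], a[3], a[4], zeta = plogis(theta_z),
                          beta = exp(theta_b))
        sim_seed <- (spec$seed + 9241L * idx + session) %%
          .Machine$integer.max
        tr <- simulate_agent(pars, sched, seed = sim_seed, subject = sid,
                             group = g, drug = drug, session = session)
        trials_all[[length(trials_all) + 1L]] <- tr
        truth[[length(truth) + 1L]] <-
          data.frame(subject = sid, group = g, drug = drug,
                     session = session,
                     t(c(unname(pars$alpha), pars$zeta, pars$beta)))
      }
    }
  }
  truth <- do.call(rbind, truth)
  names(truth)[5:10] <- c(slots, "zeta", "beta")
  structure(list(trials = do.call(rbind, trials_all), truth = truth,
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$truth), " subject-sessions, ",
      nrow(x$trials), " trials\n", sep = "")
  print(table(x$truth$group, x$truth$drug))
  invisible(x)
}

#' Write a cohort to delimited text
#'
#' Writes `trials.csv` (the standard trial columns, see [write_trials()])
#' and `truth.csv` (the ground-truth generating parameters) into `dir`.
#'
#' @param cohort A `"cohort"`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trials(cohort$trials, file.path(dir, "trials.csv"))
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}
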