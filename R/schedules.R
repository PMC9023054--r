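#' Block specification helper
#'
#' Describes one phase block of a probabilistic schedule.
#'
#' @param phase `"stable"` or `"volatile"`.
#' @param length Block length in trials. Stable blocks must be longer than
#'   30 trials, matching the task's definition of a stable phase.
#' @param p_high Reward probability of the favoured option within the block,
#'   in (0.5, 1). In a volatile block the probability alternates between
#'   `p_high` and `1 - p_high` at each reversal.
#' @return A one-row `data.frame` with columns `phase`, `length`, `p_high`.
#' @export
#' @examples
#' rbind(schedule_block("stable", 60, 0.8), schedule_block("volatile", 60, 0.8))
schedule_block <- function(phase = c("stable", "volatile"), length, p_high = 0.8) {
  phase <- match.arg(phase)
  stopifnot(is.numeric(length), length >= 1, length == round(length))
  if (p_high <= 0.5 || p_high >= 1)
    stop("p_high must lie in (0.5, 1)", call. = FALSE)
  data.frame(phase = phase, length = as.integer(length), p_high = p_high)
}

default_primary_blocks <- function(p_high = 0.8) {
  rbind(schedule_block("stable", 60L, p_high),
        schedule_block("volatile", 60L, p_high))
}

default_secondary_blocks <- function(p_high = 0.8) {
  # offset against the primary source so stable/volatile phases of the two
  # schedules are not aligned
  rbind(schedule_block("stable", 35L, p_high),
        schedule_block("volatile", 50L, p_high),
        schedule_block("stable", 35L, p_high))
}

#' Counterbalanced schedule variants
#'
#' The task assigns participants to one of four counterbalanced
#' pseudo-randomisation schedules. These are reconstructed here as the
#' 2 x 2 crossing of phase order for the two sources: the primary source is
#' either stable-first (60 stable + 60 volatile trials) or volatile-first,
#' and the secondary source is either stable-volatile-stable (35/50/35) or
#' volatile-stable-volatile (40/40/40). In every variant the stable and
#' volatile phases of the two sources are offset rather than aligned.
#'
#' @param p_high Reward probability of the favoured option (default 0.8).
#' @param n_trials Session length; the built-in block layouts are defined
#'   for 120 trials.
#' @return A named list of four [schedule_config()] objects.
#' @export
#' @examples
#' names(schedule_variants())
schedule_variants <- function(p_high = 0.8, n_trials = 120L) {
  stopifnot(n_trials == 120L)
  pri <- list(
    sv = rbind(schedule_block("stable", 60L, p_high),
               schedule_block("volatile", 60L, p_high)),
    vs = rbind(schedule_block("volatile", 60L, p_high),
               schedule_block("stable", 60L, p_high)))
  sec <- list(
    svs = rbind(schedule_block("stable", 35L, p_high),
                schedule_block("volatile", 50L, p_high),
                schedule_block("stable", 35L, p_high)),
    vsv = rbind(schedule_block("volatile", 40L, p_high),
                schedule_block("stable", 40L, p_high),
                schedule_block("volatile", 40L, p_high)))
  out <- list()
  for (pn in names(pri))
    for (sn in names(sec))
      out[[paste(pn, sn, sep = "_")]] <-
        schedule_config(n_trials = n_trials, blocks_primary = pri[[pn]],
                        blocks_secondary = sec[[sn]])
  out
}

#' Schedule configuration
#'
#' Configuration for a pair of independent probabilistic reward schedules
#' (primary and secondary source) over one session. Each source is an
#' ordered list of stable and volatile blocks; block lengths must sum to
#' `n_trials`, stable blocks must exceed 30 trials, and within volatile
#' blocks the reward probability reverses at intervals drawn from
#' `volatile_switch_range`.
#'
#' @param n_trials Number of trials per session (default 120).
#' @param blocks_primary,blocks_secondary Block tables as built by
#'   [schedule_block()]; defaults give a 60-trial stable then 60-trial
#'   volatile primary schedule and a 35/50/35 stable-volatile-stable
#'   secondary schedule, so the phases of the two sources are offset.
#' @param volatile_switch_range Integer pair: minimum and maximum number of
#'   trials between reversals in a volatile block (default `c(10, 20)`).
#' @param seed Optional integer seed making schedule generation and trial
#'   sampling reproducible.
#' @return An object of class `"schedule_config"`.
#' @export
#' @examples
#' cfg <- schedule_config(seed = 1)
#' sched <- generate_schedule(cfg)
#' head(sched)
schedule_config <- function(n_trials = 120L,
                            blocks_primary = default_primary_blocks(),
                            blocks_secondary = default_secondary_blocks(),
                            volatile_switch_range = c(10L, 20L),
                            seed = NULL) {
  cfg <- structure(list(n_trials = as.integer(n_trials),
                        blocks_primary = blocks_primary,
                        blocks_secondary = blocks_secondary,
                        volatile_switch_range = as.integer(volatile_switch_range),
                        seed = if (is.null(seed)) NULL else as.integer(seed)),
                   class = "schedule_config")
  validate_schedule_config(cfg)
  cfg
}

validate_schedule_config <- function(cfg) {
  for (side in c("blocks_primary", "blocks_secondary")) {
    blocks <- cfg[[side]]
    if (!all(c("phase", "length", "p_high") %in% names(blocks)))
      stop(side, " must have columns phase, length, p_high", call. = FALSE)
    if (sum(blocks$length) != cfg$n_trials)
      stop(side, ": block lengths sum to ", sum(blocks$length),
           ", not n_trials = ", cfg$n_trials, call. = FALSE)
    stable <- blocks$phase == "stable"
    if (any(blocks$length[stable] <= 30))
      stop(side, ": stable blocks must be longer than 30 trials",
           call. = FALSE)
    if (any(blocks$p_high <= 0.5 | blocks$p_high >= 1))
      stop(side, ": p_high must lie in (0.5, 1)", call. = FALSE)
  }
  rng <- cfg$volatile_switch_range
  if (length(rng) != 2 || rng[1] < 1 || rng[2] < rng[1])
    stop("volatile_switch_range must be an increasing integer pair",
         call. = FALSE)
  invisible(cfg)
}

# Partition a volatile block of `len` trials into reversal intervals, each
# within [lo, hi]. Intervals are drawn uniformly from the feasible subset of
# [lo, hi] that leaves a remainder of either 0 or at least lo, so no short
# leftover run can occur at the block end.
partition_intervals <- function(len, lo, hi) {
  out <- integer(0)
  remaining <- len
  while (remaining > 0) {
    feasible <- seq.int(lo, min(hi, remaining))
    feasible <- feasible[remaining - feasible == 0 | remaining - feasible >= lo]
    if (length(feasible) == 0)
      stop("volatile block of length ", len,
           " cannot be partitioned into intervals in [", lo, ", ", hi, "]",
           call. = FALSE)
    iv <- if (length(feasible) == 1) feasible else sample(feasible, 1)
    out <- c(out, iv)
    remaining <- remaining - iv
  }
  out
}

build_source_schedule <- function(blocks, rng) {
  p <- numeric(0)
  phase <- character(0)
  for (b in seq_len(nrow(blocks))) {
    len <- blocks$length[b]
    q <- blocks$p_high[b]
    if (blocks$phase[b] == "stable") {
      p <- c(p, rep(q, len))
    } else {
      intervals <- partition_intervals(len, rng[1], rng[2])
      level <- sample(c(q, 1 - q), 1)  # random starting arm of the reversal
      for (iv in intervals) {
        p <- c(p, rep(level, iv))
        level <- 1 - level
      }
    }
    phase <- c(phase, rep(blocks$phase[b], len))
  }
  list(p = p, phase = phase)
}

#' Generate a task schedule
#'
#' Realises a [schedule_config()] into per-trial reward probabilities and
#' phase labels for the primary and secondary sources. The two sources are
#' constructed independently (uncorrelated pseudo-randomised schedules):
#' reversal placement and volatile starting arms are drawn separately per
#' source.
#'
#' @param config A [schedule_config()].
#' @return A `data.frame` of class `"task_schedule"` with columns `trial`,
#'   `p_primary`, `p_secondary`, `phase_primary`, `phase_secondary`.
#'   `p_primary(t)` is the probability that the primary-congruent option is
#'   rewarded on trial `t`; `p_secondary(t)` the probability that the
#'   secondary source's advice is correct.
#' @export
generate_schedule <- function(config) {
  validate_schedule_config(config)
  build <- function() {
    rng <- config$volatile_switch_range
    pri <- build_source_schedule(config$blocks_primary, rng)
    sec <- build_source_schedule(config$blocks_secondary, rng)
    structure(data.frame(trial = seq_len(config$n_trials),
                         p_primary = pri$p, p_secondary = sec$p,
                         phase_primary = pri$phase,
                         phase_secondary = sec$phase,
                         stringsAsFactors = FALSE),
              class = c("task_schedule", "data.frame"))
  }
  if (is.null(config$seed)) build() else withr::with_seed(config$seed, build())
}

#' Sample a trial sequence from a schedule
#'
#' Draws the realised binary outcomes and advice for one session.
#' The outcome of the primary-congruent option is `r(t) ~
#' Bernoulli(p_primary(t))`; the secondary source's correctness is drawn
#' independently as `Bernoulli(p_secondary(t))`, and the advice is coded
#' relative to the primary-congruent option (`advice = 0` endorses it), so
#' that the advice endorses the rewarded option exactly when the correctness
#' draw is 1. Choices `y` are left missing; fill them with observed data or
#' with [simulate_agent()].
#'
#' @param schedule A `"task_schedule"` from [generate_schedule()].
#' @param seed Optional integer seed.
#' @param subject,group,drug,session Metadata labels copied into the output.
#' @return A `data.frame` of class `"trial_sequence"` with the schedule
#'   columns plus `r`, `advice`, `y` (all integer; `y` is `NA`), and the
#'   metadata columns `subject`, `group`, `drug`, `session`.
#' @export
sample_trials <- function(schedule, seed = NULL, subject = "agent",
                          group = c("individual-primary", "social-primary"),
                          drug = c("PLA", "HAL"), session = 1L) {
  stopifnot(inherits(schedule, "task_schedule"))
  group <- match.arg(group)
  drug <- match.arg(drug)
  draw <- function() {
    n <- nrow(schedule)
    r <- rbinom(n, 1L, schedule$p_primary)
    correct <- rbinom(n, 1L, schedule$p_secondary)
    # advice endorses the rewarded option iff the correctness draw is 1
    advice <- ifelse(correct == 1L, 1L - r, r)
    out <- schedule
    out$r <- as.integer(r)
    out$advice <- as.integer(advice)
    out$y <- NA_integer_
    out$subject <- subject
    out$group <- group
    out$drug <- drug
    out$session <- as.integer(session)
    class(out) <- c("trial_sequence", "data.frame")
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# Secondary-source correctness inferred from feedback: the advice was
# correct iff it endorsed the rewarded option.
secondary_outcome <- function(trials) {
  as.integer(trials$advice != trials$r)
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("<task_schedule> ", nrow(x), " trials\n", sep = "")
  for (side in c("primary", "secondary")) {
    ph <- x[[paste0("phase_", side)]]
    runs <- rle(ph)
    cat("  ", side, ": ", paste0(runs$values, "(", runs$lengths, ")",
                                 collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

#' Write / read trial sequences as CSV
#'
#' One row per trial with columns `trial`, `p_primary`, `p_secondary`,
#' `phase_primary`, `phase_secondary`, `r`, `advice`, `y`, `subject`,
#' `group`, `drug`, `session`. Missing choices are written as empty fields.
#' Several sessions may be concatenated in one file; [read_trials()] returns
#' the full table, and [split_trials()] recovers the per-session sequences.
#'
#' @param trials A `"trial_sequence"` (or row-bound set of them).
#' @param path File path.
#' @return `read_trials()` returns a `"trial_sequence"` data.frame.
#' @export
write_trials <- function(trials, path) {
  cols <- c("trial", "p_primary", "p_secondary", "phase_primary",
            "phase_secondary", "r", "advice", "y", "subject", "group",
            "drug", "session")
  write.csv(as.data.frame(trials)[, cols], path, row.names = FALSE,
            na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(y = "integer"))
  structure(x, class = c("trial_sequence", "data.frame"))
}

#' @rdname write_trials
#' @export
split_trials <- function(trials) {
  key <- interaction(trials$subject, trials$session, trials$drug, drop = TRUE)
  lapply(split(as.data.frame(trials), key), function(d) {
    structure(d[order(d$trial), ], class = c("trial_sequence", "data.frame"))
  })
}

#' Save / load a schedule configuration as JSON
#' @param config A [schedule_config()].
#' @param path File path.
#' @export
write_schedule_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_schedule_config
#' @export
read_schedule_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  schedule_config(n_trials = x$n_trials,
                  blocks_primary = as.data.frame(x$blocks_primary),
                  blocks_secondary = as.data.frame(x$blocks_secondary),
                  volatile_switch_range = x$volatile_switch_range,
                  seed = x$seed)
}
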