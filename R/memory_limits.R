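#' Memory-limit configuration
#'
#' Under the memory-failure protocol the planning agent has probability
#' `p_fail` of "losing its place" before each decision-bearing simulation
#' step, which terminates the trial immediately. For the flat and
#' hierarchical agents every simulated primitive step carries working
#' memory, so each step draws a check; the saltatory agent holds only one
#' decision in mind per option launch and draws one check per decision.
#' That granularity is the mechanism by which option models confer
#' robustness, and it can be overridden via `per_step_failure`.
#'
#' @param p_fail Failure probability per check, in `[0, 1]`.
#' @param counting_rule `"rollout_to_goal"` (record what the agent would
#'   have taken, by greedy rollout without learning) or `"discard"`.
#' @param per_step_failure `NA` for the per-agent default described above,
#'   or TRUE/FALSE to force per-step / per-decision checks for all agents.
#' @return A `memory_limit_config` list.
#' @export
memory_limit_config <- function(p_fail,
                                counting_rule = c("rollout_to_goal", "discard"),
                                per_step_failure = NA) {
  stopifnot(p_fail >= 0, p_fail <= 1)
  structure(list(p_fail = p_fail, counting_rule = match.arg(counting_rule),
                 per_step_failure = per_step_failure),
            class = "memory_limit_config")
}

#' Run one planning trial under a memory limit
#'
#' As [plan_trial()], but before each decision-bearing simulation step the
#' trial terminates with probability `p_fail`; learning updates apply only
#' to the pre-failure prefix (an option interrupted mid-execution is never
#' backed up). Under the `rollout_to_goal` counting rule the current greedy
#' policy is rolled out, without updates, from the failure point to the
#' goal to record the steps the agent would have taken.
#'
#' @param planner A `planner`.
#' @param config A [memory_limit_config()].
#' @return One-row tibble: trial counters plus `would_have_taken` (in the
#'   agent's simulated-action metric) and `censored` (rollout hit the cap).
#' @export
plan_trial_with_memory_limit <- function(planner, config) {
  stopifnot(inherits(config, "memory_limit_config"))
  res <- trial_core(planner, p_fail = config$p_fail,
                    per_step_failure = config$per_step_failure,
                    rollout_wht = config$counting_rule == "rollout_to_goal")
  planner$trial_index <- planner$trial_index + 1L
  tibble::tibble(trial_index = planner$trial_index,
                 primitive_steps = res$primitive_steps,
                 decisions = res$decisions,
                 sim_actions = res$sim_actions,
                 completed = res$completed,
                 would_have_taken = res$would_have_taken,
                 censored = res$censored)
}

#' Simulate many memory-limited trials of the current policy
#'
#' Repeats the memory-failure protocol `n_trials` times against the
#' planner's current value table, by default without learning, which makes
#' it the empirical counterpart of [survival_probability()]: a converged
#' policy whose trajectory takes `n` decisions completes each trial with
#' probability `(1 - p_fail)^n`.
#'
#' @param planner A `planner`.
#' @param n_trials Number of simulated trials.
#' @param config A [memory_limit_config()].
#' @param learn Apply backups during the trials (default FALSE).
#' @param epsilon Exploration rate for these trials (default 0: greedy).
#' @return Tibble with one row per trial: `primitive_steps`, `decisions`,
#'   `completed`.
#' @export
simulate_memory_trials <- function(planner, n_trials, config,
                                   learn = FALSE, epsilon = 0) {
  stopifnot(inherits(config, "memory_limit_config"))
  m <- matrix(0L, n_trials, 3L)
  for (i in seq_len(n_trials)) {
    res <- trial_core(planner, p_fail = config$p_fail,
                      per_step_failure = config$per_step_failure,
                      update = learn, epsilon = epsilon)
    m[i, ] <- c(res$primitive_steps, res$decisions, res$completed)
  }
  tibble::tibble(primitive_steps = m[, 1], decisions = m[, 2],
                 completed = as.logical(m[, 3]))
}

#' Survival probability of an n-decision plan
#'
#' With a failure check before each of `n_decisions` decisions, the
#' probability that a trial runs to completion is `(1 - p_fail)^n`.
#'
#' @param n_decisions Number of decision-bearing steps (>= 0).
#' @param p_fail Per-decision failure probability.
#' @return Probability in `[0, 1]`.
#' @export
survival_probability <- function(n_decisions, p_fail) {
  stopifnot(all(n_decisions >= 0), p_fail >= 0, p_fail <= 1)
  (1 - p_fail)^n_decisions
}
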