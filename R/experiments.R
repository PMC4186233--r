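#' Experiment configuration
#'
#' Bundles the knobs shared by the three packaged experiments. Defaults
#' reproduce the reference study conditions: the four-room map, 100
#' simulation runs of 100 trials, a 10-step moving average, failure
#' probability 0.1 for the memory-limited experiment, and gamma = 0.95.
#'
#' @param map Path to an ASCII map, or a `gridworld` (default: the shipped
#'   four-room map).
#' @param agents Agents to simulate.
#' @param n_trials,n_runs Trials per run / number of runs.
#' @param n_trials_memory Trials per run for the memory-limited experiment
#'   (default 500): truncated trials carry roughly a tenth of the learning
#'   signal of unconstrained ones, so the convergence contrast needs a
#'   longer horizon.
#' @param seed_base Base seed; run `i` uses `seed_base + i`.
#' @param p_fail Memory-failure probability (memory experiment only).
#' @param smoothing_window Moving-average window (<= n_trials).
#' @param gamma Discount.
#' @param epsilon,alpha Planner exploration rate and backup damping.
#' @param n_explore_steps Latent-learning walk length (subgoal discovery).
#' @param gamma_sr SR discount.
#' @param k_candidates Candidate cluster counts.
#' @param output_dir Optional directory for CSV outputs.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(map = NULL,
                              agents = c("flat", "hierarchical", "saltatory"),
                              n_trials = 100L, n_runs = 100L,
                              n_trials_memory = 500L,
                              seed_base = 20140480L, p_fail = 0.1,
                              smoothing_window = 10L, gamma = 0.95,
                              epsilon = 0.1, alpha = 1,
                              n_explore_steps = 1e5, gamma_sr = 0.95,
                              k_candidates = 2:8, output_dir = NULL) {
  if (is.null(map))
    map <- system.file("extdata", "rooms_default.map", package = "saltatory")
  world <- if (inherits(map, "gridworld")) map else read_map(map, discount = gamma)
  stopifnot(n_trials >= smoothing_window, n_runs >= 1,
            p_fail >= 0, p_fail <= 1)
  structure(list(world = world, agents = agents, n_trials = as.integer(n_trials),
                 n_trials_memory = as.integer(n_trials_memory),
                 n_runs = as.integer(n_runs), seed_base = as.integer(seed_base),
                 p_fail = p_fail, smoothing_window = as.integer(smoothing_window),
                 gamma = gamma, epsilon = epsilon, alpha = alpha,
                 n_explore_steps = n_explore_steps, gamma_sr = gamma_sr,
                 k_candidates = k_candidates, output_dir = output_dir),
            class = "experiment_config")
}

write_experiment_csv <- function(df, config, name) {
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(df, file.path(config$output_dir, name))
  }
  invisible(df)
}

# mean across runs first, then trailing moving average
smooth_curves <- function(trials, value_col, window) {
  value_col <- rlang::ensym(value_col)
  curves <- trials |>
    dplyr::group_by(.data$agent, .data$trial) |>
    dplyr::summarise(mean_value = mean(as.numeric(!!value_col)),
                     .groups = "drop_last") |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::reframe(trial = .data$trial[window:dplyr::n()],
                   smoothed = moving_average(.data$mean_value, window),
                   mean_value = .data$mean_value[window:dplyr::n()])
  curves
}

#' Planning-performance experiment
#'
#' Runs the configured agents on the map with shared per-run seeds and no
#' memory limit, and returns per-trial simulated-action counts averaged
#' across runs then smoothed with the configured moving average. Simulated
#' actions are primitive steps for the flat and hierarchical agents and
#' decisions for the saltatory agent (both columns are retained). Two
#' oracle reference lines accompany the curves: the minimum number of
#' primitive actions to reach the goal (BFS) and the minimum number of
#' decisions using option models.
#'
#' @param config An [experiment_config()].
#' @return A list of class `planning_curves`: `curves` (smoothed tibble),
#'   `trials` (raw per-run records), `references` (named oracle lines).
#' @export
experiment_planning_curves <- function(config) {
  world <- config$world
  trials <- run_planning(world, agents = config$agents,
                         n_trials = config$n_trials, n_runs = config$n_runs,
                         seeds = config$seed_base + seq_len(config$n_runs),
                         p_fail = 0, epsilon = config$epsilon,
                         alpha = config$alpha, gamma = config$gamma)
  curves <- smooth_curves(trials, sim_actions, config$smoothing_window)
  steps_curves <- smooth_curves(trials, primitive_steps, config$smoothing_window)
  curves$smoothed_primitive_steps <- steps_curves$smoothed
  opts <- make_doorway_options(world)
  refs <- c(min_primitive_steps = shortest_path_length(world, world$start, world$goal),
            min_option_decisions = min_decision_count(world, opts))
  out <- structure(list(curves = curves, trials = trials, references = refs,
                        config = config), class = "planning_curves")
  write_experiment_csv(curves, config, "planning_curves.csv")
  write_experiment_csv(trials, config, "planning_trials.csv")
  out
}

#' Memory-limited planning experiment
#'
#' As [experiment_planning_curves()], but each trial runs under the
#' memory-failure protocol: with probability `p_fail` per decision-bearing
#' simulation step the agent loses its place and the trial ends. The curve
#' records, per trial, the steps the agent would have taken had it been
#' allowed to continue to the goal (greedy rollout, no learning), plus
#' per-run completion rates.
#'
#' @param config An [experiment_config()] with `p_fail > 0` (use
#'   `p_fail = 0` to recover the unconstrained experiment exactly).
#' @return A list of class `memory_curves`: `curves`, `trials`,
#'   `completion` (per agent x run), `references`.
#' @export
experiment_memory_planning <- function(config) {
  world <- config$world
  if (config$p_fail == 0) {
    base <- experiment_planning_curves(config)
    return(structure(c(base, list(completion = NULL)), class = "memory_curves"))
  }
  trials <- run_planning(world, agents = config$agents,
                         n_trials = config$n_trials_memory,
                         n_runs = config$n_runs,
                         seeds = config$seed_base + seq_len(config$n_runs),
                         p_fail = config$p_fail,
                         counting_rule = "rollout_to_goal",
                         epsilon = config$epsilon, alpha = config$alpha,
                         gamma = config$gamma)
  curves <- smooth_curves(trials, would_have_taken, config$smoothing_window)
  completion <- trials |>
    dplyr::group_by(.data$agent, .data$run) |>
    dplyr::summarise(completion_rate = mean(.data$completed), .groups = "drop")
  opts <- make_doorway_options(world)
  refs <- c(min_primitive_steps = shortest_path_length(world, world$start, world$goal),
            min_option_decisions = min_decision_count(world, opts))
  out <- structure(list(curves = curves, trials = trials,
                        completion = completion, references = refs,
                        config = config), class = "memory_curves")
  write_experiment_csv(curves, config, "memory_curves.csv")
  write_experiment_csv(trials, config, "memory_trials.csv")
  write_experiment_csv(completion, config, "memory_completion.csv")
  out
}

#' Subgoal-discovery experiment
#'
#' The full latent-learning pipeline: reward-free exploration of the map
#' estimates a transition model; the successor representation is computed
#' from it; states are clustered by their predictive representations; the
#' rows are embedded in two dimensions; and bottleneck states are read off
#' the silhouette structure. On the four-room map the large clusters are
#' the rooms and the isolated low-silhouette points are the doorways.
#'
#' @param config An [experiment_config()].
#' @return A tibble of class `sr_discovery`: per state `state`, `row`,
#'   `col`, `cluster`, `silhouette`, `x`, `y`, `is_bottleneck`, with
#'   attributes `chosen_k` and `bottlenecks`.
#' @export
experiment_subgoal_discovery <- function(config) {
  world <- config$world
  Th <- transition_model_from_exploration(world, config$n_explore_steps,
                                          seed = config$seed_base)
  sr <- successor_representation(Th, config$gamma_sr)
  cl <- cluster_states(sr, config$k_candidates)
  pts <- embed_mds(sr)
  bn <- identify_bottlenecks(sr, cl)
  out <- tibble::tibble(
    state = seq_len(world$n_states),
    row = world$free[, 1], col = world$free[, 2],
    cluster = cl$labels, silhouette = cl$silhouette,
    x = pts[, 1], y = if (ncol(pts) > 1) pts[, 2] else 0,
    is_bottleneck = seq_len(world$n_states) %in% bn)
  attr(out, "chosen_k") <- cl$chosen_k
  attr(out, "bottlenecks") <- bn
  class(out) <- c("sr_discovery", class(out))
  write_experiment_csv(out, config, "sr_discovery.csv")
  out
}
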