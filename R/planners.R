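#' Create a sample-based planner
#'
#' Planning is modelled as a series of internal simulations against the
#' agent's model of the world: each trial samples a trajectory from start to
#' goal and improves the plan from its outcomes. Three agents are available:
#'
#' * `flat` - primitives only; at every visited state a full one-step
#'   Bellman backup over the four moves is applied (the agent has the flat
#'   transition model, so it backs up all actions it can predict).
#' * `hierarchical` - primitives plus doorway options, but no option models:
#'   options are executed step-by-step through the primitive model,
#'   uninterruptibly, and `Q(s, o)` is updated only from the observed
#'   execution via an SMDP backup discounted by `gamma^k`.
#' * `saltatory` - primitives plus option models: the planner leaps directly
#'   to predicted option outcomes, never simulating the low-level steps, and
#'   backs options up from the model like any other predicted action.
#'
#' Selection is epsilon-greedy over the available actions with uniform
#' random tie-breaking; values are initialized at 0, which is optimistic
#' under negative step rewards and drives systematic exploration. The
#' backup damping `alpha` defaults to 1 (full model-based backups); smaller
#' values give conventional single-rate temporal-difference updates.
#'
#' A trial is abandoned (recorded as not completed) when its simulated
#' actions exceed `step_cap`; simulated actions are primitive steps for the
#' flat and hierarchical agents and decisions for the saltatory agent,
#' which is precisely the resource that leaping over low-level steps saves.
#'
#' @param world A deterministic `gridworld`.
#' @param agent `"flat"`, `"hierarchical"` or `"saltatory"`.
#' @param options List of `option` objects; defaults to
#'   [make_doorway_options()] for the hierarchical agents.
#' @param models Optional list of `option_model`s (computed exactly when
#'   omitted).
#' @param epsilon Exploration rate in `[0, 1]`.
#' @param alpha Backup damping in `(0, 1]`.
#' @param gamma Discount; defaults to the world's.
#' @param step_cap Simulated-action cap per trial (default `10 * |S|`).
#' @return A `planner` object (mutable environment).
#' @export
new_planner <- function(world,
                        agent = c("flat", "hierarchical", "saltatory"),
                        options = NULL, models = NULL,
                        epsilon = 0.1, alpha = 1, gamma = world$discount,
                        step_cap = 10L * world$n_states) {
  agent <- match.arg(agent)
  stopifnot(epsilon >= 0, epsilon <= 1, alpha > 0, alpha <= 1)
  if (world$success_prob < 1)
    stop("planners require a deterministic world (success_prob = 1); ",
         "stochastic dynamics are supported by the option-model tools",
         call. = FALSE)
  if (agent == "flat") {
    options <- list(); models <- list()
  } else {
    if (is.null(options)) options <- make_doorway_options(world)
    if (!length(options)) stop("no options available for a hierarchical agent",
                               call. = FALSE)
    if (is.null(models))
      models <- lapply(options, compute_option_model_exact, world = world)
  }
  n <- world$n_states
  K <- length(options)

  term <- dur <- orew <- NULL
  if (K) {                      # point-mass execution tables, one col per option
    term <- matrix(NA_integer_, n, K)
    dur <- matrix(NA_real_, n, K)
    orew <- matrix(NA_real_, n, K)
    for (o in seq_len(K)) {
      oc <- models[[o]]$outcome
      term[oc$init_state, o] <- oc$term_state
      dur[oc$init_state, o] <- oc$duration
      orew[oc$init_state, o] <- unname(
        models[[o]]$expected_reward[as.character(oc$init_state)])
    }
  }
  avail <- lapply(seq_len(n), function(s) {
    ext <- if (K) which(!is.na(term[s, ])) else integer(0)
    c(1:4, 4L + ext)
  })
  rprim <- matrix(world$step_reward, n, 4) +
    world$goal_reward * (world$next_state == world$goal_id)

  e <- new.env(parent = emptyenv())
  e$world <- world; e$agent <- agent
  e$options <- options; e$models <- models
  e$epsilon <- epsilon; e$alpha <- alpha; e$gamma <- gamma
  e$step_cap <- as.integer(step_cap)
  e$n <- n; e$K <- K
  e$next_state <- world$next_state; e$rprim <- rprim
  e$term <- term; e$dur <- dur; e$orew <- orew
  e$avail <- avail
  e$goal_id <- world$goal_id; e$start_id <- world$start_id
  e$Q <- matrix(0, n, 4L + K)
  e$Vmax <- numeric(n)               # cached max_a Q(s, a) over available a
  e$visits <- matrix(0L, n, 4L + K)
  e$trial_index <- 0L
  class(e) <- "planner"
  e
}

#' @export
print.planner <- function(x, ...) {
  cat(sprintf("<planner> %s agent, %d states, %d options, %d trials run\n",
              x$agent, x$n, x$K, x$trial_index))
  invisible(x)
}

# One simulated planning trajectory. Mutates the planner's value table
# unless update = FALSE. p_fail > 0 enables the memory-failure protocol;
# per_step_failure decides whether option execution draws one failure check
# per simulated primitive step (hierarchical default) or one per decision.
# Returns a list of counters.
trial_core <- function(pl, p_fail = 0, per_step_failure = NA,
                       rollout_wht = FALSE, update = TRUE, epsilon = pl$epsilon,
                       start = pl$start_id) {
  agent <- pl$agent
  saltatory <- agent == "saltatory"
  if (is.na(per_step_failure)) per_step_failure <- !saltatory
  Q <- pl$Q; Vmax <- pl$Vmax
  nxt <- pl$next_state; rprim <- pl$rprim
  term <- pl$term; dur <- pl$dur; orew <- pl$orew
  avail <- pl$avail; goal <- pl$goal_id
  gamma <- pl$gamma; alpha <- pl$alpha; cap <- pl$step_cap
  failed <- FALSE

  s <- start; steps <- 0L; dec <- 0L; sim <- 0L; completed <- FALSE
  repeat {
    if (s == goal) { completed <- TRUE; break }
    if (sim >= cap) break
    if (p_fail > 0 && !per_step_failure && stats::runif(1) < p_fail) {
      failed <- TRUE; break
    }
    av <- avail[[s]]
    if (update) {
      # full backup over everything this agent's model can predict
      v2 <- Vmax[nxt[s, ]]
      v2[nxt[s, ] == goal] <- 0
      tgt <- rprim[s, ] + gamma * v2
      Q[s, 1:4] <- Q[s, 1:4] + alpha * (tgt - Q[s, 1:4])
      if (saltatory && length(av) > 4L) {
        oo <- av[-(1:4)] - 4L
        vt <- Vmax[term[s, oo]]
        vt[term[s, oo] == goal] <- 0
        tgt <- orew[s, oo] + gamma^dur[s, oo] * vt
        Q[s, av[-(1:4)]] <- Q[s, av[-(1:4)]] + alpha * (tgt - Q[s, av[-(1:4)]])
      }
      Vmax[s] <- max(Q[s, av])
    }
    q <- Q[s, av]
    if (epsilon > 0 && stats::runif(1) < epsilon) {
      a <- av[sample.int(length(av), 1L)]
    } else {
      cand <- av[q == max(q)]
      a <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
    }
    dec <- dec + 1L
    if (a <= 4L) {
      if (p_fail > 0 && per_step_failure && stats::runif(1) < p_fail) {
        failed <- TRUE; break
      }
      s2 <- nxt[s, a]
      if (update && agent == "hierarchical") {
        # primitive backup already applied above; nothing extra
      }
      steps <- steps + 1L; sim <- sim + 1L
      s <- s2
    } else {
      o <- a - 4L
      k <- dur[s, o]
      if (p_fail > 0 && per_step_failure) {
        # one check before each simulated primitive step of the option
        g <- stats::rgeom(1, p_fail)        # steps survived before failure
        if (g < k) {
          # interrupted mid-option: walk the policy g steps to locate the state
          opt <- pl$options[[o]]
          s1 <- s
          if (g > 0) for (i in seq_len(g)) s1 <- nxt[s1, opt$policy[s1]]
          steps <- steps + as.integer(g); sim <- sim + as.integer(g)
          s <- s1
          failed <- TRUE
          break
        }
      }
      s2 <- term[s, o]
      if (update && !saltatory) {
        # SMDP backup from the observed execution (the hierarchical agent
        # has no option model; this sample is all it knows about o)
        vt <- if (s2 == goal) 0 else Vmax[s2]
        tgt <- orew[s, o] + gamma^k * vt
        Q[s, a] <- Q[s, a] + alpha * (tgt - Q[s, a])
        Vmax[s] <- max(Q[s, avail[[s]]])
      }
      steps <- steps + as.integer(k)
      sim <- sim + if (saltatory) 1L else as.integer(k)
      s <- s2
    }
  }
  if (update) { pl$Q <- Q; pl$Vmax <- Vmax }

  wht <- NA_integer_; censored <- FALSE
  if (rollout_wht) {
    if (completed) wht <- sim
    else {
      ro <- greedy_rollout(pl, from = s, cap = cap)
      wht <- sim + ro$sim
      censored <- !ro$reached
    }
  }
  list(primitive_steps = steps, decisions = dec, sim_actions = sim,
       completed = completed, failed = failed, would_have_taken = wht,
       censored = censored)
}

# greedy (epsilon = 0) rollout without learning; counts simulated actions
greedy_rollout <- function(pl, from = pl$start_id, cap = pl$step_cap) {
  dummy <- matrix(0, 1, 1)
  cpp_greedy_rollout(pl$Q, pl$avail, pl$next_state,
                     if (is.null(pl$term)) dummy else pl$term,
                     if (is.null(pl$dur)) dummy else pl$dur,
                     pl$agent == "saltatory", from, pl$goal_id, cap)
}

#' Evaluate a planner's greedy policy
#'
#' Rolls the current greedy policy (epsilon = 0, ties broken at random)
#' from the start to the goal without learning.
#'
#' @param planner A `planner`.
#' @return One-row tibble: `primitive_steps`, `decisions`, `sim_actions`,
#'   `reached`.
#' @export
evaluate_greedy <- function(planner) {
  ro <- greedy_rollout(planner)
  tibble::tibble(primitive_steps = ro$steps, decisions = ro$decisions,
                 sim_actions = ro$sim, reached = ro$reached)
}

#' Run one planning trial
#'
#' Simulates a single epsilon-greedy trajectory from the start to the goal
#' against the planner's internal model, applying backups along the way, and
#' returns the trial's accounting. Options count as one decision however
#' many primitive steps they span.
#'
#' @param planner A `planner` from [new_planner()].
#' @return A one-row tibble: `trial_index`, `primitive_steps`, `decisions`,
#'   `sim_actions` (what the agent actually simulated), `completed`.
#' @export
plan_trial <- function(planner) {
  res <- trial_core(planner)
  planner$trial_index <- planner$trial_index + 1L
  tibble::tibble(trial_index = planner$trial_index,
                 primitive_steps = res$primitive_steps,
                 decisions = res$decisions,
                 sim_actions = res$sim_actions,
                 completed = res$completed)
}

#' Run repeated planning simulations
#'
#' Runs independent planner instances (one per run, seeded from `seeds`) for
#' `n_trials` trials each, for one or more agent types. All agents share the
#' per-run seeds, so cross-agent comparisons are paired.
#'
#' @param world A deterministic `gridworld`.
#' @param agents Character vector among `"flat"`, `"hierarchical"`,
#'   `"saltatory"`.
#' @param n_trials Trials per run.
#' @param n_runs Number of runs.
#' @param seeds Integer vector of length `n_runs` (default `seed_base + 1:n`).
#' @param seed_base Used when `seeds` is missing.
#' @param p_fail Per-decision (saltatory) or per-step (others) probability of
#'   losing one's place; 0 disables the memory-failure protocol.
#' @param counting_rule `"rollout_to_goal"` records, for failed trials, the
#'   steps the agent would have taken had it continued (greedy rollout, no
#'   learning); `"discard"` skips that accounting.
#' @param per_step_failure `NA` (default) charges the flat and hierarchical
#'   agents one failure check per simulated primitive step and the saltatory
#'   agent one per decision; TRUE/FALSE forces the rule for all agents.
#' @param ... Passed to [new_planner()] (`epsilon`, `alpha`, `options`, ...).
#' @return A `planning_result` tibble: `agent`, `run`, `trial`,
#'   `primitive_steps`, `decisions`, `sim_actions`, `completed`, and under
#'   the memory protocol `p_fail`, `would_have_taken`, `censored`.
#' @export
run_planning <- function(world, agents = "flat", n_trials = 100L,
                         n_runs = 100L, seeds = NULL, seed_base = 20140480L,
                         p_fail = 0, counting_rule = c("rollout_to_goal", "discard"),
                         per_step_failure = NA, ...) {
  counting_rule <- match.arg(counting_rule)
  if (is.null(seeds)) seeds <- seed_base + seq_len(n_runs)
  stopifnot(length(seeds) == n_runs, p_fail >= 0, p_fail <= 1)
  rollout <- p_fail > 0 && counting_rule == "rollout_to_goal"
  shared <- NULL     # option set shared across agents/runs (built once)
  out <- list()
  for (agent in agents) {
    if (agent != "flat" && is.null(shared)) {
      shared <- make_doorway_options(world)
      shared_models <- lapply(shared, compute_option_model_exact, world = world)
    }
    for (i in seq_len(n_runs)) {
      set.seed(seeds[i])
      pl <- if (agent == "flat") new_planner(world, agent, ...)
            else new_planner(world, agent, options = shared,
                             models = shared_models, ...)
      rows <- vector("list", n_trials)
      for (tr in seq_len(n_trials)) {
        res <- trial_core(pl, p_fail = p_fail,
                          per_step_failure = per_step_failure,
                          rollout_wht = rollout)
        rows[[tr]] <- c(res$primitive_steps, res$decisions, res$sim_actions,
                        res$completed, res$would_have_taken, res$censored)
      }
      m <- do.call(rbind, rows)
      out[[length(out) + 1L]] <- tibble::tibble(
        agent = agent, run = i, trial = seq_len(n_trials),
        primitive_steps = as.integer(m[, 1]), decisions = as.integer(m[, 2]),
        sim_actions = as.integer(m[, 3]), completed = as.logical(m[, 4]),
        would_have_taken = if (rollout) as.integer(m[, 5]) else NA_integer_,
        censored = if (rollout) as.logical(m[, 6]) else NA)
    }
  }
  res <- dplyr::bind_rows(out)
  if (p_fail == 0) res$would_have_taken <- res$censored <- NULL
  else res <- dplyr::mutate(res, p_fail = p_fail, .after = "agent")
  class(res) <- c("planning_result", class(res))
  attr(res, "world") <- world
  res
}

#' Semi-Markov value iteration oracle
#'
#' Exact Bellman backups over primitive actions and (optionally) option
#' models: `V(s) <- max over actions and options of [expected reward +
#' gamma^k * V(s')]`. This is the oracle against which the sample-based
#' planners are checked, and it embodies the claim that option models
#' support evaluation without step-by-step simulation.
#'
#' @param world A deterministic `gridworld`.
#' @param options Optional list of `option`s.
#' @param models Optional matching `option_model`s (computed when omitted).
#' @param include_primitives Set FALSE to plan with options alone; states
#'   from which no option chain reaches the goal keep value `-Inf`.
#' @param gamma Discount (default the world's).
#' @param tolerance Convergence threshold on the sup-norm update.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Numeric vector `V` over states (goal value 0).
#' @export
smdp_value_iteration <- function(world, options = NULL, models = NULL,
                                 include_primitives = TRUE,
                                 gamma = world$discount, tolerance = 1e-10,
                                 max_iter = 5000L) {
  stopifnot(tolerance > 0)
  n <- world$n_states
  goal <- world$goal_id
  K <- length(options)
  if (K && is.null(models))
    models <- lapply(options, compute_option_model_exact, world = world)
  rprim <- matrix(world$step_reward, n, 4) +
    world$goal_reward * (world$next_state == goal)
  oterm <- odur <- orew <- NULL
  if (K) {
    oterm <- matrix(NA_integer_, n, K); odur <- matrix(NA_real_, n, K)
    orew <- matrix(NA_real_, n, K)
    for (o in seq_len(K)) {
      oc <- models[[o]]$outcome
      oterm[oc$init_state, o] <- oc$term_state
      odur[oc$init_state, o] <- oc$duration
      orew[oc$init_state, o] <- unname(
        models[[o]]$expected_reward[as.character(oc$init_state)])
    }
  }
  V <- if (include_primitives) numeric(n) else rep(-Inf, n)
  V[goal] <- 0
  vof <- function(ids) { v <- V[ids]; v[ids == goal] <- 0; v }
  for (it in seq_len(max_iter)) {
    Vn <- rep(-Inf, n)
    if (include_primitives) {
      for (a in 1:4) Vn <- pmax(Vn, rprim[, a] + gamma * vof(world$next_state[, a]))
    }
    if (K) for (o in seq_len(K)) {
      ok <- !is.na(oterm[, o])
      cand <- orew[ok, o] + gamma^odur[ok, o] * vof(oterm[ok, o])
      Vn[ok] <- pmax(Vn[ok], cand, na.rm = FALSE)
    }
    Vn[goal] <- 0
    diff <- max(abs(Vn - V)[is.finite(Vn) & is.finite(V)], 0)
    changed_support <- !identical(is.finite(Vn), is.finite(V))
    V <- Vn
    if (!changed_support && diff < tolerance) return(V)
  }
  stop("value iteration did not converge within ", max_iter, " iterations",
       call. = FALSE)
}

#' Minimum decision count from start to goal
#'
#' The decision-count oracle: each primitive action and each option launch
#' counts as one independent choice, so aggregating a chain of actions into
#' options reduces the number of decisions needed to reach any depth. This
#' is the lower reference line for the saltatory planner.
#'
#' @param world A `gridworld`.
#' @param options List of `option`s (possibly empty: flat decision count).
#' @param from,to Cells, 0-based (default start and goal).
#' @return Integer minimum number of decisions.
#' @export
min_decision_count <- function(world, options = list(), from = world$start,
                               to = world$goal) {
  i <- cell_id(world, from); j <- cell_id(world, to)
  el <- NULL
  for (a in 1:4) {
    tgt <- world$next_state[, a]
    keep <- tgt != seq_len(world$n_states)
    el <- rbind(el, cbind(which(keep), tgt[keep]))
  }
  for (op in options) {
    m <- compute_option_model_exact(world, op)
    el <- rbind(el, cbind(m$outcome$init_state, m$outcome$term_state))
  }
  g <- igraph::graph_from_edgelist(unique(el), directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, world$n_states - igraph::vcount(g)))
  d <- igraph::distances(g, v = i, to = j, mode = "out")[1, 1]
  if (!is.finite(d)) stop("goal unreachable with the given action set", call. = FALSE)
  as.integer(d)
}

#' Trailing moving average
#'
#' Windows of exactly `window` consecutive points; the output has
#' `length(x) - window + 1` values.
#'
#' @param x Numeric series.
#' @param window Window size, `1 <= window <= length(x)`.
#' @return Numeric vector.
#' @export
moving_average <- function(x, window) {
  stopifnot(window >= 1)
  if (window > length(x)) stop("window larger than series", call. = FALSE)
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))[
    window:length(x)]
}
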