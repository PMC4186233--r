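#' Detect doorway cells of a gridworld
#'
#' A doorway is a free cell with exactly two free neighbours whose removal
#' disconnects those neighbours locally (within the radius-2 induced
#' subgraph). This local rule finds the cells that join otherwise separate
#' rooms even when the rooms form a cycle, in which case no doorway is an
#' articulation point of the whole free-cell graph. Corridor-like maps whose
#' free-cell graph is a tree have no rooms; detection is then disabled and an
#' empty result returned with a warning.
#'
#' @param world A `gridworld`.
#' @return Integer vector of doorway state ids (possibly empty); see
#'   [free_cells()] for the id-to-cell mapping.
#' @export
find_doorways <- function(world) {
  g <- world$graph
  if (igraph::ecount(g) == igraph::vcount(g) - 1L) {
    warning("free-cell graph is a tree (corridor-like map); doorway detection disabled")
    return(integer(0))
  }
  out <- integer(0)
  for (s in seq_len(world$n_states)) {
    nbs <- setdiff(world$next_state[s, ], s)
    if (length(nbs) != 2L) next
    ball <- which(abs(world$free[, 1] - world$free[s, 1]) <= 2 &
                  abs(world$free[, 2] - world$free[s, 2]) <= 2)
    keep <- setdiff(ball, s)
    memb <- igraph::components(igraph::induced_subgraph(g, keep))$membership
    if (memb[match(nbs[1], keep)] != memb[match(nbs[2], keep)]) out <- c(out, s)
  }
  if (!length(out)) warning("no doorway cells found")
  out
}

#' Room membership of free cells
#'
#' Removing the doorway cells splits the free-cell graph into rooms.
#'
#' @param world A `gridworld`.
#' @param doorways Doorway state ids, default [find_doorways()].
#' @return Integer vector over states: room label, `NA` at doorways.
#' @export
room_labels <- function(world, doorways = find_doorways(world)) {
  labs <- rep(NA_integer_, world$n_states)
  rest <- setdiff(seq_len(world$n_states), doorways)
  memb <- igraph::components(
    igraph::induced_subgraph(world$graph, rest))$membership
  labs[rest] <- as.integer(memb)
  labs
}

as_state_ids <- function(world, cells) {
  if (is.numeric(cells) && is.null(dim(cells)) && length(cells) != 2L)
    return(as.integer(cells))                       # already state ids
  if (is.data.frame(cells)) cells <- as.matrix(cells[, c("row", "col")])
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1L)
  vapply(seq_len(nrow(cells)), function(i) cell_id(world, cells[i, ]), 1L)
}

#' Learn an option policy for reaching a subgoal
#'
#' The option policy is the greedy policy of value iteration on the option's
#' pseudo-reward problem: pseudo-reward +1 on reaching the subgoal, the
#' world's step cost elsewhere, absorbing at the subgoal, with the state
#' space restricted to the initiation set plus the subgoal. In a
#' deterministic world the learned policy reaches the subgoal from any
#' initiation cell in exactly the shortest-path number of steps. The
#' termination function is 1 at the subgoal and everywhere outside the
#' initiation set, 0 inside it, so execution cannot wander beyond the
#' option's home region. The pseudo-reward is used only here; it never leaks
#' into the planner's real value function.
#'
#' @param world A `gridworld`.
#' @param subgoal Cell `(row, col)` 0-based, or a state id.
#' @param initiation_set Cells (matrix/data frame of row, col) or state ids
#'   from which the option may be launched.
#' @param id Optional label.
#' @return An `option` object with fields `id`, `subgoal`, `initiation_set`,
#'   `policy` (action index per state, `NA` where undefined), `beta`
#'   (termination probability per state) and `pseudo_reward` per state.
#' @export
learn_option_policy <- function(world, subgoal, initiation_set, id = NULL) {
  sub <- as_state_ids(world, subgoal)
  init <- setdiff(as_state_ids(world, initiation_set), sub)
  region <- c(init, sub)

  d <- igraph::distances(igraph::induced_subgraph(world$graph, region))
  dsub <- d[, match(sub, region)]
  bad <- region[!is.finite(dsub)]
  if (length(bad))
    stop("subgoal unreachable (within the initiation region) from cells: ",
         paste(sprintf("(%d,%d)", world$free[bad, 1], world$free[bad, 2]),
               collapse = ", "), call. = FALSE)

  # value iteration on the pseudo-reward problem, restricted to the region
  gam <- world$discount
  inreg <- logical(world$n_states); inreg[region] <- TRUE
  V <- numeric(world$n_states)
  repeat {
    delta <- 0
    for (s in init) {
      q <- vapply(1:4, function(a) {
        s2 <- world$next_state[s, a]
        if (!inreg[s2]) s2 <- s                       # outside region: bounce
        if (s2 == sub) world$step_reward + 1 else world$step_reward + gam * V[s2]
      }, 1)
      v <- max(q)
      delta <- max(delta, abs(v - V[s]))
      V[s] <- v
    }
    if (delta < 1e-10) break
  }
  policy <- rep(NA_integer_, world$n_states)
  for (s in init) {
    q <- vapply(1:4, function(a) {
      s2 <- world$next_state[s, a]
      if (!inreg[s2]) s2 <- s
      if (s2 == sub) world$step_reward + 1 else world$step_reward + gam * V[s2]
    }, 1)
    policy[s] <- which.max(q)                         # ties: fixed action order
  }
  beta <- rep(1, world$n_states)
  beta[init] <- 0
  pseudo <- rep(world$step_reward, world$n_states)
  pseudo[sub] <- 1

  structure(list(
    id = id %||% sprintf("to(%d,%d)", world$free[sub, 1], world$free[sub, 2]),
    subgoal = sub, initiation_set = init, policy = policy, beta = beta,
    pseudo_reward = pseudo
  ), class = "option")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.option <- function(x, ...) {
  cat(sprintf("<option> %s: %d initiation cells, subgoal state %d\n",
              x$id, length(x$initiation_set), x$subgoal))
  invisible(x)
}

#' Construct the doorway options of a rooms gridworld
#'
#' One option per doorway per adjacent room side: the option can be launched
#' anywhere in that room (and from the room's other doorways), follows a
#' shortest-path policy to the target doorway, and terminates there.
#'
#' @param world A `gridworld`.
#' @return List of `option` objects (empty, with a warning, when no doorways
#'   are detected).
#' @export
make_doorway_options <- function(world) {
  doorways <- suppressWarnings(find_doorways(world))
  if (!length(doorways)) {
    warning("no doorway options: map has no detectable doorways")
    return(list())
  }
  rooms <- room_labels(world, doorways)
  # doorway -> adjacent room labels
  adj_rooms <- lapply(doorways, function(d)
    unique(stats::na.omit(rooms[setdiff(world$next_state[d, ], d)])))
  opts <- list()
  for (i in seq_along(doorways)) {
    d <- doorways[i]
    for (r in adj_rooms[[i]]) {
      room_cells <- which(!is.na(rooms) & rooms == r)
      side_doors <- doorways[vapply(adj_rooms, function(x) r %in% x, TRUE)]
      init <- c(room_cells, setdiff(side_doors, d))
      opts[[length(opts) + 1L]] <- learn_option_policy(
        world, d, init,
        id = sprintf("to(%d,%d)room%d", world$free[d, 1], world$free[d, 2], r))
    }
  }
  opts
}

# termination test used by executors: beta == 1, plus the world goal
option_terminates <- function(world, option, s) {
  option$beta[s] >= 1 || s == world$goal_id
}

#' Exact option model
#'
#' An option model gives, per initiation cell, the joint distribution over
#' (termination state, duration) and the expected cumulative discounted
#' reward accrued during execution. For a deterministic world and policy the
#' outcome is a point mass on (subgoal, path length); for stochastic worlds
#' the model is computed by dynamic programming on the absorbing chain,
#' truncated when the unterminated tail mass falls below `tol` (an error is
#' raised if that does not happen within `horizon` steps). The world goal is
#' absorbing: execution stops there and the goal reward is collected.
#'
#' @param world A `gridworld`.
#' @param option An `option`.
#' @param horizon Truncation horizon for the absorbing-chain computation.
#' @param tol Tail mass below which the chain is considered absorbed.
#' @return An `option_model` with `outcome` tibble (`init_state`,
#'   `term_state`, `duration`, `prob`) and `expected_reward` per init state.
#' @export
compute_option_model_exact <- function(world, option, horizon = 10000L,
                                       tol = 1e-9) {
  init <- option$initiation_set
  gam <- world$discount
  if (world$success_prob >= 1) {
    rows <- lapply(init, function(s0) {
      s <- s0; k <- 0L; rew <- 0
      while (!option_terminates(world, option, s) || k == 0L) {
        if (k > world$n_states)
          stop("option policy cycles without terminating (from state ", s0, ")",
               call. = FALSE)
        a <- option$policy[s]
        if (is.na(a)) stop("option policy undefined at state ", s, call. = FALSE)
        s2 <- world$next_state[s, a]
        rew <- rew + gam^k * (world$step_reward +
                              if (s2 == world$goal_id) world$goal_reward else 0)
        k <- k + 1L
        s <- s2
        if (option_terminates(world, option, s)) break
      }
      list(term = s, k = k, rew = rew)
    })
    outcome <- tibble::tibble(
      init_state = init,
      term_state = vapply(rows, `[[`, 1L, "term"),
      duration = vapply(rows, `[[`, 1L, "k"),
      prob = 1)
    er <- stats::setNames(vapply(rows, `[[`, 1, "rew"), init)
  } else {
    # stochastic world: propagate occupancy through the absorbing chain
    n <- world$n_states
    p_ok <- world$success_prob
    # policy transition kernel restricted to non-terminal states
    trans <- vector("list", n)
    for (s in init) {
      a <- option$policy[s]
      dests <- world$next_state[s, ]
      pr <- rep((1 - p_ok) / 3, 4); pr[a] <- p_ok
      trans[[s]] <- rowsum(pr, dests)
    }
    out_rows <- list(); er <- numeric(0)
    for (s0 in init) {
      occ <- numeric(n); occ[s0] <- 1
      rew <- 0; recs <- list()
      for (t in seq_len(horizon)) {
        live <- which(occ > 0)
        nxt <- numeric(n)
        for (s in live) {
          tr <- trans[[s]]
          nxt[as.integer(rownames(tr))] <- nxt[as.integer(rownames(tr))] +
            occ[s] * tr[, 1]
        }
        rew <- rew + gam^(t - 1) * (world$step_reward * sum(occ) +
                                    world$goal_reward * nxt[world$goal_id])
        term <- which(nxt > 0 & (option$beta >= 1 | seq_len(n) == world$goal_id))
        for (s2 in term) recs[[length(recs) + 1L]] <- c(s2, t, nxt[s2])
        nxt[term] <- 0
        occ <- nxt
        if (sum(occ) < tol) break
      }
      if (sum(occ) >= tol)
        stop("absorbing-chain tail mass ", sum(occ), " above tol after horizon ",
             horizon, call. = FALSE)
      m <- do.call(rbind, recs)
      out_rows[[length(out_rows) + 1L]] <- tibble::tibble(
        init_state = s0, term_state = as.integer(m[, 1]),
        duration = as.integer(m[, 2]), prob = m[, 3] / sum(m[, 3]))
      er[as.character(s0)] <- rew
    }
    outcome <- dplyr::bind_rows(out_rows)
  }
  new_option_model(option$id, outcome, er, gam)
}

new_option_model <- function(option_id, outcome, expected_reward, gamma) {
  sums <- tapply(outcome$prob, outcome$init_state, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("option-model outcome rows do not sum to 1", call. = FALSE)
  if (any(outcome$duration < 1))
    stop("option-model durations must be positive integers", call. = FALSE)
  if (any(!is.finite(expected_reward)))
    stop("option-model expected reward must be finite", call. = FALSE)
  structure(list(option_id = option_id, outcome = outcome,
                 expected_reward = expected_reward, gamma = gamma),
            class = "option_model")
}

#' @export
print.option_model <- function(x, ...) {
  cat(sprintf("<option_model> %s: %d initiation cells, %d outcome rows\n",
              x$option_id, length(x$expected_reward), nrow(x$outcome)))
  invisible(x)
}

#' Tidy an option model into its tabular serialization
#'
#' One row per initiation-cell/outcome pair, with the expected discounted
#' reward repeated per initiation cell. `write_csv(tidy(m), ...)` is the
#' documented on-disk format.
#'
#' @param x An `option_model`.
#' @param ... Unused.
#' @export
tidy.option_model <- function(x, ...) {
  dplyr::mutate(x$outcome,
                option = x$option_id,
                expected_reward = unname(x$expected_reward[as.character(.data$init_state)]),
                .before = 1)
}

#' Monte-Carlo estimate of an option model
#'
#' Executes the option policy `n_rollouts` times from every initiation cell
#' through the (possibly stochastic) environment and tallies empirical
#' (termination state, duration) frequencies and the mean discounted reward.
#' In a deterministic world the estimate equals the exact model.
#'
#' @param world A `gridworld`.
#' @param option An `option`.
#' @param n_rollouts Rollouts per initiation cell (>= 1).
#' @param seed Integer seed for reproducibility.
#' @param max_steps Step cap per rollout; rollouts hitting the cap are
#'   recorded as censored, and an error is raised if all rollouts from some
#'   cell are censored.
#' @return An `option_model` with an extra `censored` attribute (count).
#' @export
estimate_option_model_mc <- function(world, option, n_rollouts, seed = NULL,
                                     max_steps = 100L * world$n_states) {
  stopifnot(n_rollouts >= 1)
  gam <- world$discount
  p_ok <- world$success_prob
  with_seed(seed, {
    out_rows <- list(); er <- numeric(0); n_cens <- 0L
    for (s0 in option$initiation_set) {
      terms <- integer(n_rollouts); durs <- integer(n_rollouts)
      rews <- numeric(n_rollouts); cens <- logical(n_rollouts)
      for (r in seq_len(n_rollouts)) {
        s <- s0; k <- 0L; rew <- 0
        repeat {
          a <- option$policy[s]
          if (p_ok < 1 && stats::runif(1) > p_ok) a <- sample((1:4)[-a], 1L)
          s2 <- world$next_state[s, a]
          rew <- rew + gam^k * (world$step_reward +
                                if (s2 == world$goal_id) world$goal_reward else 0)
          k <- k + 1L
          s <- s2
          if (option_terminates(world, option, s)) break
          if (k >= max_steps) { cens[r] <- TRUE; break }
        }
        terms[r] <- s; durs[r] <- k; rews[r] <- rew
      }
      if (all(cens))
        stop("all rollouts censored from state ", s0, call. = FALSE)
      n_cens <- n_cens + sum(cens)
      keep <- !cens
      tab <- as.data.frame(table(term = terms[keep], dur = durs[keep]))
      tab <- tab[tab$Freq > 0, ]
      out_rows[[length(out_rows) + 1L]] <- tibble::tibble(
        init_state = s0,
        term_state = as.integer(as.character(tab$term)),
        duration = as.integer(as.character(tab$dur)),
        prob = tab$Freq / sum(tab$Freq))
      er[as.character(s0)] <- mean(rews[keep])
    }
    m <- new_option_model(option$id, dplyr::bind_rows(out_rows), er, gam)
    attr(m, "censored") <- n_cens
    m
  })
}
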