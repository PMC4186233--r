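# Action encoding used throughout: 1 = up, 2 = down, 3 = left, 4 = right.
# Moves are offsets on 0-based (row, col) with row 0 the top line of the map.
GRID_ACTIONS <- c("up", "down", "left", "right")
GRID_MOVES <- rbind(up = c(-1L, 0L), down = c(1L, 0L),
                    left = c(0L, -1L), right = c(0L, 1L))

#' Parse an ASCII gridworld map
#'
#' Maps use `#` for walls, `.` for floor, `S` for the start cell and `G` for
#' the goal cell. Row 0 is the top line; coordinates are 0-based `(row, col)`.
#' The classic four-room layout shipped with the package
#' (`system.file("extdata", "rooms_default.map", package = "saltatory")`) has
#' an 11x11 interior with four rooms joined by four mid-wall doorways.
#'
#' @param text Map as a single string or a character vector of lines.
#' @param step_reward Reward received on every step (non-positive; default -1,
#'   so step counts and negated undiscounted returns coincide).
#' @param goal_reward Extra reward on entering the goal (default 0).
#' @param discount Discount factor gamma in (0, 1].
#' @param success_prob Probability that a move goes in the intended direction;
#'   with probability `1 - success_prob` one of the other three directions is
#'   taken instead (uniformly). Default 1 (deterministic).
#' @return A `gridworld` object.
#' @examples
#' w <- parse_map("S....G")
#' shortest_path_length(w, w$start, w$goal)
#' @export
parse_map <- function(text, step_reward = -1, goal_reward = 0,
                      discount = 0.95, success_prob = 1) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty map", call. = FALSE)
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L)
    stop("map is not rectangular: line widths ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  grid <- do.call(rbind, strsplit(lines, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(grid)), c("#", ".", "S", "G"))
  if (length(bad))
    stop("invalid map characters: ", paste(bad, collapse = " "), call. = FALSE)
  if (sum(grid == "S") != 1L) stop("map must contain exactly one start marker 'S'",
                                   call. = FALSE)
  if (sum(grid == "G") != 1L) stop("map must contain exactly one goal marker 'G'",
                                   call. = FALSE)
  stopifnot(step_reward <= 0, discount > 0, discount <= 1,
            success_prob > 0, success_prob <= 1)

  h <- nrow(grid); wdt <- ncol(grid)
  free_rc <- which(grid != "#", arr.ind = TRUE)       # 1-based
  free_rc <- free_rc[order(free_rc[, 1], free_rc[, 2]), , drop = FALSE]
  n <- nrow(free_rc)
  index <- matrix(0L, h, wdt)
  index[free_rc] <- seq_len(n)

  next_state <- matrix(0L, n, 4L)
  for (a in 1:4) {
    r2 <- free_rc[, 1] + GRID_MOVES[a, 1]
    c2 <- free_rc[, 2] + GRID_MOVES[a, 2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= wdt
    tgt <- rep(0L, n)
    tgt[ok] <- index[cbind(r2[ok], c2[ok])]
    next_state[, a] <- ifelse(tgt > 0L, tgt, seq_len(n))  # wall/off-grid bounce
  }

  start_id <- index[which(grid == "S", arr.ind = TRUE)]
  goal_id <- index[which(grid == "G", arr.ind = TRUE)]

  # undirected free-cell adjacency graph (used for BFS oracles and doorways)
  el <- cbind(rep(seq_len(n), 4L), as.vector(next_state))
  el <- el[el[, 1] < el[, 2], , drop = FALSE]
  g <- igraph::graph_from_edgelist(unique(el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))

  comp <- igraph::components(g)$membership
  unreachable <- which(comp != comp[start_id])
  if (length(unreachable)) {
    cells <- paste(sprintf("(%d,%d)", free_rc[unreachable, 1] - 1L,
                           free_rc[unreachable, 2] - 1L), collapse = ", ")
    stop("free cells unreachable from start: ", cells, call. = FALSE)
  }

  structure(list(
    height = h, width = wdt, grid = grid,
    free = unname(free_rc) - 1L,          # n x 2 matrix, 0-based (row, col)
    index = index, n_states = n,
    next_state = next_state, graph = g,
    start = unname(free_rc[start_id, ]) - 1L,
    goal = unname(free_rc[goal_id, ]) - 1L,
    start_id = start_id, goal_id = goal_id,
    step_reward = step_reward, goal_reward = goal_reward,
    discount = discount, success_prob = success_prob
  ), class = "gridworld")
}

#' Read a gridworld map from a file
#'
#' @inheritParams parse_map
#' @param path Path to an ASCII map file.
#' @return A `gridworld` object.
#' @export
read_map <- function(path, ...) {
  parse_map(readLines(path), ...)
}

#' @export
print.gridworld <- function(x, ...) {
  cat(sprintf("<gridworld> %dx%d, %d free cells, start (%d,%d), goal (%d,%d)\n",
              x$height, x$width, x$n_states, x$start[1], x$start[2],
              x$goal[1], x$goal[2]))
  cat(apply(x$grid, 1, paste, collapse = ""), sep = "\n")
  invisible(x)
}

# cell (row, col) 0-based -> state id, with validation
cell_id <- function(world, cell) {
  cell <- as.integer(cell)
  if (length(cell) != 2L || any(cell < 0) || cell[1] >= world$height ||
      cell[2] >= world$width)
    stop("cell (", paste(cell, collapse = ","), ") is outside the map", call. = FALSE)
  id <- world$index[cell[1] + 1L, cell[2] + 1L]
  if (id == 0L)
    stop("cell (", paste(cell, collapse = ","), ") is not a free cell", call. = FALSE)
  id
}

id_cell <- function(world, id) world$free[id, ]

#' Free cells of a gridworld as a tibble
#'
#' @param world A `gridworld`.
#' @return A tibble with one row per free cell: `state` (1-based id used
#'   internally), `row`, `col` (0-based map coordinates).
#' @export
free_cells <- function(world) {
  tibble::tibble(state = seq_len(world$n_states),
                 row = world$free[, 1], col = world$free[, 2])
}

#' Take one environment step
#'
#' Moving into a wall or off the grid leaves the state unchanged. The reward
#' is `step_reward`, plus `goal_reward` when the move enters the goal, in
#' which case the episode is done. With `success_prob < 1` the realized
#' direction can differ from `action` (one of the other three, uniformly);
#' pass `rng = FALSE` to force the intended direction.
#'
#' @param world A `gridworld`.
#' @param state Cell `(row, col)`, 0-based; must be free.
#' @param action One of `"up"`, `"down"`, `"left"`, `"right"` (or 1:4).
#' @param rng Use randomness for stochastic worlds (default TRUE).
#' @return List with `next_state` (cell), `reward`, `done`.
#' @export
grid_step <- function(world, state, action, rng = TRUE) {
  s <- cell_id(world, state)
  a <- if (is.character(action)) match(action, GRID_ACTIONS) else as.integer(action)
  if (is.na(a) || a < 1L || a > 4L)
    stop("action must be one of ", paste(GRID_ACTIONS, collapse = ", "), call. = FALSE)
  if (rng && world$success_prob < 1 && stats::runif(1) > world$success_prob)
    a <- sample((1:4)[-a], 1L)
  s2 <- world$next_state[s, a]
  done <- s2 == world$goal_id
  reward <- world$step_reward + if (done) world$goal_reward else 0
  list(next_state = id_cell(world, s2), reward = reward, done = done)
}

#' Breadth-first-search shortest path length between two free cells
#'
#' The BFS oracle under 4-connectivity avoiding walls; this is the "minimum
#' number of primitive actions" reference line for the planners.
#'
#' @param world A `gridworld`.
#' @param from,to Cells `(row, col)`, 0-based.
#' @return Integer number of steps.
#' @export
shortest_path_length <- function(world, from, to) {
  i <- cell_id(world, from); j <- cell_id(world, to)
  d <- igraph::distances(world$graph, v = i, to = j)[1, 1]
  if (!is.finite(d))
    stop("no path between (", paste(from, collapse = ","), ") and (",
         paste(to, collapse = ","), ")", call. = FALSE)
  as.integer(d)
}

# all-pairs BFS distances (internal, used by option construction)
grid_distances <- function(world) igraph::distances(world$graph)
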