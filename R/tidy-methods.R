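#' Tidy per-trial planning records
#'
#' @param x A `planning_result` from [run_planning()].
#' @param ... Unused.
#' @return The underlying tibble, one row per (agent, run, trial).
#' @export
tidy.planning_result <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "world") <- NULL
  out
}

#' One-row-per-agent summary of a planning result
#'
#' `trials_to_optimal` is the first trial whose completed trajectory used
#' the minimum number of primitive steps (averaged over runs; runs that
#' never produce one count as `n_trials + 1`).
#'
#' @param x A `planning_result`.
#' @param ... Unused.
#' @export
glance.planning_result <- function(x, ...) {
  world <- attr(x, "world")
  opt <- shortest_path_length(world, world$start, world$goal)
  df <- tidy(x)
  n_trials <- max(df$trial)
  base <- df |>
    dplyr::group_by(.data$agent) |>
    dplyr::summarise(
      n_runs = dplyr::n_distinct(.data$run),
      n_trials = n_trials,
      completion_rate = mean(.data$completed),
      mean_final_steps = mean(.data$primitive_steps[.data$trial > n_trials - 10]),
      mean_final_decisions = mean(.data$decisions[.data$trial > n_trials - 10]),
      .groups = "drop")
  tto <- trials_to_first_optimal(df, opt) |>
    dplyr::group_by(.data$agent) |>
    dplyr::summarise(trials_to_optimal = mean(.data$first_optimal),
                     .groups = "drop")
  dplyr::left_join(base, tto, by = "agent")
}

#' First trial with a completed minimum-length trajectory, per run
#'
#' @param result A `planning_result` (or its tidied tibble).
#' @param optimum The optimal primitive step count (BFS minimum).
#' @return Tibble `agent`, `run`, `first_optimal` (`n_trials + 1` when the
#'   run never produced an optimal trajectory).
#' @export
trials_to_first_optimal <- function(result, optimum) {
  tibble::as_tibble(result) |>
    dplyr::group_by(.data$agent, .data$run) |>
    dplyr::summarise(first_optimal = {
      hit <- which(.data$primitive_steps == optimum & .data$completed)
      if (length(hit)) .data$trial[min(hit)] else max(.data$trial) + 1L
    }, .groups = "drop")
}

#' Plot smoothed planning curves
#'
#' @param object A `planning_curves` or `memory_curves` result.
#' @param ... Unused.
#' @return A ggplot: simulated actions per trial by agent, with the oracle
#'   reference lines dashed.
#' @export
autoplot.planning_curves <- function(object, ...) {
  refs <- tibble::tibble(name = names(object$references),
                         value = as.numeric(object$references))
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$trial, y = .data$smoothed,
                               colour = .data$agent)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(data = refs,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "planning trial",
                  y = "actions simulated (smoothed mean)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.planning_curves
#' @export
autoplot.memory_curves <- autoplot.planning_curves

#' Plot an SR subgoal-discovery result
#'
#' @param object An `sr_discovery` tibble.
#' @param type `"map"` (cluster labels on the grid) or `"embedding"`
#'   (2-D multidimensional scaling of the predictive representations).
#' @param ... Unused.
#' @export
autoplot.sr_discovery <- function(object, type = c("embedding", "map"), ...) {
  type <- match.arg(type)
  df <- tibble::as_tibble(object)
  df$cluster <- factor(df$cluster)
  if (type == "embedding") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$cluster,
                                     shape = .data$is_bottleneck)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "cluster",
                    shape = "bottleneck") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                     fill = .data$cluster)) +
      ggplot2::geom_tile(colour = "white") +
      ggplot2::geom_point(data = df[df$is_bottleneck, ], size = 2) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = NULL, y = NULL, fill = "cluster") +
      ggplot2::theme_minimal()
  }
}
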