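test_that("a converged flat planner walks the corridor optimally", {
  w <- corridor_world()
  set.seed(4)
  pl <- new_planner(w, "flat")
  for (i in 1:40) plan_trial(pl)
  g <- evaluate_greedy(pl)
  expect_true(g$reached)
  expect_equal(g$primitive_steps, 5)
  expect_equal(g$decisions, 5)
})

test_that("aggregating the 7-action chain into two options gives 2 decisions", {
  w <- chain_world()
  expect_equal(shortest_path_length(w, w$start, w$goal), 7)
  expect_equal(min_decision_count(w, list()), 7)
  expect_equal(min_decision_count(w, chain_options(w)), 2)
})

test_that("converged planners on the rooms map reach the BFS minimum", {
  w <- rooms_world()
  opt <- shortest_path_length(w, w$start, w$goal)
  set.seed(7)
  pl <- new_planner(w, "flat")
  for (i in 1:200) plan_trial(pl)
  expect_equal(evaluate_greedy(pl)$primitive_steps, opt)
  pl <- new_planner(w, "hierarchical", options = rooms_options())
  for (i in 1:200) plan_trial(pl)
  g <- evaluate_greedy(pl)
  expect_equal(g$primitive_steps, opt)
  expect_lte(g$decisions, opt)          # options count once however long
})

test_that("runs are reproducible given equal seeds", {
  w <- two_rooms_world()
  res <- run_planning(w, agents = "saltatory", n_trials = 15, n_runs = 2,
                      seeds = c(99L, 99L))
  r1 <- dplyr::filter(res, .data$run == 1)
  r2 <- dplyr::filter(res, .data$run == 2)
  expect_equal(r1$primitive_steps, r2$primitive_steps)
  expect_equal(r1$decisions, r2$decisions)
})

test_that("decision counts never exceed primitive steps, and match for flat", {
  w <- two_rooms_world()
  res <- run_planning(w, agents = c("flat", "hierarchical", "saltatory"),
                      n_trials = 25, n_runs = 4)
  expect_true(all(res$decisions <= res$primitive_steps))
  flat <- dplyr::filter(res, .data$agent == "flat")
  expect_equal(flat$decisions, flat$primitive_steps)
  salt <- dplyr::filter(res, .data$agent == "saltatory")
  expect_equal(salt$sim_actions, salt$decisions)
})

test_that("mean steps decrease across trial blocks", {
  w <- rooms_world()
  res <- run_planning(w, agents = "flat", n_trials = 100, n_runs = 40)
  blocks <- dplyr::summarise(
    dplyr::group_by(tidy(res), block = ceiling(.data$trial / 10)),
    m = mean(.data$primitive_steps), .groups = "drop")$m
  increases <- sum(diff(blocks) > 0)
  # under a flat (no-improvement) null, upticks are fair coin flips
  expect_lt(stats::binom.test(increases, length(blocks) - 1,
                              alternative = "less")$p.value, 0.05)
  expect_lt(blocks[10], blocks[1] / 2)
})

test_that("value iteration sums the corridor path at gamma = 1", {
  w <- corridor_world(discount = 1)
  V <- smdp_value_iteration(w, tolerance = 1e-10)
  expect_equal(V[w$start_id], -5)
})

test_that("adding doorway option models never changes optimal values", {
  w <- two_rooms_world()
  V1 <- smdp_value_iteration(w, tolerance = 1e-12)
  V2 <- smdp_value_iteration(w, options = make_doorway_options(w),
                             tolerance = 1e-12)
  expect_lt(max(abs(V1 - V2)), 1e-8)
})

test_that("the converged flat planner attains the value-iteration optimum", {
  w <- two_rooms_world()
  V <- smdp_value_iteration(w, tolerance = 1e-12)
  set.seed(12)
  pl <- new_planner(w, "flat")
  for (i in 1:150) plan_trial(pl)
  g <- evaluate_greedy(pl)
  # optimal value at the start equals the discounted cost of the greedy path
  expect_equal(-(1 - w$discount^g$primitive_steps) / (1 - w$discount),
               V[w$start_id], tolerance = 1e-9)
})

test_that("options alone reach the goal only where chains connect to it", {
  # goal placed in the doorway: option chains can finish the job
  txt <- "#######\n#S.#..#\n#..#..#\n#..G..#\n#######"
  w <- parse_map(txt)
  opts <- make_doorway_options(w)
  V <- smdp_value_iteration(w, options = opts, include_primitives = FALSE)
  expect_true(all(is.finite(V[unique(unlist(lapply(opts, `[[`,
                                                   "initiation_set")))])))
  # goal deep in a room: no option terminates there, nothing reaches it
  w2 <- two_rooms_world()
  V2 <- smdp_value_iteration(w2, options = make_doorway_options(w2),
                             include_primitives = FALSE)
  expect_true(all(V2[-w2$goal_id] == -Inf))
})

test_that("moving averages use exact trailing windows", {
  expect_equal(moving_average(c(1, 2, 3, 4), 2), c(1.5, 2.5, 3.5))
  x <- rnorm(20)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(3.5, 8), 5), rep(3.5, 4))
  expect_error(moving_average(1:3, 4), "window")
})
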