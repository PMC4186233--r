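test_that("corridor option policy always moves right", {
  w <- corridor_world()
  op <- learn_option_policy(w, subgoal = c(0, 5), initiation_set = cbind(0, 0:4))
  expect_true(all(op$policy[op$initiation_set] == 4L))   # 4 = right
  expect_equal(op$beta[op$subgoal], 1)
  expect_true(all(op$beta[op$initiation_set] == 0))
})

test_that("unreachable subgoals are rejected with the offending cells", {
  w <- two_rooms_world()
  # right-room subgoal, left-room initiation set: the doorway is excluded
  # from the region, so the subgoal is sealed off
  rooms <- room_labels(w)
  left <- which(!is.na(rooms) & rooms == rooms[w$start_id])
  expect_error(learn_option_policy(w, subgoal = w$goal, initiation_set = left),
               "unreachable")
})

test_that("doorway detection matches the rooms layout", {
  w <- rooms_world()
  dws <- find_doorways(w)
  expect_setequal(lapply(dws, function(s) w$free[s, ]),
                  list(c(3, 6), c(6, 3), c(6, 9), c(9, 6)))
  expect_equal(length(rooms_options()), 8)      # 4 doorways x 2 sides
  expect_equal(length(make_doorway_options(two_rooms_world())), 2)
  expect_warning(expect_equal(find_doorways(corridor_world()), integer(0)),
                 "tree")
})

test_that("option rollout lengths equal BFS distances to the doorway", {
  w <- rooms_world()
  for (op in rooms_options()[c(1, 5)]) {
    m <- compute_option_model_exact(w, op)
    sub_cell <- w$free[op$subgoal, ]
    for (i in seq_len(nrow(m$outcome))) {
      from <- w$free[m$outcome$init_state[i], ]
      expect_equal(m$outcome$duration[i], shortest_path_length(w, from, sub_cell))
    }
    expect_true(all(m$outcome$term_state == op$subgoal))
  }
})

test_that("exact option models follow the discounted geometric sum", {
  w <- corridor_world()
  op <- learn_option_policy(w, subgoal = c(0, 5), initiation_set = cbind(0, 0:4))
  m <- compute_option_model_exact(w, op)
  row <- m$outcome[m$outcome$init_state == state_of(w, c(0, 0)), ]
  expect_equal(row$duration, 5L)
  expect_equal(row$prob, 1)
  expect_equal(unname(m$expected_reward[as.character(row$init_state)]),
               -sum(0.95^(0:4)))                      # -4.52438125
  # single-step option reduces to the primitive model
  op1 <- learn_option_policy(w, subgoal = c(0, 1), initiation_set = cbind(0, 0))
  m1 <- compute_option_model_exact(w, op1)
  expect_equal(m1$outcome$duration, 1L)
  expect_equal(unname(m1$expected_reward), w$step_reward)
})

test_that("outcome distributions must normalize; a 95/3/2 split is legal", {
  legal <- tibble::tibble(init_state = 1L, term_state = c(2L, 3L, 4L),
                          duration = c(3L, 5L, 2L), prob = c(0.95, 0.03, 0.02))
  m <- saltatory:::new_option_model("tickets", legal,
                                    c(`1` = -1.5), gamma = 0.95)
  expect_s3_class(m, "option_model")
  broken <- legal
  broken$prob <- c(0.95, 0.03, 0.05)
  expect_error(saltatory:::new_option_model("tickets", broken,
                                            c(`1` = -1.5), 0.95),
               "sum to 1")
  expect_error(saltatory:::new_option_model("t", dplyr::mutate(legal, duration = 0L),
                                            c(`1` = -1), 0.95),
               "positive")
})

test_that("every doorway option model row normalizes", {
  w <- rooms_world()
  for (op in rooms_options()) {
    m <- compute_option_model_exact(w, op)
    sums <- tapply(m$outcome$prob, m$outcome$init_state, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("Monte-Carlo estimates are exact in deterministic worlds", {
  w <- corridor_world()
  op <- learn_option_policy(w, subgoal = c(0, 5), initiation_set = cbind(0, 0:4))
  exact <- compute_option_model_exact(w, op)
  mc <- estimate_option_model_mc(w, op, n_rollouts = 3, seed = 1)
  expect_equal(mc$outcome, exact$outcome)
  expect_equal(mc$expected_reward, exact$expected_reward)
  one <- estimate_option_model_mc(w, op, n_rollouts = 1, seed = 2)
  sums <- tapply(one$outcome$prob, one$outcome$init_state, sum)
  expect_true(all(sums == 1))
})

test_that("stochastic exact models are proper and slower than BFS", {
  w <- corridor_world(success_prob = 2 / 3)
  op <- learn_option_policy(w, subgoal = c(0, 5), initiation_set = cbind(0, 0:4))
  m <- compute_option_model_exact(w, op)
  sums <- tapply(m$outcome$prob, m$outcome$init_state, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  mean_dur <- tapply(m$outcome$prob * m$outcome$duration,
                     m$outcome$init_state, sum)
  bfs <- vapply(as.integer(names(mean_dur)), function(s)
    shortest_path_length(w, w$free[s, ], c(0, 5)), 1L)
  expect_true(all(mean_dur > bfs))
})

test_that("composing a model with V matches step-by-step execution", {
  w <- rooms_world()
  V <- smdp_value_iteration(w, tolerance = 1e-12)
  op <- rooms_options()[[1]]
  m <- compute_option_model_exact(w, op)
  gam <- w$discount
  for (i in seq_len(nrow(m$outcome))) {
    s0 <- m$outcome$init_state[i]
    # execute the option policy through the flat model, then follow V
    s <- s0; val <- 0; k <- 0L
    repeat {
      s <- w$next_state[s, op$policy[s]]
      val <- val + gam^k * w$step_reward
      k <- k + 1L
      if (op$beta[s] >= 1 || s == w$goal_id) break
    }
    val <- val + gam^k * V[s]
    model_val <- unname(m$expected_reward[as.character(s0)]) +
      gam^m$outcome$duration[i] * V[m$outcome$term_state[i]]
    expect_equal(model_val, val, tolerance = 1e-10)
  }
})
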