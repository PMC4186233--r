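test_that("two-state swap chain matches the hand-inverted SR", {
  Tm <- matrix(c(0, 1, 1, 0), 2, 2)
  sr <- successor_representation(Tm, gamma_sr = 0.5)
  expect_equal(unname(sr$M), matrix(c(4, 2, 2, 4) / 3, 2, 2))
  sr_id <- successor_representation(diag(3), gamma_sr = 0.7)
  expect_equal(unname(sr_id$M), diag(3) / 0.3)
  expect_error(successor_representation(matrix(c(0.5, 0.2, 0.5, 0.2), 2, 2)),
               "row-stochastic")
})

test_that("SR rows conserve discounted occupancy and solve the fixed point", {
  w <- rooms_world()
  Tm <- uniform_walk_transitions(w)
  sr <- successor_representation(Tm, 0.95)
  expect_true(all(abs(rowSums(sr$M) - 1 / (1 - 0.95)) < 1e-6))
  expect_lt(max(abs(sr$M - (diag(w$n_states) + 0.95 * Tm %*% sr$M))), 1e-6)
})

test_that("closed-form SR agrees with the truncated power series", {
  Tm <- walk_transitions(schapiro_graph())
  sr <- successor_representation(Tm, 0.95)
  expect_lt(max(abs(sr$M - saltatory:::sr_power_series(Tm, 0.95))), 1e-6)
})

test_that("latent learning recovers the corridor transition matrix", {
  w <- corridor_world()
  T_true <- uniform_walk_transitions(w)
  T_hat <- transition_model_from_exploration(w, 1e5, seed = 8)
  expect_lt(max(abs(T_hat - T_true)), 0.02)
  # deterministic dynamics: at most 5 destinations (4 moves + bounce)
  expect_true(all(rowSums(T_hat > 0) <= 5))
  expect_equal(T_hat, transition_model_from_exploration(w, 1e5, seed = 8))
  expect_error(transition_model_from_exploration(rooms_world(), 3, seed = 1),
               "never visited")
})

test_that("disconnected cliques split perfectly at k = 2", {
  Tm <- matrix(0, 6, 6)
  Tm[1:3, 1:3] <- 0.5; Tm[4:6, 4:6] <- 0.5; diag(Tm) <- 0
  rownames(Tm) <- colnames(Tm) <- letters[1:6]
  cl <- cluster_states(successor_representation(Tm, 0.95), 2:4)
  expect_equal(cl$chosen_k, 2)
  expect_equal(length(unique(cl$labels[1:3])), 1)
  expect_equal(length(unique(cl$labels[4:6])), 1)
  expect_false(cl$labels[1] == cl$labels[4])
})

test_that("rooms clusters align with room membership off the doorways", {
  skip_if_not_installed("mclust")
  w <- rooms_world()
  sr <- successor_representation(uniform_walk_transitions(w), 0.95)
  cl <- cluster_states(sr)
  doors <- find_doorways(w)
  rooms <- room_labels(w, doors)
  keep <- setdiff(seq_len(w$n_states), doors)
  ari <- mclust::adjustedRandIndex(cl$labels[keep], rooms[keep])
  expect_gte(ari, 0.9)
})

test_that("within-community SR similarity exceeds between, exhaustively", {
  g <- schapiro_graph()
  sr <- successor_representation(walk_transitions(g), 0.95)
  D <- as.matrix(stats::dist(sr$M))
  com <- igraph::V(g)$community
  same <- outer(com, com, "==") & upper.tri(D)
  expect_lt(max(D[same]), min(D[!same & upper.tri(D)]))
})

test_that("a bridge vertex is identified as the bottleneck", {
  sr <- successor_representation(walk_transitions(bridge_graph()), 0.95)
  cl <- cluster_states(sr, 2:4)
  bn <- identify_bottlenecks(sr, cl)
  expect_equal(sr$states[bn], "d")
})

test_that("a fully connected graph has no bottlenecks", {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- letters[1:6]
  sr <- successor_representation(walk_transitions(g), 0.95)
  cl <- cluster_states(sr, 2:4)
  expect_length(identify_bottlenecks(sr, cl), 0)
})

test_that("three equidistant states embed as an equilateral triangle", {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- c("a", "b", "c")
  sr <- successor_representation(walk_transitions(g), 0.9)
  pts <- embed_mds(sr)
  d <- as.numeric(stats::dist(pts))
  expect_equal(max(d) - min(d), 0, tolerance = 1e-8)
  expect_equal(colMeans(pts), c(0, 0), ignore_attr = TRUE)
})

test_that("block-structured representations embed block-separated", {
  Tm <- matrix(0, 6, 6)
  Tm[1:3, 1:3] <- 0.5; Tm[4:6, 4:6] <- 0.5; diag(Tm) <- 0
  sr <- successor_representation(Tm, 0.95)
  pts <- embed_mds(sr)
  within <- c(stats::dist(pts[1:3, ]), stats::dist(pts[4:6, ]))
  between <- as.vector(as.matrix(stats::dist(pts))[1:3, 4:6])
  expect_lt(max(within), min(between))
})

test_that("the embedding preserves SR distance ranks", {
  w <- rooms_world()
  sr <- successor_representation(uniform_walk_transitions(w), 0.95)
  d_orig <- as.vector(stats::dist(sr$M))
  rho2 <- stats::cor(d_orig, as.vector(stats::dist(embed_mds(sr))),
                     method = "spearman")
  expect_gt(rho2, 0.7)
  rho10 <- stats::cor(d_orig, as.vector(stats::dist(embed_mds(sr, k = 10))),
                      method = "spearman")
  expect_gt(rho10, 0.9)
  expect_gt(rho10, rho2)
})

test_that("SR dips are larger at community bridges than within", {
  g <- schapiro_graph()
  sr <- successor_representation(walk_transitions(g), 0.95)
  walk <- random_walk_sequence(g, 2000, seed = 13)
  dips <- sr_transition_dip(sr, walk)
  com <- igraph::V(g)$community
  cross <- com[match(dips$from, sr$states)] != com[match(dips$to, sr$states)]
  expect_gt(min(dips$dip[cross]), max(dips$dip[!cross]))
})
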