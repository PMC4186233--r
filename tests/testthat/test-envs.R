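test_that("map parsing validates structure and markers", {
  expect_error(parse_map("###\n#S#\n###"), "goal")
  expect_error(parse_map("S...G\nS...."), "exactly one start")
  expect_error(parse_map("S..\nG"), "rectangular")
  expect_error(parse_map("SxG"), "invalid map characters")
  expect_error(parse_map("S#.G"), "unreachable.*\\(0,2\\)")
})

test_that("corridor map parses with 0-based coordinates", {
  w <- corridor_world()
  expect_equal(w$n_states, 6)
  expect_equal(w$start, c(0, 0))
  expect_equal(w$goal, c(0, 5))
})

test_that("shipped rooms fixture has the documented layout", {
  path <- map_file("rooms_default.map")
  # count free characters straight off the file, independent of the parser
  n_free <- sum(vapply(strsplit(readLines(path), ""),
                       function(ch) sum(ch %in% c(".", "S", "G")), 1L))
  w <- rooms_world()
  expect_equal(w$n_states, n_free)
  expect_equal(n_free, 104)
})

test_that("stepping bounces off walls and rewards goal entry", {
  w <- corridor_world()
  s <- grid_step(w, c(0, 0), "left")
  expect_equal(s$next_state, c(0, 0))
  expect_equal(s$reward, w$step_reward)
  expect_false(s$done)
  s <- grid_step(w, c(0, 4), "right")
  expect_equal(s$next_state, c(0, 5))
  expect_equal(s$reward, w$step_reward + w$goal_reward)
  expect_true(s$done)
  expect_error(grid_step(w, c(5, 5), "up"), "outside the map")
})

test_that("every move changes exactly one coordinate by one, or none", {
  w <- rooms_world()
  for (a in 1:4) {
    d <- abs(w$free[w$next_state[, a], , drop = FALSE] - w$free)
    expect_true(all(rowSums(d) %in% c(0L, 1L)))
  }
  # and the result is always a free cell (by construction of next_state ids)
  expect_true(all(w$next_state >= 1 & w$next_state <= w$n_states))
})

test_that("BFS oracle gives corridor length, identity zero, and symmetry", {
  w <- corridor_world()
  expect_equal(shortest_path_length(w, w$start, w$goal), 5)
  expect_equal(shortest_path_length(w, c(0, 3), c(0, 3)), 0)
  rooms <- rooms_world()
  cells <- free_cells(rooms)
  set.seed(11)
  for (i in sample(nrow(cells), 12)) {
    a <- c(cells$row[i], cells$col[i])
    j <- sample(nrow(cells), 1)
    b <- c(cells$row[j], cells$col[j])
    expect_equal(shortest_path_length(rooms, a, b),
                 shortest_path_length(rooms, b, a))
  }
})

test_that("random walks respect edges and degree-1 forcing", {
  path <- community_graph(data.frame(from = "a", to = "b"))
  expect_equal(random_walk_sequence(path, 4, seed = 3, start = "a"),
               c("a", "b", "a", "b"))
  g <- schapiro_graph()
  walk <- random_walk_sequence(g, 500, seed = 5)
  el <- igraph::as_edgelist(g)
  edge_key <- c(paste(el[, 1], el[, 2]), paste(el[, 2], el[, 1]))
  expect_true(all(paste(walk[-500], walk[-1]) %in% edge_key))
})

test_that("walk transition frequencies match the uniform-neighbour law", {
  g <- schapiro_graph()
  walk <- random_walk_sequence(g, 1e4, seed = 17)
  tab <- table(from = walk[-length(walk)], to = walk[-1])
  freq <- tab / rowSums(tab)
  adj <- igraph::as_adj_list(g)
  nm <- igraph::V(g)$name
  for (v in nm) {
    n_from <- sum(tab[v, ])
    se <- sqrt(0.25 * 0.75 / n_from)
    nbs <- nm[as.integer(adj[[match(v, nm)]])]
    expect_true(all(abs(freq[v, nbs] - 0.25) <= 3 * se),
                label = paste("neighbour frequencies from", v))
  }
})

test_that("graph fixtures load from the shipped edge list", {
  g <- community_graph(map_file("schapiro_graph.tsv"),
                       map_file("schapiro_communities.tsv"))
  expect_equal(igraph::vcount(g), 15)
  expect_true(all(igraph::degree(g) == 4))
  expect_equal(sort(unique(igraph::V(g)$community)), 1:3)
  expect_error(community_graph(data.frame(from = c("a", "c"), to = c("b", "d"))),
               "not connected")
})
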