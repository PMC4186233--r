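# Shared fixtures; maps are parsed once per test run.
map_file <- function(name) system.file("extdata", name, package = "saltatory")

rooms_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- read_map(map_file("rooms_default.map"))
    w
  }
})

two_rooms_world <- function() read_map(map_file("two_rooms.map"))
corridor_world <- function(...) parse_map("S....G", ...)
chain_world <- function() parse_map("S......G")

# the two options of the worked decision-count example: the first four and
# the last three actions of the 7-step chain aggregated
chain_options <- function(world = chain_world()) {
  list(
    learn_option_policy(world, subgoal = c(0, 4),
                        initiation_set = cbind(0, 0:3), id = "first_four"),
    learn_option_policy(world, subgoal = c(0, 7),
                        initiation_set = cbind(0, 4:6), id = "last_three"))
}

# doorway options of the default rooms map, built once
rooms_options <- local({
  o <- NULL
  function() {
    if (is.null(o)) o <<- make_doorway_options(rooms_world())
    o
  }
})

# state id of a 0-based (row, col) cell
state_of <- function(world, cell) {
  fc <- free_cells(world)
  fc$state[fc$row == cell[1] & fc$col == cell[2]]
}

# two 3-cliques joined by a single bridge vertex (d adjacent to c and e)
bridge_graph <- function() {
  community_graph(data.frame(
    from = c("a", "a", "b", "c", "e", "e", "f", "d"),
    to   = c("b", "c", "c", "d", "f", "g", "g", "e")))
}

# uniform random-walk transition matrix of an undirected igraph
walk_transitions <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  Tm <- A / rowSums(A)
  dimnames(Tm) <- list(igraph::V(g)$name, igraph::V(g)$name)
  Tm
}
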