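#' Build a community graph from an edge list
#'
#' Community graphs are undirected, connected, simple graphs used for
#' random-walk sequence experiments: stimuli are vertices and observers see a
#' random walk over the edges. Edge lists may carry an optional per-vertex
#' `community` labelling (fixtures only; the labels are never used by the
#' discovery code, only by tests).
#'
#' @param edges Data frame with columns `from` and `to` (vertex ids), or a
#'   path to a whitespace-delimited file with a header.
#' @param communities Optional data frame (`vertex`, `community`) or file path.
#' @return A `community_graph`: an igraph with optional `community` vertex
#'   attribute.
#' @export
community_graph <- function(edges, communities = NULL) {
  if (is.character(edges))
    edges <- utils::read.table(edges, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(edges)))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
  if (any(igraph::which_loop(g))) stop("community graph has self-loops", call. = FALSE)
  g <- igraph::simplify(g)
  if (!igraph::is_connected(g)) stop("community graph is not connected", call. = FALSE)
  if (!is.null(communities)) {
    if (is.character(communities))
      communities <- utils::read.table(communities, header = TRUE,
                                       stringsAsFactors = FALSE)
    lab <- communities$community[match(igraph::V(g)$name, communities$vertex)]
    igraph::V(g)$community <- lab
  }
  class(g) <- c("community_graph", class(g))
  g
}

#' The three-community random-walk graph
#'
#' Fifteen vertices in three communities of five; within a community every
#' pair is joined except the two boundary vertices, and each boundary vertex
#' bridges to the neighbouring community, so every vertex has degree 4.
#' Shipped as `extdata/schapiro_graph.tsv` and rebuilt here in code.
#'
#' @return A `community_graph` with a `community` vertex attribute.
#' @export
schapiro_graph <- function() {
  edges <- NULL
  for (c0 in c(0L, 5L, 10L)) {
    vs <- c0 + 1:5
    within <- t(utils::combn(vs, 2))
    within <- within[!(within[, 1] == c0 + 1L & within[, 2] == c0 + 5L), ]
    edges <- rbind(edges, within)
  }
  edges <- rbind(edges, c(5L, 6L), c(10L, 11L), c(15L, 1L))
  df <- data.frame(from = sprintf("v%02d", edges[, 1]),
                   to = sprintf("v%02d", edges[, 2]))
  community_graph(df, data.frame(vertex = sprintf("v%02d", 1:15),
                                 community = rep(1:3, each = 5)))
}

#' Random walk over a community graph
#'
#' At each step the walk moves to a uniformly chosen neighbour of the current
#' vertex. Every consecutive pair in the returned sequence is an edge.
#'
#' @param graph A `community_graph` (or any undirected igraph).
#' @param length Number of vertices in the returned sequence (>= 1).
#' @param seed Integer seed; the walk is reproducible given the seed.
#' @param start Optional start vertex name; default: uniformly random.
#' @return Character vector of vertex names, length `length`.
#' @export
random_walk_sequence <- function(graph, length, seed = NULL, start = NULL) {
  stopifnot(length >= 1)
  nm <- igraph::V(graph)$name
  adj <- igraph::as_adj_list(graph)
  with_seed(seed, {
    v <- if (is.null(start)) sample.int(igraph::vcount(graph), 1L)
         else match(start, nm)
    if (is.na(v)) stop("unknown start vertex", call. = FALSE)
    out <- integer(length)
    out[1] <- v
    if (length > 1) for (i in 2:length) {
      nbs <- adj[[v]]
      if (base::length(nbs) == 0L) stop("isolated vertex: ", nm[v], call. = FALSE)
      v <- as.integer(nbs[sample.int(base::length(nbs), 1L)])
      out[i] <- v
    }
    nm[out]
  })
}
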