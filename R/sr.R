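#' Successor representation of a Markov chain
#'
#' The successor representation (SR) of a policy's transition matrix `T` is
#' `M = (I - gamma*T)^-1`: `M[i, j]` is the expected discounted future
#' occupancy of state `j` starting from `i`. Rows of `M` are predictive
#' representations of the states; states that predict similar futures have
#' similar rows, which is what the subgoal-discovery pipeline exploits.
#'
#' @param transition Square row-stochastic matrix (rows sum to 1 within 1e-9).
#' @param gamma_sr Discount in (0, 1).
#' @param states Optional state labels (default rownames or indices).
#' @return An `sr` object: `M`, `gamma_sr`, `states`.
#' @export
successor_representation <- function(transition, gamma_sr = 0.95,
                                     states = NULL) {
  transition <- as.matrix(transition)
  if (nrow(transition) != ncol(transition))
    stop("transition matrix must be square", call. = FALSE)
  if (any(abs(rowSums(transition) - 1) > 1e-9) || any(transition < 0))
    stop("transition matrix is not row-stochastic", call. = FALSE)
  stopifnot(gamma_sr > 0, gamma_sr < 1)
  n <- nrow(transition)
  M <- solve(diag(n) - gamma_sr * transition)
  states <- states %||% rownames(transition) %||% as.character(seq_len(n))
  dimnames(M) <- list(states, states)
  structure(list(M = M, gamma_sr = gamma_sr, states = states), class = "sr")
}

#' @export
print.sr <- function(x, ...) {
  cat(sprintf("<sr> %d states, gamma_sr = %g (row sums %.4f)\n",
              nrow(x$M), x$gamma_sr, mean(rowSums(x$M))))
  invisible(x)
}

# SR via truncated power series: I + gT + (gT)^2 + ...; used as the
# cross-check for the closed-form solve
sr_power_series <- function(transition, gamma_sr, tol = 1e-10,
                            max_terms = 10000L) {
  n <- nrow(transition)
  M <- diag(n); term <- diag(n)
  for (i in seq_len(max_terms)) {
    term <- gamma_sr * (term %*% transition)
    M <- M + term
    if (max(abs(term)) < tol) return(M)
  }
  stop("power series did not converge", call. = FALSE)
}

#' Exact uniform random-walk transition matrix of a gridworld
#'
#' Marginal state-to-state transitions under the uniform policy over the
#' four moves (wall bounces contribute to the diagonal). The goal is not
#' absorbing: latent learning is reward-free.
#'
#' @param world A `gridworld`.
#' @return Row-stochastic matrix over free cells (states as `"row,col"`).
#' @export
uniform_walk_transitions <- function(world) {
  n <- world$n_states
  Tm <- matrix(0, n, n)
  for (a in 1:4) {
    idx <- cbind(seq_len(n), world$next_state[, a])
    Tm[idx] <- Tm[idx] + 0.25
  }
  dimnames(Tm) <- rep(list(sprintf("%d,%d", world$free[, 1], world$free[, 2])), 2)
  Tm
}

#' Estimate a transition model by latent learning
#'
#' Simulates reward-free exploration: `n_steps` uniformly random actions
#' from the start cell, observing the outcome of each. The empirical
#' (state, action) outcomes are marginalized to a state-to-state matrix
#' under the uniform policy and rows are renormalized.
#'
#' @param world A `gridworld`.
#' @param n_steps Number of exploration steps (>= 1).
#' @param seed Integer seed; the walk is reproducible.
#' @return Estimated row-stochastic matrix; an error lists any state never
#'   visited (increase `n_steps`).
#' @export
transition_model_from_exploration <- function(world, n_steps = 1e5,
                                              seed = NULL) {
  stopifnot(n_steps >= 1)
  n <- world$n_states
  with_seed(seed, {
    acts <- sample.int(4L, n_steps, replace = TRUE)
    counts <- matrix(0, n, n)
    s <- world$start_id
    for (i in seq_len(n_steps)) {
      if (world$success_prob < 1 && stats::runif(1) > world$success_prob)
        acts[i] <- sample((1:4)[-acts[i]], 1L)
      s2 <- world$next_state[s, acts[i]]
      counts[s, s2] <- counts[s, s2] + 1
      s <- s2
    }
    visits <- rowSums(counts)
    if (any(visits == 0)) {
      miss <- which(visits == 0)
      stop("states never visited during exploration: ",
           paste(sprintf("(%d,%d)", world$free[miss, 1], world$free[miss, 2]),
                 collapse = ", "),
           "; increase n_steps", call. = FALSE)
    }
    Tm <- counts / visits
    dimnames(Tm) <- rep(list(sprintf("%d,%d", world$free[, 1], world$free[, 2])), 2)
    Tm
  })
}

#' Cluster states by their predictive representations
#'
#' Agglomerative (Ward) clustering on the rows of the SR matrix, with the
#' number of clusters chosen to maximize the mean silhouette width over
#' `k_candidates`. Deterministic. A k-means alternative (fixed seed) is
#' available via `method = "kmeans"`.
#'
#' @param sr An `sr` object.
#' @param k_candidates Candidate cluster counts, within `[2, n - 1]`.
#' @param method `"ward"` (default) or `"kmeans"`.
#' @param kmeans_seed Seed for the k-means alternative.
#' @return An `sr_clustering`: `labels` (integer per state), `chosen_k`,
#'   `silhouette` (per state), `mean_silhouette` (per candidate k),
#'   `dist` (row distances).
#' @export
cluster_states <- function(sr, k_candidates = 2:8, method = c("ward", "kmeans"),
                           kmeans_seed = 1L) {
  method <- match.arg(method)
  n <- nrow(sr$M)
  k_candidates <- k_candidates[k_candidates >= 2 & k_candidates <= n - 1]
  if (!length(k_candidates)) stop("no admissible k candidates", call. = FALSE)
  D <- stats::dist(sr$M)
  if (max(D) < 1e-12) stop("degenerate SR: all rows identical", call. = FALSE)
  labs_for <- if (method == "ward") {
    hc <- stats::hclust(D, method = "ward.D2")
    function(k) stats::cutree(hc, k)
  } else {
    function(k) with_seed(kmeans_seed,
      stats::kmeans(sr$M, centers = k, nstart = 10L)$cluster)
  }
  all_labs <- lapply(k_candidates, labs_for)
  mean_sil <- vapply(all_labs, function(l)
    mean(cluster::silhouette(l, D)[, "sil_width"]), 1)
  best <- which.max(mean_sil)
  labels <- all_labs[[best]]
  sil <- cluster::silhouette(labels, D)[, "sil_width"]
  structure(list(labels = as.integer(labels),
                 chosen_k = k_candidates[best],
                 silhouette = as.numeric(sil),
                 mean_silhouette = stats::setNames(mean_sil,
                                                   k_candidates),
                 states = sr$states, dist = D, method = method),
            class = "sr_clustering")
}

#' @export
print.sr_clustering <- function(x, ...) {
  cat(sprintf("<sr_clustering> %s, chosen k = %d (mean silhouette %.3f)\n",
              x$method, x$chosen_k, x$mean_silhouette[as.character(x$chosen_k)]))
  invisible(x)
}

#' Identify bottleneck states from an SR clustering
#'
#' Bottlenecks (e.g. doorways) sit between clusters: they are the states
#' whose silhouette width falls below `threshold`, or that form singleton
#' clusters. On the rooms maps these are exactly the doorway cells - the
#' isolated points of the SR similarity structure, and natural subgoals.
#'
#' Bottlenecks presuppose community structure: when the clustering itself is
#' uninformative (mean silhouette below `min_structure`, as on a fully
#' connected graph) there are no between-cluster boundaries to sit on and an
#' empty result is returned.
#'
#' @param sr An `sr` object.
#' @param clustering An `sr_clustering` from [cluster_states()].
#' @param threshold Silhouette threshold (default 0.05).
#' @param min_structure Minimum mean silhouette for the clustering to count
#'   as structured (default 0.1).
#' @return Integer state indices, sorted by ascending silhouette (possibly
#'   empty).
#' @export
identify_bottlenecks <- function(sr, clustering, threshold = 0.05,
                                 min_structure = 0.1) {
  stopifnot(inherits(clustering, "sr_clustering"))
  if (mean(clustering$silhouette) < min_structure) return(integer(0))
  singleton <- clustering$labels %in%
    which(tabulate(clustering$labels) == 1L)
  low <- clustering$silhouette < threshold | singleton
  idx <- which(low)
  idx[order(clustering$silhouette[idx])]
}

#' Two-dimensional embedding of predictive representations
#'
#' Classical multidimensional scaling of the pairwise Euclidean distances
#' between SR rows. The embedding is centred at the origin; orientation is
#' arbitrary (analyses must be rotation/reflection-invariant). If the
#' distance matrix supports fewer than `k` dimensions the available ones
#' are returned with a warning.
#'
#' @param sr An `sr` object (>= 3 states).
#' @param k Target dimension (default 2).
#' @return Matrix of coordinates, one row per state.
#' @export
embed_mds <- function(sr, k = 2L) {
  n <- nrow(sr$M)
  if (n < 3L) stop("need at least 3 states to embed", call. = FALSE)
  D <- stats::dist(sr$M)
  fit <- stats::cmdscale(D, k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    warning("distance matrix is rank-deficient; returning ", ncol(pts),
            " dimension(s)")
  }
  pts <- sweep(pts, 2, colMeans(pts))
  rownames(pts) <- sr$states
  pts
}

#' SR similarity dip along a walk
#'
#' For each transition of a vertex sequence, the Euclidean distance between
#' the SR rows of the two vertices: larger at community-bridge edges than
#' within communities, which is what lets a predictive code parse a
#' sequence into events.
#'
#' @param sr An `sr` whose states are the walk's vertices.
#' @param walk Character vector of vertex names (consecutive pairs edges).
#' @return Tibble: `from`, `to`, `dip` per transition.
#' @export
sr_transition_dip <- function(sr, walk) {
  i <- match(walk[-length(walk)], sr$states)
  j <- match(walk[-1], sr$states)
  if (anyNA(i) || anyNA(j)) stop("walk contains unknown vertices", call. = FALSE)
  dip <- sqrt(rowSums((sr$M[i, , drop = FALSE] - sr$M[j, , drop = FALSE])^2))
  tibble::tibble(from = walk[-length(walk)], to = walk[-1], dip = dip)
}
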