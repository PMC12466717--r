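# Independent oracles and small generators used across the test files.

# Kruskal MST oracle: sort by (distance, edge index), union-find.
# Deliberately independent of the package's Boruvka implementation.
kruskal_total_distance <- function(edges, num_vertices) {
  ord <- order(edges$distance, seq_len(nrow(edges)))
  parent <- seq_len(num_vertices)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  total <- 0
  taken <- 0L
  for (ei in ord) {
    ru <- find(edges$u[ei] + 1L)
    rv <- find(edges$v[ei] + 1L)
    if (ru != rv) {
      parent[ru] <- rv
      total <- total + edges$distance[ei]
      taken <- taken + 1L
      if (taken == num_vertices - 1L) break
    }
  }
  stopifnot(taken == num_vertices - 1L)
  total
}

random_grid <- function(h, w, f = 3L) {
  feature_grid(array(stats::rnorm(h * w * f), dim = c(h, w, f)))
}

# random spanning tree edge list over V vertices (0-based ids):
# each non-root vertex attaches to a uniformly chosen earlier vertex
random_tree_edges <- function(V) {
  if (V == 1L) return(data.frame(u = integer(0), v = integer(0)))
  par <- vapply(seq_len(V - 1L), function(v) sample.int(v, 1L) - 1L, integer(1))
  data.frame(u = par, v = seq_len(V - 1L))
}

random_spanning_tree <- function(V, root = NULL, weights_range = c(-1, 1)) {
  edges <- random_tree_edges(V)
  if (is.null(root)) root <- sample.int(V, 1L) - 1L
  tree <- bfs_tree(edges, V, root)
  w <- stats::runif(V, weights_range[1L], weights_range[2L])
  w[tree$root + 1L] <- NA_real_
  tree$edge_similarity <- w
  tree
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-12)
}

tiny_model_config <- function(...) {
  defaults <- list(input_size = 16L, sequence_length = 2L, num_classes = 3L,
                   num_stages = 2L, stage_widths = c(6L, 8L), state_size = 4L,
                   mlp_ratio = 2L, drop_path = 0, dropout = 0,
                   fusion = "tempdiff", seed = 11L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

random_frames <- function(n, size = 16L) {
  lapply(seq_len(n), function(i) array(stats::runif(size * size * 3), c(size, size, 3)))
}
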