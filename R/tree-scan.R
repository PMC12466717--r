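#' Path-product weight between two vertices of a spanning tree
#'
#' The weight of the (unique) tree path between `i` and `j` is the product
#' of the per-edge weights along it; the empty path (`i == j`) has weight 1.
#'
#' @param tree a `spanning_tree` from [bfs_tree()]
#' @param i,j 0-based vertex ids
#' @param weights per-vertex weight of the edge to the parent (`NA` at the
#'   root); defaults to the tree's stored edge similarities
#' @return scalar path product
#' @export
path_weight <- function(tree, i, j, weights = tree$edge_similarity) {
  V <- tree$num_vertices
  if (i < 0L || i >= V || j < 0L || j >= V) stop("invalid vertex id")
  if (i == j) return(1)
  anc <- function(v) {            # vertices on the path v .. root
    out <- v
    while (!is.na(tree$parent[v + 1L])) {
      v <- tree$parent[v + 1L]
      out <- c(out, v)
    }
    out
  }
  ai <- anc(i); aj <- anc(j)
  lca <- ai[min(which(ai %in% aj))]
  up <- function(a) a[seq_len(which(a == lca) - 1L)] # strict path below the LCA
  prod(weights[c(up(ai), up(aj)) + 1L])
}

#' Brute-force path-weighted aggregation (oracle)
#'
#' Computes `h[i, ] = sum_j W(i, j) * m[j, ]` with `W(i, j)` the
#' path-product weight, by explicit O(V^2) enumeration. This is the
#' reference implementation the fast two-pass scan is tested against.
#'
#' @param m V x K matrix of per-vertex source terms
#' @param tree a `spanning_tree`
#' @param weights per-vertex parent-edge weights (root entry ignored)
#' @return V x K matrix of aggregated hidden states
#' @export
brute_force_aggregate <- function(m, tree, weights = tree$edge_similarity) {
  m <- as.matrix(m)
  V <- tree$num_vertices
  stopifnot(nrow(m) == V)
  W <- path_weight_matrix(tree, weights)
  W %*% m
}

#' All-pairs path-product weight matrix of a spanning tree
#'
#' @inheritParams brute_force_aggregate
#' @return symmetric V x V matrix with unit diagonal
#' @export
path_weight_matrix <- function(tree, weights = tree$edge_similarity) {
  V <- tree$num_vertices
  # weighted tree adjacency: v <-> parent(v) with weight w(v)
  nbr <- vector("list", V)
  wts <- vector("list", V)
  for (v in seq_len(V) - 1L) {
    p <- tree$parent[v + 1L]
    if (is.na(p)) next
    nbr[[v + 1L]] <- c(nbr[[v + 1L]], p); wts[[v + 1L]] <- c(wts[[v + 1L]], weights[v + 1L])
    nbr[[p + 1L]] <- c(nbr[[p + 1L]], v); wts[[p + 1L]] <- c(wts[[p + 1L]], weights[v + 1L])
  }
  W <- matrix(0, V, V)
  for (i in seq_len(V)) {
    # depth-first walk from i, accumulating edge products
    W[i, i] <- 1
    stk_v <- i - 1L; stk_p <- -1L     # (vertex, came-from) stacks
    while (length(stk_v) > 0L) {
      v <- stk_v[length(stk_v)]; pv <- stk_p[length(stk_v)]
      stk_v <- stk_v[-length(stk_v)]; stk_p <- stk_p[-length(stk_p)]
      for (k in seq_along(nbr[[v + 1L]])) {
        u <- nbr[[v + 1L]][k]
        if (u == pv) next
        W[i, u + 1L] <- W[i, v + 1L] * wts[[v + 1L]][k]
        stk_v <- c(stk_v, u); stk_p <- c(stk_p, v)
      }
    }
  }
  W
}

#' Linear-time two-pass tree aggregation
#'
#' Equivalent to [brute_force_aggregate()] (to floating tolerance) but
#' computed in O(V K): an upward pass accumulates each subtree
#' (`S(v) = m_v + sum_c w(c) S(c)` in reverse BFS order), and a downward
#' rerooting pass combines the subtree sum with the complement through the
#' parent (`h(v) = S(v) + w(v) (h(parent) - w(v) S(v))`).
#'
#' @inheritParams brute_force_aggregate
#' @return V x K matrix of aggregated hidden states
#' @export
tree_scan_aggregate <- function(m, tree, weights = tree$edge_similarity) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == tree$num_vertices)
  w <- weights
  w[is.na(w)] <- 0
  tree_scan_cpp(m, tree$bfs_order, ifelse(is.na(tree$parent), -1L, tree$parent), w)
}

#' TreeSSM output map
#'
#' `y_i = sum_n C_bar[n] * LN(h_i)[n, ] + D_bar * x_i`, where LN normalizes
#' each vertex's hidden block over all its (state, channel) entries, with
#' learnable affine parameters `ln_gamma`, `ln_beta`.
#'
#' @param hidden V x (N*F) matrix (state index fastest within each channel
#'   block) or V x N x F array
#' @param x V x F matrix of the layer input features
#' @param C_bar length-N output vector
#' @param D_bar length-F skip vector
#' @param ln_gamma,ln_beta affine LayerNorm parameters of length N*F
#' @return V x F output matrix
#' @export
treessm_output <- function(hidden, x, C_bar, D_bar,
                           ln_gamma = rep(1, length(C_bar) * ncol(x)),
                           ln_beta = rep(0, length(C_bar) * ncol(x))) {
  x <- as.matrix(x)
  N <- length(C_bar); F <- ncol(x)
  if (is.array(hidden) && length(dim(hidden)) == 3L)
    hidden <- matrix(hidden, dim(hidden)[1L], N * F)
  hidden <- as.matrix(hidden)
  if (nrow(hidden) != nrow(x) || ncol(hidden) != N * F)
    stop("hidden/state/channel shape mismatch")
  hn <- layer_norm_fwd(hidden, ln_gamma, ln_beta)$y
  contract <- kronecker(diag(F), matrix(C_bar, ncol = 1L))
  hn %*% contract + sweep(x, 2L, D_bar, "*")
}

#' Full TreeSSM layer on a feature grid
#'
#' Composes the whole layer: input-dependent step sizes, zero-order-hold
#' discretization, 4-connected graph construction, Boruvka minimum spanning
#' tree, BFS traversal from a seeded random root, the two-pass path-product
#' aggregation, and the normalized output map. Output has the same
#' height/width/channels as the input; the aggregation is invariant (to
#' float tolerance) to the BFS root, hence to `seed`.
#'
#' @param grid a [feature_grid()]
#' @param params a [continuous_ssm()] with `channels` matching the grid
#' @param seed integer; drives the BFS root draw
#' @param use_abar_gate if `TRUE`, the discretized `A_bar = exp(Delta A)`
#'   gates the source term elementwise (default off: the tree-scan edge
#'   weight is the cosine similarity alone)
#' @param ln_gamma,ln_beta LayerNorm affine parameters (length N*F)
#' @param debug_json optional path; if set, a JSON dump of the tree (root,
#'   parent array, edge weights) is written there
#' @return a [feature_grid()] of identical dimensions
#' @export
tree_ssm_forward <- function(grid, params, seed = 0L, use_abar_gate = FALSE,
                             ln_gamma = NULL, ln_beta = NULL,
                             debug_json = NULL) {
  if (!inherits(grid, "feature_grid")) grid <- feature_grid(grid)
  d <- dim(grid)
  V <- d[1L] * d[2L]; F <- d[3L]; N <- params$state_size
  stopifnot(F == params$channels)
  if (is.null(ln_gamma)) ln_gamma <- rep(1, N * F)
  if (is.null(ln_beta)) ln_beta <- rep(0, N * F)

  x <- grid_as_matrix(grid)
  Delta <- compute_delta(x, params$delta_weight, params$delta_bias)
  dssm <- discretize(params, Delta)
  # m[v, (f-1)N+n] = B_bar[v,n,f] * x[v,f] = B[n] * Delta[v,f] * x[v,f]
  u <- Delta * x
  m <- sweep(u[, rep(seq_len(F), each = N), drop = FALSE], 2L,
             rep(params$B, F), "*")
  if (use_abar_gate) m <- m * matrix(dssm$A_bar, V, N * F)

  graph <- build_grid_graph(grid)
  mst <- boruvka_mst(graph)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  root <- sample.int(V, 1L) - 1L
  tree <- bfs_tree(mst, V, root)
  if (!is.null(debug_json)) tree_to_json(tree, debug_json)

  h <- tree_scan_aggregate(m, tree)
  y <- treessm_output(h, x, dssm$C_bar, dssm$D_bar, ln_gamma, ln_beta)
  matrix_as_grid(y, d[1L], d[2L])
}
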