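#' Feature grid
#'
#' A feature grid is one frame's representation inside the network: an
#' `height x width` lattice of `channels`-dimensional feature vectors.
#' Vertex ids over the lattice are 0-based and row-major
#' (`id = row * width + col`).
#'
#' @param values numeric array of dimension `(height, width, channels)`;
#'   all values must be finite.
#' @return a `feature_grid` object (the array with a class attribute).
#' @export
feature_grid <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (height, width, channels)")
  if (any(dim(values) < 1L)) stop("empty grid")
  if (!all(is.finite(values))) stop("feature grid contains non-finite values")
  structure(values, class = "feature_grid")
}

#' @export
dim.feature_grid <- function(x) attr(unclass(x), "dim")

#' Flatten a feature grid to a V x F matrix in row-major vertex order
#' @param grid a [feature_grid()]
#' @return numeric matrix with `height * width` rows (vertex id + 1) and
#'   `channels` columns
#' @export
grid_as_matrix <- function(grid) {
  d <- dim(grid)
  v <- unclass(grid)
  # vertex id = row * width + col  =>  row index varies slowest per row-major
  m <- matrix(aperm(v, c(2L, 1L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
  m
}

#' Rebuild a feature grid from a V x F matrix (inverse of [grid_as_matrix()])
#' @param m numeric matrix, `height * width` rows
#' @param height,width lattice dimensions
#' @export
matrix_as_grid <- function(m, height, width) {
  arr <- aperm(array(m, dim = c(width, height, ncol(m))), c(2L, 1L, 3L))
  feature_grid(arr)
}

#' Cosine similarity between two feature vectors
#'
#' Clipped to `[-1, 1]` against rounding. If either vector's norm is below
#' `eps` the similarity is defined as 0: the cosine is undefined there, and 0
#' is maximally dissimilar without a sign bias, so dead (all-zero) feature
#' vectors never propagate NaN into the spanning tree.
#'
#' @param f_u,f_v numeric vectors of equal length
#' @param eps norm threshold below which a vector counts as zero
#' @return scalar in `[-1, 1]`
#' @export
edge_similarity <- function(f_u, f_v, eps = 1e-8) {
  if (length(f_u) != length(f_v)) stop("feature vectors differ in length")
  if (length(f_u) < 1L) stop("empty feature vectors")
  nu <- sqrt(sum(f_u^2))
  nv <- sqrt(sum(f_v^2))
  if (nu < eps || nv < eps) return(0)
  min(1, max(-1, sum(f_u * f_v) / (nu * nv)))
}

# Vectorized cosine similarity for edge endpoint index vectors into a
# V x F feature matrix (internal hot path; semantics of edge_similarity()).
cosine_sim_rows <- function(x, iu, iv, eps = 1e-8) {
  nrm <- sqrt(rowSums(x^2))
  s <- rowSums(x[iu, , drop = FALSE] * x[iv, , drop = FALSE]) /
    pmax(nrm[iu] * nrm[iv], .Machine$double.xmin)
  s[nrm[iu] < eps | nrm[iv] < eps] <- 0
  pmin(1, pmax(-1, s))
}

# Lattice neighbor edge endpoints for an H x W 4-connected grid, as 0-based
# vertex ids in lexicographic (u, v) order with u < v.
lattice_edges <- function(height, width) {
  ids <- matrix(seq_len(height * width) - 1L, nrow = height, ncol = width,
                byrow = TRUE)
  right_u <- as.integer(t(ids[, -width, drop = FALSE]))
  right_v <- right_u + 1L
  down_u <- as.integer(t(ids[-height, , drop = FALSE]))
  down_v <- down_u + width
  u <- c(right_u, down_u)
  v <- c(right_v, down_v)
  if (length(u) == 0L) return(cbind(u = integer(0), v = integer(0)))
  o <- order(u, v)
  cbind(u = u[o], v = v[o])
}

#' Build the 4-connected pixel graph of a feature grid
#'
#' Vertices are the grid cells (row-major 0-based ids); edges join lattice
#' neighbors. Each edge carries the cosine similarity of its endpoint
#' feature vectors and the corresponding cosine distance `1 - similarity`,
#' which is the quantity the minimum spanning tree minimizes.
#'
#' @param grid a [feature_grid()]
#' @param connectivity lattice connectivity; only 4 (up/down/left/right) is
#'   supported
#' @return a `grid_graph`: list with `num_vertices`, `height`, `width`,
#'   `edges` (data frame `u, v, similarity, distance`), `connectivity`
#' @export
build_grid_graph <- function(grid, connectivity = 4L) {
  if (!inherits(grid, "feature_grid")) grid <- feature_grid(grid)
  if (!identical(as.integer(connectivity), 4L)) stop("unsupported connectivity")
  d <- dim(grid)
  x <- grid_as_matrix(grid)
  e <- lattice_edges(d[1L], d[2L])
  sim <- if (nrow(e) > 0L) cosine_sim_rows(x, e[, 1L] + 1L, e[, 2L] + 1L)
         else numeric(0)
  structure(list(
    num_vertices = d[1L] * d[2L],
    height = d[1L], width = d[2L],
    edges = data.frame(u = e[, 1L], v = e[, 2L],
                       similarity = sim, distance = 1 - sim),
    connectivity = 4L
  ), class = "grid_graph")
}

#' Minimum spanning tree by Boruvka's algorithm
#'
#' Retains the `V - 1` edges minimizing total cosine distance, i.e. the
#' most-similar neighbor links; edges across strong feature boundaries are
#' eliminated. Ties are broken by the smallest `(u, v)` lexicographic edge
#' id so the result is deterministic.
#'
#' @param graph a `grid_graph` from [build_grid_graph()], or any list with
#'   `num_vertices` and an `edges` data frame with columns `u, v, distance`
#' @return data frame of the selected edges (same columns as `graph$edges`)
#' @export
boruvka_mst <- function(graph) {
  e <- graph$edges
  nv <- graph$num_vertices
  if (nv == 1L) return(e[integer(0), , drop = FALSE])
  keep <- boruvka_mst_cpp(as.integer(e$u), as.integer(e$v),
                          as.numeric(e$distance), as.integer(nv)) + 1L
  e[keep, , drop = FALSE]
}

#' Rooted breadth-first traversal of a spanning tree
#'
#' Children are visited in ascending vertex id, so every vertex appears
#' after its parent in `bfs_order`.
#'
#' @param tree_edges data frame with 0-based vertex columns `u`, `v` and
#'   optionally `similarity` (used as the parent-edge weight)
#' @param num_vertices number of vertices spanned
#' @param root 0-based root vertex id
#' @return a `spanning_tree`: list with `root`, `parent` (0-based, `NA` at
#'   the root), `children` (per-vertex 0-based lists), `bfs_order`
#'   (0-based), and `edge_similarity` (per-vertex weight of the edge to the
#'   parent, `NA` at the root)
#' @export
bfs_tree <- function(tree_edges, num_vertices, root = 0L) {
  root <- as.integer(root)
  if (root < 0L || root >= num_vertices) stop("invalid root vertex")
  res <- bfs_tree_cpp(as.integer(tree_edges$u), as.integer(tree_edges$v),
                      as.integer(num_vertices), root)
  parent <- res$parent
  children <- split(seq_len(num_vertices) - 1L, factor(parent, levels = 0:(num_vertices - 1L)))
  names(children) <- NULL
  sim <- rep(NA_real_, num_vertices)
  if (!is.null(tree_edges$similarity) && nrow(tree_edges) > 0L) {
    # orient each edge child -> parent
    pu <- parent[tree_edges$u + 1L]
    child_is_u <- !is.na(pu) & pu == tree_edges$v
    child <- ifelse(child_is_u, tree_edges$u, tree_edges$v)
    sim[child + 1L] <- tree_edges$similarity
  }
  parent[parent < 0L] <- NA_integer_
  structure(list(root = root, parent = parent, children = children,
                 bfs_order = res$order, edge_similarity = sim,
                 num_vertices = num_vertices),
            class = "spanning_tree")
}

#' Serialize a spanning tree to a JSON debug dump
#' @param tree a `spanning_tree`
#' @param path file to write; if `NULL`, the JSON string is returned
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(root = tree$root, parent = tree$parent,
              bfs_order = tree$bfs_order,
              edge_similarity = tree$edge_similarity)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
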