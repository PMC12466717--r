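test_that("path weights are products of edge weights along tree paths", {
  path <- data.frame(u = c(0L, 1L), v = c(1L, 2L), similarity = c(0.5, 0.5))
  tr <- bfs_tree(path, 3L, root = 0L)
  expect_equal(path_weight(tr, 1, 1), 1)              # empty product
  expect_equal(path_weight(tr, 0, 1), 0.5)            # single edge
  expect_equal(path_weight(tr, 0, 2), 0.25)           # two edges
  expect_equal(path_weight(tr, 2, 0), 0.25)           # symmetric
  expect_error(path_weight(tr, 0, 7), "invalid vertex")
  # the all-pairs matrix agrees entrywise and is symmetric with unit diagonal
  set.seed(6)
  tr <- random_spanning_tree(12L)
  W <- path_weight_matrix(tr)
  expect_equal(W, t(W))
  expect_equal(diag(W), rep(1, 12))
  for (i in c(0L, 5L, 11L)) for (j in c(0L, 3L, 11L))
    expect_equal(W[i + 1L, j + 1L], path_weight(tr, i, j))
})

test_that("brute-force aggregation matches direct expansions", {
  # single vertex: h = m
  tr1 <- bfs_tree(data.frame(u = integer(0), v = integer(0)), 1L, 0L)
  m <- matrix(c(2, -1), 1L)
  expect_equal(brute_force_aggregate(m, tr1, NA_real_), m)
  # two vertices joined by weight w
  tr2 <- bfs_tree(data.frame(u = 0L, v = 1L, similarity = 0.3), 2L, 0L)
  m2 <- rbind(c(1, 0), c(0, 2))
  h <- brute_force_aggregate(m2, tr2)
  expect_equal(h, rbind(m2[1, ] + 0.3 * m2[2, ], m2[2, ] + 0.3 * m2[1, ]))
  # all edge weights 1: every row is the column total
  set.seed(7)
  tr <- random_spanning_tree(9L)
  tr$edge_similarity[-(tr$root + 1L)] <- 1
  m <- matrix(rnorm(9 * 4), 9L)
  h <- brute_force_aggregate(m, tr)
  for (i in 1:9) expect_equal(h[i, ], colSums(m))
})

test_that("two-pass scan equals the brute-force oracle on random instances", {
  set.seed(8)
  for (i in 1:60) {
    V <- sample(2:64, 1)
    tr <- random_spanning_tree(V)                 # weights in [-1, 1]
    m <- matrix(rnorm(V * 3), V, 3L)
    expect_lt(rel_err(tree_scan_aggregate(m, tr), brute_force_aggregate(m, tr)),
              1e-5)
  }
})

test_that("aggregation does not depend on the BFS root", {
  set.seed(9)
  for (i in 1:10) {
    V <- sample(3:40, 1)
    edges <- random_tree_edges(V)
    edges$similarity <- runif(nrow(edges), -1, 1)
    m <- matrix(rnorm(V * 2), V, 2L)
    roots <- sample.int(V, 2L) - 1L
    h1 <- tree_scan_aggregate(m, bfs_tree(edges, V, roots[1L]))
    h2 <- tree_scan_aggregate(m, bfs_tree(edges, V, roots[2L]))
    expect_lt(rel_err(h1, h2), 1e-5)
  }
})

test_that("self coefficient is 1 and coefficients decay along a path", {
  set.seed(10)
  tr <- random_spanning_tree(20L, weights_range = c(0.05, 0.95))
  W <- path_weight_matrix(tr)
  expect_equal(diag(W), rep(1, 20))
  # walking outward from any vertex along ancestors, |W| is non-increasing
  for (v in seq_len(20L) - 1L) {
    chain <- v
    while (!is.na(tr$parent[chain[length(chain)] + 1L]))
      chain <- c(chain, tr$parent[chain[length(chain)] + 1L])
    coeffs <- W[v + 1L, chain + 1L]
    expect_true(all(diff(coeffs) <= 1e-12))
  }
})

test_that("the output map combines normalized states with the skip path", {
  set.seed(11)
  V <- 6L; N <- 3L; F <- 4L
  x <- matrix(rnorm(V * F), V, F)
  h <- matrix(rnorm(V * N * F), V, N * F)
  # C = 0, D = 1: pure skip
  y <- treessm_output(h, x, C_bar = rep(0, N), D_bar = rep(1, F))
  expect_equal(y, x)
  # constant hidden state, D = 0: LayerNorm output is the affine bias, so
  # every vertex gets the same output row
  hc <- matrix(5, V, N * F)
  beta <- rnorm(N * F)
  yc <- treessm_output(hc, x, C_bar = rnorm(N), D_bar = rep(0, F),
                       ln_beta = beta)
  for (i in 2:V) expect_equal(yc[i, ], yc[1, ])
  expect_error(treessm_output(h[, -1], x, rep(0, N), rep(1, F)), "mismatch")
})

test_that("the full TreeSSM layer preserves shape and is root-invariant", {
  set.seed(12)
  p <- continuous_ssm(state_size = 4L, channels = 4L, seed = 3)
  g <- random_grid(8, 8, 4L)
  o1 <- tree_ssm_forward(g, p, seed = 1)
  expect_identical(dim(o1), dim(g))
  expect_true(all(is.finite(unclass(o1))))
  o2 <- tree_ssm_forward(g, p, seed = 999)
  expect_lt(rel_err(unclass(o1), unclass(o2)), 1e-5)
  # spatially constant input -> spatially constant output
  gc <- feature_grid(array(rep(c(0.3, -0.2, 1, 0.5), each = 36), c(6, 6, 4)))
  oc <- grid_as_matrix(tree_ssm_forward(gc, p, seed = 1))
  for (i in 2:36) expect_equal(oc[i, ], oc[1, ], tolerance = 1e-10)
  # gate variant still preserves shape and finiteness
  og <- tree_ssm_forward(g, p, seed = 1, use_abar_gate = TRUE)
  expect_identical(dim(og), dim(g))
  expect_true(all(is.finite(unclass(og))))
})
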