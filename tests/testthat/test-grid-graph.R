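test_that("lattice edge and vertex counts match the closed forms", {
  set.seed(1)
  for (h in c(1L, 2L, 3L, 5L, 9L, 16L)) {
    for (w in c(1L, 2L, 4L, 7L, 16L)) {
      g <- build_grid_graph(random_grid(h, w))
      expect_identical(g$num_vertices, h * w)
      expect_identical(nrow(g$edges), 2L * h * w - h - w)
      if (h * w > 1L) {
        mst <- boruvka_mst(g)
        expect_identical(nrow(mst), h * w - 1L)
      }
    }
  }
})

test_that("edge similarity is cosine similarity with guards", {
  expect_equal(edge_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(edge_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(edge_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(edge_similarity(c(0, 0), c(1, 2)), 0)   # zero-norm convention
  expect_error(edge_similarity(c(1, 2), c(1, 2, 3)), "length")
  set.seed(2)
  for (i in 1:50) {
    s <- edge_similarity(rnorm(4), rnorm(4))
    expect_true(s >= -1 && s <= 1)
  }
})

test_that("grid graph construction validates its input", {
  expect_error(build_grid_graph(array(numeric(0), c(0, 2, 3))), "empty grid")
  expect_error(build_grid_graph(random_grid(2, 2), connectivity = 8),
               "unsupported connectivity")
  g <- random_grid(2, 2)
  bad <- unclass(g); bad[1] <- NA
  expect_error(feature_grid(bad), "finite")
})

test_that("edges join only 4-neighbors, once each, in row-major ids", {
  h <- 3L; w <- 4L
  g <- random_grid(h, w)
  gg <- build_grid_graph(g)
  d <- abs(gg$edges$v - gg$edges$u)
  expect_true(all(d == 1L | d == w))
  # horizontal edges never wrap across rows
  horiz <- gg$edges[d == 1L, ]
  expect_true(all(horiz$u %% w != w - 1L))
  expect_false(any(duplicated(gg$edges[, c("u", "v")])))
  expect_equal(gg$edges$distance, 1 - gg$edges$similarity)
  # vertex id = row * width + col: check one known edge's similarity
  e01 <- gg$edges[gg$edges$u == 0L & gg$edges$v == 1L, ]
  expect_equal(e01$similarity,
               edge_similarity(unclass(g)[1, 1, ], unclass(g)[1, 2, ]))
})

test_that("Boruvka total distance equals the Kruskal oracle", {
  set.seed(3)
  for (i in 1:30) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    gg <- build_grid_graph(random_grid(h, w, 4L))
    mst <- boruvka_mst(gg)
    expect_equal(sum(mst$distance), kruskal_total_distance(gg$edges, gg$num_vertices))
  }
})

test_that("Boruvka keeps trees intact and drops a cycle's heaviest edge", {
  # 1xK grid is already a tree: every edge kept
  gg <- build_grid_graph(random_grid(1, 6))
  expect_identical(nrow(boruvka_mst(gg)), 5L)
  # 2x2 grid is a 4-cycle; craft distances 0.1..0.4
  cyc <- list(num_vertices = 4L,
              edges = data.frame(u = c(0L, 0L, 1L, 2L), v = c(1L, 2L, 3L, 3L),
                                 distance = c(0.1, 0.2, 0.4, 0.3)))
  mst <- boruvka_mst(cyc)
  expect_equal(sum(mst$distance), 0.6)
  expect_false(0.4 %in% mst$distance)
  # disconnected input errors
  disc <- list(num_vertices = 4L,
               edges = data.frame(u = c(0L, 2L), v = c(1L, 3L), distance = c(1, 1)))
  expect_error(boruvka_mst(disc), "not connected")
})

test_that("identical features give unit similarities and a zero-cost tree", {
  g <- feature_grid(array(1, c(4, 5, 3)))
  gg <- build_grid_graph(g)
  expect_true(all(abs(gg$edges$similarity - 1) < 1e-12))
  mst <- boruvka_mst(gg)
  expect_equal(sum(mst$distance), 0)
})

test_that("BFS ordering visits parents before children", {
  # star rooted at center: leaves in ascending order
  star <- data.frame(u = rep(0L, 4), v = 1:4)
  tr <- bfs_tree(star, 5L, root = 0L)
  expect_identical(tr$bfs_order, c(0L, 1L, 2L, 3L, 4L))
  # path 0-1-2 rooted at the middle
  path <- data.frame(u = c(0L, 1L), v = c(1L, 2L))
  tr <- bfs_tree(path, 3L, root = 1L)
  expect_identical(tr$parent, c(1L, NA_integer_, 1L))
  expect_identical(tr$bfs_order, c(1L, 0L, 2L))
  # random trees: position(parent(v)) < position(v)
  set.seed(4)
  for (i in 1:20) {
    V <- sample(2:40, 1)
    tr <- bfs_tree(random_tree_edges(V), V, root = sample.int(V, 1) - 1L)
    pos <- match(seq_len(V) - 1L, tr$bfs_order)
    for (v in seq_len(V) - 1L) {
      if (!is.na(tr$parent[v + 1L]))
        expect_lt(pos[tr$parent[v + 1L] + 1L], pos[v + 1L])
    }
    # children/parent consistency
    for (v in seq_len(V) - 1L) {
      for (ch in tr$children[[v + 1L]])
        expect_identical(tr$parent[ch + 1L], v)
    }
  }
  # non-tree edge sets are rejected
  expect_error(bfs_tree(data.frame(u = c(0L, 1L, 0L), v = c(1L, 2L, 2L)), 3L, 0L),
               "spanning tree")
  expect_error(bfs_tree(data.frame(u = 0L, v = 1L), 3L, 0L), "spanning tree")
  expect_error(bfs_tree(data.frame(u = 0L, v = 1L), 2L, 5L), "root")
})

test_that("spanning trees serialize to JSON", {
  tr <- bfs_tree(data.frame(u = c(0L, 1L), v = c(1L, 2L),
                            similarity = c(0.5, 0.25)), 3L, 0L)
  js <- jsonlite::fromJSON(tree_to_json(tr))
  expect_identical(js$root, 0L)
  expect_identical(js$parent[2:3], c(0L, 1L))
})
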