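# Hierarchical TreeSSM network: stem -> stages of (TreeSSM + MLP) blocks
# with pre-LayerNorm, residuals, dropout and DropPath -> global average
# pooling -> temporal fusion over the sampled frames -> linear head.
# Forward passes record the caches needed by the hand-written reverse-mode
# backward passes further below.

#' Model configuration
#'
#' @param input_size square frame resolution in pixels; must be divisible
#'   by 4 (stem) times `2^(num_stages - 1)` (inter-stage downsampling)
#' @param sequence_length number of sampled frames per video
#' @param num_classes number of behavior classes
#' @param num_stages number of TreeMamba stages (one block each)
#' @param stage_widths per-stage channel counts (length `num_stages`)
#' @param state_size TreeSSM hidden state dimension N
#' @param mlp_ratio MLP expansion ratio
#' @param drop_path stochastic-depth rate in `[0, 1)`
#' @param dropout dropout rate in `[0, 1)` applied to residual branches
#' @param fusion temporal fusion of per-frame features: `"mean"` (average
#'   of pooled embeddings; order-invariant) or `"tempdiff"` (mean embedding
#'   concatenated with pooled absolute first differences of the final
#'   feature grids; order-sensitive, captures motion)
#' @param use_abar_gate gate TreeSSM source terms by `exp(Delta A)`
#' @param seed integer seed for weight initialization
#' @return a `model_config` list
#' @export
model_config <- function(input_size = 224L, sequence_length = 20L,
                         num_classes = 5L, num_stages = 4L,
                         stage_widths = c(64L, 128L, 256L, 512L),
                         state_size = 16L, mlp_ratio = 4L,
                         drop_path = 0.1, dropout = 0,
                         fusion = c("mean", "tempdiff"),
                         use_abar_gate = FALSE, seed = 0L) {
  fusion <- match.arg(fusion)
  if (num_stages != length(stage_widths))
    stop("num_stages must equal length(stage_widths)")
  if (drop_path < 0 || drop_path >= 1 || dropout < 0 || dropout >= 1)
    stop("rates must be in [0, 1)")
  stride_total <- 4L * 2L^(num_stages - 1L)
  if (input_size %% stride_total != 0L)
    stop("input_size must be divisible by ", stride_total)
  structure(list(input_size = as.integer(input_size),
                 sequence_length = as.integer(sequence_length),
                 num_classes = as.integer(num_classes),
                 num_stages = as.integer(num_stages),
                 stage_widths = as.integer(stage_widths),
                 state_size = as.integer(state_size),
                 mlp_ratio = as.integer(mlp_ratio),
                 drop_path = drop_path, dropout = dropout,
                 fusion = fusion, use_abar_gate = use_abar_gate,
                 seed = as.integer(seed)),
            class = "model_config")
}

# row-major vertex flattening of an (H, W, C) array, and its inverse
arr_to_mat <- function(arr) arr2mat_cpp(arr)
mat_to_arr <- function(m, H, W) mat2arr_cpp(m, as.integer(H), as.integer(W))

# lattice edge lists depend only on (H, W): cache them per grid size
.edge_cache <- new.env(parent = emptyenv())
lattice_edges_cached <- function(H, W) {
  key <- paste0(H, "x", W)
  e <- .edge_cache[[key]]
  if (is.null(e)) {
    e <- lattice_edges(H, W)
    .edge_cache[[key]] <- e
  }
  e
}

rnorm_arr <- function(dims, sd = 0.02) array(stats::rnorm(prod(dims), sd = sd), dim = dims)

# He-scaled initialization: fan_in = all dims but the last
he_arr <- function(dims) {
  fan_in <- prod(dims[-length(dims)])
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Initialize model parameters
#'
#' @param config a [model_config()]
#' @return a `treessm_model`: list with `config` and `params` (flat named
#'   list of numeric arrays)
#' @export
model_init <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  N <- config$state_size
  W <- config$stage_widths
  p <- list()
  C0 <- W[1L]
  p[["stem.conv1.w"]] <- he_arr(c(3, 3, 3, C0))
  p[["stem.conv1.b"]] <- numeric(C0)
  p[["stem.ln1.g"]] <- rep(1, C0); p[["stem.ln1.b"]] <- numeric(C0)
  p[["stem.conv2.w"]] <- he_arr(c(3, 3, C0, C0))
  p[["stem.conv2.b"]] <- numeric(C0)
  p[["stem.ln2.g"]] <- rep(1, C0); p[["stem.ln2.b"]] <- numeric(C0)
  for (s in seq_len(config$num_stages)) {
    C <- W[s]; pre <- sprintf("s%d.", s)
    if (s > 1L) {
      p[[paste0(pre, "down.w")]] <- he_arr(c(2, 2, W[s - 1L], C))
      p[[paste0(pre, "down.b")]] <- numeric(C)
      p[[paste0(pre, "down_ln.g")]] <- rep(1, C)
      p[[paste0(pre, "down_ln.b")]] <- numeric(C)
    }
    p[[paste0(pre, "ln_a.g")]] <- rep(1, C); p[[paste0(pre, "ln_a.b")]] <- numeric(C)
    p[[paste0(pre, "ssm.dw")]] <- he_arr(c(C, C))
    p[[paste0(pre, "ssm.db")]] <- numeric(C)
    p[[paste0(pre, "ssm.a_log")]] <- matrix(stats::runif(N * C, log(0.1), 0), N, C)
    p[[paste0(pre, "ssm.B")]] <- stats::rnorm(N, sd = 0.1)
    p[[paste0(pre, "ssm.C")]] <- stats::rnorm(N, sd = 1 / sqrt(N))
    p[[paste0(pre, "ssm.D")]] <- rep(1, C)
    p[[paste0(pre, "ssm.hln.g")]] <- rep(1, N * C)
    p[[paste0(pre, "ssm.hln.b")]] <- numeric(N * C)
    p[[paste0(pre, "ln_b.g")]] <- rep(1, C); p[[paste0(pre, "ln_b.b")]] <- numeric(C)
    Ch <- C * config$mlp_ratio
    p[[paste0(pre, "mlp.w1")]] <- he_arr(c(C, Ch))
    p[[paste0(pre, "mlp.b1")]] <- numeric(Ch)
    p[[paste0(pre, "mlp.w2")]] <- he_arr(c(Ch, C))
    p[[paste0(pre, "mlp.b2")]] <- numeric(C)
  }
  Fh <- W[config$num_stages] * (if (config$fusion == "tempdiff") 2L else 1L)
  p[["head.w"]] <- rnorm_arr(c(Fh, config$num_classes))
  p[["head.b"]] <- numeric(config$num_classes)
  structure(list(config = config, params = p), class = "treessm_model")
}

#' Count learnable parameters
#' @param x a [model_config()] or a `treessm_model`
#' @return integer total number of learnable scalars
#' @export
count_parameters <- function(x) {
  if (inherits(x, "model_config")) x <- model_init(x)
  sum(vapply(x$params, length, integer(1)))
}

#' Stem block
#'
#' Two stride-2 3x3 convolutions (GELU after the first, channel LayerNorm
#' after each), taking an `H x W x 3` frame to an `(H/4) x (W/4)` feature
#' grid with `stage_widths[1]` channels.
#'
#' @param image numeric `H x W x 3` array with H, W divisible by 4
#' @param model a `treessm_model`
#' @return a [feature_grid()]
#' @export
stem_forward <- function(image, model) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) stop("image must be H x W x 3")
  if (d[1L] %% 4L != 0L || d[2L] %% 4L != 0L)
    stop("image dimensions must be divisible by 4")
  res <- .stem_fwd(model$params, image)
  matrix_as_grid(res$x, d[1L] %/% 4L, d[2L] %/% 4L)
}

.stem_fwd <- function(p, img) {
  a1 <- conv2d_fwd(img, p[["stem.conv1.w"]], p[["stem.conv1.b"]], 2L, 1L)
  d1 <- dim(a1)
  m1 <- arr_to_mat(a1)
  g1 <- gelu_fwd(m1)
  l1 <- layer_norm_fwd(g1$y, p[["stem.ln1.g"]], p[["stem.ln1.b"]])
  a2in <- mat_to_arr(l1$y, d1[1L], d1[2L])
  a2 <- conv2d_fwd(a2in, p[["stem.conv2.w"]], p[["stem.conv2.b"]], 2L, 1L)
  d2 <- dim(a2)
  m2 <- arr_to_mat(a2)
  l2 <- layer_norm_fwd(m2, p[["stem.ln2.g"]], p[["stem.ln2.b"]])
  list(x = l2$y, H = d2[1L], W = d2[2L],
       cache = list(img = img, a1 = a1, d1 = d1, g1 = g1, l1 = l1,
                    a2in = a2in, m2 = m2, l2 = l2))
}

.stem_bwd <- function(gx, cache, p, grads) {
  l2b <- layer_norm_bwd(gx, cache$l2, p[["stem.ln2.g"]])
  grads <- grad_add(grads, "stem.ln2.g", l2b$ggamma)
  grads <- grad_add(grads, "stem.ln2.b", l2b$gbeta)
  ga2 <- mat_to_arr(l2b$gx, dim(cache$a2in)[1L] %/% 2L, dim(cache$a2in)[2L] %/% 2L)
  cb2 <- conv2d_bwd(ga2, cache$a2in, p[["stem.conv2.w"]], 2L, 1L)
  grads <- grad_add(grads, "stem.conv2.w", cb2$gw)
  grads <- grad_add(grads, "stem.conv2.b", cb2$gb)
  gl1 <- arr_to_mat(cb2$gx)
  l1b <- layer_norm_bwd(gl1, cache$l1, p[["stem.ln1.g"]])
  grads <- grad_add(grads, "stem.ln1.g", l1b$ggamma)
  grads <- grad_add(grads, "stem.ln1.b", l1b$gbeta)
  gm1 <- gelu_bwd(l1b$gx, cache$g1)
  ga1 <- mat_to_arr(gm1, cache$d1[1L], cache$d1[2L])
  cb1 <- conv2d_bwd(ga1, cache$img, p[["stem.conv1.w"]], 2L, 1L)
  grads <- grad_add(grads, "stem.conv1.w", cb1$gw)
  grads <- grad_add(grads, "stem.conv1.b", cb1$gb)
  grads
}

grad_add <- function(grads, name, val) {
  g <- grads[[name]]
  grads[[name]] <- if (is.null(g)) val else g + val
  grads
}

# --- TreeSSM layer used inside a block (matrix in, matrix out) ------------

.ssm_fwd <- function(p, pre, xa, H, W, cfg, training) {
  V <- nrow(xa); F <- ncol(xa); N <- cfg$state_size
  dw <- p[[paste0(pre, "ssm.dw")]]
  zpre <- add_cols_cpp(xa %*% dw, p[[paste0(pre, "ssm.db")]])
  Delta <- softplus(zpre)
  u <- Delta * xa
  Bv <- p[[paste0(pre, "ssm.B")]]
  m <- source_fwd_cpp(u, Bv)
  gate <- NULL
  if (isTRUE(cfg$use_abar_gate)) {
    colmap <- rep(seq_len(F), each = N)
    Aflat <- as.vector(-exp(p[[paste0(pre, "ssm.a_log")]]))   # (f-1)N+n layout
    gate <- exp(sweep(Delta[, colmap, drop = FALSE], 2L, Aflat, "*"))
    m0 <- m
    m <- m * gate
  }
  # tree routing from the layer input features (detached from gradients)
  e <- lattice_edges_cached(H, W)
  sim <- cosine_sim_rows(xa, e[, 1L] + 1L, e[, 2L] + 1L)
  keep <- boruvka_mst_cpp(e[, 1L], e[, 2L], 1 - sim, V) + 1L
  root <- if (training && V > 1L) sample.int(V, 1L) - 1L else 0L
  bfs <- bfs_tree_cpp(e[keep, 1L], e[keep, 2L], V, root)
  wpar <- numeric(V)
  if (V > 1L) {
    child_is_u <- bfs$parent[e[keep, 1L] + 1L] == e[keep, 2L]
    child <- ifelse(child_is_u, e[keep, 1L], e[keep, 2L])
    wpar[child + 1L] <- sim[keep]
  }
  h <- tree_scan_cpp(m, bfs$order, bfs$parent, wpar)
  hl <- layer_norm_fwd(h, p[[paste0(pre, "ssm.hln.g")]], p[[paste0(pre, "ssm.hln.b")]])
  Cv <- p[[paste0(pre, "ssm.C")]]
  y <- contract_fwd_cpp(hl$y, Cv, F) +
       scale_cols_cpp(xa, p[[paste0(pre, "ssm.D")]])
  list(y = y,
       cache = list(xa = xa, zpre = zpre, Delta = Delta, u = u,
                    m0 = if (is.null(gate)) NULL else m0, gate = gate,
                    order = bfs$order, parent = bfs$parent, wpar = wpar,
                    hl = hl, hn = hl$y))
}

.ssm_bwd <- function(gy, cache, p, pre, cfg, grads) {
  xa <- cache$xa
  V <- nrow(xa); F <- ncol(xa); N <- cfg$state_size
  # output map
  grads <- grad_add(grads, paste0(pre, "ssm.D"), colSums(gy * xa))
  gxa <- scale_cols_cpp(gy, p[[paste0(pre, "ssm.D")]])
  cb <- contract_bwd_cpp(gy, cache$hn, p[[paste0(pre, "ssm.C")]])
  ghn <- cb$ghn
  grads <- grad_add(grads, paste0(pre, "ssm.C"), cb$gC)
  lb <- layer_norm_bwd(ghn, cache$hl, p[[paste0(pre, "ssm.hln.g")]])
  grads <- grad_add(grads, paste0(pre, "ssm.hln.g"), lb$ggamma)
  grads <- grad_add(grads, paste0(pre, "ssm.hln.b"), lb$gbeta)
  # the scan's pair-coefficient matrix is symmetric, so its adjoint is the
  # same scan applied to the incoming gradient
  gm <- tree_scan_cpp(lb$gx, cache$order, cache$parent, cache$wpar)
  if (!is.null(cache$gate)) {
    colmap <- rep(seq_len(F), each = N)
    ggate <- gm * cache$m0
    gm <- gm * cache$gate
    gexp <- ggate * cache$gate
    Aflat <- as.vector(-exp(p[[paste0(pre, "ssm.a_log")]]))
    gDelta_gate_exp <- sweep(gexp, 2L, Aflat, "*")
    gDelta_gate <- matrix(0, V, F)
    for (f in seq_len(F))
      gDelta_gate[, f] <- rowSums(gDelta_gate_exp[, (f - 1L) * N + seq_len(N), drop = FALSE])
    gAflat <- colSums(gexp * cache$Delta[, colmap, drop = FALSE])
    # dA/da_log = A (A = -exp(a_log)); Aflat layout matches matrix(N, F)
    grads <- grad_add(grads, paste0(pre, "ssm.a_log"),
                      matrix(gAflat * Aflat, N, F))
  }
  sb2 <- source_bwd_cpp(gm, cache$u, p[[paste0(pre, "ssm.B")]])
  gu <- sb2$gu
  grads <- grad_add(grads, paste0(pre, "ssm.B"), sb2$gB)
  gDelta <- gu * xa
  if (!is.null(cache$gate)) gDelta <- gDelta + gDelta_gate
  gxa <- gxa + gu * cache$Delta
  gzpre <- gDelta * stats::plogis(cache$zpre)
  grads <- grad_add(grads, paste0(pre, "ssm.dw"), crossprod(xa, gzpre))
  grads <- grad_add(grads, paste0(pre, "ssm.db"), colSums(gzpre))
  gxa <- gxa + gzpre %*% t(p[[paste0(pre, "ssm.dw")]])
  list(gx = gxa, grads = grads)
}

# --- TreeMamba block -------------------------------------------------------

.block_fwd <- function(p, pre, x, H, W, cfg, training) {
  cache <- list()
  dp1 <- droppath_draw(cfg$drop_path, training)
  if (dp1 > 0) {
    la <- layer_norm_fwd(x, p[[paste0(pre, "ln_a.g")]], p[[paste0(pre, "ln_a.b")]])
    sm <- .ssm_fwd(p, pre, la$y, H, W, cfg, training)
    do1 <- dropout_fwd(sm$y, cfg$dropout, training)
    x <- x + dp1 * do1$y
    cache$la <- la; cache$ssm <- sm$cache; cache$do1 <- do1
  }
  cache$dp1 <- dp1
  dp2 <- droppath_draw(cfg$drop_path, training)
  if (dp2 > 0) {
    lb <- layer_norm_fwd(x, p[[paste0(pre, "ln_b.g")]], p[[paste0(pre, "ln_b.b")]])
    f1 <- linear_fwd(lb$y, p[[paste0(pre, "mlp.w1")]], p[[paste0(pre, "mlp.b1")]])
    g1 <- gelu_fwd(f1$y)
    f2 <- linear_fwd(g1$y, p[[paste0(pre, "mlp.w2")]], p[[paste0(pre, "mlp.b2")]])
    do2 <- dropout_fwd(f2$y, cfg$dropout, training)
    x <- x + dp2 * do2$y
    cache$lb <- lb; cache$f1 <- f1; cache$g1 <- g1; cache$f2 <- f2; cache$do2 <- do2
  }
  cache$dp2 <- dp2
  list(x = x, cache = cache)
}

.block_bwd <- function(gx, cache, p, pre, cfg, grads) {
  if (cache$dp2 > 0) {
    gb <- cache$dp2 * dropout_bwd(gx, cache$do2)
    l2 <- linear_bwd(gb, cache$f2, p[[paste0(pre, "mlp.w2")]])
    grads <- grad_add(grads, paste0(pre, "mlp.w2"), l2$gw)
    grads <- grad_add(grads, paste0(pre, "mlp.b2"), l2$gb)
    gg <- gelu_bwd(l2$gx, cache$g1)
    l1 <- linear_bwd(gg, cache$f1, p[[paste0(pre, "mlp.w1")]])
    grads <- grad_add(grads, paste0(pre, "mlp.w1"), l1$gw)
    grads <- grad_add(grads, paste0(pre, "mlp.b1"), l1$gb)
    nb <- layer_norm_bwd(l1$gx, cache$lb, p[[paste0(pre, "ln_b.g")]])
    grads <- grad_add(grads, paste0(pre, "ln_b.g"), nb$ggamma)
    grads <- grad_add(grads, paste0(pre, "ln_b.b"), nb$gbeta)
    gx <- gx + nb$gx
  }
  if (cache$dp1 > 0) {
    ga <- cache$dp1 * dropout_bwd(gx, cache$do1)
    sb <- .ssm_bwd(ga, cache$ssm, p, pre, cfg, grads)
    grads <- sb$grads
    na <- layer_norm_bwd(sb$gx, cache$la, p[[paste0(pre, "ln_a.g")]])
    grads <- grad_add(grads, paste0(pre, "ln_a.g"), na$ggamma)
    grads <- grad_add(grads, paste0(pre, "ln_a.b"), na$gbeta)
    gx <- gx + na$gx
  }
  list(gx = gx, grads = grads)
}

#' One TreeMamba block
#'
#' `x <- x + DropPath(Dropout(TreeSSM(LN(x))))` followed by
#' `x <- x + DropPath(Dropout(MLP(LN(x))))`; shape preserved.
#'
#' @param grid a [feature_grid()]
#' @param model a `treessm_model`
#' @param stage stage index (selects the block's parameters)
#' @param training logical; enables dropout/DropPath draws
#' @return a [feature_grid()] of the same shape
#' @export
tree_mamba_block <- function(grid, model, stage = 1L, training = FALSE) {
  if (!inherits(grid, "feature_grid")) grid <- feature_grid(grid)
  d <- dim(grid)
  res <- .block_fwd(model$params, sprintf("s%d.", stage), grid_as_matrix(grid),
                    d[1L], d[2L], model$config, training)
  matrix_as_grid(res$x, d[1L], d[2L])
}

# --- full per-frame backbone ----------------------------------------------

.frame_fwd <- function(p, cfg, img, training) {
  st <- .stem_fwd(p, img)
  x <- st$x; H <- st$H; W <- st$W
  stages <- vector("list", cfg$num_stages)
  for (s in seq_len(cfg$num_stages)) {
    pre <- sprintf("s%d.", s)
    down <- NULL
    if (s > 1L) {
      ain <- mat_to_arr(x, H, W)
      aout <- conv2d_fwd(ain, p[[paste0(pre, "down.w")]], p[[paste0(pre, "down.b")]], 2L, 0L)
      H <- dim(aout)[1L]; W <- dim(aout)[2L]
      dm <- arr_to_mat(aout)
      dl <- layer_norm_fwd(dm, p[[paste0(pre, "down_ln.g")]], p[[paste0(pre, "down_ln.b")]])
      x <- dl$y
      down <- list(ain = ain, dl = dl)
    }
    blk <- .block_fwd(p, pre, x, H, W, cfg, training)
    x <- blk$x
    stages[[s]] <- list(down = down, blk = blk$cache, H = H, W = W)
  }
  list(G = x, H = H, W = W, stem = st, stages = stages)
}

.frame_bwd <- function(gG, fw, p, cfg, grads) {
  gx <- gG
  for (s in rev(seq_len(cfg$num_stages))) {
    pre <- sprintf("s%d.", s)
    stg <- fw$stages[[s]]
    bb <- .block_bwd(gx, stg$blk, p, pre, cfg, grads)
    gx <- bb$gx; grads <- bb$grads
    if (s > 1L) {
      dn <- stg$down
      db <- layer_norm_bwd(gx, dn$dl, p[[paste0(pre, "down_ln.g")]])
      grads <- grad_add(grads, paste0(pre, "down_ln.g"), db$ggamma)
      grads <- grad_add(grads, paste0(pre, "down_ln.b"), db$gbeta)
      ga <- mat_to_arr(db$gx, stg$H, stg$W)
      cb <- conv2d_bwd(ga, dn$ain, p[[paste0(pre, "down.w")]], 2L, 0L)
      grads <- grad_add(grads, paste0(pre, "down.w"), cb$gw)
      grads <- grad_add(grads, paste0(pre, "down.b"), cb$gb)
      gx <- arr_to_mat(cb$gx)
    }
  }
  .stem_bwd(gx, fw$stem$cache, p, grads)
}

# --- video-level forward/backward -----------------------------------------

.video_fwd <- function(p, cfg, frames, training, keep_cache = FALSE) {
  T <- length(frames)
  if (T != cfg$sequence_length) stop("wrong sequence length")
  fws <- vector("list", T)
  Gs <- vector("list", T)
  for (t in seq_len(T)) {
    fw <- .frame_fwd(p, cfg, frames[[t]], training)
    Gs[[t]] <- fw$G
    fws[[t]] <- if (keep_cache) fw else NULL
  }
  V2 <- nrow(Gs[[1L]])
  ebar <- Reduce(`+`, lapply(Gs, colMeans)) / T
  feat <- ebar
  if (cfg$fusion == "tempdiff") {
    F2 <- length(ebar)
    dbar <- numeric(F2)
    if (T > 1L) {
      for (t in seq_len(T - 1L)) dbar <- dbar + colMeans(abs(Gs[[t + 1L]] - Gs[[t]]))
      dbar <- dbar / (T - 1L)
    }
    feat <- c(ebar, dbar)
  }
  logits <- as.numeric(feat %*% p[["head.w"]]) + p[["head.b"]]
  list(logits = logits, feat = feat, Gs = Gs, fws = fws, V2 = V2, T = T)
}

.video_bwd <- function(glogits, vc, p, cfg, grads) {
  grads <- grad_add(grads, "head.w", outer(vc$feat, glogits))
  grads <- grad_add(grads, "head.b", glogits)
  gfeat <- as.numeric(p[["head.w"]] %*% glogits)
  T <- vc$T; V2 <- vc$V2
  F2 <- ncol(vc$Gs[[1L]])
  gG <- vector("list", T)
  base <- matrix(gfeat[seq_len(F2)] / (T * V2), V2, F2, byrow = TRUE)
  for (t in seq_len(T)) gG[[t]] <- base
  if (cfg$fusion == "tempdiff" && T > 1L) {
    gdbar <- gfeat[F2 + seq_len(F2)] / ((T - 1L) * V2)
    for (t in seq_len(T - 1L)) {
      sgn <- sign(vc$Gs[[t + 1L]] - vc$Gs[[t]])
      contrib <- sweep(sgn, 2L, gdbar, "*")
      gG[[t + 1L]] <- gG[[t + 1L]] + contrib
      gG[[t]] <- gG[[t]] - contrib
    }
  }
  for (t in seq_len(T)) grads <- .frame_bwd(gG[[t]], vc$fws[[t]], p, cfg, grads)
  grads
}

#' Forward pass over one frame sequence
#'
#' Each frame passes through the stem and the hierarchical TreeMamba
#' stages, is globally average pooled, and the per-frame features are fused
#' over time (`config$fusion`); a linear head produces class logits. In
#' eval mode the pass is deterministic (no dropout/DropPath, BFS roots
#' fixed).
#'
#' @param model a `treessm_model`
#' @param frames list of `H x W x 3` arrays of length
#'   `config$sequence_length`
#' @param mode `"eval"` or `"train"`
#' @return numeric vector of `num_classes` logits
#' @export
model_forward <- function(model, frames, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  vc <- .video_fwd(model$params, model$config, frames, training = mode == "train")
  vc$logits
}

#' Predict class logits for a batch of videos
#' @param model a `treessm_model`
#' @param videos list of frame lists (each of length
#'   `config$sequence_length`)
#' @return `length(videos) x num_classes` logit matrix
#' @export
model_predict <- function(model, videos) {
  out <- t(vapply(videos, function(fr) model_forward(model, fr, "eval"),
                  numeric(model$config$num_classes)))
  out
}
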