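#' The fixed five-class behavior vocabulary
#'
#' Calf behavior classes: Eating, Standing, Walking, Lying, Diarrhea.
#' Walking and Standing share the same appearance and differ only in
#' temporal dynamics, so any model separating them must use temporal
#' information.
#' @export
BEHAVIOR_CLASSES <- c("Eating", "Standing", "Walking", "Lying", "Diarrhea")

#' Synthetic dataset configuration
#'
#' @param image_size square frame size in pixels
#' @param videos_per_class number of videos generated per class
#' @param frames_per_video frames per video (at a nominal 25 fps)
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (pixel values live in `[0, 1]`)
#' @param motion_amplitude Walking translation speed in pixels/frame
#' @param seed master seed; every video's content is a deterministic
#'   function of it
#' @export
synthetic_config <- function(image_size = 32L, videos_per_class = 50L,
                             frames_per_video = 40L, noise_sd = 0.02,
                             motion_amplitude = 0.35, seed = 0L) {
  stopifnot(image_size > 0, videos_per_class > 0, frames_per_video > 0,
            noise_sd >= 0, motion_amplitude >= 0)
  structure(list(image_size = as.integer(image_size),
                 videos_per_class = as.integer(videos_per_class),
                 frames_per_video = as.integer(frames_per_video),
                 noise_sd = noise_sd, motion_amplitude = motion_amplitude,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Frame sampling strategies
#'
#' Selects `length` frame indices (0-based) out of `total_frames`.
#' `"uniform"`: `floor(k * total_frames / length)` for `k = 0 .. length-1`.
#' `"random"`: drawn without replacement (with replacement only when
#' `total_frames < length`) and returned sorted ascending, so temporal
#' order is preserved.
#'
#' @param total_frames number of frames available
#' @param length number of indices to select
#' @param strategy `"uniform"` or `"random"`
#' @param seed optional seed for the random strategy; if `NULL` the current
#'   RNG stream is used (training draws fresh samples every epoch)
#' @return integer vector of 0-based, sorted, in-range frame indices
#' @export
sample_frames <- function(total_frames, length, strategy = c("uniform", "random"),
                          seed = NULL) {
  strategy <- match.arg(strategy)
  if (total_frames < 1L || length < 1L) stop("non-positive arguments")
  if (strategy == "uniform")
    return(as.integer(floor((seq_len(length) - 1L) * total_frames / length)))
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  idx <- if (total_frames >= length) sample.int(total_frames, length)
         else sample.int(total_frames, length, replace = TRUE)
  sort(idx - 1L)
}

soft_ellipse <- function(gx, gy, cx, cy, theta, a, b) {
  dx <- gx - cx; dy <- gy - cy
  xr <- (dx * cos(theta) + dy * sin(theta)) / a
  yr <- (-dx * sin(theta) + dy * cos(theta)) / b
  q <- xr^2 + yr^2
  pmin(1, pmax(0, (1.15 - q) / 0.3))
}

compose_layer <- function(img, mask, color) {
  for (c in 1:3) img[, , c] <- img[, , c] * (1 - mask) + color[c] * mask
  img
}

#' Generate one synthetic behavior video
#'
#' Renders a textured ellipse (the "calf") on a textured background with
#' class-specific dynamics:
#' * Lying - static, low aspect ratio;
#' * Standing - static, high aspect ratio;
#' * Walking - identical shape to Standing but translating at
#'   `motion_amplitude` px/frame along a random straight line kept inside
#'   the frame (with amplitude 0 and equal seeds, Walking and Standing are
#'   frame-wise identical: the two classes are separable only temporally);
#' * Eating - stationary, with a "head" blob at one end whose radius
#'   oscillates periodically;
#' * Diarrhea - stationary, with a trail of small dark particles emitted
#'   at the rear and drifting downward.
#'
#' All shared scene parameters are drawn in a fixed order so that videos of
#' different classes with the same seed share geometry; additive pixel
#' noise comes from a separate stream derived from the seed only. The
#' output is a deterministic function of `(class_label, config, seed)`.
#'
#' @param class_label one of [BEHAVIOR_CLASSES]
#' @param config a [synthetic_config()]
#' @param seed integer seed for this video
#' @return a `video_sample`: list with `frames` (list of `S x S x 3` arrays
#'   in `[0, 1]`), `label`, `fps` (25), `source_id`
#' @export
generate_synthetic_video <- function(class_label, config, seed = 0L) {
  if (!class_label %in% BEHAVIOR_CLASSES) stop("unknown label: ", class_label)
  S <- config$image_size
  T <- config$frames_per_video
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))

  # shared structure draws, identical order for every class
  set.seed(as.integer(seed))
  u_cx <- stats::runif(1); u_cy <- stats::runif(1)
  theta <- stats::runif(1, -pi / 6, pi / 6)
  jit <- stats::runif(2, 0.92, 1.08)
  tex_phase <- stats::runif(2, 0, 2 * pi)
  walk_dir <- stats::runif(1, 0, 2 * pi)
  eat_phase <- stats::runif(1, 0, 2 * pi)
  pjx <- stats::runif(64, -0.6, 0.6)

  a_std <- 0.18 * S * jit[1L]
  b_std <- 0.08 * S * jit[2L]
  # Lying exposes the body's broad side to the overhead camera: a wider,
  # larger-area silhouette; the upright classes share one slim shape
  if (class_label == "Lying") { a <- 0.16 * S * jit[1L]; b <- 0.14 * S * jit[2L] }
  else { a <- a_std; b <- b_std }
  margin <- a_std + 2
  amp <- if (class_label == "Walking") config$motion_amplitude else 0
  dxv <- amp * (T - 1) * cos(walk_dir)
  dyv <- amp * (T - 1) * sin(walk_dir)
  # clamp the straight-line path into the feasible box
  room_x <- max(S - 2 * margin - abs(dxv), 0.5)
  room_y <- max(S - 2 * margin - abs(dyv), 0.5)
  cx0 <- margin + max(0, -dxv) + u_cx * room_x
  cy0 <- margin + max(0, -dyv) + u_cy * room_y

  gx <- matrix(rep(seq_len(S), each = S), S, S)   # column coordinate
  gy <- matrix(rep(seq_len(S), times = S), S, S)  # row coordinate
  bg <- 0.42 + 0.05 * sin(2 * pi * (gx / S * 1.3 + tex_phase[1L])) +
        0.04 * sin(2 * pi * (gy / S * 0.9 + tex_phase[2L]))
  bgcol <- c(1.0, 1.05, 0.92)
  bodycol <- c(0.80, 0.62, 0.45)

  # noise stream depends on the seed only, never the class
  set.seed((as.integer(seed) + 104729L) %% 2147483647L)
  noise <- if (config$noise_sd > 0)
    stats::rnorm(S * S * 3 * T, sd = config$noise_sd) else NULL

  frames <- vector("list", T)
  for (t in seq_len(T)) {
    tt <- t - 1L
    cx <- cx0 + amp * tt * cos(walk_dir)
    cy <- cy0 + amp * tt * sin(walk_dir)
    img <- array(0, dim = c(S, S, 3))
    for (c in 1:3) img[, , c] <- bg * bgcol[c]
    body <- soft_ellipse(gx, gy, cx, cy, theta, a, b)
    # mild along-axis texture so feature similarity varies inside the body
    proj <- ((gx - cx) * cos(theta) + (gy - cy) * sin(theta)) / a
    shade <- 1 + 0.12 * sin(3 * proj + tex_phase[1L])
    for (c in 1:3) img[, , c] <- img[, , c] * (1 - body) + bodycol[c] * shade * body
    if (class_label == "Eating") {
      hc <- c(cx + 0.95 * a * cos(theta), cy + 0.95 * a * sin(theta))
      r <- 0.09 * S * (1 + 0.45 * sin(2 * pi * tt / 10 + eat_phase))
      head <- soft_ellipse(gx, gy, hc[1L], hc[2L], 0, r, r)
      img <- compose_layer(img, head, bodycol * 0.9)
    }
    if (class_label == "Diarrhea") {
      # diluted excreta: dark particles emitted at the rear that drift
      # downward and accumulate into a visible trail
      rear <- c(cx - 1.05 * a * cos(theta), cy - 1.05 * a * sin(theta))
      for (k in 0:floor((T - 1) / 2)) {
        birth <- 2L * k
        age <- tt - birth
        if (age < 0 || age > 20) next
        px <- rear[1L] + min(age, 12) * 0.45 * pjx[k %% 64 + 1L]
        py <- rear[2L] + min(age, 12) * 0.35
        r <- 0.065 * S
        part <- 0.9 * soft_ellipse(gx, gy, px, py, 0, r, r)
        img <- compose_layer(img, part, c(0.25, 0.15, 0.08))
      }
    }
    if (!is.null(noise)) {
      img <- img + array(noise[((t - 1) * S * S * 3 + 1):(t * S * S * 3)],
                         dim = c(S, S, 3))
    }
    frames[[t]] <- pmin(pmax(img, 0), 1)
  }
  structure(list(frames = frames, label = class_label, fps = 25,
                 source_id = sprintf("synthetic:%s:%d", class_label, seed)),
            class = "video_sample")
}

#' Build a stratified synthetic train/test dataset
#'
#' Generates `videos_per_class` videos for each of the five classes and
#' splits them 8:2 at the video level (stratified by class, no frame
#' leakage across the split), all driven by `config$seed`.
#'
#' @param config a [synthetic_config()] with `videos_per_class >= 5`
#' @return list with `train` and `test` (lists of `video_sample`s) and
#'   `config`
#' @export
make_dataset <- function(config) {
  if (config$videos_per_class < 5L) stop("videos_per_class must be >= 5")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  train <- list(); test <- list()
  n <- config$videos_per_class
  n_train <- round(0.8 * n)
  for (ci in seq_along(BEHAVIOR_CLASSES)) {
    cl <- BEHAVIOR_CLASSES[ci]
    vids <- lapply(seq_len(n), function(k)
      generate_synthetic_video(cl, config,
                               seed = (config$seed + ci * 100003L + k) %% 2147483647L))
    set.seed((config$seed + ci) %% 2147483647L)
    idx_train <- sort(sample.int(n, n_train))
    train <- c(train, vids[idx_train])
    test <- c(test, vids[-idx_train])
  }
  list(train = train, test = test, config = config)
}

# bilinear resize of an (H, W, C) array to out_h x out_w
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  if (d[1L] == out_h && d[2L] == out_w) return(img)
  ys <- (seq_len(out_h) - 0.5) * d[1L] / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * d[2L] / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), d[1L]); y1 <- pmin(y0 + 1, d[1L])
  x0 <- pmin(pmax(floor(xs), 1), d[2L]); x1 <- pmin(x0 + 1, d[2L])
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, d[3L]))
  for (c in seq_len(d[3L])) {
    p <- img[, , c]
    out[, , c] <- (1 - wy) %o% (1 - wx) * p[y0, x0] + (1 - wy) %o% wx * p[y0, x1] +
                  wy %o% (1 - wx) * p[y1, x0] + wy %o% wx * p[y1, x1]
  }
  out
}

#' Load a video's frames from disk
#'
#' Reads a directory of PNG (and, when the EBImage package is installed,
#' JPEG) frames in lexicographic name order, resizes each to
#' `input_size x input_size`, and scales pixel values to `[0, 1]`.
#'
#' @param path directory containing the frame images
#' @param label class label for the video
#' @param input_size target square size in pixels (default 224)
#' @return a `video_sample`
#' @export
load_video_frames <- function(path, label, input_size = 224L) {
  if (!dir.exists(path)) stop("no such frame directory: ", path)
  files <- sort(list.files(path, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no readable frames in: ", path)
  frames <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else if (requireNamespace("EBImage", quietly = TRUE)) {
      aperm(EBImage::imageData(EBImage::readImage(f)), c(2L, 1L, 3L))
    } else {
      stop("cannot read non-PNG frame (EBImage not installed): ", f)
    }
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
    if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
    resize_bilinear(img, input_size, input_size)
  })
  structure(list(frames = frames, label = label, fps = NA_real_,
                 source_id = path),
            class = "video_sample")
}

#' Read a `path,label` manifest CSV
#' @param path CSV file with header columns `path` and `label`
#' @return data frame with columns `path`, `label`
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df)))
    stop("manifest must have columns `path` and `label`")
  df
}

#' Export a dataset to a frame-directory layout with a manifest
#'
#' Writes each video as a directory of PNG frames plus a `manifest.csv`
#' (`path,label`) that [read_manifest()] / [load_video_frames()] can read
#' back.
#'
#' @param samples list of `video_sample`s
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
export_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    vs <- samples[[i]]
    vdir <- file.path(dir, sprintf("video_%04d", i))
    dir.create(vdir, showWarnings = FALSE)
    for (t in seq_along(vs$frames))
      png::writePNG(vs$frames[[t]], file.path(vdir, sprintf("frame_%04d.png", t)))
    data.frame(path = vdir, label = vs$label)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}
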