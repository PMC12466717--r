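#' Training configuration
#'
#' Defaults: Adam(0.9, 0.999), initial learning rate 0.001, weight decay
#' 0.05, step learning-rate decay by 0.1 at 60% and 85% of the total
#' epochs.
#'
#' @param batch_size videos per optimization step
#' @param learning_rate initial Adam learning rate
#' @param epochs training epochs
#' @param beta1,beta2 Adam moment decay rates
#' @param weight_decay decoupled weight decay applied to weight matrices
#'   (not biases, gains or state-space vectors)
#' @param lr_decay multiplicative step decay factor
#' @param lr_milestones epochs after which the decay applies; `NULL` means
#'   `ceiling(c(0.6, 0.85) * epochs)`
#' @param sampling frame sampling strategy during training (`"random"` or
#'   `"uniform"`); evaluation always samples uniformly so it is
#'   deterministic
#' @param grad_clip global L2-norm bound on each batch gradient
#'   (`Inf` disables); clipping prevents the occasional large-gradient
#'   step from which small-budget runs cannot recover
#' @param backbone_lr_mult learning-rate multiplier for all non-head
#'   parameters (discriminative fine-tuning); at small step budgets a
#'   value below 1 keeps full-size Adam steps on the whole backbone from
#'   wiping out the feature variance the head depends on
#' @param head_warmup_epochs during the first epochs only the classifier
#'   head is updated, the backbone staying frozen. At small step budgets
#'   this prevents a collapse mode in which backbone updates erase
#'   across-video feature variance (constant output is a loss saddle at
#'   `log K`) before the head has locked onto the class signal; once the
#'   head is informative, joint training moves away from the saddle.
#' @param seed master seed for shuffling, frame sampling and stochastic
#'   depth
#' @export
train_config <- function(batch_size = 32L, learning_rate = 0.001,
                         epochs = 30L, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 0.05, lr_decay = 0.1,
                         lr_milestones = NULL,
                         sampling = c("random", "uniform"),
                         head_warmup_epochs = 0L, backbone_lr_mult = 1,
                         grad_clip = Inf, seed = 0L) {
  sampling <- match.arg(sampling)
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1,
            weight_decay >= 0, lr_decay > 0)
  if (is.null(lr_milestones)) lr_milestones <- ceiling(c(0.6, 0.85) * epochs)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
                 lr_decay = lr_decay, lr_milestones = as.integer(lr_milestones),
                 sampling = sampling,
                 head_warmup_epochs = as.integer(head_warmup_epochs),
                 backbone_lr_mult = backbone_lr_mult, grad_clip = grad_clip,
                 seed = as.integer(seed)),
            class = "train_config")
}

label_index <- function(label) match(label, BEHAVIOR_CLASSES) - 1L

select_frames <- function(sample, seq_len, strategy, seed = NULL) {
  idx <- sample_frames(length(sample$frames), seq_len, strategy, seed)
  sample$frames[idx + 1L]
}

is_decayed_param <- function(name) {
  grepl("\\.(w|w1|w2|dw)$", name)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, tc) {
  state$t <- state$t + 1L
  b1 <- tc$beta1; b2 <- tc$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + 1e-8)
    if (tc$weight_decay > 0 && is_decayed_param(nm))
      upd <- upd + tc$weight_decay * params[[nm]]
    lr_nm <- if (grepl("^head\\.", nm)) lr else lr * tc$backbone_lr_mult
    params[[nm]] <- params[[nm]] - lr_nm * upd
  }
  list(params = params, state = state)
}

#' Evaluate a model on a set of videos
#'
#' Frames are sampled with the uniform strategy (deterministic) and the
#' model runs in eval mode, so repeated calls give identical results.
#'
#' @param model a `treessm_model`
#' @param samples list of `video_sample`s
#' @return a `metrics_report` with additional fields `loss`, `predictions`
#'   and `labels` (0-based class indices)
#' @export
evaluate <- function(model, samples) {
  cfg <- model$config
  K <- cfg$num_classes
  n <- length(samples)
  probs <- matrix(0, n, K)
  labels <- integer(n)
  for (i in seq_len(n)) {
    fr <- select_frames(samples[[i]], cfg$sequence_length, "uniform")
    logits <- model_forward(model, fr, "eval")
    probs[i, ] <- softmax_rows(matrix(logits, 1L))
    labels[i] <- label_index(samples[[i]]$label)
  }
  preds <- max.col(probs, ties.method = "first") - 1L
  rep <- compute_metrics(confusion_matrix(preds, labels, K))
  rep$loss <- cross_entropy(probs, labels)
  rep$predictions <- preds
  rep$labels <- labels
  rep
}

#' Train a TreeSSM behavior-recognition model
#'
#' Mini-batch Adam with decoupled weight decay and step learning-rate
#' decay; the loss is mean cross-entropy over the batch. Fully
#' deterministic for a fixed seed on a single thread. After each epoch the
#' model is evaluated on `dataset$test`; the per-epoch log (train loss,
#' test loss, test accuracy) is returned and optionally written as CSV
#' together with the best-accuracy checkpoint.
#'
#' @param model a `treessm_model` from [model_init()], or a
#'   [model_config()] (a fresh model is initialized from it)
#' @param dataset list with `train` and `test` lists of `video_sample`s
#' @param tc a [train_config()]
#' @param out_dir optional directory for `log.csv` and `best.ckpt`
#' @param verbose print one line per epoch
#' @return list with `model` (final weights), `best_model`
#'   (best-test-accuracy weights), `log` (data frame), `best_accuracy`
#' @export
train <- function(model, dataset, tc = train_config(), out_dir = NULL,
                  verbose = FALSE) {
  if (inherits(model, "model_config")) model <- model_init(model)
  cfg <- model$config
  if (length(dataset$train) == 0L) stop("empty training set")
  params <- model$params
  opt <- adam_init(params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    test_loss = numeric(0), test_accuracy = numeric(0))
  best_acc <- -Inf; best_params <- params
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ntr <- length(dataset$train)
  K <- cfg$num_classes
  train_labels <- vapply(dataset$train, function(v) v$label, character(1))
  for (epoch in seq_len(tc$epochs)) {
    lr <- tc$learning_rate * tc$lr_decay^sum(epoch > tc$lr_milestones)
    set.seed((tc$seed + epoch * 1009L) %% 2147483647L)
    # class-stratified order: shuffle within class, then round-robin over
    # classes, so every mini-batch is (nearly) class-balanced.  All feature
    # vectors share a large common component, and unbalanced batches turn it
    # into gradient noise proportional to the batch's class imbalance.
    by_class <- lapply(split(seq_len(ntr), train_labels), sample)
    ord <- integer(0)
    for (k in seq_len(max(lengths(by_class)))) {
      for (ci in seq_along(by_class)) {
        if (k <= length(by_class[[ci]])) ord <- c(ord, by_class[[ci]][k])
      }
    }
    epoch_loss <- 0; nb <- 0L
    for (start in seq(1L, ntr, by = tc$batch_size)) {
      batch <- ord[start:min(start + tc$batch_size - 1L, ntr)]
      grads <- list()
      bloss <- 0
      for (vi in batch) {
        vs <- dataset$train[[vi]]
        fr <- select_frames(vs, cfg$sequence_length, tc$sampling)
        vc <- .video_fwd(params, cfg, fr, training = TRUE, keep_cache = TRUE)
        pr <- softmax_rows(matrix(vc$logits, 1L))
        y <- label_index(vs$label)
        bloss <- bloss - log(max(pr[1L, y + 1L], 1e-12))
        gl <- as.numeric(pr)
        gl[y + 1L] <- gl[y + 1L] - 1
        grads <- .video_bwd(gl / length(batch), vc, params, cfg, grads)
      }
      bloss <- bloss / length(batch)
      if (!is.finite(bloss))
        stop(sprintf("training diverged: non-finite loss at epoch %d", epoch))
      if (epoch <= tc$head_warmup_epochs)
        grads <- grads[grepl("^head\\.", names(grads))]
      if (is.finite(tc$grad_clip)) {
        gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gnorm > tc$grad_clip)
          grads <- lapply(grads, function(g) g * (tc$grad_clip / gnorm))
      }
      st <- adam_step(params, grads, opt, lr, tc)
      params <- st$params; opt <- st$state
      epoch_loss <- epoch_loss + bloss; nb <- nb + 1L
    }
    model$params <- params
    ev <- evaluate(model, dataset$test)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = epoch_loss / nb,
                                 test_loss = ev$loss, test_accuracy = ev$accuracy))
    if (ev$accuracy > best_acc) {
      best_acc <- ev$accuracy
      best_params <- params
      if (!is.null(out_dir)) {
        bm <- model; bm$params <- best_params
        save_checkpoint(bm, file.path(out_dir, "best.ckpt"),
                        meta = list(epoch = epoch, test_accuracy = best_acc))
      }
    }
    if (!is.null(out_dir))
      utils::write.csv(log, file.path(out_dir, "log.csv"), row.names = FALSE)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train loss %.4f  test loss %.4f  test acc %.2f%%",
                      epoch, lr, epoch_loss / nb, ev$loss, ev$accuracy))
  }
  best_model <- model; best_model$params <- best_params
  list(model = model, best_model = best_model, log = log,
       best_accuracy = best_acc)
}

CHECKPOINT_VERSION <- "treessm-ckpt-1"

#' Save / load model checkpoints
#'
#' A checkpoint is a single file holding the weights plus a JSON metadata
#' block (format version, model configuration, and any extra metadata);
#' the loader refuses mismatched format versions.
#'
#' @param model a `treessm_model`
#' @param path file path
#' @param meta optional named list stored in the metadata block
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  meta_json <- jsonlite::toJSON(c(list(version = CHECKPOINT_VERSION,
                                       config = unclass(model$config)), meta),
                                auto_unbox = TRUE, digits = NA)
  saveRDS(list(version = CHECKPOINT_VERSION, meta_json = as.character(meta_json),
               config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("checkpoint version mismatch: ", obj$version)
  structure(list(config = obj$config, params = obj$params),
            class = "treessm_model")
}

#' Accuracy on a subset of classes
#'
#' Restricts an evaluation to samples whose true class is in `classes` and
#' returns the percentage predicted correctly — used e.g. to probe the
#' Walking-vs-Standing pair, which is separable only through temporal
#' information.
#'
#' @param report result of [evaluate()]
#' @param classes character vector of class names
#' @return percentage accuracy on the subset
#' @export
pair_accuracy <- function(report, classes) {
  idx <- label_index(classes)
  sel <- report$labels %in% idx
  if (!any(sel)) stop("no samples of the requested classes")
  100 * mean(report$predictions[sel] == report$labels[sel])
}
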