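# Training / inference / evaluation orchestration.
#
# Training follows the reference protocol: SGD with momentum 0.9, learning
# rate 0.0025 and weight decay 1e-4, batch size 2, batch normalization
# active, validation after every epoch, best checkpoint kept by validation
# mAP. All randomness flows from the config seed.

#' Build a training configuration
#'
#' Defaults mirror the reference protocol (SGD, lr 0.0025, weight decay
#' 1e-4, momentum 0.9, batch 2, 200 epochs, constant learning rate).
#'
#' @param image_size input image side in px.
#' @param learning_rate,weight_decay,momentum SGD hyperparameters.
#' @param batch_size mini-batch size (drop-last batching).
#' @param epochs training epochs (>= 1).
#' @param seed master seed for weights, shuffling and any augmentation.
#' @param backbone list: `width`, `blocks` (length 4), `deformable_stages`.
#' @param fpn_channels pyramid width.
#' @param bfp_level 1-based index of the intermediate (balanced) level
#'   among Q2..Q5; the default 3 is Q4.
#' @param grid a [grid_spec()].
#' @param head list: `channels`, `n_convs`, `cate_level` (pyramid index fed
#'   to the category branch), `cate_prior`.
#' @param loss list: `gamma` (mask weight), `alpha`, `gamma_f` (focal).
#' @param decode list: `score_thresh`, `mask_bin_thresh`, `nms_iou`,
#'   `max_keep`.
#' @return a `nucseg_config` list.
#' @export
nucseg_config <- function(image_size = 250L,
                          learning_rate = 0.0025, weight_decay = 1e-4,
                          momentum = 0.9, batch_size = 2L, epochs = 200L,
                          seed = 1L,
                          backbone = list(width = 64L, blocks = c(3L, 4L, 6L, 3L),
                                          deformable_stages = c("stage3", "stage4", "stage5")),
                          fpn_channels = 256L,
                          bfp_level = 3L,
                          grid = grid_spec(S = 24L, C = 1L),
                          head = list(channels = 64L, n_convs = 2L,
                                      cate_level = 2L, cate_prior = 0.01),
                          loss = list(gamma = 3, alpha = 0.25, gamma_f = 2),
                          decode = list(score_thresh = 0.1, mask_bin_thresh = 0.5,
                                        nms_iou = 0.5, max_keep = 100L)) {
  assert_that(learning_rate > 0 && weight_decay >= 0 && momentum >= 0,
              "hyperparameters must be positive")
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  cfg <- list(image_size = as.integer(image_size),
              learning_rate = learning_rate, weight_decay = weight_decay,
              momentum = momentum, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed),
              backbone = backbone, fpn_channels = as.integer(fpn_channels),
              bfp_level = as.integer(bfp_level), grid = grid, head = head,
              loss = loss, decode = decode)
  class(cfg) <- "nucseg_config"
  cfg
}

#' Small-footprint configuration for CPU-scale experiments
#'
#' 128x128 inputs, a narrow one-block-per-stage backbone, a small pyramid
#' and a single 6x6 grid: the same network end to end, scaled to run on one
#' CPU core in minutes. At this parameter count (~10^5 weights) the
#' full-scale learning rate is far below the stable-and-fast regime, so the
#' profile raises it to 0.02; all other protocol constants (momentum,
#' weight decay, batch size, loss weights) keep the reference values.
#'
#' @param epochs epochs (default 8; smoke-training runs use more).
#' @param seed master seed.
#' @param learning_rate profile learning rate (default 0.02).
#' @param ... overrides forwarded to [nucseg_config()].
#' @return a `nucseg_config`.
#' @export
desk_config <- function(epochs = 8L, seed = 1L, learning_rate = 0.02, ...) {
  nucseg_config(
    image_size = 128L, epochs = epochs, seed = seed,
    learning_rate = learning_rate,
    backbone = list(width = 8L, blocks = c(1L, 1L, 1L, 1L),
                    deformable_stages = c("stage3", "stage4", "stage5")),
    fpn_channels = 16L,
    grid = grid_spec(S = 6L, C = 1L),
    head = list(channels = 16L, n_convs = 1L, cate_level = 2L,
                cate_prior = 0.01),
    ...)
}

# SGD with momentum and decoupled-from-nothing weight decay (classic
# L2-in-gradient form): v <- mu v + g + wd p;  p <- p - lr v.
sgd_step <- function(params, lr, momentum, weight_decay) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$value
    p$velocity <- if (is.null(p$velocity)) g else momentum * p$velocity + g
    p$value <- p$value - lr * p$velocity
  }
  invisible(NULL)
}

#' Train the segmentation network on a set of patches
#'
#' @param patches list of `synthetic_scene` patches (training images with
#'   ground-truth labels).
#' @param config a [nucseg_config()].
#' @param val_patches optional validation patches; evaluated after every
#'   epoch, and the parameter state with the best validation mAP is
#'   restored into the returned model.
#' @param log_path optional JSONL file receiving one record per iteration.
#' @param model optional pre-built model (to continue training).
#' @return `train_state`: list with `model`, `losses` (per iteration),
#'   `epoch_losses`, `iterations`, `best_val_mAP`, `val_mAP` (per epoch).
#' @export
train_model <- function(patches, config, val_patches = NULL, log_path = NULL,
                        model = NULL) {
  assert_that(length(patches) >= 1, "training split is empty")
  for (p in patches)
    assert_that(inherits(p, "synthetic_scene"), "patches must be synthetic_scene objects")
  model <- model %||% nucseg_model(config)
  xs <- lapply(patches, scene_tensor)
  targets <- lapply(patches, function(p)
    assign_targets(scene_instances(p), config$grid,
                   c(p$height, p$width)))
  n <- length(patches)
  bs <- config$batch_size
  iters_per_epoch <- n %/% bs
  assert_that(iters_per_epoch >= 1,
              "batch_size exceeds the number of training patches")
  losses <- numeric(0)
  epoch_losses <- numeric(0)
  val_map <- numeric(0)
  best <- list(mAP = -Inf, values = NULL)
  if (!is.null(log_path)) {
    dir.create(dirname(log_path), showWarnings = FALSE, recursive = TRUE)
    con <- file(log_path, open = "wt")
    on.exit(close(con), add = TRUE)
  }
  iter <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + epoch, sample(n))
    ep_loss <- 0
    for (b in seq_len(iters_per_epoch)) {
      idx <- ord[((b - 1) * bs + 1):(b * bs)]
      xb <- do.call(abind4, xs[idx])
      outs <- model$forward(xb, training = TRUE)
      lb <- ag_batch_loss(outs, targets[idx],
                          gamma = config$loss$gamma,
                          alpha = config$loss$alpha,
                          gamma_f = config$loss$gamma_f)
      ag_zero_grad(model$params)
      ag_backward(lb$total)
      sgd_step(model$params, config$learning_rate, config$momentum,
               config$weight_decay)
      iter <- iter + 1L
      losses <- c(losses, lb$total$value)
      ep_loss <- ep_loss + lb$total$value
      if (!is.null(log_path))
        writeLines(jsonlite::toJSON(
          list(epoch = epoch, iteration = iter, loss = lb$total$value,
               category = lb$category_term, mask = lb$mask_term),
          auto_unbox = TRUE), con)
    }
    epoch_losses <- c(epoch_losses, ep_loss / iters_per_epoch)
    if (!is.null(val_patches) && length(val_patches)) {
      preds <- predict_patches(model, val_patches)
      gts <- lapply(val_patches, scene_instances)
      s <- summarize_eval(preds, gts)
      val_map <- c(val_map, s$mAP)
      if (s$mAP > best$mAP)
        best <- list(mAP = s$mAP, values = lapply(model$params, `[[`, "value"))
    }
  }
  if (!is.null(best$values))
    for (i in seq_along(model$params)) model$params[[i]]$value <- best$values[[i]]
  structure(list(model = model, losses = losses, epoch_losses = epoch_losses,
                 iterations = iter, val_mAP = val_map,
                 best_val_mAP = if (is.finite(best$mAP)) best$mAP else NA_real_,
                 config = config),
            class = "train_state")
}

# bind (1,C,H,W) tensors along the batch dimension
abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(0, dim = c(length(xs), d[2], d[3], d[4]))
  for (i in seq_along(xs)) out[i, , , ] <- xs[[i]][1, , , ]
  out
}

#' Expected iteration count of a training run
#'
#' Drop-last batching: `epochs * floor(n_train / batch_size)`.
#'
#' @param n_train training patches.
#' @param batch_size batch size.
#' @param epochs epochs.
#' @return integer iteration count.
#' @export
iteration_count <- function(n_train, batch_size, epochs)
  as.integer(epochs * (n_train %/% batch_size))

#' Run inference on patches
#'
#' Forward pass in inference mode (batch-norm running statistics), then
#' per-image decoding and mask NMS, merging grid levels when several are
#' configured. Deterministic: no RNG is consumed.
#'
#' @param model a trained model (from [train_model()] or [nucseg_model()]).
#' @param patches list of `synthetic_scene` patches (or (1,3,H,W) arrays).
#' @return list of [instance_set()] predictions, one per input.
#' @export
predict_patches <- function(model, patches) {
  dec <- model$config$decode
  lapply(patches, function(p) {
    x <- if (is.array(p)) p else scene_tensor(p)
    outs <- model$forward(x, training = FALSE)
    per_level <- lapply(outs, function(o) {
      S <- dim(o$cate$value)[3]
      C <- dim(o$cate$value)[2]
      cate <- array(aperm(o$cate$value[1, , , , drop = FALSE], c(1, 3, 4, 2)),
                    dim = c(S, S, C))
      mask <- aperm(o$mask$value[1, , , , drop = FALSE], c(1, 3, 4, 2))
      mask <- array(mask, dim = dim(mask)[2:4])
      decode_instances(cate, mask, dec$score_thresh, dec$mask_bin_thresh)
    })
    merged <- instance_set(
      do.call(c, lapply(per_level, `[[`, "masks")),
      unlist(lapply(per_level, `[[`, "scores")),
      unlist(lapply(per_level, `[[`, "categories")))
    mask_nms(merged, dec$nms_iou, dec$max_keep)
  })
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the parameter values,
#' batch-norm running statistics and the config snapshot.
#'
#' @param model model environment.
#' @param path checkpoint path.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  bns <- collect_bn_states(model)
  obj <- list(values = lapply(model$params, `[[`, "value"),
              bn = bns, config = model$config)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- nucseg_model(obj$config)
  assert_that(length(model$params) == length(obj$values),
              "checkpoint is incompatible with its config snapshot")
  for (i in seq_along(model$params)) {
    assert_that(identical(dim(model$params[[i]]$value) %||% length(model$params[[i]]$value),
                          dim(obj$values[[i]]) %||% length(obj$values[[i]])),
                sprintf("checkpoint parameter %d has mismatched shape", i))
    model$params[[i]]$value <- obj$values[[i]]
  }
  restore_bn_states(model, obj$bn)
  model
}

collect_bn_states <- function(model) {
  out <- list()
  walk <- function(v) {
    if (is.environment(v)) {
      if (!is.null(v$running_mean))
        out[[length(out) + 1L]] <<- list(mean = v$running_mean, var = v$running_var)
      return()
    }
    if (is.list(v)) for (el in v) walk(el)
  }
  walk(list(model$backbone, model$fpn, model$nonlocal, model$head))
  out
}

restore_bn_states <- function(model, states) {
  i <- 0L
  walk <- function(v) {
    if (is.environment(v)) {
      if (!is.null(v$running_mean)) {
        i <<- i + 1L
        v$running_mean <- states[[i]]$mean
        v$running_var <- states[[i]]$var
      }
      return()
    }
    if (is.list(v)) for (el in v) walk(el)
  }
  walk(list(model$backbone, model$fpn, model$nonlocal, model$head))
  invisible(NULL)
}

#' Evaluate result and ground-truth annotation files
#'
#' Thin wrapper over [summarize_eval()] for COCO-dialect files on disk.
#'
#' @param results_path predictions JSON (from [write_results()]).
#' @param gt_path ground-truth JSON (from [write_annotations()]).
#' @return an `eval_summary`.
#' @export
evaluate_files <- function(results_path, gt_path) {
  gts <- read_annotations(gt_path)
  preds <- read_results(results_path, names(gts))
  summarize_eval(preds, gts)
}
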