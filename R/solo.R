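# Location-based one-stage mask prediction: the image is divided into an
# S x S grid; the cell (i, j) containing an instance's center predicts its
# category, and channel k = i*S + j of the mask bank predicts its mask.
# Training combines a focal loss on the category grid with a dice loss on
# the positive mask channels: L = L_focal + gamma * L_m, with
# L_m = (1/N) sum over positive cells of L_dice.

#' Instance set container
#'
#' A collection of per-instance binary masks with scores and category
#' labels on one image; used for both ground truth and predictions.
#'
#' @param masks list of H x W binary (0/1) matrices.
#' @param scores numeric confidences in `[0, 1]` (ground truth may use 1).
#' @param categories integer labels (single-category default 1).
#' @return object of class `instance_set`.
#' @export
instance_set <- function(masks, scores = rep(1, length(masks)),
                         categories = rep(1L, length(masks))) {
  assert_that(length(masks) == length(scores) && length(masks) == length(categories),
              "masks, scores and categories must have equal length")
  structure(list(masks = masks, scores = as.numeric(scores),
                 categories = as.integer(categories)),
            class = "instance_set")
}

#' @export
length.instance_set <- function(x) length(x$masks)

#' @export
print.instance_set <- function(x, ...) {
  cat("<instance_set of", length(x$masks), "instances>\n")
  invisible(x)
}

#' Grid specification for the location-based head
#'
#' @param S integer vector of grid sides, one per grid level (a single
#'   value gives the single-grid reference configuration).
#' @param C number of categories (default 1: "nucleus").
#' @param scale_ranges numeric matrix with columns `min`, `max` and one row
#'   per level: an instance belongs to the level whose range contains
#'   sqrt(mask area). Default: a single unbounded range for one level.
#' @param center_fraction optional fraction of the instance bounding box
#'   treated as its center region (0 = literal center-point assignment,
#'   the default).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(S = 24L, C = 1L, scale_ranges = NULL,
                      center_fraction = 0) {
  assert_that(all(S >= 1), "S must be >= 1")
  assert_that(C >= 1, "C must be >= 1")
  if (is.null(scale_ranges)) {
    scale_ranges <- cbind(min = rep(0, length(S)), max = rep(Inf, length(S)))
    if (length(S) > 1) {
      # geometric ladder: finer grids own smaller instances
      edges <- 2^seq(3, 3 + length(S) - 1)
      scale_ranges <- cbind(min = c(0, edges[-length(edges)]),
                            max = c(edges[-length(edges)], Inf))
    }
  }
  assert_that(nrow(scale_ranges) == length(S),
              "scale_ranges must have one row per grid level")
  structure(list(S = as.integer(S), C = as.integer(C),
                 scale_ranges = scale_ranges,
                 center_fraction = center_fraction),
            class = "grid_spec")
}

# center of mass of a binary mask, 0-based pixel-centered (cy, cx)
mask_centroid <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  c(mean(w[, 1]) - 1, mean(w[, 2]) - 1)
}

#' Encode ground-truth instances onto the S x S grid
#'
#' Each instance's center of mass selects the cell (i, j) responsible for
#' it; the category grid is set at (i, j) and mask channel k = i*S + j
#' carries the instance's full-resolution binary mask. If two instances
#' land in one cell the larger one wins (ties broken by instance index).
#' With multiple grid levels, sqrt(mask area) decides which level owns the
#' instance.
#'
#' @param instances an [instance_set()] of ground truth masks.
#' @param spec a [grid_spec()].
#' @param image_size c(H, W).
#' @return for a single-level spec, a `grid_target`: list with `category`
#'   (S x S x C array), `positive` (0-based channel indices k),
#'   `masks` (list keyed by as.character(k)), `cells` (data.frame i, j, k,
#'   instance). For multi-level specs, a list of `grid_target`s.
#' @export
assign_targets <- function(instances, spec, image_size) {
  H <- image_size[1]; W <- image_size[2]
  n <- length(instances$masks)
  areas <- vapply(instances$masks, function(m) sum(m != 0), numeric(1))
  scales <- sqrt(areas)
  per_level <- lapply(seq_along(spec$S), function(li) {
    S <- spec$S[li]
    rng <- spec$scale_ranges[li, ]
    own <- which(scales >= rng[1] & scales < rng[2] & areas > 0)
    category <- array(0, dim = c(S, S, spec$C))
    cell_owner <- list()  # key "i,j" -> instance index
    for (ins in own) {
      ctr <- mask_centroid(instances$masks[[ins]])
      cells <- centre_cells(ctr, instances$masks[[ins]], S, H, W,
                            spec$center_fraction)
      for (r in seq_len(nrow(cells))) {
        key <- paste(cells[r, 1], cells[r, 2], sep = ",")
        prev <- cell_owner[[key]]
        if (is.null(prev) || areas[ins] > areas[prev]) cell_owner[[key]] <- ins
      }
    }
    ks <- integer(0); masks <- list()
    cells_df <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                           instance = integer(0))
    for (key in names(cell_owner)) {
      ij <- as.integer(strsplit(key, ",")[[1]])
      k <- ij[1] * S + ij[2]
      ins <- cell_owner[[key]]
      category[ij[1] + 1, ij[2] + 1, instances$categories[ins]] <- 1
      ks <- c(ks, k)
      masks[[as.character(k)]] <- instances$masks[[ins]]
      cells_df <- rbind(cells_df,
                        data.frame(i = ij[1], j = ij[2], k = k, instance = ins))
    }
    ord <- order(ks)
    structure(list(category = category, positive = ks[ord],
                   masks = masks[as.character(ks[ord])],
                   cells = cells_df[ord, , drop = FALSE],
                   S = S, C = spec$C, image_size = image_size),
              class = "grid_target")
  })
  if (length(spec$S) == 1) per_level[[1]] else per_level
}

# cells covered by the instance's center region; a fraction of 0 gives the
# single cell containing the center of mass
centre_cells <- function(ctr, mask, S, H, W, fraction) {
  cell_i <- function(y) min(S - 1L, max(0L, floor(y / H * S)))
  cell_j <- function(x) min(S - 1L, max(0L, floor(x / W * S)))
  if (fraction <= 0)
    return(cbind(i = cell_i(ctr[1]), j = cell_j(ctr[2])))
  w <- which(mask != 0, arr.ind = TRUE)
  hh <- (max(w[, 1]) - min(w[, 1]) + 1) * fraction / 2
  ww <- (max(w[, 2]) - min(w[, 2]) + 1) * fraction / 2
  i0 <- cell_i(ctr[1] - hh); i1 <- cell_i(ctr[1] + hh)
  j0 <- cell_j(ctr[2] - ww); j1 <- cell_j(ctr[2] + ww)
  as.matrix(expand.grid(i = i0:i1, j = j0:j1))
}

# ---------------------------------------------------------------- losses ---

#' Focal loss over a category grid
#'
#' Per-cell focal term -alpha_t (1 - p_t)^gamma_f log(p_t), summed over the
#' grid and normalized by the number of positive cells (by 1 when there are
#' none).
#'
#' @param pred numeric array of predicted scores in (0, 1), same shape as
#'   `target`.
#' @param target binary array of ground-truth labels.
#' @param alpha positive-class balance weight (default 0.25).
#' @param gamma_f focusing exponent (default 2).
#' @return scalar loss (>= 0).
#' @export
focal_loss <- function(pred, target, alpha = 0.25, gamma_f = 2) {
  assert_that(all(pred > 0 & pred < 1), "pred scores must lie in (0, 1)")
  assert_that(identical(dim(pred) %||% length(pred),
                        dim(target) %||% length(target)),
              "pred and target shapes differ")
  npos <- sum(target != 0)
  pos <- -alpha * (1 - pred)^gamma_f * log(pred)
  neg <- -(1 - alpha) * pred^gamma_f * log(1 - pred)
  sum(ifelse(target != 0, pos, neg)) / max(1, npos)
}

#' Dice loss between a soft predicted mask and a binary ground truth
#'
#' 1 - 2 sum(p q) / (sum(p^2) + sum(q^2)); 0 for identical binary masks,
#' 1 for disjoint non-empty masks.
#'
#' @param pred_mask numeric array in `[0, 1]`.
#' @param gt_mask binary array of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred_mask, gt_mask) {
  assert_that(identical(dim(pred_mask) %||% length(pred_mask),
                        dim(gt_mask) %||% length(gt_mask)),
              "pred and ground-truth mask shapes differ")
  denom <- sum(pred_mask^2) + sum(gt_mask^2)
  if (denom == 0) return(0)
  1 - 2 * sum(pred_mask * gt_mask) / denom
}

#' Combined training loss of the grid head
#'
#' total = L_focal + gamma * L_m where L_m averages the dice loss over the
#' N positive mask channels (0 when N = 0).
#'
#' @param cate_pred S x S x C array of category scores in (0, 1).
#' @param mask_pred H x W x S^2 array of soft masks.
#' @param target a `grid_target` from [assign_targets()].
#' @param gamma mask-loss weight (default 3).
#' @param alpha,gamma_f focal-loss parameters.
#' @return a `loss_report` list: total, category_term, mask_term, gamma, n_pos.
#' @export
total_loss <- function(cate_pred, mask_pred, target, gamma = 3,
                       alpha = 0.25, gamma_f = 2) {
  cat_term <- focal_loss(cate_pred, target$category, alpha, gamma_f)
  n <- length(target$positive)
  mask_term <- if (n == 0) 0 else
    mean(vapply(seq_along(target$positive), function(idx) {
      k <- target$positive[idx]
      dice_loss(mask_pred[, , k + 1L], target$masks[[as.character(k)]])
    }, numeric(1)))
  structure(list(total = cat_term + gamma * mask_term,
                 category_term = cat_term, mask_term = mask_term,
                 gamma = gamma, n_pos = n),
            class = "loss_report")
}

# Autodiff version used in training: same arithmetic on ag nodes.
ag_dice <- function(p, q, eps = 1e-8) {
  pv <- p$value
  inter <- sum(pv * q)
  denom <- sum(pv^2) + sum(q^2) + eps
  new_ag(1 - 2 * inter / denom, list(p), function(g)
    list(g * (-2) * (q * denom - 2 * inter * pv) / denom^2))
}

# Mean dice over all positive channels of a batched mask bank, fused into
# one node so the backward pass fills a single gradient array. `items` is a
# list of (n, k0, mask) with k0 the 0-based channel.
ag_dice_bank <- function(mask_node, items, eps = 1e-8) {
  v <- mask_node$value
  m <- length(items)
  stats <- lapply(items, function(it) {
    pv <- v[it$n, it$k0 + 1L, , ]
    q <- it$mask
    list(inter = sum(pv * q), denom = sum(pv^2) + sum(q) + eps)
  })
  val <- mean(vapply(stats, function(s) 1 - 2 * s$inter / s$denom, numeric(1)))
  new_ag(val, list(mask_node), function(g) {
    gx <- array(0, dim = dim(v))
    for (i in seq_len(m)) {
      it <- items[[i]]; s <- stats[[i]]
      pv <- v[it$n, it$k0 + 1L, , ]
      gx[it$n, it$k0 + 1L, , ] <- gx[it$n, it$k0 + 1L, , ] +
        (g / m) * (-2) * (it$mask * s$denom - 2 * s$inter * pv) / s$denom^2
    }
    list(gx)
  })
}

ag_focal <- function(p, target, alpha = 0.25, gamma_f = 2, eps = 1e-7) {
  npos <- sum(target != 0)
  pc <- ag_clamp(p, eps, 1 - eps)
  pos_w <- (target != 0) * alpha
  neg_w <- (target == 0) * (1 - alpha)
  t1 <- ag_mul(ag_mul(ag_const(pos_w), ag_pow_const(ag_sub(1, pc), gamma_f)),
               ag_log(pc))
  t2 <- ag_mul(ag_mul(ag_const(neg_w), ag_pow_const(pc, gamma_f)),
               ag_log(ag_sub(1, pc)))
  ag_scale(ag_add(ag_sum(t1), ag_sum(t2)), -1 / max(1, npos))
}

# Training loss for one batch over (possibly several) grid levels.
# `outs` is the model forward output; `targets` a list (per image) of
# per-level grid_targets.
ag_batch_loss <- function(outs, targets, gamma = 3, alpha = 0.25, gamma_f = 2) {
  n_img <- length(targets)
  n_lvl <- length(outs)
  cate_nodes <- list(); dice_nodes <- list(); dice_items <- list()
  for (li in seq_len(n_lvl)) {
    cate <- outs[[li]]$cate   # (N, C, S, S)
    mask <- outs[[li]]$mask   # (N, S^2, H, W)
    for (n in seq_len(n_img)) {
      tg <- if (inherits(targets[[n]], "grid_target")) targets[[n]]
            else targets[[n]][[li]]
      tgt_arr <- aperm(tg$category, c(3, 1, 2))          # (C, S, S)
      d <- dim(cate$value)
      full <- array(0, dim = c(1, d[2], d[3], d[4]))
      full[1, , , ] <- tgt_arr
      pslice <- ag_reshape(ag_subset_batch(cate, n), c(1, d[2], d[3], d[4]))
      cate_nodes[[length(cate_nodes) + 1L]] <-
        ag_focal(pslice, full, alpha, gamma_f)
      for (k in tg$positive)
        dice_items[[length(dice_items) + 1L]] <-
          list(n = n, k0 = k, mask = tg$masks[[as.character(k)]], lvl = li)
    }
    if (length(dice_items)) {
      dice_nodes[[length(dice_nodes) + 1L]] <-
        list(node = ag_dice_bank(mask, dice_items), n = length(dice_items))
    }
    dice_items <- list()
  }
  cat_term <- cate_nodes[[1]]
  if (length(cate_nodes) > 1)
    for (i in 2:length(cate_nodes)) cat_term <- ag_add(cat_term, cate_nodes[[i]])
  cat_term <- ag_scale(cat_term, 1 / length(cate_nodes))
  n_pos <- sum(vapply(dice_nodes, `[[`, numeric(1), "n"))
  if (n_pos > 0) {
    # weighted mean over the per-level banks = mean over all positives
    m_term <- ag_scale(dice_nodes[[1]]$node, dice_nodes[[1]]$n / n_pos)
    if (length(dice_nodes) > 1)
      for (i in 2:length(dice_nodes))
        m_term <- ag_add(m_term, ag_scale(dice_nodes[[i]]$node,
                                          dice_nodes[[i]]$n / n_pos))
    total <- ag_add(cat_term, ag_scale(m_term, gamma))
  } else {
    m_term <- ag_const(0)
    total <- cat_term
  }
  list(total = total, category_term = cat_term$value, mask_term = m_term$value,
       n_pos = n_pos)
}

# ---------------------------------------------------------------- decode ---

#' Decode grid-head predictions into instances
#'
#' Cells whose category score reaches `score_thresh` emit their mask
#' channel k = i*S + j, binarized at `mask_bin_thresh`; the final score is
#' the category score multiplied by the mask's mean foreground confidence.
#' Empty masks are discarded.
#'
#' @param cate_pred S x S x C array of category scores.
#' @param mask_pred H x W x S^2 array of soft masks.
#' @param score_thresh,mask_bin_thresh thresholds in (0, 1).
#' @return an [instance_set()] (possibly empty).
#' @export
decode_instances <- function(cate_pred, mask_pred, score_thresh = 0.1,
                             mask_bin_thresh = 0.5) {
  assert_that(score_thresh > 0 && score_thresh < 1 &&
                mask_bin_thresh > 0 && mask_bin_thresh < 1,
              "thresholds must lie in (0, 1)")
  S <- dim(cate_pred)[1]
  masks <- list(); scores <- numeric(0); cats <- integer(0)
  for (i in 0:(S - 1)) for (j in 0:(S - 1)) {
    for (cc in seq_len(dim(cate_pred)[3])) {
      sc <- cate_pred[i + 1, j + 1, cc]
      if (sc < score_thresh) next
      k <- i * S + j
      soft <- mask_pred[, , k + 1L]
      bin <- (soft >= mask_bin_thresh) * 1L
      if (!any(bin == 1)) next
      conf <- mean(soft[bin == 1])
      masks[[length(masks) + 1L]] <- bin
      scores <- c(scores, sc * conf)
      cats <- c(cats, cc)
    }
  }
  instance_set(masks, scores, cats)
}

#' Greedy mask non-maximum suppression
#'
#' Predictions are visited in descending score order; each survivor
#' suppresses later predictions whose mask IoU with it reaches
#' `iou_thresh`.
#'
#' @param predictions an [instance_set()].
#' @param iou_thresh IoU threshold (default 0.5).
#' @param max_keep cap on survivors (default 100, matching the evaluator's
#'   AR cap).
#' @return filtered [instance_set()], in descending score order.
#' @export
mask_nms <- function(predictions, iou_thresh = 0.5, max_keep = 100L) {
  n <- length(predictions$masks)
  if (n == 0) return(predictions)
  ord <- order(predictions$scores, decreasing = TRUE)
  keep <- integer(0)
  for (idx in ord) {
    ok <- TRUE
    for (kidx in keep)
      if (mask_iou(predictions$masks[[idx]], predictions$masks[[kidx]]) >= iou_thresh) {
        ok <- FALSE; break
      }
    if (ok) keep <- c(keep, idx)
    if (length(keep) >= max_keep) break
  }
  instance_set(predictions$masks[keep], predictions$scores[keep],
               predictions$categories[keep])
}
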