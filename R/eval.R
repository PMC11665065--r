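# Mask-level COCO-style evaluation: greedy IoU matching, precision/recall,
# 101-point interpolated AP per IoU threshold in {0.50, 0.55, ..., 0.95},
# AR with a top-100-per-image cap, and mAP/mAR as the ten-threshold means.

#' Intersection-over-union of two binary masks
#'
#' @param a,b binary matrices of equal shape.
#' @return |a & b| / |a | b|; 0 when the union is empty.
#' @export
mask_iou <- function(a, b) {
  assert_that(identical(dim(a), dim(b)), "mask shapes differ")
  ai <- a != 0; bi <- b != 0
  u <- sum(ai | bi)
  if (u == 0) return(0)
  sum(ai & bi) / u
}

# IoU matrix between two instance sets (rows: predictions, cols: gts)
iou_matrix <- function(preds, gts) {
  np <- length(preds$masks); ng <- length(gts$masks)
  m <- matrix(0, np, ng)
  if (np == 0 || ng == 0) return(m)
  for (p in seq_len(np)) for (g in seq_len(ng))
    m[p, g] <- mask_iou(preds$masks[[p]], gts$masks[[g]])
  m
}

#' Match predictions to ground truth at one IoU threshold
#'
#' Predictions are sorted by descending score; each is greedily matched to
#' the still-unmatched ground truth of highest IoU, provided that IoU
#' reaches the threshold. Matched predictions are true positives, the rest
#' false positives; unmatched ground truths are false negatives.
#'
#' @param preds,gts [instance_set()]s for one image.
#' @param iou_thresh IoU threshold.
#' @param ious optional precomputed [iou_matrix()] (rows follow `preds`).
#' @return `match_result`: list with `order` (indices into preds by
#'   descending score), `tp` logical vector aligned with `order`, `scores`,
#'   `fn` count and `n_gt`.
#' @export
match_predictions <- function(preds, gts, iou_thresh, ious = NULL) {
  np <- length(preds$masks); ng <- length(gts$masks)
  ord <- order(preds$scores, decreasing = TRUE)
  if (is.null(ious)) ious <- iou_matrix(preds, gts)
  matched_gt <- rep(FALSE, ng)
  tp <- logical(np)
  for (r in seq_along(ord)) {
    p <- ord[r]
    if (ng == 0) break
    cand <- which(!matched_gt)
    if (!length(cand)) next
    best <- cand[which.max(ious[p, cand])]
    if (ious[p, best] >= iou_thresh) {
      tp[r] <- TRUE
      matched_gt[best] <- TRUE
    }
  }
  structure(list(order = ord, tp = tp, scores = preds$scores[ord],
                 fn = sum(!matched_gt), n_gt = ng),
            class = "match_result")
}

#' Precision and recall of a match result
#'
#' Precision = TP / (TP + FP) (0 when there are no predictions, by
#' convention) and Recall = TP / (TP + FN) (0 when there is no ground
#' truth).
#'
#' @param match a `match_result` from [match_predictions()].
#' @return named numeric vector c(precision, recall).
#' @export
precision_recall <- function(match) {
  tp <- sum(match$tp)
  np <- length(match$tp)
  prec <- if (np == 0) 0 else tp / np
  rec <- if (match$n_gt == 0) 0 else tp / match$n_gt
  c(precision = prec, recall = rec)
}

# Build the score-ranked PR sequence from per-image match results and
# return the 101-point interpolated AP plus the curve samples.
ap_from_matches <- function(matches) {
  scores <- unlist(lapply(matches, `[[`, "scores"))
  tps <- unlist(lapply(matches, `[[`, "tp"))
  n_gt <- sum(vapply(matches, `[[`, numeric(1), "n_gt"))
  r_points <- seq(0, 1, by = 0.01)
  if (n_gt == 0 || length(scores) == 0) {
    ap <- if (n_gt == 0 && length(scores) == 0) 0 else 0
    return(list(ap = ap, recall = if (n_gt == 0) 0 else 0,
                curve = data.frame(recall = r_points, precision = 0)))
  }
  ord <- order(scores, decreasing = TRUE)
  tp_c <- cumsum(tps[ord])
  fp_c <- cumsum(!tps[ord])
  prec <- tp_c / (tp_c + fp_c)
  rec <- tp_c / n_gt
  # interpolated precision: running max from the right
  p_int <- rev(cummax(rev(prec)))
  # p_interp(r) = max precision at recall >= r; 0 past the achieved recall
  p_at <- vapply(r_points, function(r) {
    i <- which(rec >= r)
    if (!length(i)) 0 else p_int[i[1]]
  }, numeric(1))
  list(ap = mean(p_at), recall = rec[length(rec)],
       curve = data.frame(recall = r_points, precision = p_at))
}

#' 101-point interpolated average precision at one IoU threshold
#'
#' Aggregates match results over the dataset, ranks all predictions by
#' score, forms the precision-recall sequence, interpolates precision as
#' p_interp(r) = max over r' >= r of p(r'), and averages over the 101
#' recall points {0, 0.01, ..., 1}.
#'
#' @param matches list of `match_result`s (one per image).
#' @return scalar AP in `[0, 1]`.
#' @export
ap_at_iou <- function(matches) ap_from_matches(matches)$ap

#' Summarize predictions against ground truth over the IoU ladder
#'
#' Computes AP and AR at each IoU threshold in {0.50, 0.55, ..., 0.95}
#' (AR with at most `max_dets` top-scoring predictions per image; with a
#' single category AR at a threshold equals the recall there), plus mAP and
#' mAR as the ten-threshold means, AP50/AP75/AR50/AR75, and the
#' precision-recall curve samples per threshold.
#'
#' @param preds_by_image list of [instance_set()] predictions.
#' @param gts_by_image list of [instance_set()] ground truths (parallel).
#' @param iou_thresholds numeric vector (default `seq(0.5, 0.95, 0.05)`).
#' @param max_dets per-image cap on predictions (default 100).
#' @return `eval_summary`: list with `ap`, `ar` (named by threshold),
#'   `mAP`, `mAR`, `AP50`, `AP75`, `AR50`, `AR75`, `pr_curves` (list of
#'   data.frames).
#' @export
summarize_eval <- function(preds_by_image, gts_by_image,
                           iou_thresholds = seq(0.5, 0.95, by = 0.05),
                           max_dets = 100L) {
  assert_that(length(preds_by_image) == length(gts_by_image),
              "prediction and ground-truth image lists differ in length")
  capped <- lapply(preds_by_image, function(p) {
    if (length(p$masks) <= max_dets) return(p)
    ord <- order(p$scores, decreasing = TRUE)[seq_len(max_dets)]
    instance_set(p$masks[ord], p$scores[ord], p$categories[ord])
  })
  ious <- lapply(seq_along(capped), function(i)
    iou_matrix(capped[[i]], gts_by_image[[i]]))
  ap <- ar <- setNames(numeric(length(iou_thresholds)),
                       sprintf("%.2f", iou_thresholds))
  curves <- setNames(vector("list", length(iou_thresholds)), names(ap))
  for (t in seq_along(iou_thresholds)) {
    matches <- lapply(seq_along(capped), function(i)
      match_predictions(capped[[i]], gts_by_image[[i]], iou_thresholds[t],
                        ious = ious[[i]]))
    res <- ap_from_matches(matches)
    ap[t] <- res$ap
    n_gt <- sum(vapply(matches, `[[`, numeric(1), "n_gt"))
    tp <- sum(vapply(matches, function(m) sum(m$tp), numeric(1)))
    ar[t] <- if (n_gt == 0) 0 else tp / n_gt
    curves[[t]] <- res$curve
  }
  structure(list(ap = ap, ar = ar,
                 mAP = mean(ap), mAR = mean(ar),
                 AP50 = ap[["0.50"]], AP75 = ap[["0.75"]],
                 AR50 = ar[["0.50"]], AR75 = ar[["0.75"]],
                 pr_curves = curves, iou_thresholds = iou_thresholds),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("mAP %.1f%%  mAR %.1f%%  AP50 %.1f%%  AP75 %.1f%%  AR50 %.1f%%  AR75 %.1f%%\n",
              100 * x$mAP, 100 * x$mAR, 100 * x$AP50, 100 * x$AP75,
              100 * x$AR50, 100 * x$AR75))
  invisible(x)
}

#' Write precision-recall curves as CSV and PNG
#'
#' @param summary an `eval_summary`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
export_pr_curves <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(summary$pr_curves)) {
    csv <- file.path(dir, paste0("pr_iou_", nm, ".csv"))
    utils::write.csv(summary$pr_curves[[nm]], csv, row.names = FALSE)
    paths <- c(paths, csv)
  }
  png_path <- file.path(dir, "pr_curves.png")
  grDevices::png(png_path, width = 720, height = 600)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                 ylab = "Precision", main = "P-R curves over IoU thresholds")
  cols <- grDevices::hcl.colors(length(summary$pr_curves), "viridis")
  for (i in seq_along(summary$pr_curves))
    graphics::lines(summary$pr_curves[[i]]$recall,
                    summary$pr_curves[[i]]$precision, col = cols[i], lwd = 2)
  graphics::legend("topright", legend = names(summary$pr_curves), col = cols,
                   lwd = 2, cex = 0.7, title = "IoU")
  grDevices::dev.off()
  invisible(c(paths, png_path))
}
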