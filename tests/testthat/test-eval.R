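# Mask evaluation: IoU, matching, precision/recall, AP, summaries.

sq_mask <- function(h, w, y0, x0, hh, ww) {
  m <- matrix(0L, h, w)
  m[y0:(y0 + hh - 1), x0:(x0 + ww - 1)] <- 1L
  m
}

test_that("mask IoU counts pixels", {
  a <- sq_mask(8, 8, 1, 1, 2, 2)
  expect_equal(mask_iou(a, a), 1)
  b <- sq_mask(8, 8, 5, 5, 2, 2)
  expect_equal(mask_iou(a, b), 0)
  # two 2x2 squares sharing one column: intersection 2, union 6
  c1 <- sq_mask(8, 8, 1, 1, 2, 2); c2 <- sq_mask(8, 8, 1, 2, 2, 2)
  expect_equal(mask_iou(c1, c2), 2 / 6)
  expect_equal(mask_iou(matrix(0L, 3, 3), matrix(0L, 3, 3)), 0)
  expect_error(mask_iou(a, matrix(0L, 3, 3)), "shape")
})

test_that("greedy matching respects score order and per-gt exclusivity", {
  g1 <- sq_mask(16, 16, 1, 1, 4, 4)
  g2 <- sq_mask(16, 16, 10, 10, 4, 4)
  gts <- instance_set(list(g1, g2))
  # predictions identical to ground truth: all TP
  m <- match_predictions(instance_set(list(g1, g2), scores = c(0.7, 0.9)), gts, 0.5)
  expect_true(all(m$tp))
  expect_equal(m$fn, 0)
  expect_equal(m$scores, c(0.9, 0.7))  # sorted by descending score
  # no predictions: all FN
  m0 <- match_predictions(instance_set(list()), gts, 0.5)
  expect_equal(m0$fn, 2)
  # two predictions on one gt: the higher-scored wins, the other is FP
  m2 <- match_predictions(instance_set(list(g1, g1), scores = c(0.6, 0.8)),
                          instance_set(list(g1)), 0.5)
  expect_equal(m2$tp, c(TRUE, FALSE))
  expect_equal(sum(m2$tp), 1)
})

test_that("precision and recall follow their defining ratios and conventions", {
  fake <- function(tp, fp, fn) structure(
    list(order = seq_len(tp + fp), tp = c(rep(TRUE, tp), rep(FALSE, fp)),
         scores = seq(1, 0.5, length.out = max(1, tp + fp)), fn = fn,
         n_gt = tp + fn), class = "match_result")
  expect_equal(unname(precision_recall(fake(8, 2, 2))), c(0.8, 0.8))
  expect_equal(unname(precision_recall(fake(0, 0, 5))), c(0, 0))
  expect_equal(unname(precision_recall(fake(5, 0, 0))), c(1, 1))
})

test_that("interpolated AP reproduces its closed forms", {
  g1 <- sq_mask(16, 16, 1, 1, 4, 4)
  g2 <- sq_mask(16, 16, 10, 10, 4, 4)
  far <- sq_mask(16, 16, 6, 1, 2, 2)
  gts <- instance_set(list(g1, g2))
  # perfect predictions: AP = 1
  mp <- match_predictions(instance_set(list(g1, g2), scores = c(0.9, 0.8)), gts, 0.5)
  expect_equal(ap_at_iou(list(mp)), 1)
  # no predictions: AP = 0
  expect_equal(ap_at_iou(list(match_predictions(instance_set(list()), gts, 0.5))), 0)
  # ranked (TP, FP) over 2 gts: precision 1 up to recall 0.5 -> AP = 51/101
  m <- match_predictions(instance_set(list(g1, far), scores = c(0.9, 0.8)), gts, 0.5)
  expect_equal(m$tp, c(TRUE, FALSE))
  expect_equal(ap_at_iou(list(m)), 51 / 101)
})

test_that("summary means, single-category AR identity and monotonicity hold", {
  set.seed(51)
  fixtures <- lapply(1:6, function(i) random_instance_fixture(i))
  preds <- lapply(fixtures, `[[`, "preds")
  gts <- lapply(fixtures, `[[`, "gts")
  s <- summarize_eval(preds, gts)
  expect_equal(s$mAP, mean(s$ap))
  expect_equal(s$mAR, mean(s$ar))
  expect_gte(s$AP50, s$AP75)
  expect_true(all(s$ap >= 0 & s$ap <= 1) && all(s$ar >= 0 & s$ar <= 1))
  # AP at stricter IoU never exceeds AP at looser IoU
  expect_true(all(diff(s$ap) < 1e-12))
  # single-category AR at a threshold equals the recall there
  for (t in seq_along(s$iou_thresholds)) {
    matches <- lapply(seq_along(preds), function(i)
      match_predictions(preds[[i]], gts[[i]], s$iou_thresholds[t]))
    tp <- sum(vapply(matches, function(m) sum(m$tp), numeric(1)))
    ngt <- sum(vapply(matches, `[[`, numeric(1), "n_gt"))
    expect_equal(unname(s$ar[t]), tp / ngt, tolerance = 1e-12)
  }
  # interpolated precision is non-increasing in recall on every curve
  for (cv in s$pr_curves)
    expect_true(all(diff(cv$precision) < 1e-12))
  # perfect predictions: everything is 1
  sp <- summarize_eval(gts[1], gts[1])
  expect_equal(sp$mAP, 1); expect_equal(sp$mAR, 1)
  expect_equal(unname(sp$AP50), 1); expect_equal(unname(sp$AP75), 1)
  # identical AP at every threshold: the mean is that value (degenerate check
  # via the perfect case covers it; empty predictions give the zero floor)
  s0 <- summarize_eval(list(instance_set(list())), gts[1])
  expect_equal(s0$mAP, 0); expect_equal(s0$mAR, 0)
})

test_that("evaluation agrees with the straight-line reference implementation", {
  errs <- numeric(0)
  for (i in 1:20) {
    fx <- random_instance_fixture(100 + i)
    s <- summarize_eval(list(fx$preds), list(fx$gts))
    o <- oracle_coco_eval(list(fx$preds), list(fx$gts))
    errs <- c(errs, abs(s$mAP - o$mAP), abs(s$mAR - o$mAR),
              max(abs(unname(s$ap) - o$ap)), max(abs(unname(s$ar) - o$ar)))
  }
  expect_lt(max(errs), 1e-3)
})

test_that("PR curves export as CSV files plus a plot", {
  fx <- random_instance_fixture(7)
  s <- summarize_eval(list(fx$preds), list(fx$gts))
  dir <- file.path(tempdir(), "prcurves")
  paths <- export_pr_curves(s, dir)
  expect_length(list.files(dir, pattern = "\\.csv$"), 10)
  expect_true(file.exists(file.path(dir, "pr_curves.png")))
  back <- utils::read.csv(file.path(dir, "pr_iou_0.50.csv"))
  expect_equal(nrow(back), 101)
  expect_equal(back$precision, s$pr_curves[["0.50"]]$precision)
})
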