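# Grid head: target assignment, losses, decoding and NMS.

disc_mask <- function(h, w, cy, cx, r) {
  m <- matrix(0L, h, w)
  m[(row(m) - 1 - cy)^2 + (col(m) - 1 - cx)^2 <= r^2] <- 1L
  m
}

test_that("cell/channel indexing is the k = i*S + j bijection", {
  S <- 5
  ks <- outer(0:(S - 1), 0:(S - 1), function(i, j) i * S + j)
  expect_equal(sort(as.vector(ks)), 0:(S^2 - 1))        # bijection onto 0..S^2-1
  for (k in 0:(S^2 - 1)) {                               # round trip
    i <- k %/% S; j <- k %% S
    expect_equal(i * S + j, k)
  }
  # an instance centered in cell (2, 3) of a 5x5 grid gets channel 13
  m <- disc_mask(100, 100, cy = 49, cx = 69, r = 6)     # center (49, 69) -> cell (2, 3)
  tg <- assign_targets(instance_set(list(m)), grid_spec(S = 5), c(100, 100))
  expect_equal(tg$positive, 13L)
  expect_equal(tg$category[3, 4, 1], 1)
  # center of mass at the top-left pixel -> cell (0, 0), channel 0
  m0 <- matrix(0L, 100, 100); m0[1, 1] <- 1L
  tg0 <- assign_targets(instance_set(list(m0)), grid_spec(S = 5), c(100, 100))
  expect_equal(tg0$positive, 0L)
})

test_that("target assignment is exclusive per cell and collision-resolved by area", {
  masks <- list(disc_mask(120, 120, 20, 20, 7), disc_mask(120, 120, 90, 90, 9))
  tg <- assign_targets(instance_set(masks), grid_spec(S = 6), c(120, 120))
  expect_length(tg$positive, 2)
  # all other channels carry no mask
  expect_equal(sort(names(tg$masks)), sort(as.character(tg$positive)))
  expect_equal(sum(tg$category), 2)
  # collision: two instances whose centers share a cell -> larger area wins
  big <- disc_mask(120, 120, 15, 15, 10)
  small <- disc_mask(120, 120, 25, 25, 4)
  tgc <- assign_targets(instance_set(list(small, big)), grid_spec(S = 3), c(120, 120))
  expect_length(tgc$positive, 1)
  expect_identical(tgc$masks[[1]], big)
})

test_that("multi-level grids assign instances by scale range", {
  small <- disc_mask(128, 128, 30, 30, 4)    # sqrt(area) ~ 7
  large <- disc_mask(128, 128, 90, 90, 14)   # sqrt(area) ~ 25
  spec <- grid_spec(S = c(16, 8), C = 1,
                    scale_ranges = cbind(min = c(0, 12), max = c(12, Inf)))
  tgs <- assign_targets(instance_set(list(small, large)), spec, c(128, 128))
  expect_length(tgs, 2)
  expect_length(tgs[[1]]$positive, 1)   # fine grid owns the small nucleus
  expect_length(tgs[[2]]$positive, 1)   # coarse grid owns the large one
  expect_identical(tgs[[1]]$masks[[1]], small)
  expect_identical(tgs[[2]]$masks[[1]], large)
})

test_that("focal and dice losses reproduce their closed forms", {
  # dice: identical masks -> 0; disjoint -> 1; half-overlap -> 1/3
  a <- matrix(0, 4, 4); a[1:2, ] <- 1
  expect_equal(dice_loss(a, a), 0)
  b <- matrix(0, 4, 4); b[3:4, ] <- 1
  expect_equal(dice_loss(a, b), 1)
  gt <- matrix(0, 4, 4); gt[1:2, ] <- 1          # area 8
  pred <- matrix(0, 4, 4); pred[1, ] <- 1        # area 4, all overlapping
  expect_equal(dice_loss(pred, gt), 1 / 3, tolerance = 1e-6)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")

  # focal: single positive with p = 0.5, alpha 0.25, gamma 2
  expect_equal(focal_loss(array(0.5, c(1, 1, 1)), array(1, c(1, 1, 1))),
               0.25 * 0.25 * log(2), tolerance = 1e-6)
  # gamma_f = 0, alpha = 0.5: plain binary cross-entropy scaled by alpha
  set.seed(31)
  p <- array(runif(16, 0.1, 0.9), c(4, 4, 1))
  t <- array(rbinom(16, 1, 0.3), c(4, 4, 1))
  bce <- -sum(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(focal_loss(p, t, alpha = 0.5, gamma_f = 0),
               0.5 * bce / max(1, sum(t)), tolerance = 1e-10)
  # perfect prediction drives the loss to 0
  expect_lt(focal_loss(array(1 - 1e-9, c(2, 2, 1)), array(1, c(2, 2, 1))), 1e-6)
  expect_error(focal_loss(array(1.5, c(1, 1, 1)), array(1, c(1, 1, 1))), "in \\(0, 1\\)")
})

test_that("total loss obeys the additive composition with the mask weight", {
  S <- 4; H <- 32; W <- 32
  m1 <- disc_mask(H, W, 6, 6, 3)
  m2 <- disc_mask(H, W, 24, 24, 4)
  tg <- assign_targets(instance_set(list(m1, m2)), grid_spec(S = S), c(H, W))
  expect_length(tg$positive, 2)
  cate <- array(0.01, c(S, S, 1))
  for (r in seq_len(nrow(tg$cells)))
    cate[tg$cells$i[r] + 1, tg$cells$j[r] + 1, 1] <- 0.95
  mask_pred <- array(0, c(H, W, S * S))
  # craft dice losses: channel of m1 predicted exactly (dice 0), channel of
  # m2 predicted as half-area overlap (dice 1/3)
  k1 <- tg$cells$k[tg$cells$instance == 1]
  k2 <- tg$cells$k[tg$cells$instance == 2]
  mask_pred[, , k1 + 1] <- m1
  half <- m2 * 0
  idx <- which(m2 == 1)
  half[idx[seq_len(floor(length(idx) / 2))]] <- 1
  # make the overlap exactly half the gt area
  mask_pred[, , k2 + 1] <- half
  lr <- total_loss(cate, mask_pred, tg, gamma = 3)
  d2 <- dice_loss(half, m2)
  expect_equal(lr$mask_term, (0 + d2) / 2, tolerance = 1e-12)
  expect_equal(lr$total, lr$category_term + 3 * lr$mask_term, tolerance = 1e-12)
  expect_equal(lr$n_pos, 2)
  # no positives: mask term vanishes
  tg0 <- assign_targets(instance_set(list()), grid_spec(S = S), c(H, W))
  lr0 <- total_loss(array(0.1, c(S, S, 1)), mask_pred, tg0)
  expect_equal(lr0$mask_term, 0)
  expect_equal(lr0$total, lr0$category_term)
})

test_that("encoding ground truth and decoding ideal predictions round-trips", {
  set.seed(32)
  H <- 128
  scene <- generate_scene(H, H, 8, seed = 41)
  inst <- scene_instances(scene)
  spec <- grid_spec(S = 8)
  tg <- assign_targets(inst, spec, c(H, H))
  # collision-free fixture: every instance owns its own cell
  expect_length(tg$positive, length(inst$masks))
  cate <- array(0.01, c(8, 8, 1))
  cate[, , 1][as.matrix(tg$cells[, c("i", "j")]) + 1] <- 0.9
  mask_pred <- array(0, c(H, H, 64))
  for (k in tg$positive) mask_pred[, , k + 1] <- tg$masks[[as.character(k)]]
  dec <- decode_instances(cate, mask_pred, score_thresh = 0.1, mask_bin_thresh = 0.5)
  expect_equal(length(dec$masks), length(inst$masks))
  # mask arrays recover exactly (match by centroid ordering)
  key <- function(m) paste(round(nucseg:::mask_centroid(m), 3), collapse = ",")
  got <- dec$masks[order(vapply(dec$masks, key, character(1)))]
  want <- inst$masks[order(vapply(inst$masks, key, character(1)))]
  for (i in seq_along(want)) expect_identical(got[[i]], want[[i]])
  # raising the score threshold never increases the instance count
  n_last <- Inf
  for (th in c(0.05, 0.5, 0.95)) {
    n <- length(decode_instances(cate, mask_pred, th, 0.5)$masks)
    expect_lte(n, n_last)
    n_last <- n
  }
  # all scores below threshold: empty set
  expect_length(decode_instances(array(0.01, c(8, 8, 1)), mask_pred, 0.5, 0.5)$masks, 0)
  expect_error(decode_instances(cate, mask_pred, 0, 0.5), "thresholds")
})

test_that("mask NMS suppresses duplicates greedily and is idempotent", {
  m1 <- disc_mask(64, 64, 20, 20, 8)
  m2 <- disc_mask(64, 64, 45, 45, 8)
  # disjoint predictions all survive
  p <- instance_set(list(m1, m2), scores = c(0.9, 0.8))
  expect_length(mask_nms(p, 0.5)$masks, 2)
  # identical masks: only the higher-scored survives
  dup <- instance_set(list(m1, m1, m2), scores = c(0.8, 0.9, 0.7))
  kept <- mask_nms(dup, 0.5)
  expect_length(kept$masks, 2)
  expect_equal(kept$scores[1], 0.9)
  # idempotence
  again <- mask_nms(kept, 0.5)
  expect_identical(again$masks, kept$masks)
  expect_identical(again$scores, kept$scores)
  # empty input passes through
  expect_length(mask_nms(instance_set(list()), 0.5)$masks, 0)
  # survivors are pairwise below the threshold
  shifted <- instance_set(list(m1, disc_mask(64, 64, 22, 20, 8), m2),
                          scores = c(0.9, 0.85, 0.8))
  surv <- mask_nms(shifted, 0.3)
  if (length(surv$masks) > 1)
    for (i in 1:(length(surv$masks) - 1))
      for (j in (i + 1):length(surv$masks))
        expect_lt(mask_iou(surv$masks[[i]], surv$masks[[j]]), 0.3)
})

test_that("head forward produces grid-shaped sigmoid outputs", {
  set.seed(35)
  cfg <- desk_config(seed = 5)
  cfg$grid <- grid_spec(S = 12L, C = 1L)
  m <- nucseg_model(cfg)
  x <- array(runif(1 * 3 * 128 * 128), c(1, 3, 128, 128))
  outs <- m$forward(x, training = TRUE)
  expect_equal(dim(outs[[1]]$cate$value), c(1, 1, 12, 12))
  expect_equal(dim(outs[[1]]$mask$value), c(1, 144, 128, 128))
  expect_true(all(outs[[1]]$cate$value > 0 & outs[[1]]$cate$value < 1))
  expect_true(all(outs[[1]]$mask$value >= 0 & outs[[1]]$mask$value <= 1))
})
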