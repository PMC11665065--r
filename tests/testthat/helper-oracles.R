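# Independent reference implementations used as oracles. These are
# deliberately written as plain scalar loops, separate from the package's
# vectorized code paths.

# Deformable convolution by direct evaluation of the sampling sum:
# y(p0) = sum_n w(p_n) x(p0 + p_n + dp_n), bilinear interpolation written
# out longhand with zero padding.
oracle_dconv <- function(x, w, grid, off, b, stride = 1, pad = 1) {
  ks <- attr(grid, "kernel_size"); dil <- attr(grid, "dilation")
  r <- (ks - 1) / 2 * dil
  N <- dim(x)[1]; C <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  O <- dim(w)[1]; Ho <- dim(off)[3]; Wo <- dim(off)[4]
  samp <- function(n, c, y, xx) {
    v <- 0
    for (qy in floor(y) + 0:1) for (qx in floor(xx) + 0:1) {
      g <- max(0, 1 - abs(qy - y)) * max(0, 1 - abs(qx - xx))
      if (g > 0 && qy >= 0 && qy < H && qx >= 0 && qx < W)
        v <- v + g * x[n, c, qy + 1, qx + 1]
    }
    v
  }
  y <- array(0, c(N, O, Ho, Wo))
  for (n in 1:N) for (o in 1:O) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- b[o]
    for (k in 1:nrow(grid)) {
      sy <- (ho - 1) * stride - pad + r + grid[k, "dy"] + off[n, 2 * k - 1, ho, wo]
      sx <- (wo - 1) * stride - pad + r + grid[k, "dx"] + off[n, 2 * k, ho, wo]
      ki <- (k - 1) %/% ks + 1; kj <- (k - 1) %% ks + 1
      for (c in 1:C) acc <- acc + w[o, c, ki, kj] * samp(n, c, sy, sx)
    }
    y[n, o, ho, wo] <- acc
  }
  y
}

# Non-local block by a double loop over positions, mirroring
# U_i = (1/C(v)) sum_j f(v_i, v_j) g(v_j) for the embedded-Gaussian
# instantiation of a given block (softmax normalization, residual add).
oracle_nonlocal <- function(x, block) {
  wt <- block$params$w_theta$value; wp <- block$params$w_phi$value
  wg <- block$params$w_g$value; wz <- block$params$w_z$value
  d <- dim(x)
  out <- array(0, dim = d)
  for (n in 1:d[1]) {
    vm <- matrix(x[n, , , , drop = FALSE], nrow = d[2])  # (C, HW)
    npos <- ncol(vm)
    ym <- matrix(0, d[2], npos)
    for (i in 1:npos) {
      f <- numeric(npos)
      for (j in 1:npos)
        f[j] <- exp(sum((wt %*% vm[, i]) * (wp %*% vm[, j])))
      f <- f / sum(f)  # C(v) = sum_j f(v_i, v_j)
      acc <- numeric(nrow(wg))
      for (j in 1:npos) acc <- acc + f[j] * (wg %*% vm[, j])
      ym[, i] <- wz %*% acc
    }
    out[n, , , ] <- array(ym, dim = d[2:4]) + x[n, , , ]
  }
  out
}

# Straight-line reference mask evaluator: per-threshold greedy matching and
# an explicit 101-point interpolated-precision loop.
oracle_coco_eval <- function(preds_by_image, gts_by_image,
                             thresholds = seq(0.5, 0.95, 0.05),
                             max_dets = 100) {
  iou <- function(a, b) {
    i <- sum(a == 1 & b == 1); u <- sum(a == 1 | b == 1)
    if (u == 0) 0 else i / u
  }
  ap <- ar <- numeric(length(thresholds))
  for (t in seq_along(thresholds)) {
    th <- thresholds[t]
    all_scores <- numeric(0); all_tp <- logical(0); total_gt <- 0
    for (img in seq_along(preds_by_image)) {
      p <- preds_by_image[[img]]; g <- gts_by_image[[img]]
      ord <- order(p$scores, decreasing = TRUE)
      if (length(ord) > max_dets) ord <- ord[1:max_dets]
      used <- rep(FALSE, length(g$masks))
      total_gt <- total_gt + length(g$masks)
      for (pi in ord) {
        best_iou <- -1; best_j <- 0
        for (j in seq_along(g$masks)) {
          if (used[j]) next
          v <- iou(p$masks[[pi]], g$masks[[j]])
          if (v > best_iou) { best_iou <- v; best_j <- j }
        }
        hit <- best_j > 0 && best_iou >= th
        if (hit) used[best_j] <- TRUE
        all_scores <- c(all_scores, p$scores[pi])
        all_tp <- c(all_tp, hit)
      }
    }
    if (total_gt == 0 || length(all_scores) == 0) { ap[t] <- 0; ar[t] <- 0; next }
    o <- order(all_scores, decreasing = TRUE)
    tp_c <- cumsum(all_tp[o]); fp_c <- cumsum(!all_tp[o])
    precs <- tp_c / (tp_c + fp_c); recs <- tp_c / total_gt
    acc <- 0
    for (r in seq(0, 1, 0.01)) {
      # envelope: max precision at any point with recall >= r, else 0
      best <- 0
      for (q in seq_along(recs))
        if (recs[q] >= r && precs[q] > best) best <- precs[q]
      acc <- acc + best
    }
    ap[t] <- acc / 101
    ar[t] <- recs[length(recs)]
  }
  list(ap = ap, ar = ar, mAP = mean(ap), mAR = mean(ar))
}

# Central finite-difference gradient of a scalar-valued function of one
# entry of `node$value`.
fd_grad <- function(node, i, loss_fn, h = 1e-3) {
  v0 <- node$value[i]
  node$value[i] <- v0 + h; lp <- loss_fn()
  node$value[i] <- v0 - h; lm <- loss_fn()
  node$value[i] <- v0
  (lp - lm) / (2 * h)
}

# Random instance-set fixture: a few blobby rectangles with random scores.
random_instance_fixture <- function(seed, h = 48, w = 48, n_gt = 6,
                                    n_pred = 8) {
  set.seed(seed)
  rect_mask <- function() {
    m <- matrix(0L, h, w)
    y0 <- sample(1:(h - 8), 1); x0 <- sample(1:(w - 8), 1)
    hh <- sample(3:8, 1); ww <- sample(3:8, 1)
    m[y0:min(h, y0 + hh), x0:min(w, x0 + ww)] <- 1L
    m
  }
  gts <- instance_set(replicate(n_gt, rect_mask(), simplify = FALSE))
  # predictions: jittered copies of gts plus pure noise
  preds <- list()
  for (i in seq_len(n_pred)) {
    if (i <= n_gt && runif(1) < 0.7) {
      m <- gts$masks[[i]]
      dy <- sample(-2:2, 1); dx <- sample(-2:2, 1)
      shifted <- matrix(0L, h, w)
      ys <- pmax(1, 1 + dy):pmin(h, h + dy)
      shifted[ys, ] <- m[ys - dy, ]
      if (dx != 0) {
        tmp <- matrix(0L, h, w)
        xs <- pmax(1, 1 + dx):pmin(w, w + dx)
        tmp[, xs] <- shifted[, xs - dx]
        shifted <- tmp
      }
      preds[[i]] <- shifted
    } else preds[[i]] <- rect_mask()
  }
  preds <- Filter(function(m) sum(m) > 0, preds)
  list(preds = instance_set(preds, scores = runif(length(preds))), gts = gts)
}
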