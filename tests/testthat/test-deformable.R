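# Deformable convolution operator and backbone plumbing.

test_that("regular_grid enumerates centered dilation-scaled displacements", {
  g <- regular_grid(3, 1)
  expect_equal(unname(g[, "dy"]), rep(-1:1, each = 3))
  expect_equal(unname(g[, "dx"]), rep(-1:1, times = 3))
  expect_equal(nrow(g), 9)
  # symmetric about the origin
  expect_equal(colSums(g), c(dy = 0, dx = 0))

  expect_equal(nrow(regular_grid(1, 1)), 1)
  expect_equal(unname(regular_grid(1, 1)[1, ]), c(0, 0))

  g2 <- regular_grid(3, 2)
  expect_equal(unname(g2[, "dy"]), 2 * unname(g[, "dy"]))
  expect_equal(unname(g2[, "dx"]), 2 * unname(g[, "dx"]))

  expect_error(regular_grid(4, 1), "odd")
})

test_that("bilinear sampling is exact at integers and a partition of unity", {
  m <- matrix(c(0, 2, 1, 3), 2, 2)  # m[y+1, x+1]: x(0,0)=0 x(0,1)=1 x(1,0)=2 x(1,1)=3
  expect_equal(bilinear_sample(m, c(1, 0)), 2)
  expect_equal(bilinear_sample(m, c(0.5, 0.5)), 1.5)
  # integer locations return the stored value exactly
  mm <- matrix(rnorm(35), 5, 7)
  for (i in 0:4) for (j in 0:6)
    expect_identical(bilinear_sample(mm, c(i, j)), mm[i + 1, j + 1])
  # constant field: any in-bounds fractional point returns the constant
  cm <- matrix(4.2, 6, 6)
  set.seed(1)
  for (r in 1:20) {
    p <- runif(2, 0, 4.99)
    expect_equal(bilinear_sample(cm, p), 4.2, tolerance = 1e-12)
  }
  # out-of-bounds contributions are zero-padded
  expect_equal(bilinear_sample(cm, c(-0.5, 0)), 2.1)
})

test_that("deformable convolution reduces to standard convolution at zero offset", {
  set.seed(10)
  g <- regular_grid(3, 1)
  worst <- 0
  for (rep in 1:100) {
    x <- array(rnorm(1 * 2 * 6 * 6), c(1, 2, 6, 6))
    w <- array(rnorm(3 * 2 * 3 * 3), c(3, 2, 3, 3))
    b <- rnorm(3)
    off <- array(0, c(1, 18, 6, 6))
    yd <- deform_conv2d(x, w, g, off, b, stride = 1, pad = 1)
    ys <- conv2d(x, w, b, stride = 1, pad = 1)
    worst <- max(worst, max(abs(yd - ys)) / max(abs(ys)))
  }
  expect_lt(worst, 1e-5)
})

test_that("vectorized deformable convolution matches the scalar sampling-sum oracle", {
  set.seed(11)
  g <- regular_grid(3, 1)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    x <- array(rnorm(2 * 2 * n * n), c(2, 2, n, n))
    w <- array(rnorm(2 * 2 * 3 * 3), c(2, 2, 3, 3))
    b <- rnorm(2)
    off <- array(runif(2 * 18 * n * n, -1.5, 1.5), c(2, 18, n, n))
    yv <- deform_conv2d(x, w, g, off, b, stride = 1, pad = 1)
    yo <- oracle_dconv(x, w, g, off, b, stride = 1, pad = 1)
    expect_lt(max(abs(yv - yo)) / max(abs(yo)), 1e-5)
  }
  # constant input: interpolation of a constant is the constant, so every
  # output equals c * sum(w) + b regardless of the offsets
  xc <- array(3, c(1, 1, 8, 8))
  w1 <- array(rnorm(9), c(1, 1, 3, 3))
  offr <- array(runif(18 * 4 * 4, -0.9, 0.9), c(1, 18, 4, 4))
  # interior outputs only (stride 2, no pad) so zero padding never bites
  yc <- deform_conv2d(xc, w1, g, offr, 0, stride = 2, pad = 0)
  expect_equal(as.vector(yc)[6], 3 * sum(w1), tolerance = 1e-10)
})

test_that("offset gradients agree with central finite differences", {
  set.seed(12)
  g <- regular_grid(3, 1)
  x <- nucseg:::ag_param(array(rnorm(1 * 2 * 6 * 6), c(1, 2, 6, 6)))
  w <- nucseg:::ag_param(array(rnorm(2 * 2 * 3 * 3), c(2, 2, 3, 3)))
  b <- nucseg:::ag_param(rnorm(2))
  # keep fractional parts away from integers so the piecewise-linear
  # bilinear kernel is differentiable at every probe
  off <- nucseg:::ag_param(array(runif(1 * 18 * 6 * 6, 0.15, 0.85) *
                                   sample(c(-1, 1), 18 * 36, TRUE),
                                 c(1, 18, 6, 6)))
  loss <- function() {
    y <- nucseg:::ag_dconv2d(x, w, b, off, 1L, 1L, 1L)
    nucseg:::ag_sum(nucseg:::ag_mul(y, y))
  }
  root <- loss()
  nucseg:::ag_backward(root)
  probes <- sample(length(off$value), 25)
  for (i in probes) {
    fd <- fd_grad(off, i, function() loss()$value, h = 1e-3)
    expect_equal(off$grad[i], fd, tolerance = 1e-3)
  }
  # input and weight gradients too
  for (i in sample(length(x$value), 8))
    expect_equal(x$grad[i], fd_grad(x, i, function() loss()$value), tolerance = 1e-3)
  for (i in sample(length(w$value), 8))
    expect_equal(w$grad[i], fd_grad(w, i, function() loss()$value), tolerance = 1e-3)
})

test_that("freshly initialized offset branch is zero and preserves standard conv", {
  g <- regular_grid(3, 1)
  set.seed(3)
  x <- array(rnorm(1 * 4 * 8 * 8), c(1, 4, 8, 8))
  off <- offset_branch(x, g)
  expect_equal(dim(off), c(1, 18, 8, 8))
  expect_true(all(off == 0))
  w <- array(rnorm(2 * 4 * 3 * 3), c(2, 4, 3, 3))
  expect_equal(deform_conv2d(x, w, g, off, stride = 1, pad = 1),
               conv2d(x, w, stride = 1, pad = 1), tolerance = 1e-12)
  # a gradient step on a loss depending on the offsets moves the branch
  lyr <- nucseg:::layer_deform_conv(4, 2)
  xa <- nucseg:::ag_const(x)
  y0 <- lyr$forward(xa)
  tgt <- array(rnorm(length(y0$value)), dim(y0$value))
  root <- nucseg:::ag_sum(nucseg:::ag_mul(nucseg:::ag_sub(y0, nucseg:::ag_const(tgt)),
                                          nucseg:::ag_sub(y0, nucseg:::ag_const(tgt))))
  nucseg:::ag_backward(root)
  expect_false(is.null(lyr$params$off_w$grad))
  nucseg:::sgd_step(lyr$params, 0.01, 0, 0)
  off2 <- lyr$forward(xa)
  expect_false(identical(off2$value, y0$value))
})

test_that("backbone emits the stride-4/8/16/32 ladder and finite gradients", {
  set.seed(4)
  bb <- build_backbone(stage_blocks = c(1, 1, 1, 1), deformable_stages = "stage4",
                       width = 4)
  x <- array(rnorm(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  cs <- backbone_forward(bb, x, training = TRUE)
  expect_equal(names(cs), c("C2", "C3", "C4", "C5"))
  expect_equal(dim(cs$C2$value)[3:4], c(16, 16))
  expect_equal(dim(cs$C3$value)[3:4], c(8, 8))
  expect_equal(dim(cs$C4$value)[3:4], c(4, 4))
  expect_equal(dim(cs$C5$value)[3:4], c(2, 2))
  root <- nucseg:::ag_sum(nucseg:::ag_mul(cs$C5, cs$C5))
  nucseg:::ag_backward(root)
  params <- nucseg:::collect_params(bb)
  grads <- lapply(params, `[[`, "grad")
  expect_true(all(vapply(grads, function(g) is.null(g) || all(is.finite(g)), logical(1))))
  expect_error(build_backbone(deformable_stages = "stage7"), "unknown stage")
})

test_that("FPN levels share the channel width and halve spatially", {
  set.seed(5)
  fpn <- build_fpn(c(4, 8, 16, 32), out_channels = 6)
  feats <- list(
    nucseg:::ag_const(array(rnorm(1 * 4 * 16 * 16), c(1, 4, 16, 16))),
    nucseg:::ag_const(array(rnorm(1 * 8 * 8 * 8), c(1, 8, 8, 8))),
    nucseg:::ag_const(array(rnorm(1 * 16 * 4 * 4), c(1, 16, 4, 4))),
    nucseg:::ag_const(array(rnorm(1 * 32 * 2 * 2), c(1, 32, 2, 2))))
  qs <- fpn_forward(fpn, feats)
  expect_equal(names(qs), c("Q2", "Q3", "Q4", "Q5"))
  for (q in qs) expect_equal(dim(q$value)[2], 6)
  expect_equal(dim(qs$Q4$value)[3:4], dim(qs$Q3$value)[3:4] / 2)
  # single level: projection + smoothing only
  q1 <- fpn_forward(build_fpn(4, out_channels = 5), feats[1])
  expect_equal(dim(q1$Q2$value), c(1, 5, 16, 16))
})
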