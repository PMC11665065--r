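# Network assembly: residual backbone with deformable stages, feature
# pyramid, balanced feature pyramid (rescale -> integrate -> refine ->
# strengthen) and the location-based segmentation head.

# ----------------------------------------------------------- backbone ------

basic_block <- function(in_ch, out_ch, stride = 1L, deform = FALSE) {
  conv_fn <- if (deform) layer_deform_conv else function(i, o, k = 3L, stride = 1L)
    layer_conv(i, o, 3L, stride = stride)
  blk <- list(
    conv1 = conv_fn(in_ch, out_ch, 3L, stride = stride),
    bn1 = layer_batchnorm(out_ch),
    conv2 = conv_fn(out_ch, out_ch, 3L),
    bn2 = layer_batchnorm(out_ch)
  )
  if (stride != 1L || in_ch != out_ch) {
    blk$down <- layer_conv(in_ch, out_ch, 1L, stride = stride, pad = 0L)
    blk$down_bn <- layer_batchnorm(out_ch)
  }
  blk
}

block_forward <- function(blk, x, training) {
  h <- ag_relu(blk$bn1$forward(blk$conv1$forward(x, training), training))
  h <- blk$bn2$forward(blk$conv2$forward(h, training), training)
  sc <- if (!is.null(blk$down))
    blk$down_bn$forward(blk$down$forward(x, training), training) else x
  ag_relu(ag_add(h, sc))
}

#' Build a residual backbone with optional deformable stages
#'
#' A ResNet-style backbone: a strided 7x7 stem plus four stages of basic
#' residual blocks, emitting feature maps C2..C5 at strides 4/8/16/32.
#' In the stages named in `deformable_stages` the 3x3 convolutions are
#' deformable (learned per-location fractional sampling offsets, zero-
#' initialized so training starts from standard-convolution behavior).
#'
#' @param stage_blocks integer vector of length 4: blocks per stage
#'   (ResNet-50-equivalent default `c(3, 4, 6, 3)`).
#' @param deformable_stages character subset of
#'   `c("stage2", "stage3", "stage4", "stage5")`.
#' @param width channel width of stage 2 (doubles per stage).
#' @param in_channels input image channels.
#' @return backbone object (list of layers) for [backbone_forward()].
#' @export
build_backbone <- function(stage_blocks = c(3L, 4L, 6L, 3L),
                           deformable_stages = c("stage3", "stage4", "stage5"),
                           width = 64L, in_channels = 3L) {
  stages <- paste0("stage", 2:5)
  bad <- setdiff(deformable_stages, stages)
  assert_that(length(bad) == 0,
              paste0("unknown stage name(s): ", paste(bad, collapse = ", ")))
  assert_that(length(stage_blocks) == 4, "stage_blocks must have length 4")
  bb <- list(
    stem_conv = layer_conv(in_channels, width, 7L, stride = 2L, pad = 3L),
    stem_bn = layer_batchnorm(width),
    stages = list()
  )
  in_ch <- width
  for (s in seq_len(4)) {
    out_ch <- width * 2L^(s - 1L)
    deform <- stages[s] %in% deformable_stages
    blocks <- list()
    for (b in seq_len(stage_blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blocks[[b]] <- basic_block(in_ch, out_ch, stride, deform)
      in_ch <- out_ch
    }
    bb$stages[[stages[s]]] <- blocks
  }
  bb$out_channels <- width * 2L^(0:3)
  bb
}

#' Run the backbone, returning the C2..C5 feature maps
#'
#' @param bb backbone from [build_backbone()].
#' @param x input tensor `ag_node` or array, dim (N, 3, H, W); H and W must
#'   be divisible by 32.
#' @param training logical; controls batch-norm statistics.
#' @return named list of `ag_node`s C2..C5 at strides 4/8/16/32.
#' @export
backbone_forward <- function(bb, x, training = TRUE) {
  x <- as_ag(x)
  h <- ag_relu(bb$stem_bn$forward(bb$stem_conv$forward(x, training), training))
  h <- ag_maxpool(h, 3L, 2L, 1L)
  out <- list()
  for (s in names(bb$stages)) {
    for (blk in bb$stages[[s]]) h <- block_forward(blk, h, training)
    out[[sub("stage", "C", s)]] <- h
  }
  out
}

# ----------------------------------------------------------------- FPN -----

#' Build a feature pyramid network over backbone outputs
#'
#' Lateral 1x1 projections, top-down 2x bilinear upsampling with addition,
#' then a 3x3 smoothing convolution per level; every output level has
#' `out_channels` channels.
#'
#' @param in_channels integer vector, channels of each input level
#'   (finest first).
#' @param out_channels uniform output width (default 256).
#' @return fpn object for [fpn_forward()].
#' @export
build_fpn <- function(in_channels, out_channels = 256L) {
  list(
    lateral = lapply(in_channels, function(c) layer_conv(c, out_channels, 1L, pad = 0L)),
    smooth = lapply(in_channels, function(c) layer_conv(out_channels, out_channels, 3L)),
    out_channels = out_channels
  )
}

#' Apply the FPN to a list of feature maps (finest first)
#'
#' @param fpn from [build_fpn()].
#' @param feats list of `ag_node`s/arrays with strictly increasing strides.
#' @param training logical.
#' @return list of `ag_node`s Q2..Qn, all at `out_channels` channels.
#' @export
fpn_forward <- function(fpn, feats, training = TRUE) {
  L <- length(feats)
  feats <- lapply(feats, as_ag)
  lat <- lapply(seq_len(L), function(l) fpn$lateral[[l]]$forward(feats[[l]], training))
  tops <- vector("list", L)
  tops[[L]] <- lat[[L]]
  if (L > 1) for (l in (L - 1):1) {
    d <- dim(lat[[l]]$value)
    tops[[l]] <- ag_add(lat[[l]], ag_resize(tops[[l + 1]], d[3], d[4]))
  }
  out <- lapply(seq_len(L), function(l) fpn$smooth[[l]]$forward(tops[[l]], training))
  names(out) <- paste0("Q", seq_len(L) + 1L)
  out
}

# --------------------------------------------------- balanced pyramid ------

#' Rescale all pyramid levels to one level's resolution
#'
#' Finer levels are max-pooled down; coarser levels are bilinearly
#' interpolated up, matching the target level's spatial size.
#'
#' @param pyramid list of `ag_node`s/arrays, finest first, strides doubling.
#' @param target_level index into `pyramid` (1-based).
#' @return list of `ag_node`s, all at the target resolution.
#' @export
rescale_to_level <- function(pyramid, target_level) {
  assert_that(target_level >= 1 && target_level <= length(pyramid),
              sprintf("target_level %d not in pyramid (L = %d)",
                      target_level, length(pyramid)))
  pyramid <- lapply(pyramid, as_ag)
  td <- dim(pyramid[[target_level]]$value)
  lapply(seq_along(pyramid), function(l) {
    x <- pyramid[[l]]
    d <- dim(x$value)
    if (l == target_level) x
    else if (d[3] > td[3]) ag_maxpool(x, d[3] %/% td[3])
    else ag_resize(x, td[3], td[4])
  })
}

#' Element-wise mean of same-shape feature maps (balanced integration)
#'
#' Computes Q_int = (1/L) * sum_l Q_l over the rescaled levels, so every
#' resolution contributes equally to the balanced semantic feature.
#'
#' @param rescaled list of same-shape `ag_node`s/arrays.
#' @return an `ag_node` of the same shape.
#' @export
integrate_levels <- function(rescaled) {
  rescaled <- lapply(rescaled, as_ag)
  d0 <- dim(rescaled[[1]]$value)
  for (x in rescaled)
    assert_that(identical(dim(x$value), d0), "integrate: shape mismatch across levels")
  acc <- rescaled[[1]]
  if (length(rescaled) > 1)
    for (l in 2:length(rescaled)) acc <- ag_add(acc, rescaled[[l]])
  ag_scale(acc, 1 / length(rescaled))
}

# Embedded-Gaussian non-local block: f(v_i, v_j) = exp(theta(v_i).phi(v_j)),
# C(v) = sum_j f (softmax), g and the output projection are 1x1 convs
# (matrix multiplies over the channel dimension), plus a residual add.
build_nonlocal <- function(ch, bottleneck = max(1L, ch %/% 2L)) {
  e <- new.env(parent = emptyenv())
  sd <- sqrt(2 / ch)
  e$params <- list(
    w_theta = ag_param(matrix(stats::rnorm(bottleneck * ch, sd = sd), bottleneck, ch)),
    w_phi = ag_param(matrix(stats::rnorm(bottleneck * ch, sd = sd), bottleneck, ch)),
    w_g = ag_param(matrix(stats::rnorm(bottleneck * ch, sd = sd), bottleneck, ch)),
    w_z = ag_param(matrix(0, ch, bottleneck))  # zero-init: block starts as identity
  )
  e$forward <- function(x, training = TRUE) {
    d <- dim(x$value)
    outs <- lapply(seq_len(d[1]), function(n) {
      xs <- ag_subset_batch(x, n)                       # (C, HW)
      theta <- ag_matmul(e$params$w_theta, xs)          # (B, HW)
      phi <- ag_matmul(e$params$w_phi, xs)
      gx <- ag_matmul(e$params$w_g, xs)
      aff <- ag_softmax_rows(ag_matmul(ag_aperm(theta, c(2, 1)), phi))  # (HW, HW)
      y <- ag_matmul(gx, ag_aperm(aff, c(2, 1)))        # (B, HW)
      ag_matmul(e$params$w_z, y)                        # (C, HW)
    })
    ag_add(x, ag_stack_batch(outs, d[2:4]))
  }
  e
}

#' Non-local refinement of a balanced feature
#'
#' Computes U_i = (1/C(v)) * sum_j f(v_i, v_j) g(v_j) over all spatial
#' positions j. The network instantiation is the embedded Gaussian
#' (`context = NULL` builds one, or pass a block from an existing model)
#' with softmax normalization and a residual connection. For analysis, a
#' custom context `list(f = function(vi, vj), g = function(vj),
#' normalizer = function(n_pos))` evaluates the generic form by direct
#' summation (no residual add), where `vi`, `vj` are channel vectors.
#'
#' @param balanced array (N, C, H, W) or `ag_node`.
#' @param context NULL, a block from [build_nonlocal()], or a custom list.
#' @return same type/shape as the input.
#' @export
nonlocal_refine <- function(balanced, context = NULL) {
  if (is.list(context) && !is.environment(context)) {
    v <- ag_value(balanced)
    d <- dim(v)
    npos <- d[3] * d[4]
    out <- array(0, dim = d)
    for (n in seq_len(d[1])) {
      vm <- matrix(v[n, , , , drop = FALSE], nrow = d[2])  # (C, HW)
      ym <- matrix(0, d[2], npos)
      for (i in seq_len(npos)) {
        acc <- numeric(d[2])
        for (j in seq_len(npos))
          acc <- acc + context$f(vm[, i], vm[, j]) * context$g(vm[, j])
        ym[, i] <- acc / context$normalizer(npos)
      }
      out[n, , , ] <- array(ym, dim = d[2:4])
    }
    return(out)
  }
  was_array <- !is_ag(balanced)
  x <- as_ag(balanced)
  if (is.null(context)) context <- build_nonlocal(dim(x$value)[2])
  y <- context$forward(x, training = FALSE)
  if (was_array) y$value else y
}

#' Redistribute a refined balanced feature over the pyramid
#'
#' The refined map is resized to each level's resolution (bilinear
#' interpolation toward finer levels, max-pooling toward coarser ones) and
#' added element-wise to the original level, yielding strengthened outputs
#' U2..Un with the input pyramid's shapes.
#'
#' @param refined `ag_node`/array at the intermediate level's resolution.
#' @param pyramid original pyramid (list, finest first).
#' @return list of `ag_node`s (or arrays if both inputs were arrays).
#' @export
strengthen <- function(refined, pyramid) {
  was_array <- !is_ag(refined) && !any(vapply(pyramid, is_ag, logical(1)))
  refined <- as_ag(refined)
  rd <- dim(refined$value)
  out <- lapply(pyramid, function(q) {
    q <- as_ag(q)
    d <- dim(q$value)
    r <- if (d[3] >= rd[3]) ag_resize(refined, d[3], d[4])
         else ag_maxpool(refined, rd[3] %/% d[3])
    ag_add(q, r)
  })
  names(out) <- sub("^Q", "U", names(pyramid) %||% paste0("Q", seq_along(pyramid) + 1L))
  if (was_array) lapply(out, ag_value) else out
}

# --------------------------------------------------------------- head ------

# Normalized coordinate channels in [-1, 1], dim (N, 2, H, W): channel 1 is
# y, channel 2 is x. Standard input for location-sensitive mask branches.
coord_channels <- function(n, h, w) {
  ys <- if (h > 1) seq(-1, 1, length.out = h) else 0
  xs <- if (w > 1) seq(-1, 1, length.out = w) else 0
  cc <- array(0, dim = c(n, 2, h, w))
  cc[, 1, , ] <- array(rep(ys, times = w), dim = c(1, 1, h, w))[rep(1, n), , , , drop = FALSE]
  cc[, 2, , ] <- array(rep(xs, each = h), dim = c(1, 1, h, w))[rep(1, n), , , , drop = FALSE]
  cc
}

build_grid_head <- function(in_ch, spec, head_ch = in_ch, n_convs = 2L,
                            cate_prior = 0.01) {
  lvls <- lapply(seq_along(spec$S), function(i) {
    S <- spec$S[i]
    h <- list(
      cate_convs = lapply(seq_len(n_convs), function(j)
        layer_conv(if (j == 1) in_ch else head_ch, head_ch, 3L)),
      cate_bns = lapply(seq_len(n_convs), function(j) layer_batchnorm(head_ch)),
      cate_out = layer_conv(head_ch, spec$C, 3L),
      mask_convs = lapply(seq_len(n_convs), function(j)
        layer_conv(if (j == 1) in_ch + 2L else head_ch, head_ch, 3L)),
      mask_bns = lapply(seq_len(n_convs), function(j) layer_batchnorm(head_ch)),
      mask_out = layer_conv(head_ch, S * S, 1L, pad = 0L)
    )
    # focal prior: start category scores near `cate_prior`
    h$cate_out$params$b$value[] <- -log((1 - cate_prior) / cate_prior)
    h
  })
  list(levels = lvls, spec = spec, n_convs = n_convs)
}

# Forward one grid level of the head. `feat_cate` is the pyramid level used
# for category prediction (resized to S x S); `feat_mask` is the finest
# level, which keeps its resolution until the final upsampling to H x W.
grid_head_forward <- function(head, lvl_idx, feat_cate, feat_mask, image_size,
                              training = TRUE) {
  h <- head$levels[[lvl_idx]]
  S <- head$spec$S[lvl_idx]
  cate <- ag_resize(feat_cate, S, S)
  for (j in seq_along(h$cate_convs))
    cate <- ag_relu(h$cate_bns[[j]]$forward(h$cate_convs[[j]]$forward(cate, training), training))
  cate <- ag_sigmoid(h$cate_out$forward(cate, training))      # (N, C, S, S)
  md <- dim(feat_mask$value)
  m <- ag_concat_channels(feat_mask, coord_channels(md[1], md[3], md[4]))
  for (j in seq_along(h$mask_convs))
    m <- ag_relu(h$mask_bns[[j]]$forward(h$mask_convs[[j]]$forward(m, training), training))
  m <- ag_sigmoid(h$mask_out$forward(m, training))            # (N, S^2, h, w)
  m <- ag_resize(m, image_size[1], image_size[2])
  list(cate = cate, mask = m)
}

# --------------------------------------------------------- full model ------

#' Assemble the full segmentation network
#'
#' Backbone (with deformable stages) -> FPN -> balanced feature pyramid
#' (rescale, integrate, non-local refine, strengthen) -> grid head with
#' category and mask branches.
#'
#' @param config a [nucseg_config()] list.
#' @return model environment with `$forward(x, training)` and `$params`.
#' @export
nucseg_model <- function(config) {
  m <- new.env(parent = emptyenv())
  m$config <- config
  with_seed(config$seed, {
    bb <- config$backbone
    m$backbone <- build_backbone(bb$blocks, bb$deformable_stages, bb$width)
    m$fpn <- build_fpn(m$backbone$out_channels, config$fpn_channels)
    m$nonlocal <- build_nonlocal(config$fpn_channels)
    m$head <- build_grid_head(config$fpn_channels, config$grid,
                              head_ch = config$head$channels,
                              n_convs = config$head$n_convs,
                              cate_prior = config$head$cate_prior)
  })
  m$params <- collect_params(list(m$backbone, m$fpn, m$nonlocal, m$head))
  m$forward <- function(x, training = TRUE) {
    cs <- backbone_forward(m$backbone, x, training)
    qs <- fpn_forward(m$fpn, cs, training)
    resc <- rescale_to_level(qs, m$config$bfp_level)
    bal <- integrate_levels(resc)
    ref <- m$nonlocal$forward(bal, training)
    us <- strengthen(ref, qs)
    img <- dim(ag_value(x))[3:4]
    lapply(seq_along(m$config$grid$S), function(i)
      grid_head_forward(m$head, i,
                        us[[m$config$head$cate_level]], us[[1]],
                        img, training))
  }
  m
}
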