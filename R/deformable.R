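# Deformable convolution: regular sampling grids, bilinear sampling and the
# deformable 2-D convolution operator.
#
# A standard convolution samples the input feature map x on a regular grid
# R = {(-1,-1), ..., (1,1)} around each output location p0 and forms
# y(p0) = sum_n w(p_n) x(p0 + p_n). The deformable variant adds a learned
# fractional displacement dp_n to every sampling point,
# y(p0) = sum_n w(p_n) x(p0 + p_n + dp_n), with x(.) evaluated at fractional
# locations by bilinear interpolation, so the gradients flow into the
# offsets as well as into the weights and the input.

#' Regular convolution sampling grid
#'
#' Enumerates the displacements of a square convolution kernel, row-major,
#' centered on (0, 0) and scaled by the dilation. For a 3x3 kernel with
#' dilation 1 this is (-1,-1), (-1,0), ..., (1,0), (1,1).
#'
#' @param kernel_size odd integer kernel side.
#' @param dilation integer dilation factor (>= 1).
#' @return object of class `sampling_grid`: a matrix with columns `dy`, `dx`
#'   (one row per sampling point) and attributes `kernel_size`, `dilation`.
#' @examples
#' regular_grid(3, 1)
#' @export
regular_grid <- function(kernel_size, dilation = 1L) {
  assert_that(length(kernel_size) == 1 && kernel_size >= 1 &&
                kernel_size %% 2 == 1,
              "kernel_size must be an odd integer >= 1")
  assert_that(dilation >= 1, "dilation must be >= 1")
  r <- (kernel_size - 1) / 2
  pts <- expand.grid(dx = (-r:r) * dilation, dy = (-r:r) * dilation)
  g <- cbind(dy = pts$dy, dx = pts$dx)  # row-major: dy varies slowest
  attr(g, "kernel_size") <- as.integer(kernel_size)
  attr(g, "dilation") <- as.integer(dilation)
  class(g) <- c("sampling_grid", class(g))
  g
}

#' Bilinear sampling of a single-channel map at a fractional location
#'
#' Evaluates x(p) = sum_q G(p, q) x(q) where the sum runs over the integer
#' pixel locations q, G(p, q) = g(q_y, p_y) g(q_x, p_x) and
#' g(a, b) = max(0, 1 - |a - b|). Locations outside the map contribute zero
#' (zero padding), and at integer p the kernel collapses to an indicator so
#' the stored value is returned exactly.
#'
#' @param map numeric matrix (single channel), 0-based pixel-centered
#'   coordinates: the element `map[1, 1]` sits at (0, 0).
#' @param location numeric length-2 vector `c(y, x)`, fractional allowed.
#' @return scalar sampled value.
#' @examples
#' m <- matrix(c(0, 2, 1, 3), 2, 2)  # m[y+1, x+1]
#' bilinear_sample(m, c(0.5, 0.5))   # mean of the four corners
#' @export
bilinear_sample <- function(map, location) {
  y <- location[1]; x <- location[2]
  H <- nrow(map); W <- ncol(map)
  y0 <- floor(y); x0 <- floor(x)
  v <- 0
  for (qy in c(y0, y0 + 1)) {
    wy <- max(0, 1 - abs(qy - y))
    if (wy == 0 || qy < 0 || qy >= H) next
    for (qx in c(x0, x0 + 1)) {
      wx <- max(0, 1 - abs(qx - x))
      if (wx == 0 || qx < 0 || qx >= W) next
      v <- v + wy * wx * map[qy + 1, qx + 1]
    }
  }
  v
}

#' Deformable 2-D convolution (dense arrays)
#'
#' Applies y(p0) = sum_n w(p_n) x(p0 + p_n + dp_n) over a batch, evaluating
#' fractional sampling locations bilinearly with zero padding outside the
#' map. With an all-zero offset field this reduces exactly to the standard
#' convolution with the same weights.
#'
#' @param input numeric array, dim (N, C, H, W).
#' @param weights numeric array, dim (O, C, k, k).
#' @param grid a [regular_grid()] describing kernel size and dilation.
#' @param offsets numeric array, dim (N, 2k^2, Ho, Wo): displacements
#'   (dy, dx) interleaved per sampling point, row-major over the grid.
#' @param bias optional numeric vector of length O.
#' @param stride,pad integer stride and zero padding.
#' @return numeric array, dim (N, O, Ho, Wo).
#' @export
deform_conv2d <- function(input, weights, grid, offsets, bias = NULL,
                          stride = 1L, pad = 0L) {
  k <- attr(grid, "kernel_size")
  dil <- attr(grid, "dilation")
  assert_that(length(dim(input)) == 4, "input must be a 4-D (N,C,H,W) array")
  assert_that(dim(offsets)[2] == 2 * nrow(grid),
              sprintf("offsets must have %d channels (2 per sampling point), got %d",
                      2 * nrow(grid), dim(offsets)[2]))
  assert_that(dim(weights)[2] == dim(input)[2],
              "weights and input disagree on channel count")
  b <- if (is.null(bias)) numeric(0) else as.numeric(bias)
  cpp_dconv2d_fwd(input, weights, b, offsets,
                  as.integer(stride), as.integer(pad), as.integer(dil))
}

#' Standard 2-D convolution (dense arrays)
#'
#' @inheritParams deform_conv2d
#' @return numeric array, dim (N, O, Ho, Wo).
#' @export
conv2d <- function(input, weights, bias = NULL, stride = 1L, pad = 0L) {
  b <- if (is.null(bias)) numeric(0) else as.numeric(bias)
  cpp_conv2d_fwd(input, weights, b, as.integer(stride), as.integer(pad))
}

# ------------------------------------------------------------- layers ------
# A layer is an environment with $params (named list of ag_param) plus
# whatever state it needs, and a $forward(x, training) closure.

he_init <- function(o, c, kh, kw) {
  sd <- sqrt(2 / (c * kh * kw))
  array(stats::rnorm(o * c * kh * kw, sd = sd), dim = c(o, c, kh, kw))
}

layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       bias = TRUE, init = c("he", "zero")) {
  init <- match.arg(init)
  e <- new.env(parent = emptyenv())
  w0 <- if (init == "zero") array(0, dim = c(out_ch, in_ch, k, k))
        else he_init(out_ch, in_ch, k, k)
  e$params <- list(w = ag_param(w0))
  if (bias) e$params$b <- ag_param(numeric(out_ch))
  e$forward <- function(x, training = TRUE) {
    b <- e$params$b %||% ag_const(numeric(0))
    ag_conv2d(x, e$params$w, b, stride, pad)
  }
  e
}

# Deformable 3x3 conv: the offset field is produced by a plain convolution
# over the same input ("offset branch"), zero-initialized so training starts
# from the standard-convolution regime.
layer_deform_conv <- function(in_ch, out_ch, k = 3L, stride = 1L,
                              pad = (k - 1L) %/% 2L, dilation = 1L) {
  e <- new.env(parent = emptyenv())
  e$grid <- regular_grid(k, dilation)
  n_off <- 2L * k * k
  e$params <- list(
    w = ag_param(he_init(out_ch, in_ch, k, k)),
    b = ag_param(numeric(out_ch)),
    off_w = ag_param(array(0, dim = c(n_off, in_ch, k, k))),
    off_b = ag_param(numeric(n_off))
  )
  e$forward <- function(x, training = TRUE) {
    off <- ag_conv2d(x, e$params$off_w, e$params$off_b, stride, pad)
    ag_dconv2d(x, e$params$w, e$params$b, off, stride, pad, dilation)
  }
  e
}

layer_batchnorm <- function(ch, momentum = 0.1) {
  e <- new.env(parent = emptyenv())
  e$params <- list(gamma = ag_param(rep(1, ch)), beta = ag_param(numeric(ch)))
  e$running_mean <- numeric(ch)
  e$running_var <- rep(1, ch)
  e$momentum <- momentum
  e$forward <- function(x, training = TRUE)
    ag_batchnorm(x, e$params$gamma, e$params$beta, e, training)
  e
}

#' Offset branch of a deformable convolution
#'
#' Builds the zero-initialized convolution that predicts the per-location
#' (dy, dx) offset field for a host convolution with the given sampling
#' grid. Freshly initialized, it returns an all-zero field, so the host
#' deformable convolution starts out identical to a standard convolution.
#'
#' @param input numeric array (N, C, H, W).
#' @param grid a [regular_grid()].
#' @param weights,bias optional branch parameters; default zeros.
#' @param stride,pad stride and padding of the host convolution.
#' @return numeric array (N, 2 k^2, Ho, Wo) of offsets.
#' @export
offset_branch <- function(input, grid, weights = NULL, bias = NULL,
                          stride = 1L, pad = (attr(grid, "kernel_size") - 1L) %/% 2L) {
  k <- attr(grid, "kernel_size")
  n_off <- 2L * nrow(grid)
  if (is.null(weights)) weights <- array(0, dim = c(n_off, dim(input)[2], k, k))
  if (is.null(bias)) bias <- numeric(n_off)
  conv2d(input, weights, bias, stride = stride, pad = pad)
}

# Collect all ag_param leaves from a nested structure of layers.
collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (is.environment(v) && !is.null(v$params)) {
      for (p in v$params) out[[length(out) + 1L]] <<- p
      for (nm in names(v)) if (nm %in% c("layers", "blocks")) walk(v[[nm]])
    } else if (is.list(v)) {
      for (el in v) walk(el)
    }
  }
  walk(x)
  out
}
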