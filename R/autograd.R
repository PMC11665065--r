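# Minimal reverse-mode autodiff over dense R arrays.
#
# A node is an environment holding `value` (numeric array), `grad`,
# `parents` (list of nodes) and `backward` (function(grad) -> list of
# gradients aligned with `parents`, or NULL for parents that need none).
# The graph is built eagerly by the op constructors; `ag_backward()` runs a
# topological sweep from a scalar root.

.ag_state <- new.env(parent = emptyenv())
.ag_state$counter <- 0L

new_ag <- function(value, parents = list(), backward = NULL,
                   requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  .ag_state$counter <- .ag_state$counter + 1L
  e$id <- .ag_state$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  class(e) <- "ag_node"
  e
}

#' Create a trainable tensor node
#'
#' Wraps a numeric array as a leaf node of the autodiff graph that
#' accumulates gradients during the backward pass.
#'
#' @param value numeric array (any shape).
#' @return an `ag_node` with `requires_grad = TRUE`.
#' @keywords internal
ag_param <- function(value) new_ag(value, requires_grad = TRUE)

ag_const <- function(value) new_ag(value)

is_ag <- function(x) inherits(x, "ag_node")

as_ag <- function(x) if (is_ag(x)) x else ag_const(x)

ag_value <- function(x) if (is_ag(x)) x$value else x

#' @export
print.ag_node <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_node ", if (is.null(d)) length(x$value) else paste(d, collapse = "x"),
      if (x$requires_grad) " grad" else "", ">\n", sep = "")
  invisible(x)
}

# Topological order by iterative DFS (post-order), then reverse sweep.
ag_backward <- function(root, seed = 1) {
  stopifnot(is_ag(root))
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    id <- as.character(top$node$id)
    if (top$expanded) {
      order[[length(order) + 1L]] <- top$node
      next
    }
    if (!is.null(seen[[id]])) next
    seen[[id]] <- TRUE
    stack[[length(stack) + 1L]] <- list(node = top$node, expanded = TRUE)
    for (p in top$node$parents)
      if (p$requires_grad && is.null(seen[[as.character(p$id)]]))
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
  }
  root$grad <- if (is.null(dim(root$value))) rep(seed, length(root$value))
               else array(seed, dim = dim(root$value))
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    grads <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$requires_grad || is.null(grads[[j]])) next
      p$grad <- if (is.null(p$grad)) grads[[j]] else p$grad + grads[[j]]
    }
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ------------------------------------------------------------ elementwise ---

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag(a$value * b$value, list(a, b),
         function(g) list(g * b$value, g * a$value))
}

ag_scale <- function(a, s) {
  new_ag(a$value * s, list(a), function(g) list(g * s))
}

ag_relu <- function(a) {
  mask <- a$value > 0
  new_ag(a$value * mask, list(a), function(g) list(g * mask))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  new_ag(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_log <- function(a) {
  new_ag(log(a$value), list(a), function(g) list(g / a$value))
}

ag_pow_const <- function(a, k) {
  new_ag(a$value^k, list(a), function(g) list(g * k * a$value^(k - 1)))
}

# clamp with zero gradient outside [lo, hi]
ag_clamp <- function(a, lo, hi) {
  inside <- a$value >= lo & a$value <= hi
  new_ag(pmin(pmax(a$value, lo), hi), list(a), function(g) list(g * inside))
}

ag_sum <- function(a) {
  d <- dim(a$value)
  new_ag(sum(a$value), list(a), function(g) list(array(g, dim = d)))
}

ag_mean <- function(a) {
  n <- length(a$value)
  d <- dim(a$value)
  new_ag(sum(a$value) / n, list(a), function(g) list(array(g / n, dim = d)))
}

# ------------------------------------------------------------ shape ops ----

ag_reshape <- function(a, newdim) {
  olddim <- dim(a$value)
  v <- a$value
  dim(v) <- newdim
  new_ag(v, list(a), function(g) { dim(g) <- olddim; list(g) })
}

ag_aperm <- function(a, perm) {
  inv <- order(perm)
  new_ag(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_ag(a$value %*% b$value, list(a, b),
         function(g) list(g %*% t(b$value), t(a$value) %*% g))
}

# softmax over rows of a matrix
ag_softmax_rows <- function(a) {
  m <- a$value - apply(a$value, 1, max)
  e <- exp(m)
  s <- e / rowSums(e)
  new_ag(s, list(a), function(g) list(s * (g - rowSums(g * s))))
}

# x[n, , , ] of an (N,C,H,W) tensor as a (C, H*W) matrix
ag_subset_batch <- function(a, n) {
  d <- dim(a$value)
  v <- a$value[n, , , , drop = FALSE]
  dim(v) <- c(d[2], d[3] * d[4])
  new_ag(v, list(a), function(g) {
    gx <- array(0, dim = d)
    dim(g) <- c(d[2], d[3], d[4])
    gx[n, , , ] <- g
    list(gx)
  })
}

# assemble a list of (C, H*W) matrices back into an (N,C,H,W) tensor
ag_stack_batch <- function(nodes, chw) {
  N <- length(nodes)
  v <- array(0, dim = c(N, chw[1], chw[2], chw[3]))
  for (n in seq_len(N)) {
    m <- nodes[[n]]$value
    dim(m) <- chw
    v[n, , , ] <- m
  }
  new_ag(v, nodes, function(g) {
    lapply(seq_len(N), function(n) {
      gn <- g[n, , , , drop = FALSE]
      dim(gn) <- c(chw[1], chw[2] * chw[3])
      gn
    })
  })
}

# append constant channels (e.g. coordinate maps) along dim 2
ag_concat_channels <- function(a, const_chans) {
  d <- dim(a$value)
  k <- dim(const_chans)[2]
  v <- array(0, dim = c(d[1], d[2] + k, d[3], d[4]))
  v[, seq_len(d[2]), , ] <- a$value
  v[, d[2] + seq_len(k), , ] <- const_chans
  new_ag(v, list(a), function(g) list(g[, seq_len(d[2]), , , drop = FALSE]))
}

# pick one channel of an (N,C,H,W) tensor as an (H,W) matrix (batch index n)
ag_slice_channel <- function(a, n, c) {
  d <- dim(a$value)
  v <- a$value[n, c, , ]
  new_ag(v, list(a), function(g) {
    gx <- array(0, dim = d)
    gx[n, c, , ] <- g
    list(gx)
  })
}

# ------------------------------------------------------------ cnn ops ------

ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  y <- cpp_conv2d_fwd(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  new_ag(y, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(x$value, w$value, g, as.integer(stride), as.integer(pad))
    list(r$gx, r$gw, r$gb)
  })
}

ag_dconv2d <- function(x, w, b, off, stride = 1L, pad = 0L, dilation = 1L) {
  y <- cpp_dconv2d_fwd(x$value, w$value, b$value, off$value,
                       as.integer(stride), as.integer(pad), as.integer(dilation))
  new_ag(y, list(x, w, b, off), function(g) {
    r <- cpp_dconv2d_bwd(x$value, w$value, off$value, g,
                         as.integer(stride), as.integer(pad), as.integer(dilation))
    list(r$gx, r$gw, r$gb, r$goff)
  })
}

ag_maxpool <- function(x, k, stride = k, pad = 0L) {
  r <- cpp_maxpool_fwd(x$value, as.integer(k), as.integer(stride), as.integer(pad))
  xd <- dim(x$value)
  new_ag(r$y, list(x), function(g)
    list(cpp_maxpool_bwd(g, r$argmax, as.integer(xd))))
}

ag_resize <- function(x, out_h, out_w) {
  xd <- dim(x$value)
  if (xd[3] == out_h && xd[4] == out_w) return(x)
  y <- cpp_resize_fwd(x$value, as.integer(out_h), as.integer(out_w))
  new_ag(y, list(x), function(g) list(cpp_resize_bwd(g, as.integer(xd))))
}

# ------------------------------------------------------------ batch norm ---
#
# Standard batch normalization over (N, H, W) per channel; `state` is the
# layer environment carrying running_mean / running_var / momentum.

ag_batchnorm <- function(x, gamma, beta, state, training = TRUE, eps = 1e-5) {
  d <- dim(x$value)
  m <- d[1] * d[3] * d[4]
  xm <- aperm(x$value, c(1, 3, 4, 2))
  dim(xm) <- c(m, d[2])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
    state$running_mean <- (1 - state$momentum) * state$running_mean + state$momentum * mu
    state$running_var <- (1 - state$momentum) * state$running_var + state$momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  sd_ <- sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, sd_, "/")
  ym <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  dim(ym) <- c(d[1], d[3], d[4], d[2])
  y <- aperm(ym, c(1, 4, 2, 3))
  new_ag(y, list(x, gamma, beta), function(g) {
    gm <- aperm(g, c(1, 3, 4, 2))
    dim(gm) <- c(m, d[2])
    gbeta <- colSums(gm)
    ggamma <- colSums(gm * xhat)
    if (training) {
      gxhat <- sweep(gm, 2, gamma$value, "*")
      gx <- sweep(
        gxhat - matrix(colMeans(gxhat), m, d[2], byrow = TRUE) -
          xhat * matrix(colMeans(gxhat * xhat), m, d[2], byrow = TRUE),
        2, sd_, "/")
    } else {
      gx <- sweep(sweep(gm, 2, gamma$value, "*"), 2, sd_, "/")
    }
    dim(gx) <- c(d[1], d[3], d[4], d[2])
    list(aperm(gx, c(1, 4, 2, 3)), ggamma, gbeta)
  })
}
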