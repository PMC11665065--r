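# Small shared helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 4-D tensor constructor: dim (N, C, H, W)
tensor4 <- function(data, n, c, h, w) array(data, dim = c(n, c, h, w))

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
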