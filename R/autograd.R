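# Tape-based reverse-mode automatic differentiation over base R matrices.
#
# Every differentiable quantity is a "node": an environment holding a value
# (a numeric matrix, pixels-by-channels for feature maps), a requires-grad
# flag, and, for non-leaves, vector-Jacobian-product closures back to its
# parents. ag_backward() walks the tape in reverse creation order, so the
# forward pass must create nodes in topological order (it always does, since
# node creation *is* the forward pass).

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, value, parents = NULL, vjps = NULL,
                    requires_grad = NULL) {
  nd <- new.env(parent = emptyenv())
  if (is.null(requires_grad)) {
    requires_grad <- any(vapply(parents, function(p) p$rg, logical(1)))
  }
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  nd$value <- value
  nd$parents <- parents
  nd$vjps <- vjps
  nd$grad <- NULL
  nd$rg <- requires_grad
  tape$nodes[[tape$n]] <- nd
  nd
}

#' @noRd
ag_leaf <- function(tape, value, requires_grad = TRUE) {
  ag_node(tape, value, requires_grad = requires_grad)
}

ag_const <- function(tape, value) ag_leaf(tape, value, requires_grad = FALSE)

# Accumulate gradients of `loss` (a scalar node) into every requires-grad
# node on the tape. Subgraphs with rg = FALSE are skipped entirely.
ag_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq.int(loss$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$parents)) next
    g <- nd$grad
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!p$rg) next
      contrib <- nd$vjps[[j]](g)
      p$grad <- if (is.null(p$grad)) contrib else p$grad + contrib
    }
    nd$grad <- NULL # free as we go
  }
  invisible(loss)
}

## ---- elementwise and linear-algebra primitives -----------------------------

ag_add <- function(a, b, tape) {
  ag_node(tape, a$value + b$value, list(a, b),
          list(function(g) g, function(g) g))
}

# x: n-by-C matrix node, b: length-C bias node
ag_add_bias <- function(x, b, tape) {
  ag_node(tape, sweep(x$value, 2L, as.vector(b$value), "+"), list(x, b),
          list(function(g) g, function(g) colSums(g)))
}

ag_matmul <- function(a, b, tape) {
  av <- a$value; bv <- b$value
  ag_node(tape, av %*% bv, list(a, b),
          list(function(g) g %*% t(bv), function(g) crossprod(av, g)))
}

ag_scale <- function(a, s, tape) {
  ag_node(tape, a$value * s, list(a), list(function(g) g * s))
}

ag_relu <- function(x, tape) {
  mask <- x$value > 0
  ag_node(tape, x$value * mask, list(x), list(function(g) g * mask))
}

# Exact Gaussian-CDF GELU: x * pnorm(x).
ag_gelu <- function(x, tape) {
  xv <- x$value
  ph <- stats::pnorm(xv)
  ag_node(tape, xv * ph, list(x),
          list(function(g) g * (ph + xv * stats::dnorm(xv))))
}

# Row gather: y = x[idx, ]. Used for cyclic shifts, window (de)partition,
# cropping. Backward scatter-adds.
ag_index_rows <- function(x, idx, tape) {
  n_in <- nrow(x$value)
  ag_node(tape, x$value[idx, , drop = FALSE], list(x), list(function(g) {
    out <- matrix(0, n_in, ncol(g))
    rs <- rowsum(g, idx)
    out[as.integer(rownames(rs)), ] <- rs
    out
  }))
}

# Row scatter into a larger zero matrix: y[idx, ] = x. Used for zero-stuffing
# in transposed convolution.
ag_embed_rows <- function(x, idx, n_out, tape) {
  v <- matrix(0, n_out, ncol(x$value))
  v[idx, ] <- x$value
  ag_node(tape, v, list(x), list(function(g) g[idx, , drop = FALSE]))
}

ag_cbind <- function(a, b, tape) {
  ca <- ncol(a$value)
  ag_node(tape, cbind(a$value, b$value), list(a, b),
          list(function(g) g[, seq_len(ca), drop = FALSE],
               function(g) g[, -seq_len(ca), drop = FALSE]))
}

# Mean squared error against a constant target; the scalar training loss.
ag_mse <- function(pred, target, tape) {
  d <- pred$value - target
  n <- length(d)
  ag_node(tape, mean(d * d), list(pred),
          list(function(g) g * (2 / n) * d))
}

# Mean of all entries (used for gradient-connectivity checks).
ag_mean <- function(x, tape) {
  n <- length(x$value)
  dims <- dim(x$value)
  ag_node(tape, mean(x$value), list(x),
          list(function(g) array(g / n, dims)))
}

## ---- LayerNorm over channels ----------------------------------------------

# x: n-by-C; gamma, beta: length-C nodes. Normalizes each row (token) over
# its C channels.
ag_layernorm <- function(x, gamma, beta, tape, eps = 1e-5) {
  xv <- x$value
  C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$value)
  y <- sweep(xhat, 2L, gv, "*")
  y <- sweep(y, 2L, as.vector(beta$value), "+")
  ag_node(tape, y, list(x, gamma, beta), list(
    function(g) {
      dxhat <- sweep(g, 2L, gv, "*")
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    },
    function(g) colSums(g * xhat),
    function(g) colSums(g)
  ))
}
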