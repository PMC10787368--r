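# Network layer primitives on top of the autodiff tape.
#
# Feature maps are stored as (H*W)-by-C matrices with row-major pixel order:
# pixel (r, c) lives at row (r-1)*W + c. Convolutions are im2col gathers
# followed by one matrix multiply; geometry (gather indices) is cached per
# (H, W, k, stride, pad) so repeated forward passes only pay for the matmul.

.geom_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (is.null(.geom_cache[[key]])) .geom_cache[[key]] <- make()
  .geom_cache[[key]]
}

# im2col geometry for a k-by-k convolution with given stride and zero pad.
conv_geom <- function(H, W, k, stride, pad) {
  key <- paste("conv", H, W, k, stride, pad, sep = "_")
  cache_get(key, function() {
    Hp <- H + 2L * pad; Wp <- W + 2L * pad
    Ho <- (Hp - k) %/% stride + 1L
    Wo <- (Wp - k) %/% stride + 1L
    n_out <- Ho * Wo
    ro <- rep(seq_len(Ho), each = Wo)
    co <- rep(seq_len(Wo), times = Ho)
    r0 <- (ro - 1L) * stride   # 0-based top-left row in padded image
    c0 <- (co - 1L) * stride
    K <- matrix(0L, n_out, k * k)
    t <- 0L
    for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
      t <- t + 1L
      K[, t] <- (r0 + dr) * Wp + (c0 + dc + 1L)
    }
    # positions of the original pixels inside the padded image
    rr <- rep(seq_len(H), each = W)
    cc <- rep(seq_len(W), times = H)
    inner <- (rr + pad - 1L) * Wp + (cc + pad)
    list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, n_out = n_out,
         K = as.vector(K), k2 = k * k, inner = inner)
  })
}

conv_im2col <- function(xv, geom) {
  C <- ncol(xv)
  Xpad <- matrix(0, geom$Hp * geom$Wp, C)
  Xpad[geom$inner, ] <- xv
  G <- Xpad[geom$K, , drop = FALSE]        # (n_out*k2) x C, output-pixel fastest
  matrix(G, nrow = geom$n_out)             # n_out x (k2*C), col = (ci-1)*k2 + t
}

conv_col2im <- function(dXcol, geom, C_in) {
  dG <- matrix(as.vector(dXcol), nrow = geom$n_out * geom$k2)
  rs <- rowsum(dG, geom$K)
  dXpad <- matrix(0, geom$Hp * geom$Wp, C_in)
  dXpad[as.integer(rownames(rs)), ] <- rs
  dXpad[geom$inner, , drop = FALSE]
}

# x: (H*W) x C_in node; w: (k2*C_in) x C_out node with row order
# (channel-major, tap-minor) matching conv_im2col; b: length-C_out node.
ag_conv2d <- function(x, w, b, H, W, tape, k = 3L, stride = 1L, pad = 1L) {
  geom <- conv_geom(H, W, k, stride, pad)
  C_in <- ncol(x$value)
  Xcol <- conv_im2col(x$value, geom)
  wv <- w$value
  y <- sweep(Xcol %*% wv, 2L, as.vector(b$value), "+")
  nd <- ag_node(tape, y, list(x, w, b), list(
    function(g) conv_col2im(g %*% t(wv), geom, C_in),
    function(g) crossprod(Xcol, g),
    function(g) colSums(g)
  ))
  attr(nd, "out_hw") <- c(geom$Ho, geom$Wo)
  nd
}

# Transposed convolution: zero-stuff the input into a canvas, then run a
# stride-1 valid convolution. With k = 3 the canvas padding (left 1 /
# right 2 for stride 2, 1/1 for stride 1) makes the output exactly
# stride * H, matching the head's downsampling factor on the way back up.
tconv_geom <- function(H, W, k, stride) {
  key <- paste("tconv", H, W, k, stride, sep = "_")
  cache_get(key, function() {
    pl <- k - 2L                            # 1 for k = 3
    pr <- if (stride == 2L) k - 1L else k - 2L
    Hc <- (H - 1L) * stride + 1L + pl + pr
    Wc <- (W - 1L) * stride + 1L + pl + pr
    rr <- rep(seq_len(H), each = W)
    cc <- rep(seq_len(W), times = H)
    stuff <- ((rr - 1L) * stride + pl) * Wc + ((cc - 1L) * stride + pl + 1L)
    list(Hc = Hc, Wc = Wc, stuff = stuff,
         Ho = Hc - k + 1L, Wo = Wc - k + 1L)
  })
}

ag_conv_transpose2d <- function(x, w, b, H, W, tape, k = 3L, stride = 2L) {
  tg <- tconv_geom(H, W, k, stride)
  z <- ag_embed_rows(x, tg$stuff, tg$Hc * tg$Wc, tape)
  ag_conv2d(z, w, b, tg$Hc, tg$Wc, tape, k = k, stride = 1L, pad = 0L)
}

# Non-overlapping 2x2 max pooling. Each input pixel feeds exactly one
# window, so the backward scatter needs no accumulation.
ag_maxpool2 <- function(x, H, W, tape) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  key <- paste("pool", H, W, sep = "_")
  idx <- cache_get(key, function() {
    ro <- rep(seq_len(Ho), each = Wo); co <- rep(seq_len(Wo), times = Ho)
    r0 <- (ro - 1L) * 2L; c0 <- (co - 1L) * 2L
    cbind((r0) * W + c0 + 1L, (r0) * W + c0 + 2L,
          (r0 + 1L) * W + c0 + 1L, (r0 + 1L) * W + c0 + 2L)
  })
  xv <- x$value
  C <- ncol(xv)
  n_in <- nrow(xv)
  best <- xv[idx[, 1L], , drop = FALSE]
  arg <- matrix(idx[, 1L], nrow(best), C)
  for (j in 2:4) {
    cand <- xv[idx[, j], , drop = FALSE]
    better <- cand > best
    best[better] <- cand[better]
    arg[better] <- matrix(idx[, j], nrow(best), C)[better]
  }
  ag_node(tape, best, list(x), list(function(g) {
    dx <- numeric(n_in * C)
    pos <- as.vector(arg + (col(arg) - 1L) * n_in)
    dx[pos] <- as.vector(g)
    matrix(dx, n_in, C)
  }))
}

## ---- window utilities ------------------------------------------------------

# Permutation that reorders row-major pixels into window-major token order:
# windows in row-major tile order, tokens row-major within each window.
window_perm <- function(H, W, M) {
  key <- paste("wperm", H, W, M, sep = "_")
  cache_get(key, function() {
    stopifnot(H %% M == 0L, W %% M == 0L)
    perm <- integer(H * W)
    k <- 0L
    for (wr in seq_len(H %/% M)) for (wc in seq_len(W %/% M)) {
      for (i in seq_len(M)) for (j in seq_len(M)) {
        k <- k + 1L
        perm[k] <- ((wr - 1L) * M + i - 1L) * W + (wc - 1L) * M + j
      }
    }
    perm
  })
}

inverse_perm <- function(p) {
  inv <- integer(length(p))
  inv[p] <- seq_along(p)
  inv
}

# Cyclic up-left shift by s: shifted(r, c) = x(r + s mod H, c + s mod W).
shift_perm <- function(H, W, s) {
  key <- paste("shift", H, W, s, sep = "_")
  cache_get(key, function() {
    r <- ((seq_len(H) - 1L + s) %% H) + 1L
    c <- ((seq_len(W) - 1L + s) %% W) + 1L
    as.vector(t(outer((r - 1L) * W, c, "+")))
  })
}

# Relative-position index: M^2 x M^2 matrix of 1-based rows into the
# (2M-1)^2 bias table, indexed purely by in-window coordinate differences.
rel_pos_index <- function(M) {
  key <- paste("rpi", M, sep = "_")
  cache_get(key, function() {
    ri <- rep(seq_len(M), each = M); ci <- rep(seq_len(M), times = M)
    dr <- outer(ri, ri, "-") + M          # 1 .. 2M-1
    dc <- outer(ci, ci, "-") + M
    (dr - 1L) * (2L * M - 1L) + dc
  })
}

# Attention masks for shifted windows: region labels in the shifted frame
# (cuts at H-M and H-s); token pairs with different labels may not attend.
# A dimension no larger than the window contributes a single region, so a
# one-window map is shifted without masking.
swin_masks <- function(H, W, M, s) {
  key <- paste("mask", H, W, M, s, sep = "_")
  cache_get(key, function() {
    lab1 <- function(n) {
      if (n <= M) return(rep(0L, n))
      l <- integer(n)
      l[seq_len(n) > n - M] <- 1L
      l[seq_len(n) > n - s] <- 2L
      l
    }
    lh <- lab1(H); lw <- lab1(W)
    lab <- as.vector(t(outer(lh * 3L, lw, "+")))   # row-major H*W labels
    labw <- lab[window_perm(H, W, M)]
    M2 <- M * M
    n_win <- (H * W) %/% M2
    masks <- vector("list", n_win)
    any_masked <- FALSE
    for (w in seq_len(n_win)) {
      lw_ <- labw[((w - 1L) * M2 + 1L):(w * M2)]
      m <- outer(lw_, lw_, "!=") * -1e9
      if (any(m != 0)) any_masked <- TRUE
      masks[[w]] <- m
    }
    if (!any_masked) return(NULL)
    masks
  })
}

## ---- windowed multi-head self-attention ------------------------------------

# x: (n_win*M2) x C node in window-major token order. p: named list of
# parameter nodes (pq, bq, pk, bk, pv, bv, po, bo, btab). btab has
# (2M-1)^2 rows and n_heads columns. masks: NULL or list of M2 x M2
# additive logit masks, one per window. Forward and all vector-Jacobian
# products are computed in one closure and memoized, because the grads of
# all ten parents share the same intermediates.
ag_window_mha <- function(x, p, n_win, M, n_heads, tape, masks = NULL) {
  xv <- x$value
  C <- ncol(xv)
  d <- C %/% n_heads
  M2 <- M * M
  rpi <- rel_pos_index(M)
  sc <- 1 / sqrt(d)

  Qf <- sweep(xv %*% p$pq$value, 2L, as.vector(p$bq$value), "+")
  Kf <- sweep(xv %*% p$pk$value, 2L, as.vector(p$bk$value), "+")
  Vf <- sweep(xv %*% p$pv$value, 2L, as.vector(p$bv$value), "+")
  Bg <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    Bg[[h]] <- matrix(p$btab$value[rpi, h], M2, M2)
  }
  O <- matrix(0, nrow(xv), C)
  Aws <- vector("list", n_win * n_heads)
  for (w in seq_len(n_win)) {
    rows <- ((w - 1L) * M2 + 1L):(w * M2)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      S <- tcrossprod(Qf[rows, cols, drop = FALSE],
                      Kf[rows, cols, drop = FALSE]) * sc + Bg[[h]]
      if (!is.null(masks)) S <- S + masks[[w]]
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      A <- E / rowSums(E)
      Aws[[(w - 1L) * n_heads + h]] <- A
      O[rows, cols] <- A %*% Vf[rows, cols, drop = FALSE]
    }
  }
  out <- sweep(O %*% p$po$value, 2L, as.vector(p$bo$value), "+")

  memo <- new.env(parent = emptyenv())
  backall <- function(g) {
    if (!is.null(memo$done)) return(memo$grads)
    pov <- p$po$value
    dO <- g %*% t(pov)
    dQf <- matrix(0, nrow(xv), C); dKf <- dQf; dVf <- dQf
    dBtab <- matrix(0, nrow(p$btab$value), n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      dBg <- matrix(0, M2, M2)
      for (w in seq_len(n_win)) {
        rows <- ((w - 1L) * M2 + 1L):(w * M2)
        A <- Aws[[(w - 1L) * n_heads + h]]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- Vf[rows, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dVf[rows, cols] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dBg <- dBg + dS
        dQf[rows, cols] <- dS %*% Kf[rows, cols, drop = FALSE] * sc
        dKf[rows, cols] <- crossprod(dS, Qf[rows, cols, drop = FALSE]) * sc
      }
      rs <- rowsum(as.vector(dBg), as.vector(rpi))
      dBtab[as.integer(rownames(rs)), h] <- rs
    }
    memo$grads <- list(
      x = dQf %*% t(p$pq$value) + dKf %*% t(p$pk$value) +
        dVf %*% t(p$pv$value),
      pq = crossprod(xv, dQf), bq = colSums(dQf),
      pk = crossprod(xv, dKf), bk = colSums(dKf),
      pv = crossprod(xv, dVf), bv = colSums(dVf),
      po = crossprod(O, g), bo = colSums(g),
      btab = dBtab)
    memo$done <- TRUE
    memo$grads
  }
  pick <- function(nm) function(g) backall(g)[[nm]]
  ag_node(tape, out,
          list(x, p$pq, p$bq, p$pk, p$bk, p$pv, p$bv, p$po, p$bo, p$btab),
          list(pick("x"), pick("pq"), pick("bq"), pick("pk"), pick("bk"),
               pick("pv"), pick("bv"), pick("po"), pick("bo"), pick("btab")))
}
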