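# Desk-scale study conditions shared across test files, with memoization so
# expensive fixtures (datasets, training runs) are built once per session.
#
# The synthetic conditions: 64 x 64 fields of view, 6 FOVs x 3 timestamps,
# peak signal 800 photons over a 500-count baseline, bleaching losing ~55%
# of signal per timestamp so timestamps 2-3 are strongly degraded; vesicle
# data additionally carries a honeycomb artifact. Training uses the tiny
# Swin configuration (C = 24, 2 RSTBs of 2 STLs, window 4) and Adam 1e-3.

.desk_cache <- new.env(parent = emptyenv())

desk_memo <- function(key, fn) {
  if (is.null(.desk_cache[[key]])) .desk_cache[[key]] <- fn()
  .desk_cache[[key]]
}

desk_synth_config <- function(kind, seed) {
  synthetic_config(structure_kind = kind, image_size = 64, n_fovs = 6,
                   n_timestamps = 3, n_objects = 6, peak_signal = 800,
                   bleach_rate = 0.8, read_noise_sigma = 2,
                   baseline_offset = 500, honeycomb_amplitude = 0.3,
                   honeycomb_period = 8, seed = seed)
}

tiny_swint_config <- function() {
  swint_config(n_rstb = 2, n_stl = 2, window_size = 4, channels = 24,
               n_heads = 4)
}

# generated dataset directory, memoized by (kind, seed)
desk_dataset <- function(kind, seed) {
  desk_memo(paste("data", kind, seed, sep = "_"), function() {
    dir <- file.path(tempdir(), paste0("desk_", kind, "_", seed))
    generate_dataset(desk_synth_config(kind, seed), dir)
    dir
  })
}

# train/test manifests: inputs are timestamps 2-3, last 2 FOVs held out
desk_split <- function(kind, seed) {
  sp <- split_train_test(pairs_from_dataset(desk_dataset(kind, seed),
                                            c(2, 3)),
                         n_test_fovs = 2)
  sp
}

# the scaled-down scratch-training run: 8 filament pairs, 30 epochs
desk_scratch_run <- function() {
  desk_memo("scratch_run", function() {
    sp <- desk_split("filament", 101)
    tc <- train_config(epochs = 30, learning_rate = 1e-3, crop_size = 64,
                       seed = 1)
    train(swint_model(tiny_swint_config(), seed = 1), sp$train, tc)
  })
}

# brute-force dense windowed attention with explicit softmax loops; the
# independent oracle for the tape implementation
dense_window_attention <- function(X, p, M, n_heads, masks = NULL,
                                   rpi = NULL) {
  C <- ncol(X); d <- C %/% n_heads; M2 <- M * M
  n_win <- nrow(X) %/% M2
  if (is.null(rpi)) {
    ri <- rep(seq_len(M), each = M); ci <- rep(seq_len(M), times = M)
    dr <- outer(ri, ri, "-") + M
    dc <- outer(ci, ci, "-") + M
    rpi <- (dr - 1L) * (2L * M - 1L) + dc
  }
  Q <- sweep(X %*% p$pq, 2, p$bq, "+")
  K <- sweep(X %*% p$pk, 2, p$bk, "+")
  V <- sweep(X %*% p$pv, 2, p$bv, "+")
  O <- matrix(0, nrow(X), C)
  for (w in seq_len(n_win)) {
    rows <- ((w - 1L) * M2 + 1L):(w * M2)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      for (ii in seq_len(M2)) {
        i <- rows[ii]
        s <- numeric(M2)
        for (jj in seq_len(M2)) {
          s[jj] <- sum(Q[i, cols] * K[rows[jj], cols]) / sqrt(d) +
            p$btab[rpi[ii, jj], h]
          if (!is.null(masks)) s[jj] <- s[jj] + masks[[w]][ii, jj]
        }
        a <- exp(s - max(s))
        a <- a / sum(a)
        O[i, cols] <- colSums(a * V[rows, cols, drop = FALSE])
      }
    }
  }
  sweep(O %*% p$po, 2, p$bo, "+")
}

# 4-connected flood-fill component count on a logical matrix
flood_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    n <- n + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- n
    while (length(queue) > 0L) {
      rc <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r <- rc[1] + d[1]; c <- rc[2] + d[2]
        if (r >= 1L && r <= nrow(mask) && c >= 1L && c <= ncol(mask) &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- n
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  n
}

# type-7 quantile by explicit sort and linear interpolation
sort_quantile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
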