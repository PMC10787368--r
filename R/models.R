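# Model architectures: SwinT-fairSIM (compression head, residual Swin
# Transformer blocks, decompression tail), the 30-layer residual
# encoder-decoder baseline (Red-fairSIM) and the 4-level U-Net baseline
# (UNet-fairSIM). A model is a plain list: architecture tag, config, named
# parameter arrays and a named logical trainable mask. Forward passes build
# an autodiff tape so the same code serves inference and training.

#' SwinT-fairSIM architecture hyperparameters
#'
#' Defaults pin the published configuration: 5 residual Swin Transformer
#' blocks (RSTBs) of 5 Swin Transformer layers (STLs) each, window size 8,
#' and 120 feature channels, read as the embedding width with 6 attention
#' heads. The MLP hidden width is `mlp_ratio * channels`; the shifted
#' window offset is `window_size / 2`.
#'
#' @param n_rstb Number of residual Swin Transformer blocks.
#' @param n_stl Number of Swin Transformer layers per block.
#' @param window_size Attention window side length M (pixels).
#' @param channels Embedding width C; must be divisible by `n_heads`.
#' @param n_heads Number of attention heads.
#' @param mlp_ratio Hidden-layer expansion of the per-token MLP.
#' @return An object of class `swint_config`.
#' @export
swint_config <- function(n_rstb = 5L, n_stl = 5L, window_size = 8L,
                         channels = 120L, n_heads = 6L, mlp_ratio = 2) {
  stopifnot(n_rstb >= 1L, n_stl >= 1L, window_size >= 1L,
            channels %% n_heads == 0L)
  shift <- window_size %/% 2L
  stopifnot(shift < window_size)
  structure(list(n_rstb = as.integer(n_rstb), n_stl = as.integer(n_stl),
                 window_size = as.integer(window_size),
                 channels = as.integer(channels),
                 n_heads = as.integer(n_heads), mlp_ratio = mlp_ratio,
                 shift = shift),
            class = "swint_config")
}

# truncated normal on [-2sd, 2sd], the usual transformer init
rtruncnorm02 <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

init_linear <- function(n_in, n_out) {
  matrix(rtruncnorm02(n_in * n_out), n_in, n_out)
}

# Kaiming (He) initialization; fan-in = k2 * C_in rows of the im2col weight
init_conv <- function(k2_cin, c_out) {
  matrix(stats::rnorm(k2_cin * c_out, sd = sqrt(2 / k2_cin)), k2_cin, c_out)
}

new_attn_params <- function(C, M, n_heads) {
  list(pq = init_linear(C, C), bq = numeric(C),
       pk = init_linear(C, C), bk = numeric(C),
       pv = init_linear(C, C), bv = numeric(C),
       po = init_linear(C, C), bo = numeric(C),
       btab = matrix(rtruncnorm02((2L * M - 1L)^2 * n_heads),
                     (2L * M - 1L)^2, n_heads))
}

flatten_params <- function(lst, prefix = "") {
  out <- list()
  for (nm in names(lst)) {
    v <- lst[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else out[[key]] <- v
  }
  out
}

new_model <- function(arch, config, params) {
  structure(list(arch = arch, config = config, params = params,
                 trainable = stats::setNames(rep(TRUE, length(params)),
                                             names(params))),
            class = c(paste0(arch, "_model"), "sim_model"))
}

#' Build a SwinT-fairSIM model
#'
#' Compression head (three 3x3 convolutions, the first two with stride 2),
#' `n_rstb` residual Swin Transformer blocks with a global residual, and a
#' decompression tail (three 3x3 transposed convolutions, the first two with
#' stride 2, plus the 1-channel output convolution). Head and tail stages at
#' matching resolution are joined by additive skip connections.
#'
#' @param config A [swint_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `sim_model` with named parameters and an all-trainable mask.
#' @export
swint_model <- function(config = swint_config(), seed = 1L) {
  with_seed(seed, {
    C <- config$channels; M <- config$window_size; H <- config$n_heads
    mlp_h <- as.integer(round(config$mlp_ratio * C))
    p <- list(
      head = list(conv1 = list(w = init_conv(9L, C), b = numeric(C)),
                  conv2 = list(w = init_conv(9L * C, C), b = numeric(C)),
                  conv3 = list(w = init_conv(9L * C, C), b = numeric(C))))
    for (r in seq_len(config$n_rstb)) {
      blk <- list()
      for (l in seq_len(config$n_stl)) {
        blk[[paste0("stl", l)]] <- list(
          ln1 = list(g = rep(1, C), b = numeric(C)),
          attn = new_attn_params(C, M, H),
          ln2 = list(g = rep(1, C), b = numeric(C)),
          mlp = list(w1 = init_linear(C, mlp_h), b1 = numeric(mlp_h),
                     w2 = init_linear(mlp_h, C), b2 = numeric(C)))
      }
      blk$conv <- list(w = init_conv(9L * C, C), b = numeric(C))
      p[[paste0("rstb", r)]] <- blk
    }
    p$tail <- list(
      tconv1 = list(w = init_conv(9L * C, C), b = numeric(C)),
      tconv2 = list(w = init_conv(9L * C, C), b = numeric(C)),
      tconv3 = list(w = init_conv(9L * C, C), b = numeric(C)),
      conv_out = list(w = init_conv(9L * C, 1L), b = numeric(1L)))
    new_model("swint", config, flatten_params(p))
  })
}

#' Build a Red-fairSIM baseline (30-layer residual encoder-decoder)
#'
#' 15 convolutional then 15 transposed-convolutional layers, all 3x3 with 64
#' channels and unit stride, ReLU activations, and additive skip connections
#' from every second encoder layer to the mirrored decoder layer.
#'
#' @param channels Feature width (64 in the published configuration).
#' @param n_layers Total weighted layers; must be even (30 published).
#' @param seed Integer seed for weight initialization.
#' @export
red_model <- function(channels = 64L, n_layers = 30L, seed = 1L) {
  stopifnot(n_layers %% 2L == 0L)
  with_seed(seed, {
    C <- as.integer(channels)
    p <- list()
    for (i in seq_len(n_layers)) {
      cin <- if (i == 1L) 1L else C
      cout <- if (i == n_layers) 1L else C
      p[[paste0("layer", i)]] <- list(w = init_conv(9L * cin, cout),
                                      b = numeric(cout))
    }
    new_model("red", list(channels = C, n_layers = as.integer(n_layers)),
              flatten_params(p))
  })
}

#' Build a UNet-fairSIM baseline (4-level U-Net)
#'
#' Three encoder blocks (64, 128, 256 channels) with 2x2 max pooling, a
#' 512-channel bottleneck, three decoder blocks with transposed-convolution
#' upsampling and concatenation skips, and a 1-channel output convolution.
#' Every block holds two 3x3 convolutions with ReLU.
#'
#' @param base Channel width of the first level.
#' @param seed Integer seed for weight initialization.
#' @export
unet_model <- function(base = 64L, seed = 1L) {
  with_seed(seed, {
    b <- as.integer(base)
    ch <- c(b, 2L * b, 4L * b, 8L * b)
    blk <- function(cin, cout) list(
      conv1 = list(w = init_conv(9L * cin, cout), b = numeric(cout)),
      conv2 = list(w = init_conv(9L * cout, cout), b = numeric(cout)))
    p <- list(enc1 = blk(1L, ch[1]), enc2 = blk(ch[1], ch[2]),
              enc3 = blk(ch[2], ch[3]), bott = blk(ch[3], ch[4]))
    for (lv in 3:1) {
      p[[paste0("dec", lv)]] <- c(
        list(up = list(w = init_conv(9L * ch[lv + 1L], ch[lv]),
                       b = numeric(ch[lv]))),
        blk(2L * ch[lv], ch[lv]))
    }
    p$out <- list(w = init_conv(9L * ch[1], 1L), b = numeric(1L))
    new_model("unet", list(base = b), flatten_params(p))
  })
}

## ---- forward passes --------------------------------------------------------

param_leaves <- function(model, tape) {
  lv <- vector("list", length(model$params))
  names(lv) <- names(model$params)
  for (nm in names(model$params)) {
    lv[[nm]] <- ag_leaf(tape, model$params[[nm]],
                        requires_grad = model$trainable[[nm]])
  }
  lv
}

#' Partition a feature map into attention windows
#'
#' Reorders a row-major (H*W) x C feature-map matrix into window-major token
#' order: HW/M^2 non-overlapping M x M tiles in row-major tile order, tokens
#' row-major within each tile.
#'
#' @param x Numeric (H*W) x C matrix.
#' @param H,W Feature map height and width; both divisible by `M`.
#' @param M Window side length.
#' @return The reordered matrix; `window_reverse()` undoes it.
#' @export
window_partition <- function(x, H, W, M) {
  if (H %% M != 0L || W %% M != 0L) {
    stop("feature map size (", H, "x", W, ") not divisible by window ", M)
  }
  x[window_perm(H, W, M), , drop = FALSE]
}

#' @rdname window_partition
#' @export
window_reverse <- function(x, H, W, M) {
  x[inverse_perm(window_perm(H, W, M)), , drop = FALSE]
}

# One Swin Transformer layer on the tape: LN -> (S)W-MSA -> +x, then
# LN -> MLP(GELU) -> +x.
stl_forward <- function(x, lv, prefix, cfg, H, W, tape, shifted) {
  M <- cfg$window_size; s <- cfg$shift
  P <- function(nm) lv[[paste0(prefix, ".", nm)]]
  y <- ag_layernorm(x, P("ln1.g"), P("ln1.b"), tape)
  if (shifted && s > 0L) y <- ag_index_rows(y, shift_perm(H, W, s), tape)
  wp <- window_perm(H, W, M)
  y <- ag_index_rows(y, wp, tape)
  masks <- if (shifted && s > 0L) swin_masks(H, W, M, s) else NULL
  ap <- list(pq = P("attn.pq"), bq = P("attn.bq"), pk = P("attn.pk"),
             bk = P("attn.bk"), pv = P("attn.pv"), bv = P("attn.bv"),
             po = P("attn.po"), bo = P("attn.bo"), btab = P("attn.btab"))
  y <- ag_window_mha(y, ap, (H * W) %/% (M * M), M, cfg$n_heads, tape,
                     masks = masks)
  y <- ag_index_rows(y, inverse_perm(wp), tape)
  if (shifted && s > 0L) {
    y <- ag_index_rows(y, inverse_perm(shift_perm(H, W, s)), tape)
  }
  x <- ag_add(x, y, tape)
  z <- ag_layernorm(x, P("ln2.g"), P("ln2.b"), tape)
  z <- ag_add_bias(ag_matmul(z, P("mlp.w1"), tape), P("mlp.b1"), tape)
  z <- ag_gelu(z, tape)
  z <- ag_add_bias(ag_matmul(z, P("mlp.w2"), tape), P("mlp.b2"), tape)
  ag_add(x, z, tape)
}

# RSTB: n_stl STLs alternating W-MSA / SW-MSA (starting unshifted), one 3x3
# convolution, and a block-level residual.
rstb_shift_pattern <- function(n_stl) (seq_len(n_stl) %% 2L) == 0L

rstb_forward <- function(x, lv, prefix, cfg, H, W, tape) {
  y <- x
  shifts <- rstb_shift_pattern(cfg$n_stl)
  for (l in seq_len(cfg$n_stl)) {
    y <- stl_forward(y, lv, paste0(prefix, ".stl", l), cfg, H, W, tape,
                     shifted = shifts[l])
  }
  y <- ag_conv2d(y, lv[[paste0(prefix, ".conv.w")]],
                 lv[[paste0(prefix, ".conv.b")]], H, W, tape)
  ag_add(x, y, tape)
}

swint_forward <- function(model, x, H, W, tape, leaves = NULL) {
  cfg <- model$config
  if (H %% 32L != 0L || W %% 32L != 0L) {
    stop("input size (", H, "x", W, ") must be a multiple of 32; ",
         "use pad_to_multiple() first")
  }
  lv <- if (is.null(leaves)) param_leaves(model, tape) else leaves
  h1 <- ag_relu(ag_conv2d(x, lv$head.conv1.w, lv$head.conv1.b, H, W, tape,
                          stride = 2L), tape)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  h2 <- ag_relu(ag_conv2d(h1, lv$head.conv2.w, lv$head.conv2.b, H2, W2, tape,
                          stride = 2L), tape)
  H4 <- H %/% 4L; W4 <- W %/% 4L
  h3 <- ag_conv2d(h2, lv$head.conv3.w, lv$head.conv3.b, H4, W4, tape)
  y <- h3
  for (r in seq_len(cfg$n_rstb)) {
    y <- rstb_forward(y, lv, paste0("rstb", r), cfg, H4, W4, tape)
  }
  y <- ag_add(y, h3, tape)                      # global residual around body
  y <- ag_add(y, h2, tape)                      # skip: head stage 2 -> tail
  t1 <- ag_relu(ag_conv_transpose2d(y, lv$tail.tconv1.w, lv$tail.tconv1.b,
                                    H4, W4, tape, stride = 2L), tape)
  t1 <- ag_add(t1, h1, tape)                    # skip: head stage 1 -> tail
  t2 <- ag_relu(ag_conv_transpose2d(t1, lv$tail.tconv2.w, lv$tail.tconv2.b,
                                    H2, W2, tape, stride = 2L), tape)
  t3 <- ag_relu(ag_conv_transpose2d(t2, lv$tail.tconv3.w, lv$tail.tconv3.b,
                                    H, W, tape, stride = 1L), tape)
  out <- ag_conv2d(t3, lv$tail.conv_out.w, lv$tail.conv_out.b, H, W, tape)
  list(out = out, leaves = lv, body_hw = c(H4, W4))
}

red_forward <- function(model, x, H, W, tape, leaves = NULL) {
  n <- model$config$n_layers
  lv <- if (is.null(leaves)) param_leaves(model, tape) else leaves
  y <- x
  skips <- list()
  for (i in seq_len(n)) {
    y <- ag_conv2d(y, lv[[paste0("layer", i, ".w")]],
                   lv[[paste0("layer", i, ".b")]], H, W, tape)
    half <- n %/% 2L
    if (i <= half && i %% 2L == 0L) skips[[as.character(i)]] <- y
    mirror <- n - i
    if (i > half && i < n && mirror %% 2L == 0L && mirror >= 2L) {
      y <- ag_add(y, skips[[as.character(mirror)]], tape)
    }
    if (i < n) y <- ag_relu(y, tape)
  }
  list(out = y, leaves = lv)
}

unet_forward <- function(model, x, H, W, tape, leaves = NULL) {
  lv <- if (is.null(leaves)) param_leaves(model, tape) else leaves
  blk <- function(y, nm, h, w) {
    y <- ag_relu(ag_conv2d(y, lv[[paste0(nm, ".conv1.w")]],
                           lv[[paste0(nm, ".conv1.b")]], h, w, tape), tape)
    ag_relu(ag_conv2d(y, lv[[paste0(nm, ".conv2.w")]],
                      lv[[paste0(nm, ".conv2.b")]], h, w, tape), tape)
  }
  e1 <- blk(x, "enc1", H, W)
  p1 <- ag_maxpool2(e1, H, W, tape)
  e2 <- blk(p1, "enc2", H %/% 2L, W %/% 2L)
  p2 <- ag_maxpool2(e2, H %/% 2L, W %/% 2L, tape)
  e3 <- blk(p2, "enc3", H %/% 4L, W %/% 4L)
  p3 <- ag_maxpool2(e3, H %/% 4L, W %/% 4L, tape)
  y <- blk(p3, "bott", H %/% 8L, W %/% 8L)
  up <- function(y, nm, h, w, skip) {
    y <- ag_conv_transpose2d(y, lv[[paste0(nm, ".up.w")]],
                             lv[[paste0(nm, ".up.b")]], h, w, tape,
                             stride = 2L)
    ag_cbind(skip, y, tape)
  }
  y <- blk(up(y, "dec3", H %/% 8L, W %/% 8L, e3), "dec3", H %/% 4L, W %/% 4L)
  y <- blk(up(y, "dec2", H %/% 4L, W %/% 4L, e2), "dec2", H %/% 2L, W %/% 2L)
  y <- blk(up(y, "dec1", H %/% 2L, W %/% 2L, e1), "dec1", H, W)
  out <- ag_conv2d(y, lv$out.w, lv$out.b, H, W, tape)
  list(out = out, leaves = lv)
}

model_forward <- function(model, x, H, W, tape, leaves = NULL) {
  switch(model$arch,
         swint = swint_forward(model, x, H, W, tape, leaves),
         red = red_forward(model, x, H, W, tape, leaves),
         unet = unet_forward(model, x, H, W, tape, leaves),
         stop("unknown architecture: ", model$arch))
}

## ---- padding, inference ----------------------------------------------------

#' Reflect-pad an image matrix so both sides are multiples of `mult`
#'
#' @param img Numeric H x W matrix.
#' @param mult Required divisor of the padded size (32 for SwinT-fairSIM:
#'   two stride-2 stages times window size 8).
#' @return List with the padded matrix and the original size for cropping.
#' @export
pad_to_multiple <- function(img, mult = 32L) {
  H <- nrow(img); W <- ncol(img)
  Hp <- as.integer(ceiling(H / mult) * mult)
  Wp <- as.integer(ceiling(W / mult) * mult)
  if (Hp > 2L * H || Wp > 2L * W) {
    stop("image too small to reflect-pad to a multiple of ", mult)
  }
  ridx <- c(seq_len(H), rev(seq_len(H)))[seq_len(Hp)]
  cidx <- c(seq_len(W), rev(seq_len(W)))[seq_len(Wp)]
  list(img = img[ridx, cidx, drop = FALSE], H = H, W = W)
}

#' Run a model on one image
#'
#' Pads the image by reflection to a multiple of 32, runs the forward pass,
#' and crops the output back to the input size. Input and output are plain
#' H x W matrices on the normalized intensity scale.
#'
#' @param model A `sim_model`.
#' @param img Numeric H x W matrix.
#' @return The restored H x W matrix.
#' @export
denoise_image <- function(model, img) {
  pd <- pad_to_multiple(img, 32L)
  Hp <- nrow(pd$img); Wp <- ncol(pd$img)
  tape <- ag_tape()
  x <- ag_const(tape, matrix(as.vector(t(pd$img)), ncol = 1L))
  fw <- model_forward(model, x, Hp, Wp, tape)
  out <- matrix(fw$out$value, Hp, Wp, byrow = TRUE)
  out[seq_len(pd$H), seq_len(pd$W), drop = FALSE]
}

## ---- parameter accounting and freezing -------------------------------------

#' Count model parameters
#'
#' @param model A `sim_model`.
#' @param trainable_only Count only parameters not frozen by
#'   [apply_freeze_policy()].
#' @return Integer-valued scalar count.
#' @export
count_parameters <- function(model, trainable_only = FALSE) {
  nms <- names(model$params)
  if (trainable_only) nms <- nms[model$trainable[nms]]
  sum(vapply(model$params[nms], length, numeric(1)))
}

#' Apply the per-architecture fine-tuning freeze policy
#'
#' Marks the published trainable/frozen partition for fine-tuning: for
#' SwinT-fairSIM the head, tail, and first and last RSTB stay trainable and
#' the middle RSTBs freeze; for the residual encoder-decoder the first and
#' last 5 of the 30 layers stay trainable; for the U-Net the first two
#' encoder blocks, the final two decoder blocks and the output convolution
#' stay trainable.
#'
#' @param model A `sim_model`.
#' @param architecture Policy name; must match `model$arch`.
#' @return The model with its `trainable` mask updated.
#' @export
apply_freeze_policy <- function(model, architecture = model$arch) {
  if (!identical(architecture, model$arch)) {
    stop("freeze policy '", architecture, "' does not match a '",
         model$arch, "' model")
  }
  nms <- names(model$params)
  keep <- switch(architecture,
    swint = {
      n <- model$config$n_rstb
      pref <- c("head.", "tail.", "rstb1.", paste0("rstb", n, "."))
      Reduce(`|`, lapply(pref, function(p) startsWith(nms, p)))
    },
    red = {
      n <- model$config$n_layers
      idx <- as.integer(sub("^layer(\\d+)\\..*$", "\\1", nms))
      idx <= 5L | idx > n - 5L
    },
    unet = {
      pref <- c("enc1.", "enc2.", "dec2.", "dec1.", "out.")
      Reduce(`|`, lapply(pref, function(p) startsWith(nms, p)))
    },
    stop("no freeze policy for architecture: ", architecture))
  model$trainable <- stats::setNames(keep, nms)
  model
}

## ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding a format version, the
#' architecture tag, its config, the named parameter arrays and the
#' trainable mask.
#'
#' @param model A `sim_model`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = 1L, arch = model$arch, config = model$config,
               params = model$params, trainable = model$trainable), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != 1L) {
    stop("unsupported checkpoint version in ", path)
  }
  m <- new_model(ck$arch, ck$config, ck$params)
  m$trainable <- ck$trainable
  m
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  code
}
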