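#' Network architecture configuration
#'
#' Describes the two-path wavelet-coefficient prediction network. The
#' approximate path (1-channel input, ReLU activations — approximate
#' coefficients are non-negative) and the detail path (3-channel input,
#' Tanh activations — detail coefficients are signed) are configured
#' independently. Two block combinations are supported: `G+S` (ghost block
#' in the approximate path, spatial-attention ghost block in the detail
#' path — the default) and `G+G` (ghost blocks in both).
#'
#' @param scale integer super-resolution factor: 2, 3 or 4.
#' @param approx_block_kind,detail_block_kind `"ghost"` or
#'   `"attention_ghost"`; only the G+G and G+S combinations are valid.
#' @param base_filters number of primary filters per block (default 32).
#' @param kernel convolution kernel size (odd, default 3).
#' @param normalization pixel divisor applied before the wavelet transform
#'   (default 255, mapping the approximate band into `[0, 2]` and the
#'   detail bands into `[-1, 1]`).
#' @param residual if `TRUE` (default) the network predicts corrections to
#'   bicubic-upscaled low-resolution coefficient planes, so an untrained
#'   model already reproduces a bicubic-equivalent reconstruction and
#'   training only has to learn the missing high-frequency differences;
#'   `FALSE` predicts the high-resolution coefficients directly.
#' @param head_init_scale multiplier on the initial weights of the two
#'   sub-pixel prediction heads. In residual mode a small value (default
#'   0.01) keeps the untrained correction near zero while leaving a
#'   nonzero gradient path to every layer; in direct mode it is ignored
#'   (scale 1).
#' @return list of class `wfsan_config`.
#' @export
network_config <- function(scale = 2,
                           approx_block_kind = "ghost",
                           detail_block_kind = "attention_ghost",
                           base_filters = 32,
                           kernel = 3,
                           normalization = 255,
                           residual = TRUE,
                           head_init_scale = 0.01) {
  scale <- check_scale(scale)
  kinds <- c("ghost", "attention_ghost")
  if (!approx_block_kind %in% kinds || !detail_block_kind %in% kinds) {
    stop("block kinds must be 'ghost' or 'attention_ghost'")
  }
  if (approx_block_kind == "attention_ghost") {
    stop("supported combinations are G+G and G+S: the approximate path ",
         "uses the plain ghost block")
  }
  if (kernel %% 2 != 1 || kernel < 1) stop("kernel size must be odd")
  if (base_filters < 1) stop("base_filters must be at least 1")
  cfg <- list(scale = scale,
              approx_block_kind = approx_block_kind,
              detail_block_kind = detail_block_kind,
              base_filters = as.integer(base_filters),
              kernel = as.integer(kernel),
              normalization = normalization,
              residual = isTRUE(residual),
              head_init_scale = if (isTRUE(residual)) head_init_scale else 1,
              approx_activation = "relu",
              detail_activation = "tanh")
  class(cfg) <- "wfsan_config"
  cfg
}

#' Initialize the network weights
#'
#' He-uniform initialization on the ReLU (approximate) path,
#' Glorot-uniform on the Tanh (detail) path, zero biases. The attention
#' merge convolution is bias-free. Weight creation order is fixed, so a
#' given seed always produces identical weights.
#'
#' @param config a [network_config()] object.
#' @param seed integer seed.
#' @return list of class `wfsan_model` with elements `params` (named list
#'   of weight arrays) and `config`.
#' @export
init_wfsan <- function(config = network_config(), seed = 1L) {
  set.seed(seed)
  nf <- config$base_filters
  k <- config$kernel
  s <- config$scale
  p <- list()
  # approximate path: conv -> ghost -> 1x1 conv -> ghost -> conv -> sub-pixel
  p$a1_w <- init_conv_w(k, 1L, nf, "relu");       p$a1_b <- numeric(nf)
  p <- c(p, block_params("ag1", config$approx_block_kind, nf, nf, k, "relu"))
  p$a2_w <- init_conv_w(1L, 2L * nf, nf, "relu"); p$a2_b <- numeric(nf)
  p <- c(p, block_params("ag2", config$approx_block_kind, nf, nf, k, "relu"))
  p$a3_w <- init_conv_w(k, 2L * nf, nf, "relu");  p$a3_b <- numeric(nf)
  hs <- config$head_init_scale
  p$ah_w <- hs * init_conv_w(k, nf, s * s, "relu")
  p$ah_b <- numeric(s * s)
  # detail path: conv -> (attention) ghost -> 1x1 conv -> sub-pixel
  p$d1_w <- init_conv_w(k, 3L, nf, "tanh");       p$d1_b <- numeric(nf)
  p <- c(p, block_params("dg1", config$detail_block_kind, nf, nf, k, "tanh"))
  p$d2_w <- init_conv_w(1L, 2L * nf, nf, "tanh"); p$d2_b <- numeric(nf)
  p$dh_w <- hs * init_conv_w(k, nf, 3L * s * s, "tanh")
  p$dh_b <- numeric(3L * s * s)
  model <- list(params = p, config = config)
  class(model) <- "wfsan_model"
  model
}

block_params <- function(prefix, kind, c_in, filters, k, act) {
  p <- list()
  p[[paste0(prefix, "_pw")]] <- init_conv_w(k, c_in, filters, act)
  p[[paste0(prefix, "_pb")]] <- numeric(filters)
  p[[paste0(prefix, "_dw")]] <- init_dw_w(k, filters, act)
  if (kind == "attention_ghost") {
    p[[paste0(prefix, "_aw")]] <- init_conv_w(k, 2L, 1L, act)
  }
  p
}

#' Ghost extension block
#'
#' Produces `2 * filters` output channels from `filters` primary features:
#' the first half `F` comes from a standard convolution of the input, the
#' second half is the "cheap" per-channel (depthwise) linear operation
#' `phi(F)`; both halves pass the block activation and are concatenated.
#'
#' @param input feature array `[H, W, C_in, N]` (3-d treated as batch 1).
#' @param weights list with `primary_w` (`[k, k, C_in, filters]`),
#'   `primary_b` (`filters`), `cheap_w` (`[k, k, filters]` depthwise,
#'   bias-free); see [init_block_weights()].
#' @param activation `"relu"` or `"tanh"`.
#' @return feature array `[H, W, 2 * filters, N]`.
#' @export
ghost_extension_block <- function(input, weights, activation = "relu") {
  fwd <- ghost_fwd(as_feature_map(input), weights$primary_w,
                   weights$primary_b, weights$cheap_w, activation)
  fwd$y
}

#' Spatial attention map
#'
#' Collapses a feature stack to a single `[0, 1]` gate per pixel:
#' channel-wise average pooling (global information) and channel-wise max
#' pooling (salient information) give two `H x W` maps, which are
#' concatenated and merged by one bias-free convolution; a hard-sigmoid
#' normalizes the merged map.
#'
#' @param features feature array `[H, W, C, N]`.
#' @param weights merge kernel `[k, k, 2, 1]`.
#' @param bias optional scalar added before the hard-sigmoid (diagnostic;
#'   the instantiated network uses none, default 0).
#' @return array `[H, W, 1, N]` with values in `[0, 1]`.
#' @export
spatial_attention_map <- function(features, weights, bias = 0) {
  features <- as_feature_map(features)
  pooled <- pool_concat(features)
  hard_sigmoid(conv2d(pooled, weights, bias))
}

#' Spatial-attention ghost extension block
#'
#' Identical to [ghost_extension_block()] except that the cheap half
#' `phi(F)` is gated by the spatial attention map computed from `phi(F)`
#' itself (element-wise product, broadcast over channels) before
#' concatenation.
#'
#' @inheritParams ghost_extension_block
#' @param weights as for the ghost block plus `attention_w`
#'   (`[k, k, 2, 1]`, bias-free).
#' @param attention_override optional `[H, W, 1, N]` array replacing the
#'   computed attention map (diagnostic).
#' @return feature array `[H, W, 2 * filters, N]`.
#' @export
attention_ghost_extension_block <- function(input, weights,
                                            activation = "tanh",
                                            attention_override = NULL) {
  fwd <- ghost_fwd(as_feature_map(input), weights$primary_w,
                   weights$primary_b, weights$cheap_w, activation,
                   aw = weights$attention_w,
                   att_override = attention_override)
  fwd$y
}

#' Initialize weights for a standalone block
#'
#' @param kind `"ghost"` or `"attention_ghost"`.
#' @param c_in input channels.
#' @param filters primary filter count.
#' @param kernel kernel size (odd).
#' @param activation `"relu"` or `"tanh"` (controls the initializer).
#' @param seed integer seed.
#' @return named weight list as consumed by the block functions.
#' @export
init_block_weights <- function(kind, c_in, filters, kernel = 3,
                               activation = "relu", seed = 1L) {
  set.seed(seed)
  raw <- block_params("b", kind, c_in, filters, kernel, activation)
  w <- list(primary_w = raw$b_pw, primary_b = raw$b_pb, cheap_w = raw$b_dw)
  if (kind == "attention_ghost") w$attention_w <- raw$b_aw
  w
}

#' Sub-pixel upscaling head
#'
#' A convolution producing `scale^2 * out_channels` channels followed by
#' the pixel-shuffle rearrangement, yielding an
#' `out_channels x (scale*H) x (scale*W)` map. The convolution is linear
#' (no activation) so predicted coefficients can take any sign.
#'
#' @param features input feature array `[H, W, C, N]`.
#' @param scale integer factor, one of 2, 3, 4.
#' @param out_channels channels after the shuffle.
#' @param weights list with `w` (`[k, k, C, scale^2 * out_channels]`) and
#'   `b`.
#' @return array `[scale*H, scale*W, out_channels, N]`.
#' @export
subpixel_upsample <- function(features, scale, out_channels, weights) {
  scale <- check_scale(scale)
  features <- as_feature_map(features)
  h <- conv2d(features, weights$w, weights$b)
  if (dim(h)[3] != scale * scale * out_channels) {
    stop("head convolution emits ", dim(h)[3], " channels; expected ",
         scale * scale * out_channels)
  }
  pixel_shuffle(h, scale)
}

# ---- internal block forward/backward ---------------------------------------

pool_concat <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], 2L, d[4]))
  out[, , 1L, ] <- channel_avg_pool(x)
  out[, , 2L, ] <- channel_max_pool(x)
  out
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[c(1, 2, 4)] == db[c(1, 2, 4)])) {
    stop("cannot concatenate feature maps of different spatial/batch shape")
  }
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

broadcast_gate <- function(att, c) att[, , rep(1L, c), , drop = FALSE]

channel_sum <- function(x) {
  d <- dim(x)
  m <- rowSums(array(aperm(x, c(1, 2, 4, 3)), c(d[1] * d[2] * d[4], d[3])))
  array(aperm(array(m, c(d[1], d[2], d[4], 1L)), c(1, 2, 4, 3)),
        c(d[1], d[2], 1L, d[4]))
}

ghost_fwd <- function(x, pw, pb, dw, act, aw = NULL, att_override = NULL,
                      slot = -1L) {
  f <- conv2d(x, pw, pb, act, slot)
  p <- dwconv2d(f, dw, act)
  cache <- list(x = x, f = f, p = p, act = act, slot = slot)
  if (!is.null(aw) || !is.null(att_override)) {
    if (!is.null(att_override)) {
      att <- as_feature_map(att_override)
      cache$override <- TRUE
    } else {
      cache$pooled <- pool_concat(p)
      cache$za <- conv2d(cache$pooled, aw, 0)
      att <- hard_sigmoid(cache$za)
    }
    cache$att <- att
    gated <- p * broadcast_gate(att, dim(p)[3])
    cache$y <- concat_channels(f, gated)
  } else {
    cache$y <- concat_channels(f, p)
  }
  cache
}

ghost_bwd <- function(cache, pw, dw, aw, dy) {
  cc <- dim(cache$f)[3]
  df <- dy[, , seq_len(cc), , drop = FALSE]
  dsecond <- dy[, , cc + seq_len(cc), , drop = FALSE]
  grads <- list()
  if (!is.null(cache$att)) {
    dp <- dsecond * broadcast_gate(cache$att, cc)
    if (is.null(cache$override)) {
      datt <- channel_sum(dsecond * cache$p)
      dza <- datt * hard_sigmoid_grad(cache$za)
      r <- conv2d_bwd(cache$pooled, aw, numeric(0), dza)
      grads$aw <- r$dw
      dpool <- r$dx
      # average pool spreads its gradient uniformly over channels
      dp <- dp + broadcast_gate(dpool[, , 1L, , drop = FALSE], cc) / cc
      # max pool routes its gradient to the (first) argmax channel
      mx <- cache$pooled[, , 2L, , drop = FALSE]
      dmx <- dpool[, , 2L, , drop = FALSE]
      taken <- array(FALSE, dim(mx))
      for (c in seq_len(cc)) {
        sel <- (cache$p[, , c, , drop = FALSE] >= mx) & !taken
        dp[, , c, ] <- dp[, , c, , drop = FALSE] + dmx * sel
        taken <- taken | sel
      }
    }
  } else {
    dp <- dsecond
  }
  r2 <- dwconv2d_bwd(cache$f, dw, cache$p, dp, cache$act)
  grads$dw_k <- r2$dw
  r3 <- conv2d_bwd(cache$x, pw, cache$f, df + r2$dx, cache$act, cache$slot)
  grads$pw <- r3$dw
  grads$pb <- r3$db
  grads$dx <- r3$dx
  grads
}

# ---- full forward / backward ------------------------------------------------

conv_act_fwd <- function(x, w, b, act, slot = -1L) {
  y <- conv2d(x, w, b, act, slot)
  list(x = x, y = y, act = act, slot = slot)
}

conv_act_bwd <- function(cache, w, dy) {
  conv2d_bwd(cache$x, w, cache$y, dy, cache$act, cache$slot)
}

block_weight_view <- function(p, prefix) {
  list(pw = p[[paste0(prefix, "_pw")]],
       pb = p[[paste0(prefix, "_pb")]],
       dw = p[[paste0(prefix, "_dw")]],
       aw = p[[paste0(prefix, "_aw")]])
}

# Forward pass of both paths on band tensors (lca [h,w,1,N], lcd [h,w,3,N]).
# Returns predictions plus (optionally) the caches needed for backprop.
wfsan_forward_full <- function(model, lca, lcd, keep_cache = FALSE,
                               resid_base = NULL) {
  p <- model$params
  cfg <- model$config
  s <- cfg$scale
  sl <- function(i) if (keep_cache) as.integer(i) else -1L
  ca <- list()
  # approximate path (ReLU)
  ca$c1 <- conv_act_fwd(lca, p$a1_w, p$a1_b, "relu", sl(0))
  wg1 <- block_weight_view(p, "ag1")
  ca$g1 <- ghost_fwd(ca$c1$y, wg1$pw, wg1$pb, wg1$dw, "relu", aw = wg1$aw,
                     slot = sl(1))
  ca$c2 <- conv_act_fwd(ca$g1$y, p$a2_w, p$a2_b, "relu")
  wg2 <- block_weight_view(p, "ag2")
  ca$g2 <- ghost_fwd(ca$c2$y, wg2$pw, wg2$pb, wg2$dw, "relu", aw = wg2$aw,
                     slot = sl(2))
  ca$c3 <- conv_act_fwd(ca$g2$y, p$a3_w, p$a3_b, "relu", sl(3))
  ca$head_x <- ca$c3$y
  ha <- conv2d(ca$head_x, p$ah_w, p$ah_b, "linear", sl(4))
  hca <- pixel_shuffle(ha, s)
  # detail path (Tanh)
  cd <- list()
  cd$c1 <- conv_act_fwd(lcd, p$d1_w, p$d1_b, "tanh", sl(5))
  wd1 <- block_weight_view(p, "dg1")
  cd$g1 <- ghost_fwd(cd$c1$y, wd1$pw, wd1$pb, wd1$dw, "tanh", aw = wd1$aw,
                     slot = sl(6))
  cd$c2 <- conv_act_fwd(cd$g1$y, p$d2_w, p$d2_b, "tanh")
  hd <- conv2d(cd$c2$y, p$dh_w, p$dh_b, "linear", sl(7))
  hcd <- pixel_shuffle(hd, s)
  ca$head_slot <- sl(4)
  cd$head_slot <- sl(7)
  if (cfg$residual) {
    if (is.null(resid_base)) resid_base <- wavesr_residual_base(lca, lcd, s)
    hca <- hca + resid_base$a
    hcd <- hcd + resid_base$d
  }
  out <- list(hca = hca, hcd = hcd)
  if (keep_cache) out$cache <- list(a = ca, d = cd)
  out
}

# Residual base for a batch of band tensors: the wavelet planes of the
# bicubic upscale of each low-resolution sample. These planes are a
# consistent transform, so with zero network correction the inverse
# transform reproduces the bicubic upscale exactly.
wavesr_residual_base <- function(lca, lcd, s) {
  d <- dim(lca)
  base_a <- array(0, c(d[1] * s, d[2] * s, 1L, d[4]))
  base_d <- array(0, c(d[1] * s, d[2] * s, 3L, d[4]))
  for (n in seq_len(d[4])) {
    lr <- iswt2_level1(merge_bands(lca[, , 1L, n], lcd[, , , n]))
    sp <- split_bands(swt2_level1(bicubic_upscale(lr, s)))
    base_a[, , 1L, n] <- sp$approx
    base_d[, , , n] <- sp$detail
  }
  list(a = base_a, d = base_d)
}

# Backward pass: gradients of a scalar loss wrt every parameter, given the
# gradients wrt the two predictions. The residual shortcut is an identity,
# so it does not alter the parameter gradients.
wfsan_backward <- function(model, cache, d_hca, d_hcd) {
  p <- model$params
  s <- model$config$scale
  g <- list()
  # approximate path
  ca <- cache$a
  dha <- pixel_unshuffle(d_hca, s)
  r <- conv2d_bwd(ca$c3$y, p$ah_w, numeric(0), dha, "linear", ca$head_slot)
  g$ah_w <- r$dw; g$ah_b <- r$db
  r <- conv_act_bwd(ca$c3, p$a3_w, r$dx)
  g$a3_w <- r$dw; g$a3_b <- r$db
  wg2 <- block_weight_view(p, "ag2")
  bg <- ghost_bwd(ca$g2, wg2$pw, wg2$dw, wg2$aw, r$dx)
  g$ag2_pw <- bg$pw; g$ag2_pb <- bg$pb; g$ag2_dw <- bg$dw_k
  if (!is.null(bg$aw)) g$ag2_aw <- bg$aw
  r <- conv_act_bwd(ca$c2, p$a2_w, bg$dx)
  g$a2_w <- r$dw; g$a2_b <- r$db
  wg1 <- block_weight_view(p, "ag1")
  bg <- ghost_bwd(ca$g1, wg1$pw, wg1$dw, wg1$aw, r$dx)
  g$ag1_pw <- bg$pw; g$ag1_pb <- bg$pb; g$ag1_dw <- bg$dw_k
  if (!is.null(bg$aw)) g$ag1_aw <- bg$aw
  r <- conv_act_bwd(ca$c1, p$a1_w, bg$dx)
  g$a1_w <- r$dw; g$a1_b <- r$db
  # detail path
  cd <- cache$d
  dhd <- pixel_unshuffle(d_hcd, s)
  r <- conv2d_bwd(cd$c2$y, p$dh_w, numeric(0), dhd, "linear", cd$head_slot)
  g$dh_w <- r$dw; g$dh_b <- r$db
  r <- conv_act_bwd(cd$c2, p$d2_w, r$dx)
  g$d2_w <- r$dw; g$d2_b <- r$db
  wd1 <- block_weight_view(p, "dg1")
  bg <- ghost_bwd(cd$g1, wd1$pw, wd1$dw, wd1$aw, r$dx)
  g$dg1_pw <- bg$pw; g$dg1_pb <- bg$pb; g$dg1_dw <- bg$dw_k
  if (!is.null(bg$aw)) g$dg1_aw <- bg$aw
  r <- conv_act_bwd(cd$c1, p$d1_w, bg$dx)
  g$d1_w <- r$dw; g$d1_b <- r$db
  g[names(model$params)]
}

#' Predict high-resolution wavelet coefficients
#'
#' Runs the two separated paths on low-resolution coefficient tensors and
#' returns the predicted high-resolution approximate (1-channel) and
#' detail (3-channel) coefficient tensors at `scale` times the input
#' spatial size.
#'
#' @param model a `wfsan_model` (from [init_wfsan()] or [train_model()]).
#' @param lca approximate band tensor `[h, w, 1]` or `[h, w, 1, N]`.
#' @param lcd detail band tensor `[h, w, 3]` or `[h, w, 3, N]`.
#' @return list with arrays `hca` and `hcd`.
#' @export
wfsan_forward <- function(model, lca, lcd) {
  lca <- as_feature_map(lca)
  lcd <- as_feature_map(lcd)
  if (dim(lca)[3] != 1L) stop("approximate input must have 1 channel")
  if (dim(lcd)[3] != 3L) stop("detail input must have 3 channels")
  if (!all(dim(lca)[c(1, 2, 4)] == dim(lcd)[c(1, 2, 4)])) {
    stop("approximate and detail inputs must share spatial/batch shape")
  }
  out <- wfsan_forward_full(model, lca, lcd)
  out[c("hca", "hcd")]
}

#' Super-resolve a grayscale image
#'
#' Full single-image pipeline: normalize pixels by the configured divisor,
#' decompose with the stationary Haar transform, predict the
#' high-resolution coefficients with the two-path network, recombine with
#' the inverse transform, rescale and clip to `[0, 255]`.
#'
#' @param image numeric matrix in `[0, 255]` (grayscale). 3-d arrays are
#'   rejected: convert multi-channel images to a single channel first.
#' @param model a `wfsan_model`.
#' @return numeric matrix of size `scale * dim(image)`, values in
#'   `[0, 255]`.
#' @export
super_resolve <- function(image, model) {
  if (!is.null(dim(image)) && length(dim(image)) == 3L) {
    stop("multi-channel input: convert the image to a single grayscale ",
         "channel first (e.g. read_grayscale(..., to_gray = TRUE))")
  }
  image <- as_pixel_matrix(image)
  norm <- model$config$normalization
  bands <- swt2_level1(image / norm)
  sp <- split_bands(bands)
  out <- wfsan_forward(model, sp$approx, sp$detail)
  hr_bands <- merge_bands(
    matrix(out$hca, dim(out$hca)[1], dim(out$hca)[2]),
    array(out$hcd, dim(out$hcd)[1:3])
  )
  clip_pixels(iswt2_level1(hr_bands) * norm)
}
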