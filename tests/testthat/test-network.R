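test_that("dense and depthwise convolutions match a naive reference", {
  set.seed(61)
  x <- array(rnorm(7 * 6 * 3 * 2), c(7, 6, 3, 2))
  for (k in c(1, 3)) {
    w <- array(rnorm(k * k * 3 * 4, sd = 0.5), c(k, k, 3, 4))
    b <- rnorm(4)
    expect_equal(wavesr:::conv2d(x, w, b), naive_conv(x, w, b),
                 tolerance = 1e-5)
  }
  # depthwise = dense conv with per-channel-isolated kernels
  dw <- array(rnorm(27), c(3, 3, 3))
  wiso <- array(0, c(3, 3, 3, 3))
  for (c in 1:3) wiso[, , c, c] <- dw[, , c]
  expect_equal(wavesr:::dwconv2d(x, dw), naive_conv(x, wiso, numeric(3)),
               tolerance = 1e-10)
})

test_that("convolution gradients agree with directional finite differences", {
  set.seed(62)
  x <- array(rnorm(8 * 8 * 3 * 2, sd = 0.5), c(8, 8, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4, sd = 0.3), c(3, 3, 3, 4))
  b <- rnorm(4, sd = 0.1)
  dy <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  eps <- 1e-3
  for (act in c("linear", "tanh")) { # smooth activations: strict check
    y <- wavesr:::conv2d(x, w, b, act)
    g <- wavesr:::conv2d_bwd(x, w, y, dy, act)
    dvec <- array(rnorm(length(w)), dim(w))
    num <- (sum(wavesr:::conv2d(x, w + eps * dvec, b, act) * dy) -
            sum(wavesr:::conv2d(x, w - eps * dvec, b, act) * dy)) / (2 * eps)
    expect_equal(sum(g$dw * dvec), num, tolerance = 1e-3)
    dxv <- array(rnorm(length(x)), dim(x))
    numx <- (sum(wavesr:::conv2d(x + eps * dxv, w, b, act) * dy) -
             sum(wavesr:::conv2d(x - eps * dxv, w, b, act) * dy)) / (2 * eps)
    expect_equal(sum(g$dx * dxv), numx, tolerance = 1e-3)
  }
  # relu checked in its saturated regimes (kink-free)
  for (shift in c(5, -5)) {
    bb <- rep(shift, 4)
    y <- wavesr:::conv2d(x, w, bb, "relu")
    g <- wavesr:::conv2d_bwd(x, w, y, dy, "relu")
    if (shift > 0) {
      ylin <- wavesr:::conv2d(x, w, bb, "linear")
      glin <- wavesr:::conv2d_bwd(x, w, ylin, dy, "linear")
      expect_equal(g$dw, glin$dw)
      expect_equal(g$dx, glin$dx)
    } else {
      expect_true(all(g$dw == 0) && all(g$dx == 0))
    }
  }
  # depthwise gradients, double-precision path
  dwk <- array(rnorm(27, sd = 0.3), c(3, 3, 3))
  yd <- wavesr:::dwconv2d(x, dwk)
  dyd <- array(rnorm(length(yd)), dim(yd))
  gd <- wavesr:::dwconv2d_bwd(x, dwk, yd, dyd)
  dd <- array(rnorm(27), c(3, 3, 3))
  eps <- 1e-6
  num <- (sum(wavesr:::dwconv2d(x, dwk + eps * dd) * dyd) -
          sum(wavesr:::dwconv2d(x, dwk - eps * dd) * dyd)) / (2 * eps)
  expect_equal(sum(gd$dw * dd), num, tolerance = 1e-6)
})

test_that("ghost block doubles channels and wires the cheap half from F", {
  w <- init_block_weights("ghost", 4, 4, seed = 3)
  set.seed(4)
  x <- array(abs(rnorm(5 * 5 * 4)), c(5, 5, 4, 1))
  y <- ghost_extension_block(x, w, "relu")
  expect_equal(dim(y), c(5L, 5L, 8L, 1L))
  # identity depthwise kernel (centered delta): second half equals F
  w$cheap_w[] <- 0
  w$cheap_w[2, 2, ] <- 1
  y2 <- ghost_extension_block(x, w, "relu")
  expect_equal(y2[, , 1:4, ], y2[, , 5:8, ]) # relu(F) = F for F >= 0
  # zero input with zero biases stays zero
  y0 <- ghost_extension_block(array(0, dim(x)), w, "relu")
  expect_true(all(y0 == 0))
})

test_that("spatial attention map lies in [0,1] and honors its closed form", {
  w <- array(rnorm(3 * 3 * 2), c(3, 3, 2, 1))
  set.seed(5)
  x <- array(rnorm(6 * 6 * 5 * 2), c(6, 6, 5, 2))
  att <- spatial_attention_map(x, w)
  expect_equal(dim(att), c(6L, 6L, 1L, 2L))
  expect_true(all(att >= 0 & att <= 1))
  # zero merge weights with bias b: hard_sigmoid(b) everywhere; b = 3 -> 1
  wz <- array(0, c(3, 3, 2, 1))
  expect_true(all(spatial_attention_map(x, wz, bias = 3) == 1))
  expect_true(all(spatial_attention_map(x, wz, bias = 0) == 0.5))
  # constant features: avg and max pools agree, and away from the
  # zero-padded border the merged map is constant
  xc <- array(2, c(8, 8, 3, 1))
  attc <- spatial_attention_map(xc, w)
  interior <- attc[2:7, 2:7, 1, 1]
  expect_equal(max(interior) - min(interior), 0)
  expect_true(all(attc >= 0 & attc <= 1))
  expect_equal(hard_sigmoid(c(-4, -3, 0, 3, 4)), c(0, 0, 0.5, 1, 1))
})

test_that("attention ghost block reduces to the ghost block under a unit gate", {
  w <- init_block_weights("attention_ghost", 4, 4, activation = "tanh",
                          seed = 6)
  set.seed(7)
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  ones <- array(1, c(6, 6, 1, 2))
  ghost_w <- w[c("primary_w", "primary_b", "cheap_w")]
  expect_identical(
    attention_ghost_extension_block(x, w, "tanh", attention_override = ones),
    ghost_extension_block(x, ghost_w, "tanh")
  )
  # zero gate annihilates the cheap half only
  zeros <- array(0, c(6, 6, 1, 2))
  y0 <- attention_ghost_extension_block(x, w, "tanh",
                                        attention_override = zeros)
  yg <- ghost_extension_block(x, ghost_w, "tanh")
  expect_true(all(y0[, , 5:8, ] == 0))
  expect_equal(y0[, , 1:4, ], yg[, , 1:4, ])
  expect_equal(dim(attention_ghost_extension_block(x, w, "tanh")),
               c(6L, 6L, 8L, 1L + 1L))
})

test_that("pixel shuffle is a value-preserving bijection", {
  x <- array(1:16, c(2, 2, 4, 1))
  y <- pixel_shuffle(x, 2)
  expect_equal(dim(y), c(4L, 4L, 1L, 1L))
  expect_setequal(as.vector(y), 1:16)
  expect_equal(wavesr:::pixel_unshuffle(y, 2), x)
  expect_error(pixel_shuffle(array(0, c(2, 2, 3, 1)), 2), "multiple")
  expect_error(pixel_shuffle(x, 1), "at least 2")
})

test_that("sub-pixel head emits scale^2 channel algebra", {
  set.seed(9)
  x <- array(rnorm(4 * 4 * 3 * 1), c(4, 4, 3, 1))
  for (s in c(2, 3)) {
    w <- list(w = array(rnorm(3 * 3 * 3 * s * s * 2, sd = 0.2),
                        c(3, 3, 3, s * s * 2)),
              b = numeric(s * s * 2))
    y <- subpixel_upsample(x, s, 2, w)
    expect_equal(dim(y), c(4L * s, 4L * s, 2L, 1L))
  }
  expect_error(subpixel_upsample(x, 5, 1, list()), "scale")
})

test_that("forward pipeline respects shape covariance and determinism", {
  cfg <- tiny_config()
  model <- init_wfsan(cfg, seed = 2)
  set.seed(10)
  lca <- array(runif(12 * 10, 0, 2), c(12, 10, 1, 1))
  lcd <- array(runif(12 * 10 * 3, -1, 1), c(12, 10, 3, 1))
  out <- wfsan_forward(model, lca, lcd)
  expect_equal(dim(out$hca), c(24L, 20L, 1L, 1L))
  expect_equal(dim(out$hcd), c(24L, 20L, 3L, 1L))
  out2 <- wfsan_forward(model, lca, lcd)
  expect_identical(out, out2)
  expect_error(wfsan_forward(model, lcd, lcd), "1 channel")
  expect_error(wfsan_forward(model, lca, lca), "3 channels")
})

test_that("a scalar loss propagates gradient into every trainable tensor", {
  for (kind in c("ghost", "attention_ghost")) {
    cfg <- network_config(scale = 2, base_filters = 4,
                          detail_block_kind = kind)
    model <- init_wfsan(cfg, seed = 3)
    set.seed(11)
    lca <- array(runif(8 * 8, 0, 2), c(8, 8, 1, 2))
    lcd <- array(runif(8 * 8 * 3, -1, 1), c(8, 8, 3, 2))
    out <- wavesr:::wfsan_forward_full(model, lca, lcd, keep_cache = TRUE)
    g <- wavesr:::wfsan_backward(model, out$cache,
                                 out$hca * 0 + 1, out$hcd * 0 + 1)
    expect_setequal(names(g), names(model$params))
    for (nm in names(g)) {
      expect_true(any(g[[nm]] != 0), info = nm)
    }
  }
})

test_that("whole-model gradients match directional finite differences", {
  # tanh detail path only (smooth); the relu path is covered layer-wise
  cfg <- network_config(scale = 2, base_filters = 3, residual = FALSE)
  model <- init_wfsan(cfg, seed = 11)
  set.seed(99)
  model$params <- lapply(model$params,
                         function(p) p + runif(length(p), -0.03, 0.03))
  n <- 2
  lca <- array(runif(6 * 6 * n, 0, 2), c(6, 6, 1, n))
  lcd <- array(runif(6 * 6 * 3 * n, -1, 1), c(6, 6, 3, n))
  hcd <- array(runif(12 * 12 * 3 * n, -1, 1), c(12, 12, 3, n))
  loss_d <- function(m) {
    out <- wavesr:::wfsan_forward_full(m, lca, lcd)
    sum((out$hcd - hcd)^2) / (2 * n)
  }
  out <- wavesr:::wfsan_forward_full(model, lca, lcd, keep_cache = TRUE)
  g <- wavesr:::wfsan_backward(model, out$cache, out$hca * 0,
                               (out$hcd - hcd) / n)
  d_names <- grep("^d", names(model$params), value = TRUE)
  set.seed(1)
  dirs <- lapply(model$params[d_names], function(p) {
    a <- rnorm(length(p))
    dim(a) <- dim(p)
    a
  })
  eps <- 1e-3
  m2 <- model
  m3 <- model
  for (nm in d_names) {
    m2$params[[nm]] <- m2$params[[nm]] + eps * dirs[[nm]]
    m3$params[[nm]] <- m3$params[[nm]] - eps * dirs[[nm]]
  }
  num <- (loss_d(m2) - loss_d(m3)) / (2 * eps)
  ana <- sum(mapply(function(gg, dd) sum(gg * dd), g[d_names], dirs))
  expect_equal(ana, num, tolerance = 0.02)
})

test_that("super-resolution returns clipped 8-bit output at the right size", {
  cfg <- tiny_config()
  model <- init_wfsan(cfg, seed = 4)
  img <- make_phantom(phantom_params(size = 64, seed = 6))
  out <- super_resolve(img, model)
  expect_equal(dim(out), c(128L, 128L))
  expect_true(all(out >= 0 & out <= 255))
  expect_error(super_resolve(array(0, c(8, 8, 3)), model), "grayscale")
})

test_that("coefficient injection reproduces the bicubic upscale exactly", {
  # if the network emitted exactly the wavelet planes of the bicubic
  # upscale, the inverse transform must return that upscale: the identity
  # ISWT(SWT(x)) composed with injected coefficients
  img <- make_phantom(phantom_params(size = 64, seed = 8))
  up <- bicubic_upscale(img, 2)
  sp <- split_bands(swt2_level1(up))
  rec <- iswt2_level1(merge_bands(sp$approx, sp$detail))
  expect_lt(max(abs(rec - up)), 1e-6)
})

test_that("residual mode starts near the bicubic-equivalent reconstruction", {
  img <- make_phantom(phantom_params(size = 64, seed = 10))
  model <- init_wfsan(network_config(scale = 2, base_filters = 4,
                                     residual = TRUE), seed = 5)
  out <- super_resolve(img, model)
  ref <- pmin(pmax(bicubic_upscale(img, 2), 0), 255)
  # untrained correction heads are near zero, so the output tracks bicubic
  expect_gt(psnr(ref, out), 30)
})
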