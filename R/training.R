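#' Training configuration
#'
#' Hyperparameters of the wavelet-domain training loop. Defaults follow
#' the published recipe: 48-pixel HR patches with 50% overlap, batch size
#' 128, Adam with initial learning rate 0.001 under cosine decay
#' (`alpha = 1e-4`, `decay_epoch = 100`), gradient global-norm clipping at
#' 0.001, 100 epochs, 10% of the patches held out for validation.
#'
#' @param batch_size patches per optimization step.
#' @param patch_size HR crop side length in pixels (must be divisible by
#'   `scale`).
#' @param patch_stride grid stride between HR crops.
#' @param initial_lr initial Adam learning rate.
#' @param alpha cosine-decay floor parameter.
#' @param decay_epoch cosine period / step-decay interval in epochs.
#' @param max_epochs number of training epochs.
#' @param grad_clip_norm global gradient-norm clip threshold.
#' @param scale super-resolution factor (2, 3 or 4).
#' @param val_fraction fraction of patches held out for validation.
#' @param seed integer seed fixing shuffling, splits and initialization.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 128, patch_size = 48,
                         patch_stride = 24, initial_lr = 0.001,
                         alpha = 1e-4, decay_epoch = 100, max_epochs = 100,
                         grad_clip_norm = 0.001, scale = 2,
                         val_fraction = 0.1, seed = 1L) {
  if (patch_size < 8) stop("patch_size must be at least 8")
  if (batch_size < 1) stop("batch_size must be at least 1")
  if (initial_lr <= 0 || alpha <= 0 || grad_clip_norm <= 0) {
    stop("rates must be positive")
  }
  scale <- check_scale(scale)
  if (patch_size %% scale != 0) {
    stop("patch_size must be divisible by the scale factor")
  }
  cfg <- list(batch_size = as.integer(batch_size),
              patch_size = as.integer(patch_size),
              patch_stride = as.integer(patch_stride),
              initial_lr = initial_lr, alpha = alpha,
              decay_epoch = as.integer(decay_epoch),
              max_epochs = as.integer(max_epochs),
              grad_clip_norm = grad_clip_norm, scale = scale,
              val_fraction = val_fraction, seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

#' Wavelet-domain L2 loss
#'
#' `Loss = 1/(2N) * sum_n (||HCA_n - pred_A_n||^2 + ||HCD_n - pred_D_n||^2)`
#' where the norms are plain sums of squared coefficient errors over the
#' approximate and detail tensors of sample `n`.
#'
#' @param pred_hca,pred_hcd predicted coefficient tensors.
#' @param true_hca,true_hcd target coefficient tensors (same shapes).
#' @param batch_n batch size `N`; defaults to the 4th dimension of
#'   `pred_hca` (1 for unbatched input).
#' @return scalar loss.
#' @export
wavelet_l2_loss <- function(pred_hca, pred_hcd, true_hca, true_hcd,
                            batch_n = NULL) {
  pred_hca <- as_feature_map(pred_hca); true_hca <- as_feature_map(true_hca)
  pred_hcd <- as_feature_map(pred_hcd); true_hcd <- as_feature_map(true_hcd)
  if (!identical(dim(pred_hca), dim(true_hca)) ||
      !identical(dim(pred_hcd), dim(true_hcd))) {
    stop("prediction and target shapes differ")
  }
  if (is.null(batch_n)) batch_n <- dim(pred_hca)[4]
  if (batch_n < 1) stop("batch_n must be at least 1")
  (sum((pred_hca - true_hca)^2) + sum((pred_hcd - true_hcd)^2)) /
    (2 * batch_n)
}

#' Cosine-decay learning-rate schedule
#'
#' The published schedule, taken literally: at epochs that are multiples
#' of `decay_epoch` the current rate is multiplied by 0.1; at every other
#' epoch the rate is set (absolutely, not multiplicatively) to
#' `(1 - alpha) * 0.5 * (1 + cos(pi * epoch / decay_epoch)) + alpha`.
#' The absolute branch therefore yields values in `[alpha, 1]`; the
#' training loop applies this trace as a decay multiplier on the
#' configured initial learning rate (see the methods vignette).
#'
#' @param state list with `epoch` (current epoch, >= 1) and `lr` (rate
#'   carried from the previous epoch).
#' @param config a [train_config()] (fields `alpha`, `decay_epoch`).
#' @return the updated learning rate (scalar).
#' @export
cosine_decay_lr <- function(state, config) {
  if (config$decay_epoch <= 0) stop("decay_epoch must be positive")
  if (state$epoch < 1) stop("epoch must be at least 1")
  if (state$epoch %% config$decay_epoch == 0) {
    state$lr * 0.1
  } else {
    (1 - config$alpha) *
      (0.5 * (1 + cos(pi * state$epoch / config$decay_epoch))) +
      config$alpha
  }
}

#' Cut an HR image into aligned LR/HR patch pairs
#'
#' HR crops of side `patch_size` are taken on a regular grid with stride
#' `patch_stride`; each crop is paired with its bicubic downscale by
#' `1/scale` (the standard degradation protocol). Images smaller than the
#' patch size yield an empty list with a warning.
#'
#' @param hr_image numeric matrix in `[0, 255]`.
#' @param config a [train_config()].
#' @return list of pairs `list(lr = , hr = )`.
#' @export
extract_patches <- function(hr_image, config) {
  hr_image <- as_pixel_matrix(hr_image)
  p <- config$patch_size
  stride <- config$patch_stride
  if (nrow(hr_image) < p || ncol(hr_image) < p) {
    warning("image ", nrow(hr_image), "x", ncol(hr_image),
            " is smaller than the patch size ", p)
    return(list())
  }
  rows <- seq(1L, nrow(hr_image) - p + 1L, by = stride)
  cols <- seq(1L, ncol(hr_image) - p + 1L, by = stride)
  pairs <- vector("list", length(rows) * length(cols))
  i <- 0L
  for (r in rows) {
    for (cc in cols) {
      hr <- hr_image[r:(r + p - 1L), cc:(cc + p - 1L)]
      i <- i + 1L
      pairs[[i]] <- list(lr = bicubic_downscale(hr, config$scale), hr = hr)
    }
  }
  pairs
}

#' Clip gradients by global norm
#'
#' Scales the whole gradient set so its global L2 norm does not exceed
#' `max_norm` (gradients below the threshold are returned unchanged).
#'
#' @param grads named list of gradient arrays.
#' @param max_norm positive clip threshold.
#' @return list with `grads` (clipped) and `norm` (pre-clip global norm).
#' @export
clip_gradients <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  list(grads = grads, norm = total)
}

# ---- internal: dataset tensors and Adam ------------------------------------

# Stack a list of patch pairs into the band tensors the network consumes.
stack_band_tensors <- function(pairs, norm) {
  n <- length(pairs)
  lr1 <- pairs[[1]]$lr
  hr1 <- pairs[[1]]$hr
  lca <- array(0, c(dim(lr1), 1L, n)); lcd <- array(0, c(dim(lr1), 3L, n))
  hca <- array(0, c(dim(hr1), 1L, n)); hcd <- array(0, c(dim(hr1), 3L, n))
  for (i in seq_len(n)) {
    sl <- split_bands(swt2_level1(pairs[[i]]$lr / norm))
    sh <- split_bands(swt2_level1(pairs[[i]]$hr / norm))
    lca[, , 1L, i] <- sl$approx; lcd[, , , i] <- sl$detail
    hca[, , 1L, i] <- sh$approx; hcd[, , , i] <- sh$detail
  }
  list(lca = lca, lcd = lcd, hca = hca, hcd = hcd)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the coefficient-prediction network
#'
#' Optimizes the wavelet-domain L2 loss with Adam under the cosine decay
#' schedule (applied as a multiplier on `initial_lr`) and global
#' gradient-norm clipping. Both patch sides are transformed to the wavelet
#' domain once up front; a `val_fraction` share of the shuffled patches is
#' held out and scored by reconstruction PSNR after every epoch. Fully
#' deterministic for a fixed `train_config$seed`.
#'
#' @param dataset list of LR/HR patch pairs (e.g. from [make_dataset()] or
#'   [extract_patches()]).
#' @param net_config a [network_config()]; its scale must match
#'   `train_config$scale`.
#' @param train_config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return a `wfsan_model` with an additional `history` data.frame
#'   (columns `epoch`, `lr`, `train_loss`, `val_psnr`, `bicubic_psnr`).
#' @export
train_model <- function(dataset, net_config, train_config,
                        verbose = FALSE) {
  if (length(dataset) == 0) stop("dataset is empty")
  if (net_config$scale != train_config$scale) {
    stop("network scale and training scale differ")
  }
  set.seed(train_config$seed)
  dataset <- dataset[sample.int(length(dataset))]
  n_val <- max(1L, floor(train_config$val_fraction * length(dataset)))
  if (n_val >= length(dataset)) stop("dataset too small for a validation split")
  val_pairs <- dataset[(length(dataset) - n_val + 1L):length(dataset)]
  tr_pairs <- dataset[seq_len(length(dataset) - n_val)]

  norm <- net_config$normalization
  tr <- stack_band_tensors(tr_pairs, norm)
  val <- stack_band_tensors(val_pairs, norm)
  # the residual bases are fixed per sample: upsample them once
  tr_base <- val_base <- NULL
  if (net_config$residual) {
    s <- net_config$scale
    tr_base <- wavesr_residual_base(tr$lca, tr$lcd, s)
    val_base <- wavesr_residual_base(val$lca, val$lcd, s)
  }
  bicubic_ref <- mean(vapply(val_pairs, function(pr) {
    psnr(pr$hr, clip_pixels(bicubic_upscale(pr$lr, train_config$scale)))
  }, numeric(1)))

  model <- init_wfsan(net_config, seed = train_config$seed)
  opt <- adam_init(model$params)
  n_tr <- length(tr_pairs)
  sched <- 1.0
  history <- vector("list", train_config$max_epochs)

  for (epoch in seq_len(train_config$max_epochs)) {
    sched <- cosine_decay_lr(list(epoch = epoch, lr = sched), train_config)
    lr <- train_config$initial_lr * sched
    order <- sample.int(n_tr)
    epoch_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n_tr, by = train_config$batch_size)) {
      idx <- order[start:min(start + train_config$batch_size - 1L, n_tr)]
      nb <- length(idx)
      lca <- tr$lca[, , , idx, drop = FALSE]
      lcd <- tr$lcd[, , , idx, drop = FALSE]
      hca <- tr$hca[, , , idx, drop = FALSE]
      hcd <- tr$hcd[, , , idx, drop = FALSE]
      base <- if (is.null(tr_base)) NULL else {
        list(a = tr_base$a[, , , idx, drop = FALSE],
             d = tr_base$d[, , , idx, drop = FALSE])
      }
      fwd <- wfsan_forward_full(model, lca, lcd, keep_cache = TRUE,
                                resid_base = base)
      diff_a <- fwd$hca - hca
      diff_d <- fwd$hcd - hcd
      loss <- (sum(diff_a^2) + sum(diff_d^2)) / (2 * nb)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      grads <- wfsan_backward(model, fwd$cache, diff_a / nb, diff_d / nb)
      grads <- clip_gradients(grads, train_config$grad_clip_norm)$grads
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$state
      epoch_loss <- epoch_loss + loss
      n_batches <- n_batches + 1L
    }
    val_psnr <- validate_psnr(model, val, val_pairs, norm, val_base)
    history[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = epoch_loss / n_batches,
      val_psnr = val_psnr, bicubic_psnr = bicubic_ref
    )
    if (verbose) {
      message(sprintf("epoch %3d  lr %.3g  loss %.5f  val PSNR %.2f dB",
                      epoch, lr, epoch_loss / n_batches, val_psnr))
    }
  }
  model$history <- do.call(rbind, history)
  model$train_config <- train_config
  model
}

# Mean reconstruction PSNR of the held-out patches.
validate_psnr <- function(model, val, val_pairs, norm, val_base = NULL) {
  out <- wfsan_forward_full(model, val$lca, val$lcd,
                            resid_base = val_base)
  n <- length(val_pairs)
  total <- 0
  for (i in seq_len(n)) {
    bands <- merge_bands(out$hca[, , 1L, i], out$hcd[, , , i])
    rec <- clip_pixels(iswt2_level1(bands) * norm)
    total <- total + psnr(val_pairs[[i]]$hr, rec)
  }
  total / n
}
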