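#' Closed-form parameter counts for the block types
#'
#' Analytic trainable-parameter counts for the three lightweight block
#' designs, with `N` input channels, `C` primary filters, kernel size `k`
#' and (for the mini-grid block only) `M` second-stage output channels:
#' \itemize{
#'   \item mini grid network: `(N*k^2 + 1)*C + (C*k^2 + 1)*M`
#'   \item ghost extension block: `(N*k^2 + 1)*C + C*k^2`
#'   \item attention ghost extension block: ghost `+ 2*k^2`
#' }
#' The `+1` terms are the biases of the dense convolutions; the cheap
#' depthwise stage and the attention merge convolution are bias-free, so
#' the attention variant costs exactly `2*k^2` extra parameters.
#'
#' @param kind `"mini_grid"`, `"ghost"` or `"attention_ghost"`.
#' @param N input channels.
#' @param C primary filter count.
#' @param k kernel size.
#' @param M second-stage output channels (mini-grid only; ignored
#'   otherwise).
#' @return parameter count.
#' @export
param_count <- function(kind, N, C, k = 3, M = NULL) {
  check_complexity_inputs(N = N, C = C, k = k)
  switch(kind,
    mini_grid = {
      check_complexity_inputs(M = M)
      (N * k^2 + 1) * C + (C * k^2 + 1) * M
    },
    ghost = (N * k^2 + 1) * C + C * k^2,
    attention_ghost = (N * k^2 + 1) * C + C * k^2 + 2 * k^2,
    stop("unknown block kind '", kind, "'")
  )
}

#' Closed-form FLOP counts for the block types
#'
#' One multiply-accumulate counts as 2 FLOPs. On an `H x W` feature map:
#' mini grid `2*k^2*C*H*W*(N+M)`; ghost `2*k^2*C*H*W*(N+1)` (the `+1` is
#' the depthwise cheap stage); attention ghost adds `4*k^2*H*W` for the
#' 2-channel merge convolution.
#'
#' @inheritParams param_count
#' @param H,W spatial size of the feature maps.
#' @return FLOP count.
#' @export
flop_count <- function(kind, N, C, H, W, k = 3, M = NULL) {
  check_complexity_inputs(N = N, C = C, k = k, H = H, W = W)
  switch(kind,
    mini_grid = {
      check_complexity_inputs(M = M)
      2 * k^2 * C * H * W * (N + M)
    },
    ghost = 2 * k^2 * C * H * W * (N + 1),
    attention_ghost = 2 * k^2 * C * H * W * (N + 1) + 4 * k^2 * H * W,
    stop("unknown block kind '", kind, "'")
  )
}

check_complexity_inputs <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (is.null(v) || length(v) != 1 || !is.numeric(v) || v < 1 ||
        v != round(v)) {
      stop("complexity input ", nm, " must be a positive integer")
    }
  }
  invisible(NULL)
}

#' Per-layer parameter census of an instantiated network
#'
#' Instantiates the network described by `config` and enumerates the
#' trainable parameters of every weight tensor. Block subtotals equal the
#' analytic [param_count()] values, which the test-suite asserts for every
#' supported configuration.
#'
#' @param config a [network_config()] object.
#' @return data.frame with columns `layer` and `parameters`; the total is
#'   attached as attribute `total` and also printed by `sum()` over the
#'   column.
#' @export
model_param_census <- function(config = network_config()) {
  model <- init_wfsan(config, seed = 1L)
  census <- data.frame(
    layer = names(model$params),
    parameters = vapply(model$params, length, integer(1)),
    row.names = NULL
  )
  attr(census, "total") <- sum(census$parameters)
  census
}
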