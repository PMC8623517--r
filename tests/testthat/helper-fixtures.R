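# Shared helpers: independent oracles and small generators used across the
# test files. The SWT oracle slides a 2x2 window with periodic wrap-around
# and evaluates the signed half-sums directly, independent of the package's
# vectorized implementation.

oracle_swt <- function(x) {
  h <- nrow(x)
  w <- ncol(x)
  A <- H <- V <- D <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      a <- x[i, j]
      b <- x[i, j %% w + 1]
      c <- x[i %% h + 1, j]
      d <- x[i %% h + 1, j %% w + 1]
      A[i, j] <- (a + b + c + d) / 2
      H[i, j] <- (a + b - c - d) / 2
      V[i, j] <- (a - b + c - d) / 2
      D[i, j] <- (a - b - c + d) / 2
    }
  }
  list(A = A, H = H, V = V, D = D)
}

rand_image <- function(h, w = h) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# naive dense convolution (zero same-padding), for cross-checking the
# GEMM-based implementation
naive_conv <- function(x, w, b) {
  d <- dim(x)
  k <- dim(w)[1]
  p <- (k - 1) / 2
  co <- dim(w)[4]
  y <- array(0, c(d[1], d[2], co, d[4]))
  for (n in seq_len(d[4])) {
    for (oc in seq_len(co)) {
      acc <- matrix(b[oc], d[1], d[2])
      for (ic in seq_len(d[3])) {
        for (kh in seq_len(k)) {
          for (kw in seq_len(k)) {
            for (i in seq_len(d[1])) {
              ii <- i + kh - 1 - p
              if (ii < 1 || ii > d[1]) next
              for (j in seq_len(d[2])) {
                jj <- j + kw - 1 - p
                if (jj < 1 || jj > d[2]) next
                acc[i, j] <- acc[i, j] + x[ii, jj, ic, n] * w[kh, kw, ic, oc]
              }
            }
          }
        }
      }
      y[, , oc, n] <- acc
    }
  }
  y
}

tiny_config <- function(...) {
  network_config(scale = 2, base_filters = 4, ...)
}
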