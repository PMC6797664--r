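# Internal separable convolution with symmetric (edge-repeating) boundary
# handling.  Convolutions are realized as banded-matrix products so that
# BLAS does the work; kernels used here are symmetric or used in symmetric
# pairs, so convolution and correlation coincide up to signs that cancel.

# Banded matrix mapping a symmetrically padded signal of length n + 2r to
# the n filter responses.
.convBand <- function(n, k) {
  L <- length(k)
  K <- matrix(0, n, n + L - 1L)
  for (j in seq_len(L)) K[cbind(seq_len(n), seq_len(n) + j - 1L)] <- k[j]
  K
}

.symPadIdx <- function(n, r) {
  if (r >= n) stop("kernel radius exceeds image extent")
  c(r:1, 1:n, n:(n - r + 1L))
}

# Separable filtering of matrix X: kernel kRow runs along dim 1 (down each
# column), kCol along dim 2.  Both kernels must have odd length.
.sepFilter <- function(X, kRow, kCol) {
  rR <- (length(kRow) - 1L) %/% 2L
  rC <- (length(kCol) - 1L) %/% 2L
  Y <- .convBand(nrow(X), kRow) %*% X[.symPadIdx(nrow(X), rR), , drop = FALSE]
  Y <- Y[, .symPadIdx(ncol(X), rC), drop = FALSE] %*% t(.convBand(ncol(X), kCol))
  Y
}

# Sampled Gaussian and its scale-space derivatives (order 0, 1, 2).
.gaussKernel <- function(sigma, order = 0L, radius = ceiling(3 * sigma)) {
  t <- seq(-radius, radius)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(order + 1L,
    g,
    -t / sigma^2 * g,
    (t^2 - sigma^2) / sigma^4 * g)
}
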