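# Daubechies-7 discrete wavelet detrending.  The analysis/synthesis filter
# bank is the standard orthogonal db7 bank; signals are extended
# symmetrically (edge value repeated) before each convolution, and all
# boundary coefficients are kept so the transform is perfectly invertible.

.DB7_DEC_LO <- c(
   0.00035371379997452024, -0.0018016407040474908,  0.0004295779729213665,
   0.01255099855609984,    -0.01657454163066688,   -0.03802993693501441,
   0.08061260915108308,     0.07130921926683026,   -0.22403618499387498,
  -0.14390600392856498,     0.4697822874051931,     0.7291320908462351,
   0.3965393194819173,      0.07785205408500918)
.DB7_DEC_HI <- rev(.DB7_DEC_LO) * rep_len(c(-1, 1), 14L)
.DB7_REC_LO <- rev(.DB7_DEC_LO)
.DB7_REC_HI <- rev(.DB7_DEC_HI)

# Full convolution along rows of X (each row a signal) by shift-add.
.convRowsFull <- function(X, f) {
  n <- ncol(X); L <- length(f)
  Y <- matrix(0, nrow(X), n + L - 1L)
  for (t in seq_len(L))
    Y[, t:(t + n - 1L)] <- Y[, t:(t + n - 1L)] + f[t] * X
  Y
}

# One analysis step for all rows of X: symmetric extension by L-1, valid
# convolution, dyadic downsampling.  Output length floor((n + L - 1) / 2).
.dwtStepRows <- function(X, f) {
  L <- length(f); p <- L - 1L; n <- ncol(X)
  XE <- X[, c(p:1, 1:n, n:(n - p + 1L)), drop = FALSE]
  Y <- .convRowsFull(XE, f)
  valid <- Y[, L:(ncol(Y) - L + 1L), drop = FALSE]
  valid[, seq(2L, ncol(valid), by = 2L), drop = FALSE]
}

# One synthesis step from approximation coefficients only (details zero).
.idwtStepRows <- function(cA, outLen, f) {
  L <- length(f)
  U <- matrix(0, nrow(cA), 2L * ncol(cA))
  U[, seq(1L, ncol(U), by = 2L)] <- cA
  Y <- .convRowsFull(U, f)
  Y[, (L - 1L):(L - 2L + outLen), drop = FALSE]
}

# Low-frequency trend of each row: cascade the analysis lowpass `level`
# times, then resynthesize the approximation branch alone.
.rowTrend <- function(X, level) {
  lens <- integer(level)
  A <- X
  for (j in seq_len(level)) {
    lens[j] <- ncol(A)
    A <- .dwtStepRows(A, .DB7_DEC_LO)
  }
  for (j in rev(seq_len(level)))
    A <- .idwtStepRows(A, lens[j], .DB7_REC_LO)
  A
}

#' Remove the low-frequency illumination trend from a grayscale image
#'
#' Detrends the image with a Daubechies-7 discrete wavelet decomposition:
#' every image row is decomposed to \code{waveletLevel} levels, the
#' approximation (trend) branch is resynthesized and subtracted, and the
#' same procedure is then applied to every column of the row-detrended
#' result.  Boundary handling is symmetric, so a constant image detrends to
#' (numerically) zero and the operation is linear in the input.
#'
#' @param img numeric matrix, grayscale image indexed \code{[row, col]}.
#' @param waveletLevel integer, decomposition depth (default 7).
#' @return numeric matrix of the same dimensions: \code{img} minus its
#'   smooth trend.
#' @examples
#' x <- outer(seq_len(256), seq_len(256), function(i, j) i / 256 + j / 512)
#' d <- detrendImage(x)
#' max(abs(d)) < 1e-6   # a smooth ramp is pure trend
#' @export
detrendImage <- function(img, waveletLevel = 7L) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (!all(is.finite(img))) stop("image contains non-finite values")
  waveletLevel <- as.integer(waveletLevel)
  if (waveletLevel < 1L) stop("waveletLevel must be >= 1")
  if (min(dim(img)) < 2^waveletLevel)
    stop("image too small for wavelet level ", waveletLevel,
         " (need min dimension >= ", 2^waveletLevel, ")")
  Y <- img - .rowTrend(img, waveletLevel)
  Y <- t(t(Y) - .rowTrend(t(Y), waveletLevel))
  Y
}
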