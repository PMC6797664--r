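#' Prominence-based peak detection
#'
#' Finds the significant peaks of a 1-D signal.  Local maxima (plateau
#' centers) are kept when their topographic prominence is at least
#' \code{prominenceFrac} times the signal range.  Each kept peak is
#' reported with its onset and offset -- the nearest flanking local minima,
#' clipped at the signal ends -- its amplitude (signal value at the peak)
#' and its width, the number of samples strictly between onset and offset.
#'
#' @param signal numeric vector, all finite.
#' @param prominenceFrac fraction of the signal range a peak's prominence
#'   must reach (default 0.1).
#' @return data.frame with one row per peak and columns \code{peak} (index),
#'   \code{on}, \code{off}, \code{amplitude}, \code{width},
#'   \code{prominence}.  Zero rows for flat or empty signals.
#' @examples
#' s <- c(0, 0, 1, 3, 1, 0, 0, 2, 0)
#' detectPeaks(s)
#' @export
detectPeaks <- function(signal, prominenceFrac = 0.1) {
  empty <- data.frame(peak = integer(0), on = integer(0), off = integer(0),
                      amplitude = numeric(0), width = numeric(0),
                      prominence = numeric(0))
  n <- length(signal)
  if (n < 3L) return(empty)
  if (!all(is.finite(signal))) stop("signal must be finite")
  rng <- max(signal) - min(signal)
  if (rng == 0) return(empty)

  # plateau-aware local maxima: runs strictly higher than both neighbours
  r <- rle(signal)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  isMax <- logical(k)
  for (i in seq_len(k)) {
    lo <- if (i == 1L) -Inf else r$values[i - 1L]
    hi <- if (i == k) -Inf else r$values[i + 1L]
    isMax[i] <- r$values[i] > lo && r$values[i] > hi
  }
  # plateau minima, boundary runs included (used for onset/offset search)
  isMin <- logical(k)
  for (i in seq_len(k)) {
    lo <- if (i == 1L) Inf else r$values[i - 1L]
    hi <- if (i == k) Inf else r$values[i + 1L]
    isMin[i] <- r$values[i] < lo && r$values[i] < hi
  }
  peakIdx <- (starts[isMax] + ends[isMax]) %/% 2L
  if (!length(peakIdx)) return(empty)
  minPos <- sort(c(starts[isMin], ends[isMin]))

  # nearest strictly higher sample on each side (monotonic stack, O(n))
  nhl <- integer(n); stack <- integer(0)
  for (i in seq_len(n)) {
    while (length(stack) && signal[stack[length(stack)]] <= signal[i])
      stack <- stack[-length(stack)]
    nhl[i] <- if (length(stack)) stack[length(stack)] else 0L
    stack <- c(stack, i)
  }
  nhr <- integer(n); stack <- integer(0)
  for (i in rev(seq_len(n))) {
    while (length(stack) && signal[stack[length(stack)]] <= signal[i])
      stack <- stack[-length(stack)]
    nhr[i] <- if (length(stack)) stack[length(stack)] else n + 1L
    stack <- c(stack, i)
  }
  # sparse table for range minima
  logn <- max(1L, floor(log2(n)))
  tab <- matrix(0, n, logn + 1L)
  tab[, 1L] <- signal
  for (j in seq_len(logn)) {
    len <- 2L^(j - 1L)
    idx <- seq_len(n - 2L * len + 1L)
    tab[idx, j + 1L] <- pmin(tab[idx, j], tab[idx + len, j])
  }
  rangeMin <- function(a, b) {       # vectorized over pairs, a <= b
    j <- ifelse(b > a, floor(log2(b - a + 1L)), 0L)
    len <- 2L^j
    pmin(tab[cbind(a, j + 1L)], tab[cbind(b - len + 1L, j + 1L)])
  }
  h <- signal[peakIdx]
  lv <- rangeMin(pmax(nhl[peakIdx] + 1L, 1L), peakIdx)
  rv <- rangeMin(peakIdx, pmin(nhr[peakIdx] - 1L, n))
  # a side with no valley below the peak (boundary peak or plateau flush
  # with the signal end) does not constrain the prominence
  lv[lv >= h] <- -Inf
  rv[rv >= h] <- -Inf
  prom <- h - pmax(lv, rv)
  keep <- prom >= prominenceFrac * rng
  peakIdx <- peakIdx[keep]
  if (!length(peakIdx)) return(empty)
  on <- vapply(peakIdx, function(i) {
    lmins <- minPos[minPos < i]
    if (length(lmins)) max(lmins) else 1L
  }, integer(1))
  off <- vapply(peakIdx, function(i) {
    rmins <- minPos[minPos > i]
    if (length(rmins)) min(rmins) else n
  }, integer(1))
  data.frame(peak = peakIdx, on = on, off = off,
             amplitude = signal[peakIdx],
             width = pmax(off - on - 1L, 1L),
             prominence = prom[keep])
}
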