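# Independent brute-force oracle for the 24 features: plain loops and
# explicit least squares, sharing no code with the package implementation.

oracleSG <- function(v, p, n, m) {
  h <- (n - 1) %/% 2
  N <- length(v)
  out <- numeric(N)
  fitAt <- function(win, at) {
    t <- seq_along(win) - 1
    X <- outer(t, 0:p, "^")
    cf <- qr.solve(X, win)
    s <- 0
    for (j in m:p)
      s <- s + cf[j + 1] * factorial(j) / factorial(j - m) * at^(j - m)
    s
  }
  for (i in seq_len(N)) {
    out[i] <- if (i <= h) fitAt(v[1:n], i - 1)
    else if (i > N - h) fitAt(v[(N - n + 1):N], n - (N - i) - 1)
    else fitAt(v[(i - h):(i + h)], h)
  }
  out
}

oraclePeaks <- function(signal, prominenceFrac = 0.1) {
  empty <- data.frame(peak = integer(0), on = integer(0), off = integer(0),
                      amplitude = numeric(0), width = numeric(0))
  n <- length(signal)
  if (n < 3) return(empty)
  rng <- max(signal) - min(signal)
  if (rng == 0) return(empty)
  runStart <- c(1, which(diff(signal) != 0) + 1)
  runEnd <- c(runStart[-1] - 1, n)
  vals <- signal[runStart]
  k <- length(vals)
  peaks <- integer(0); mins <- integer(0)
  for (i in seq_len(k)) {
    lo <- if (i == 1) -Inf else vals[i - 1]
    hi <- if (i == k) -Inf else vals[i + 1]
    if (vals[i] > lo && vals[i] > hi)
      peaks <- c(peaks, (runStart[i] + runEnd[i]) %/% 2)
    lo2 <- if (i == 1) Inf else vals[i - 1]
    hi2 <- if (i == k) Inf else vals[i + 1]
    if (vals[i] < lo2 && vals[i] < hi2)
      mins <- c(mins, runStart[i], runEnd[i])
  }
  mins <- sort(unique(mins))
  rows <- empty
  for (pk in peaks) {
    h <- signal[pk]
    lv <- h; j <- pk
    while (j > 1) { j <- j - 1; if (signal[j] > h) break
      lv <- min(lv, signal[j]) }
    rv <- h; j <- pk
    while (j < n) { j <- j + 1; if (signal[j] > h) break
      rv <- min(rv, signal[j]) }
    if (lv >= h) lv <- -Inf     # side without a valley is unconstrained
    if (rv >= h) rv <- -Inf
    if (h - max(lv, rv) >= prominenceFrac * rng) {
      l <- mins[mins < pk]; r <- mins[mins > pk]
      on <- if (length(l)) max(l) else 1L
      off <- if (length(r)) min(r) else n
      rows <- rbind(rows, data.frame(peak = pk, on = on, off = off,
                                     amplitude = h,
                                     width = max(off - on - 1, 1)))
    }
  }
  rows
}

.oracleSignChanges <- function(v, tol) {
  d <- if (length(v) < 5) diff(v) else oracleSG(v, 2, 5, 1)
  s <- integer(0)
  for (x in d) {
    if (abs(x) <= tol) next
    s <- c(s, if (x > 0) 1L else -1L)
  }
  cnt <- 0L
  if (length(s) > 1)
    for (i in 2:length(s)) if (s[i] != s[i - 1]) cnt <- cnt + 1L
  cnt
}

.oraclePolyErr <- function(v) {
  t <- seq_along(v)
  X <- cbind(1, t, t^2, t^3)
  r <- v - X %*% qr.solve(X, v)
  sqrt(mean(r^2))
}

oracleFeatures <- function(ind, prominenceFrac = 0.1, angTol = 0.2,
                           disTol = 0.05, curFloor = 0.02) {
  hgdv <- hgd(ind); riav <- ria(ind)
  angL <- ang(ind); disL <- dis(ind); curv <- cur(ind)
  F <- numeric(24)
  # HGD
  if (length(hgdv)) {
    for (x in hgdv) F[1] <- F[1] + x^2
    F[2] <- min(hgdv); F[3] <- max(hgdv) - min(hgdv)
    pk <- oraclePeaks(hgdv, prominenceFrac)
    if (F[1] > 0 && nrow(pk)) {
      e <- 0
      for (i in seq_len(nrow(pk)))
        for (g in pk$on[i]:pk$off[i]) e <- e + hgdv[g]^2
      F[4] <- e / F[1]
    }
  }
  # RIA
  if (length(riav)) {
    for (x in riav) F[5] <- F[5] + x^2
    pk <- oraclePeaks(riav, prominenceFrac)
    F[6] <- nrow(pk)
    if (nrow(pk) && F[5] > 0) {
      es <- numeric(nrow(pk)); rat <- numeric(nrow(pk))
      for (i in seq_len(nrow(pk))) {
        for (g in pk$on[i]:pk$off[i]) es[i] <- es[i] + riav[g]^2
        rat[i] <- pk$amplitude[i] / pk$width[i]
      }
      F[7] <- mean(es) / F[5]
      F[8] <- mean(rat)
    }
  }
  # ANG / DIS blocks
  blocks <- list(list(angL, angTol, 9L), list(disL, disTol, 15L))
  for (b in blocks) {
    L <- b[[1]]; tol <- b[[2]]; o <- b[[3]]
    if (length(L)) {
      s <- vapply(L, .oracleSignChanges, integer(1), tol = tol)
      F[o] <- mean(s); F[o + 1] <- sum(s); F[o + 2] <- max(s)
      F[o + 3] <- median(s)
      fit <- L[vapply(L, length, integer(1)) >= 4]
      if (length(fit)) {
        e <- vapply(fit, .oraclePolyErr, numeric(1))
        F[o + 4] <- mean(e); F[o + 5] <- median(e)
      }
    }
  }
  # CUR
  if (length(curv)) {
    for (x in curv) F[21] <- F[21] + x^2
    F[22] <- if (length(curv) > 1) var(curv) else 0
    pk <- oraclePeaks(abs(curv), prominenceFrac)
    pk <- pk[pk$amplitude >= curFloor, , drop = FALSE]
    F[23] <- nrow(pk)
    if (nrow(pk)) F[24] <- nrow(pk) * sum(pk$amplitude)
  }
  names(F) <- featureNames()
  F
}

randomIndicatorSet <- function(seed) {
  set.seed(seed)
  M <- sample(2:6, 1)
  lens <- sample(25:60, M, replace = TRUE)
  angL <- lapply(lens, function(L) cumsum(rnorm(L, sd = 3)) + 90)
  disL <- lapply(lens, function(L) cumsum(runif(L, -0.4, 1.2)))
  hgdv <- abs(rnorm(180))^2
  hgdv <- hgdv / sum(hgdv)
  riav <- as.numeric(stats::filter(abs(rnorm(240)), rep(0.2, 5), sides = 2))
  riav[is.na(riav)] <- 0
  curv <- rnorm(sum(lens), sd = 0.05)
  makeIndicatorSet(hgd = hgdv, ria = riav, ang = angL, dis = disL,
                   cur = curv, curLengths = lens)
}
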