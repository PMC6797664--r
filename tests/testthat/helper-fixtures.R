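# Shared fixtures: digital curves, indicator-set construction, and a
# memoized synthetic-benchmark feature table so the expensive extraction
# runs once per test session.

circlePath <- function(r, center = c(110, 110)) {
  th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * r * 6))
  p <- cbind(round(center[1] + r * cos(th)), round(center[2] + r * sin(th)))
  p[c(TRUE, rowSums(abs(diff(p))) > 0), , drop = FALSE]
}

digitalLinePath <- function(slope, len = 80, row0 = 10) {
  cc <- seq_len(len)
  cbind(round(row0 + slope * cc), cc)
}

segmentSetFromPaths <- function(paths, dim = c(220L, 220L)) {
  new("SegmentSet",
      segments = lapply(paths, assignReference),
      imageDim = as.integer(dim))
}

makeIndicatorSet <- function(hgd = numeric(0), ria = numeric(0),
                             ang = list(), dis = list(),
                             cur = numeric(0),
                             curLengths = if (length(cur)) length(cur)
                                          else integer(0)) {
  new("IndicatorSet", hgd = hgd, ria = ria,
      riaLengths = if (length(ria)) length(ria) else integer(0),
      ang = ang, dis = dis, cur = cur,
      curLengths = as.integer(curLengths))
}

# a zigzag profile with exactly k direction reversals (long linear runs,
# so the smoothed derivative has k sign changes)
zigzag <- function(k, runLen = 12, amp = 10) {
  v <- 0
  dir <- 1
  for (i in seq_len(k + 1)) {
    v <- c(v, v[length(v)] + dir * amp * seq_len(runLen) / runLen)
    dir <- -dir
  }
  v
}

# ---- memoized benchmark feature table ------------------------------------
.benchEnv <- new.env(parent = emptyenv())

.benchGens <- list(order = genOrder, disorder = genDisorder,
                   very_disorder = genVeryDisorder)

benchFeatureRow <- function(cl, i, seed = 7) {
  key <- sprintf("f_%d_%s_%d", seed, cl, i)
  if (is.null(.benchEnv[[key]])) {
    cfg <- synthConfig(seed = seed)
    .benchEnv[[key]] <-
      imageFeatures(synthImage(.benchGens[[cl]](cfg, i)))
  }
  .benchEnv[[key]]
}

benchFeatureTable <- function(nPerClass, seed = 7) {
  rows <- list()
  for (cl in names(.benchGens)) for (i in seq_len(nPerClass)) {
    rows[[paste(cl, i)]] <- data.frame(label = cl,
                                       t(benchFeatureRow(cl, i, seed)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}
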