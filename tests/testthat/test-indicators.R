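# The five indicator signals and the peak detector.

test_that("HGD concentrates the mass of parallel stripes in two bins", {
  img <- matrix(rep(sin(2 * pi * (1:128) / 16), each = 128), 128, 128)
  h <- computeHGD(img)
  expect_equal(sum(h), 1)
  expect_true(all(h >= 0))
  top <- order(h, decreasing = TRUE)[1:2]
  expect_equal(abs(diff(top)), 90)      # 180 degrees apart at 2 deg bins
  expect_gt(sum(h[top]), 0.6)
})

test_that("HGD is invariant under uniform intensity scaling", {
  set.seed(21)
  img <- matrix(rnorm(90 * 90), 90, 90)
  expect_equal(computeHGD(img), computeHGD(17 * img), tolerance = 1e-12)
  expect_length(computeHGD(matrix(1, 80, 80)), 0)
})

test_that("rotating the image by 90 degrees shifts the HGD circularly", {
  set.seed(31)
  base <- matrix(rnorm(40 * 40), 40, 40)
  img <- VesselQuant:::.sepFilter(base, VesselQuant:::.gaussKernel(2),
                                  VesselQuant:::.gaussKernel(2))
  rot90 <- t(img)[nrow(t(img)):1, ]     # proper 90 degree rotation
  h <- computeHGD(img)
  h2 <- computeHGD(rot90)
  # gradient angles drop by 90 degrees (45 bins) under this rotation
  aligned <- c(h2[136:180], h2[1:135])
  expect_lt(sum(abs(h - aligned)) / 2, 0.1)
})

test_that("RIA concatenates per-rotation row means with zero fill", {
  z <- matrix(0, 96, 96)
  r <- computeRIA(z)
  expect_true(all(r$values == 0))
  expect_equal(length(r$values), sum(r$lengths))
  expect_length(r$lengths, 8)

  imf <- matrix(0, 128, 128)
  imf[c(30, 60, 90), ] <- 1
  r <- computeRIA(imf)
  s0 <- r$values[seq_len(r$lengths[1])]
  expect_equal(nrow(detectPeaks(s0)), 3)

  # energy at the aligned rotation dominates the orthogonal one
  s90 <- r$values[(sum(r$lengths[1:2]) + 1):sum(r$lengths[1:3])]
  expect_gt(sum(s0^2), sum(s90^2))
})

test_that("ANG and DIS follow the reference-point geometry", {
  p <- cbind(rep(10L, 30), 5L + 0:29)   # along the baseline through A
  ss <- segmentSetFromPaths(list(p), c(64, 64))
  ad <- computeAngDis(ss)
  expect_equal(ad$dis[[1]], 0:29)
  expect_equal(ad$ang[[1]], rep(0, 30))

  # C at 90 degrees from the baseline, |AC| = 5
  p2 <- cbind(10L + 0:20, rep(5L, 21))
  ad2 <- computeAngDis(segmentSetFromPaths(list(p2), c(64, 64)))
  expect_equal(ad2$dis[[1]][6], 5)
  expect_equal(ad2$ang[[1]][6], 90)
  expect_equal(ad2$ang[[1]][1], 0)      # C == A is defined as angle 0

  # full-period sinusoidal segment: DIS is non-monotone
  t <- seq(0, 2 * pi, length.out = 120)
  ps <- cbind(round(60 + 15 * sin(t)), round(10 + t * 18))
  ps <- ps[c(TRUE, rowSums(abs(diff(ps))) > 0), ]
  ad3 <- computeAngDis(segmentSetFromPaths(list(ps), c(256, 256)))
  dd <- diff(ad3$dis[[1]])
  expect_gte(sum(diff(sign(dd[dd != 0])) != 0), 2)
  expect_true(all(ad3$ang[[1]] >= 0 & ad3$ang[[1]] <= 180))
})

test_that("curvature matches the analytic circle and line oracles", {
  for (r in c(10, 20, 40)) {
    ss <- segmentSetFromPaths(list(circlePath(r)))
    k <- computeCUR(ss)$values
    expect_lt(abs(mean(abs(k)) - 1 / r) * r, 0.2)
  }
  for (sl in c(0, 1, 0.5, 0.25)) {
    ss <- segmentSetFromPaths(list(digitalLinePath(sl)), c(120, 120))
    expect_lt(max(abs(computeCUR(ss)$values)), 0.01)
  }
})

test_that("curvature magnitude is orientation-invariant and concatenates", {
  p <- circlePath(15)
  ssF <- segmentSetFromPaths(list(p))
  ssR <- segmentSetFromPaths(list(p[nrow(p):1, ]))
  kF <- computeCUR(ssF)$values
  kR <- computeCUR(ssR)$values
  expect_equal(abs(kF), rev(abs(kR)), tolerance = 1e-9)
  expect_equal(sign(kF[10]), -sign(rev(kR)[10]))  # reversal flips the sign

  ss2 <- segmentSetFromPaths(list(circlePath(12), digitalLinePath(0, 60)))
  cc <- computeCUR(ss2)
  expect_equal(length(cc$values), sum(cc$lengths))
  expect_equal(cc$lengths,
               vapply(segments(ss2), function(s) nrow(s@path), integer(1)))
})

test_that("peak detection honours prominence and plateau geometry", {
  expect_equal(nrow(detectPeaks(rep(1, 30))), 0)
  expect_equal(nrow(detectPeaks(numeric(0))), 0)

  tri <- c(0, 0, 1, 2, 3, 2, 1, 0, 0)
  pk <- detectPeaks(tri)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak, 5)
  expect_equal(pk$on, 2)
  expect_equal(pk$off, 8)
  expect_equal(pk$amplitude, 3)

  g <- dnorm(1:100, 30, 3) + 0.05 * dnorm(1:100, 70, 3)
  expect_equal(nrow(detectPeaks(g / max(g), prominenceFrac = 0.1)), 1)
  expect_error(detectPeaks(c(1, NA, 2)), "finite")
})

test_that("peak count is non-increasing in the prominence threshold", {
  set.seed(99)
  s <- as.numeric(stats::filter(rnorm(300), rep(0.25, 4), sides = 2))
  s[is.na(s)] <- 0
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8),
                   function(f) nrow(detectPeaks(s, f)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("computeIndicators assembles exactly the five indicators", {
  syn <- genVeryDisorder(synthConfig(seed = 4), 1)
  ind <- computeIndicators(preprocessFrame(synthImage(syn)))
  expect_s4_class(ind, "IndicatorSet")
  expect_gt(length(hgd(ind)), 0)
  expect_gt(length(ria(ind)), 0)
  expect_gt(length(ang(ind)), 0)
  expect_identical(length(ang(ind)), length(dis(ind)))
  expect_gt(length(cur(ind)), 0)
  # DIS starts at 0 under the A-at-head convention; ANG stays in range
  expect_true(all(vapply(dis(ind), function(v) v[1] == 0, logical(1))))
  expect_true(all(unlist(ang(ind)) >= 0 & unlist(ang(ind)) <= 180))
  expect_true(all(unlist(dis(ind)) >= 0))
})
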