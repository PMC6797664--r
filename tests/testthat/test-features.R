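# The 24 scalar features: analytic cases, block relations, and the
# brute-force oracle equivalence.

test_that("HGD features reproduce the closed-form cases", {
  B <- 20
  flat <- rep(1 / B, B)
  expect_equal(unname(hgdFeatures(flat)), c(1 / B, 1 / B, 0, 0))

  delta <- c(1, rep(0, B - 1))
  expect_equal(unname(hgdFeatures(delta)), c(1, 0, 1, 1))

  v <- c(0.5, 0.3, 0.2)
  f <- hgdFeatures(v)
  expect_equal(unname(f[1:3]), c(0.38, 0.2, 0.3))

  expect_equal(unname(hgdFeatures(numeric(0))), rep(0, 4))
})

test_that("RIA features reproduce the closed-form pulse cases", {
  expect_equal(unname(riaFeatures(rep(0, 40))), rep(0, 4))

  a <- 2.5; w <- 5
  pulse <- c(rep(0, 10), rep(a, w), rep(0, 10))
  f <- riaFeatures(pulse)
  expect_equal(unname(f["F5"]), a^2 * w)
  expect_equal(unname(f["F6"]), 1)
  expect_equal(unname(f["F7"]), 1)
  expect_equal(unname(f["F8"]), a / w)

  two <- c(rep(0, 8), rep(a, w), rep(0, 8), rep(a, w), rep(0, 8))
  expect_equal(unname(riaFeatures(two)["F7"]), 0.5)
})

test_that("sign-change features aggregate per-segment counts", {
  segs <- list(zigzag(2), zigzag(4), zigzag(6))
  expect_equal(signChangeCounts(segs), c(2L, 4L, 6L))
  f <- signChangeFeatures(segs)
  expect_equal(unname(f), c(4, 12, 6, 4))    # mean, total, max, median

  mono <- list(cumsum(runif(40, 0.1, 1)), seq(5, 50, length.out = 30))
  expect_equal(unname(signChangeFeatures(mono)), rep(0, 4))
  expect_equal(unname(signChangeFeatures(list())), rep(0, 4))
})

test_that("sinusoidal segments show two sign changes per period", {
  for (k in c(2, 3, 5)) {
    v <- 10 * sin(2 * pi * k * seq(0, 1, length.out = 40 * k))
    s <- signChangeCounts(list(v))
    expect_lte(abs(s - 2 * k), 1)
  }
})

test_that("cubic-fit errors vanish for cubics and aggregate correctly", {
  idx <- 1:50
  cubic <- 2 + 0.5 * idx - 0.02 * idx^2 + 1e-4 * idx^3
  f <- polyfitErrorFeatures(list(cubic))
  expect_lt(f[["mean"]], 1e-8)

  # residual-orthogonal construction: sequences with exact RMS 1, 2, 9
  mkErr <- function(target, n = 40, seed = 1) {
    set.seed(seed)
    raw <- rnorm(n)
    r <- resid(lm(raw ~ poly(seq_len(n), 3)))
    base <- 1 + 0.1 * seq_len(n)
    base + r * target / sqrt(mean(r^2))
  }
  segs <- lapply(c(1, 2, 9), mkErr)
  f <- polyfitErrorFeatures(segs)
  expect_equal(unname(f), c(4, 2), tolerance = 1e-8)

  # wavy segments fit worse than straight ones of equal length
  straight <- list(seq(0, 10, length.out = 60))
  wavy <- list(5 * sin(seq(0, 6 * pi, length.out = 60)))
  expect_gt(polyfitErrorFeatures(wavy)[["mean"]],
            polyfitErrorFeatures(straight)[["mean"]])
  expect_equal(unname(polyfitErrorFeatures(list(1:3))), c(0, 0))
})

test_that("CUR features reproduce the degenerate cases", {
  expect_equal(unname(curFeatures(numeric(0))), rep(0, 4))
  const <- rep(0.3, 25)
  f <- curFeatures(const)
  expect_equal(unname(f), c(25 * 0.09, 0, 0, 0))
})

test_that("extractFeatures assembles 24 named features in fixed order", {
  expect_identical(featureNames(), paste0("F", 1:24))

  blank <- makeIndicatorSet()
  expect_identical(unname(extractFeatures(blank)), rep(0, 24))

  ind <- randomIndicatorSet(500)
  fv1 <- extractFeatures(ind)
  fv2 <- extractFeatures(ind)
  expect_identical(fv1, fv2)
  expect_length(fv1, 24)
  expect_identical(names(fv1), featureNames())
  expect_true(all(is.finite(fv1)))
})

test_that("feature block identities hold on random indicator sets", {
  for (seed in c(3, 17, 88)) {
    ind <- randomIndicatorSet(seed)
    fv <- extractFeatures(ind)
    M <- length(ang(ind))
    sA <- signChangeCounts(ang(ind), tol = 0.2)
    expect_equal(unname(fv["F10"]), sum(sA))
    expect_equal(unname(fv["F9"]), fv[["F10"]] / M)
    expect_gte(fv[["F11"]], fv[["F12"]])
    expect_gte(fv[["F11"]], fv[["F9"]])
    sD <- signChangeCounts(dis(ind), tol = 0.05)
    expect_equal(unname(fv["F16"]), sum(sD))
    expect_equal(unname(fv["F15"]), fv[["F16"]] / M)
    expect_gte(fv[["F17"]], fv[["F18"]])
    expect_true(fv[["F4"]] >= 0 && fv[["F4"]] <= 1 + 1e-12)
    expect_true(fv[["F7"]] >= 0 && fv[["F7"]] <= 1 + 1e-12)
    expect_gte(fv[["F2"]], 0)
    expect_gte(fv[["F3"]], 0)
  }
})

test_that("features match the independent brute-force oracle", {
  for (seed in 1:20) {
    ind <- randomIndicatorSet(seed)
    a <- extractFeatures(ind)
    b <- oracleFeatures(ind)
    expect_true(all(abs(a - b) <= 1e-9 * pmax(1, abs(b))),
                info = paste("seed", seed))
  }
})
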