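# Preprocessing stages: grayscale policy, wavelet detrending, Frangi
# enhancement, binarization + thinning, and the composed chain.

test_that("grayscale conversion follows the channel policy", {
  g <- matrix(0.7, 32, 48)
  frame <- array(0, c(32, 48, 3))
  frame[, , 1] <- 0.2; frame[, , 2] <- 0.7; frame[, , 3] <- 0.9
  expect_equal(toGray(frame), g)

  gray <- matrix(runif(32 * 48), 32, 48)
  expect_identical(toGray(gray), gray)

  set.seed(11)
  rgb <- array(runif(32 * 48 * 3), c(32, 48, 3))
  expect_identical(toGray(rgb), rgb[, , 2])
  lum <- toGray(rgb, policy = "luminance")
  expect_equal(lum, 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] +
                 0.114 * rgb[, , 3])

  bad <- array(0.5, c(32, 48, 2))
  expect_error(toGray(bad), "channel")
})

test_that("wavelet detrending removes smooth trends and keeps lines", {
  const <- matrix(7.3, 160, 160)
  expect_lt(max(abs(detrendImage(const))), 1e-8 * 7.3)

  # smooth 2-D ramp plus a thin bright line grid: the detrended image
  # should essentially be the grid.  The grid lines run diagonally --
  # a line that is constant along a whole row (or column) IS that
  # signal's trend and is removed by design.
  n <- 256
  ramp <- outer(seq_len(n), seq_len(n), function(i, j)
    2 * i / n + j / n + (i * j) / n^2)
  grid <- outer(seq_len(n), seq_len(n), function(i, j)
    as.numeric((i + j) %% 40 == 0 | (i - j) %% 40 == 0))
  out <- detrendImage(ramp + grid)
  expect_identical(dim(out), dim(grid))
  expect_gt(cor(as.numeric(out), as.numeric(grid)), 0.9)
})

test_that("detrending is linear and matches an external DWT oracle", {
  set.seed(5)
  img <- matrix(rnorm(150 * 140), 150, 140)
  a <- detrendImage(img, waveletLevel = 4)
  b <- detrendImage(2.5 * img, waveletLevel = 4)
  expect_lt(max(abs(b - 2.5 * a)) / max(abs(b)), 1e-9)

  # frozen oracle: db7 level-3 decomposition of a 64-sample signal with the
  # approximation branch zeroed, computed with an independent DWT
  # implementation
  x <- c(0.000369046007,0.169357786625,0.166481509381,-0.021330962881,
    -0.078367119067,-0.296496006201,-0.199087846057,0.282341806975,
    0.214044930774,0.107267540193,0.333585234614,0.520016416427,
    0.631005770492,0.431230436444,0.501819969070,0.789776006773,
    0.465876721952,0.407957073005,-0.083044669570,-0.390540912140,
    -0.863696344113,-0.854858604070,-1.155727469138,-0.994983082126,
    -0.868592676774,-0.845306880798,-1.520969714679,-1.603212504068,
    -1.538397708323,-1.425039933157,-1.804715583444,-1.868676486889,
    -2.082867130941,-2.246153223403,-1.848518557022,-2.011413880257,
    -1.941805312375,-1.597123272795,-1.692838323253,-1.646983828763,
    -1.534479506424,-1.435979894782,-1.724131563342,-1.621924414864,
    -1.134912308976,-1.519690633050,-1.182510747278,-1.067339460204,
    -1.180415499071,-0.500925455804,-0.192882462813,-0.473304054080,
    -0.371584106083,-0.119212151617,-0.096481709857,0.187756449667,
    0.247166332987,0.526705680602,1.037627537464,0.914293941528,
    1.054600604010,0.994973410413,1.112519013146,0.835725734156)
  y <- c(0.081437028440,0.253441908717,0.237819835733,0.015124983708,
    -0.098880475319,-0.388648400947,-0.371815834139,0.028966223073,
    -0.113071261671,-0.285211887046,-0.107106814254,0.060395144244,
    0.184026923941,0.025190959421,0.160935837820,0.527379065358,
    0.293284629860,0.345369593942,-0.017154361216,-0.181081554557,
    -0.496114004324,-0.320425323505,-0.447001735811,-0.101355474976,
    0.214537995822,0.420522968061,-0.088362655606,-0.032347253104,
    0.138116850148,0.332332081935,0.011277620428,-0.011413969483,
    -0.198167595852,-0.352521348686,0.039858904486,-0.133561413421,
    -0.079680493832,0.241673080734,0.111978977946,0.104388830746,
    0.144578745684,0.162649527209,-0.210909908693,-0.195440529743,
    0.205478235311,-0.271455070646,-0.033693889569,-0.024379754949,
    -0.253146415498,0.298853985803,0.463116868204,0.014432810779,
    -0.074907014021,-0.025979053392,-0.210634939576,-0.124325223283,
    -0.244659236303,-0.126863315938,0.249967326700,0.033160035536,
    0.120916510727,0.043624746875,0.169517823008,-0.091581154687)
  X <- matrix(x, nrow = 1)
  mine <- as.numeric(X - VesselQuant:::.rowTrend(X, 3))
  expect_equal(mine, y, tolerance = 1e-9)

  expect_error(detrendImage(matrix(0, 40, 40), waveletLevel = 7),
               "too small")
})

test_that("Frangi response peaks on the centerline and stays in [0, 1]", {
  expect_equal(max(frangiEnhance(matrix(2, 70, 70))), 0)

  img <- matrix(1, 80, 120)
  prof <- exp(-((1:80) - 40)^2 / (2 * 2^2))
  img <- img - 0.6 * matrix(prof, 80, 120)
  v <- frangiEnhance(img, sigmas = 1:4)
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)
  centerline <- apply(v, 2, which.max)
  expect_true(all(abs(centerline - 40) <= 1))

  expect_error(frangiEnhance(img, sigmas = numeric(0)), "sigmas")
  expect_error(frangiEnhance(img, sigmas = c(1, -2)), "sigmas")
})

test_that("Frangi response is robust to ridge rotation", {
  n <- 121
  mk <- function(angleDeg) {
    a <- angleDeg * pi / 180
    i <- matrix(rep(seq_len(n), n), n) - (n + 1) / 2
    j <- matrix(rep(seq_len(n), each = n), n) - (n + 1) / 2
    d <- i * cos(a) + j * sin(a)     # signed distance to the ridge
    1 - 0.6 * exp(-d^2 / (2 * 2^2))
  }
  # compare the response on the true centerline band, away from borders
  resp <- function(img) {
    v <- frangiEnhance(img, sigmas = 1:4)
    core <- v[41:81, 41:81]
    mean(core[core > 0.5 * max(core)])
  }
  r0 <- resp(mk(0)); r45 <- resp(mk(45))
  expect_lt(abs(r45 - r0) / r0, 0.2)
})

test_that("binarization and thinning produce a one-pixel-wide skeleton", {
  z <- matrix(0, 60, 60)
  expect_identical(binarizeSkeletonize(z), matrix(FALSE, 60, 60))

  bar <- matrix(0, 40, 80)
  bar[19:21, 10:59] <- 1
  sk <- binarizeSkeletonize(bar)
  expect_true(sum(sk) >= 44 && sum(sk) <= 52)    # a single ~48 px path
  cn <- VesselQuant:::.crossingNumberMatrix(sk)
  expect_true(all(cn[sk] <= 2))                  # no branching
  expect_false(VesselQuant:::.hasFullBlock(sk))
  expect_identical(thinMask(sk), sk)             # thinning is idempotent
})

test_that("thinned masks never contain a fully set 2x2 block", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(runif(60 * 60) > 0.6, 60, 60)
    sk <- thinMask(m)
    expect_false(VesselQuant:::.hasFullBlock(sk))
    expect_identical(thinMask(sk), sk)
  }
})

test_that("the preprocessing chain composes and preserves dimensions", {
  syn <- genOrder(synthConfig(seed = 3))
  pp <- preprocessFrame(synthImage(syn))
  d <- dim(synthImage(syn))
  expect_identical(dim(enhanced(pp)), d)
  expect_identical(dim(filtered(pp)), d)
  expect_identical(dim(skeleton(pp)), d)
  segs <- extractSegments(skeleton(pp))
  expect_gte(nSegments(segs), 1)
  expect_gt(max(vapply(segments(segs), function(s) nrow(s@path),
                       integer(1))), 20)

  blank <- matrix(0.5, 128, 128)
  ppb <- preprocessFrame(blank)
  expect_identical(sum(skeleton(ppb)), 0L)
})

test_that("most true centerline pixels of an ordered frame are recovered", {
  syn <- genOrder(synthConfig(seed = 7))
  pp <- preprocessFrame(synthImage(syn))
  cl <- do.call(rbind, centerlines(syn))
  sk <- which(skeleton(pp), arr.ind = TRUE)
  d2 <- outer(cl[, 1], sk[, 1], "-")^2 + outer(cl[, 2], sk[, 2], "-")^2
  coverage <- mean(sqrt(apply(d2, 1, min)) <= 2)
  expect_gte(coverage, 0.8)
})
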