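# Synthetic CE+NBI-like frames for the three vascular disorder grades:
# "order" (thin near-parallel vessels), "disorder" (longitudinally wavy
# vessels), "very_disorder" (dense IPCL-like loops and hooks).  Vessels are
# rendered dark on a bright, smoothly trended background (NBI vessels
# absorb), with Gaussian cross-profile, optical blur and sensor noise, so
# every preprocessing stage is exercised meaningfully.

#' Configuration of the synthetic image generator
#'
#' The defaults define the benchmark conditions used throughout the
#' package: 256 x 256 px frames, moderate vessel contrast and noise, a
#' smooth illumination trend, and class-specific geometry (5-15 parallel
#' lines; waves of 8-16 px amplitude; 25-45 loops of 6-18 px radius).
#'
#' @param imageSize integer c(rows, cols), default c(256, 256).
#' @param nPerClass images per class for \code{\link{genDataset}}.
#' @param seed integer master seed; each image derives its own RNG stream
#'   from (seed, class, index), so datasets are order-independent.
#' @param vesselContrast peak intensity drop of a vessel (default 0.45).
#' @param noiseSd additive Gaussian noise sd (default 0.03).
#' @param blurSigma optical blur in px (default 1).
#' @param trendAmplitude peak-to-peak illumination trend (default 0.15).
#' @param vesselWidth Gaussian cross-profile sigma in px (default 1.2).
#' @param nLinesRange,lineJitter "order"/"disorder" line count range and
#'   small per-line jitter amplitude (px).
#' @param waveAmplitudeRange,wavePeriodsRange "disorder" centerline wave
#'   amplitude (px) and number of periods along the line.
#' @param loopCountRange,loopRadiusRange "very_disorder" loop count and
#'   radius ranges (px).
#' @return named list with class \code{"synthConfig"}.
#' @export
synthConfig <- function(imageSize = c(256L, 256L), nPerClass = 100L,
                        seed = 7L, vesselContrast = 0.45, noiseSd = 0.03,
                        blurSigma = 1, trendAmplitude = 0.15,
                        vesselWidth = 1.2, nLinesRange = c(5L, 15L),
                        lineJitter = 1.5, waveAmplitudeRange = c(8, 16),
                        wavePeriodsRange = c(1.5, 3),
                        loopCountRange = c(25L, 45L),
                        loopRadiusRange = c(6, 18)) {
  stopifnot(length(imageSize) == 2L, all(imageSize >= 64L),
            vesselContrast >= 0, noiseSd >= 0, blurSigma >= 0,
            trendAmplitude >= 0, vesselWidth > 0)
  structure(list(imageSize = as.integer(imageSize),
                 nPerClass = as.integer(nPerClass), seed = as.integer(seed),
                 vesselContrast = vesselContrast, noiseSd = noiseSd,
                 blurSigma = blurSigma, trendAmplitude = trendAmplitude,
                 vesselWidth = vesselWidth,
                 nLinesRange = as.integer(nLinesRange),
                 lineJitter = lineJitter,
                 waveAmplitudeRange = waveAmplitudeRange,
                 wavePeriodsRange = wavePeriodsRange,
                 loopCountRange = as.integer(loopCountRange),
                 loopRadiusRange = loopRadiusRange),
            class = "synthConfig")
}

#' SynthImage: one generated frame with ground truth
#'
#' @slot image numeric matrix in \code{[0, 1]}.
#' @slot label one of \code{"order"}, \code{"disorder"},
#'   \code{"very_disorder"}.
#' @slot centerlines list of integer matrices (row, col): the true vessel
#'   centerline pixels, all inside the image bounds.
#'
#' @exportClass SynthImage
setClass("SynthImage",
  representation(image = "matrix", label = "character",
                 centerlines = "list"))

setValidity("SynthImage", function(object) {
  d <- dim(object@image)
  ok <- vapply(object@centerlines, function(p)
    all(p[, 1L] >= 1L & p[, 1L] <= d[1L] & p[, 2L] >= 1L & p[, 2L] <= d[2L]),
    logical(1))
  if (!all(ok)) return("centerline pixels outside image bounds")
  if (!object@label %in% c("order", "disorder", "very_disorder"))
    return("unknown label")
  TRUE
})

#' @rdname SynthImage-class
#' @param object a \code{SynthImage}
#' @export
setGeneric("synthImage", function(object) standardGeneric("synthImage"))
#' @rdname SynthImage-class
#' @export
setGeneric("synthLabel", function(object) standardGeneric("synthLabel"))
#' @rdname SynthImage-class
#' @export
setGeneric("centerlines", function(object) standardGeneric("centerlines"))
#' @rdname SynthImage-class
#' @export
setMethod("synthImage", "SynthImage", function(object) object@image)
#' @rdname SynthImage-class
#' @export
setMethod("synthLabel", "SynthImage", function(object) object@label)
#' @rdname SynthImage-class
#' @export
setMethod("centerlines", "SynthImage", function(object) object@centerlines)

setMethod("show", "SynthImage", function(object) {
  cat("SynthImage:", paste(dim(object@image), collapse = " x "), "px,",
      object@label, "--", length(object@centerlines), "vessels\n")
})

.classIndex <- c(order = 1L, disorder = 2L, very_disorder = 3L)

# per-image RNG stream; constants are primes, result kept below 2^31
.seedFor <- function(seed, label, index)
  as.integer((as.double(seed) * 7919 + .classIndex[[label]] * 104729 +
              as.double(index) * 15485863) %% 2147483647)

# path points (k x 2, fractional row/col) -> in-bounds integer pixel path
.rasterizePath <- function(pts, d) {
  px <- cbind(round(pts[, 1L]), round(pts[, 2L]))
  keep <- px[, 1L] >= 1 & px[, 1L] <= d[1L] & px[, 2L] >= 1 & px[, 2L] <= d[2L]
  px <- px[keep, , drop = FALSE]
  if (nrow(px) > 1L) px <- px[c(TRUE, rowSums(abs(diff(px))) > 0), ,
                              drop = FALSE]
  storage.mode(px) <- "integer"
  px
}

# smooth bright background: base + random low-order polynomial + vignette
.background <- function(d, trendAmplitude) {
  u <- matrix(rep(seq(-1, 1, length.out = d[1L]), d[2L]), d[1L])
  v <- matrix(rep(seq(-1, 1, length.out = d[2L]), each = d[1L]), d[1L])
  co <- runif(5, -1, 1)
  tr <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * u^2 + co[5] * v^2
  tr <- tr - 0.4 * (u^2 + v^2)                     # vignette
  rng <- range(tr)
  if (diff(rng) > 0)
    tr <- (tr - rng[1L]) / diff(rng) * trendAmplitude
  0.8 - trendAmplitude / 2 + tr
}

.renderFrame <- function(cfg, pathsPts, width) {
  d <- cfg$imageSize
  img <- .background(d, cfg$trendAmplitude)
  mask <- matrix(FALSE, d[1L], d[2L])
  rasters <- lapply(pathsPts, .rasterizePath, d = d)
  rasters <- Filter(function(p) nrow(p) > 0L, rasters)
  for (p in rasters) mask[p] <- TRUE
  if (any(mask)) {
    dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(!mask)))
    img <- img - cfg$vesselContrast * exp(-dist^2 / (2 * width^2))
  }
  if (cfg$blurSigma > 0)
    img <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                               sigma = cfg$blurSigma)))
  if (cfg$noiseSd > 0)
    img <- img + matrix(rnorm(length(img), sd = cfg$noiseSd), d[1L])
  list(image = pmin(pmax(img, 0), 1), centerlines = rasters)
}

# near-parallel straight-ish lines; wave* = 0 gives the "order" geometry
.linePaths <- function(cfg, wavy) {
  d <- cfg$imageSize
  nLines <- if (cfg$nLinesRange[1L] == cfg$nLinesRange[2L])
    cfg$nLinesRange[1L]
  else sample(cfg$nLinesRange[1L]:cfg$nLinesRange[2L], 1L)
  alpha <- runif(1, 0, pi)                         # common orientation
  u <- c(cos(alpha), sin(alpha))                   # along-line unit (row,col)
  nv <- c(-u[2L], u[1L])                           # normal
  ctr <- (d + 1) / 2
  span <- sqrt(sum(d^2)) / 2
  offs <- seq(-0.85, 0.85, length.out = nLines) * span / 1.6 +
    runif(nLines, -4, 4)
  ts <- seq(-span, span, by = 0.5)
  lapply(seq_len(nLines), function(i) {
    phase <- runif(1, 0, 2 * pi)
    jitterF <- runif(1, 0.5, 1.5)
    if (wavy) {
      amp <- runif(1, cfg$waveAmplitudeRange[1L], cfg$waveAmplitudeRange[2L])
      per <- runif(1, cfg$wavePeriodsRange[1L], cfg$wavePeriodsRange[2L])
      disp <- amp * sin(2 * pi * per * (ts + span) / (2 * span) + phase)
    } else {
      disp <- cfg$lineJitter * sin(2 * pi * jitterF * ts / (2 * span) + phase)
    }
    w <- offs[i] + disp
    cbind(ctr[1L] + ts * u[1L] + w * nv[1L],
          ctr[2L] + ts * u[2L] + w * nv[2L])
  })
}

#' Generate an "order" frame: thin near-parallel vessels
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param index image index within the class (default 1); with the seed it
#'   fixes the image's RNG stream, so regeneration is bitwise-reproducible.
#' @return a \code{\linkS4class{SynthImage}}.
#' @examples
#' syn <- genOrder(synthConfig(seed = 1))
#' syn
#' @export
genOrder <- function(cfg, index = 1L) {
  set.seed(.seedFor(cfg$seed, "order", index))
  r <- .renderFrame(cfg, .linePaths(cfg, wavy = FALSE), cfg$vesselWidth)
  new("SynthImage", image = r$image, label = "order",
      centerlines = r$centerlines)
}

#' Generate a "disorder" frame: longitudinally wavy vessels
#'
#' @inheritParams genOrder
#' @return a \code{\linkS4class{SynthImage}}.
#' @export
genDisorder <- function(cfg, index = 1L) {
  set.seed(.seedFor(cfg$seed, "disorder", index))
  r <- .renderFrame(cfg, .linePaths(cfg, wavy = TRUE), cfg$vesselWidth)
  new("SynthImage", image = r$image, label = "disorder",
      centerlines = r$centerlines)
}

#' Generate a "very disorder" frame: dense IPCL-like loops and hooks
#'
#' Scatters high-curvature arcs (open hooks through full curls, slightly
#' elliptical) over the field; vessels are drawn a little wider, mimicking
#' dilated capillary loops.
#'
#' @inheritParams genOrder
#' @return a \code{\linkS4class{SynthImage}}.
#' @export
genVeryDisorder <- function(cfg, index = 1L) {
  set.seed(.seedFor(cfg$seed, "very_disorder", index))
  d <- cfg$imageSize
  nLoops <- if (cfg$loopCountRange[1L] == cfg$loopCountRange[2L])
    cfg$loopCountRange[1L]
  else sample(cfg$loopCountRange[1L]:cfg$loopCountRange[2L], 1L)
  paths <- lapply(seq_len(nLoops), function(i) {
    rad <- runif(1, cfg$loopRadiusRange[1L], cfg$loopRadiusRange[2L])
    c0 <- c(runif(1, rad + 2, d[1L] - rad - 1),
            runif(1, rad + 2, d[2L] - rad - 1))
    spanDeg <- runif(1, 240, 420)
    th0 <- runif(1, 0, 2 * pi)
    ecc <- runif(1, 0.8, 1.25)
    th <- seq(0, spanDeg * pi / 180, by = 0.5 / rad)
    cbind(c0[1L] + rad * cos(th0 + th),
          c0[2L] + ecc * rad * sin(th0 + th))
  })
  r <- .renderFrame(cfg, paths, cfg$vesselWidth * 1.4)
  new("SynthImage", image = r$image, label = "very_disorder",
      centerlines = r$centerlines)
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes \code{nPerClass} PNG images per class plus a manifest CSV
#' (\code{filename}, \code{label}, \code{seed}).  Fully deterministic for a
#' given configuration.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param dir output directory (created if needed).
#' @param classes which classes to generate.
#' @return invisibly, the manifest data.frame (also written to
#'   \code{dir/manifest.csv}).
#' @export
genDataset <- function(cfg, dir,
                       classes = c("order", "disorder", "very_disorder")) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  gens <- list(order = genOrder, disorder = genDisorder,
               very_disorder = genVeryDisorder)
  classes <- match.arg(classes, names(gens), several.ok = TRUE)
  rows <- list()
  for (cl in classes) for (i in seq_len(cfg$nPerClass)) {
    syn <- gens[[cl]](cfg, index = i)
    fn <- sprintf("%s_%03d.png", cl, i)
    writeGray(syn@image, file.path(dir, fn))
    rows[[length(rows) + 1L]] <- data.frame(
      filename = fn, label = cl, seed = .seedFor(cfg$seed, cl, i))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
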