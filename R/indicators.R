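# The five per-image indicator signals.

#' Histogram of gradient directions (HGD)
#'
#' Per-pixel gradients of the enhanced image are taken with central
#' differences; pixels whose gradient magnitude exceeds the
#' \code{magPercentile} quantile of the nonzero magnitudes are considered
#' significant, and their direction angles (full \code{[0, 360)} range) are
#' accumulated into \code{nBins} bins, each pixel weighted by its gradient
#' magnitude.  The histogram is normalized to unit sum.  Parallel vessels
#' concentrate the mass in two bins 180 degrees apart; chaotic patterns
#' spread it out.
#'
#' @param enhancedImg numeric matrix (the detrended image \code{I_H}).
#' @param nBins number of direction bins (default 180, i.e. 2 degrees).
#' @param magPercentile significance quantile in \code{[0, 1)} (default
#'   0.75).
#' @return numeric vector of length \code{nBins} summing to 1, or an empty
#'   vector for a constant image.
#' @export
computeHGD <- function(enhancedImg, nBins = 180L, magPercentile = 0.75) {
  stopifnot(is.matrix(enhancedImg), nBins >= 2L)
  nr <- nrow(enhancedImg); nc <- ncol(enhancedImg)
  if (nr < 3L || nc < 3L) return(numeric(0))
  # central differences on the interior
  gr <- (enhancedImg[3:nr, 2:(nc - 1L)] - enhancedImg[1:(nr - 2L), 2:(nc - 1L)]) / 2
  gc <- (enhancedImg[2:(nr - 1L), 3:nc] - enhancedImg[2:(nr - 1L), 1:(nc - 2L)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  nz <- mag[mag > 0]
  if (!length(nz)) return(numeric(0))
  thr <- quantile(nz, magPercentile, names = FALSE)
  keep <- mag >= thr & mag > 0
  if (!any(keep)) return(numeric(0))
  theta <- atan2(gr[keep], gc[keep]) * 180 / pi
  theta <- theta %% 360
  bin <- pmin(floor(theta / (360 / nBins)) + 1L, nBins)
  w <- mag[keep]
  h <- numeric(nBins)
  tab <- tapply(w, bin, sum)
  h[as.integer(names(tab))] <- tab
  h / sum(h)
}

#' Rotational image averaging (RIA)
#'
#' The vesselness image is rotated to each angle in \code{angles} (canvas
#' expanded, zero fill, so no vessel pixel is cropped); at each rotation the
#' mean of every row across its columns forms the profile
#' \code{s_row^theta}, and the final indicator is the concatenation of the
#' profiles in angle order.  Profiles are peaky at rotations that align
#' vessels with the image rows and flat for curved patterns.
#'
#' @param filteredImg numeric matrix in \code{[0, 1]} (\code{I_F}).
#' @param angles rotation angles in degrees (default \code{seq(0, 315, 45)};
#'   360 would duplicate 0 and is dropped).
#' @return list with \code{values} (concatenated profiles) and
#'   \code{lengths} (rows contributed per angle).
#' @export
computeRIA <- function(filteredImg, angles = seq(0, 315, by = 45)) {
  stopifnot(is.matrix(filteredImg))
  profs <- lapply(angles, function(a) {
    if (a %% 360 == 0) {
      rot <- filteredImg
    } else {
      # EBImage rotates in its (x, y) frame; transposition in and out keeps
      # the [row, col] convention
      rot <- t(EBImage::imageData(EBImage::rotate(
        EBImage::Image(t(filteredImg)), a, bg.col = 0)))
    }
    rowMeans(rot)
  })
  list(values = unlist(profs, use.names = FALSE),
       lengths = vapply(profs, length, integer(1)))
}

#' Per-segment angle (ANG) and distance (DIS) profiles
#'
#' For every segment with reference points A, B and every path pixel C, DIS
#' is the Euclidean distance from A to C and ANG is the angle between the
#' vectors AB and AC, computed as \code{atan2(|AB x AC|, AB . AC)} so that
#' antiparallel vectors map to 180 degrees.  When C coincides with A the
#' angle is defined as 0.
#'
#' @param segset a \code{\linkS4class{SegmentSet}}.
#' @return list with elements \code{ang} and \code{dis}: lists of numeric
#'   vectors (degrees / pixels), one per segment, ordered along the path.
#' @export
computeAngDis <- function(segset) {
  stopifnot(is(segset, "SegmentSet"))
  angL <- list(); disL <- list()
  for (m in seq_len(nSegments(segset))) {
    s <- segset@segments[[m]]
    A <- as.numeric(s@refA); B <- as.numeric(s@refB)
    ab <- B - A
    dr <- s@path[, 1L] - A[1L]
    dc <- s@path[, 2L] - A[2L]
    d <- sqrt(dr^2 + dc^2)
    dot <- ab[1L] * dr + ab[2L] * dc
    crs <- ab[1L] * dc - ab[2L] * dr
    th <- atan2(abs(crs), dot) * 180 / pi
    th[d == 0] <- 0
    angL[[m]] <- th
    disL[[m]] <- d
  }
  list(ang = angL, dis = disL)
}

#' Digital curvature (CUR) along all vessel segments
#'
#' Curvature is estimated per path pixel from smoothed tangents: the
#' \code{row(t)}, \code{col(t)} coordinate sequences of each segment are
#' differentiated with a Savitzky-Golay filter over \code{2 * window + 1}
#' samples and the signed parametric curvature
#' \deqn{\kappa = (x' y'' - y' x'') / (x'^2 + y'^2)^{3/2}}
#' is formed; for a digital straight line it vanishes and for a digital
#' circle of radius r it approaches 1/r.  The indicator is the
#' concatenation over segments in segment order; sign is kept (features
#' that need it use \code{|CUR|}).
#'
#' @param segset a \code{\linkS4class{SegmentSet}}.
#' @param window half-width of the tangent-estimation window in samples
#'   (default 5); truncated automatically for short segments.
#' @return list with \code{values} (concatenated signed curvature, 1/px)
#'   and \code{lengths} (samples per segment).
#' @export
computeCUR <- function(segset, window = 5L) {
  stopifnot(is(segset, "SegmentSet"), window >= 1L)
  out <- lapply(segset@segments, function(s)
    .pathCurvature(s@path, window))
  vals <- unlist(out, use.names = FALSE)
  list(values = if (is.null(vals)) numeric(0) else vals,
       lengths = vapply(out, length, integer(1)))
}

.pathCurvature <- function(path, window) {
  n <- nrow(path)
  if (n < 5L) return(rep(0, n))
  x <- as.numeric(path[, 1L]); y <- as.numeric(path[, 2L])
  # two moving-average passes suppress the square-grid staircase before
  # the tangents are estimated
  maW <- 5L
  ma <- function(v) {
    f <- stats::filter(v, rep(1 / maW, maW), sides = 2L)
    f[is.na(f)] <- v[is.na(f)]
    as.numeric(f)
  }
  if (n >= maW) { x <- ma(ma(x)); y <- ma(ma(y)) }
  flen <- min(2L * as.integer(window) + 1L, if (n %% 2L) n else n - 1L)
  p <- min(3L, flen - 2L)
  d1 <- function(v) signal::sgolayfilt(v, p = p, n = flen, m = 1L)
  d2 <- function(v) signal::sgolayfilt(v, p = p, n = flen, m = 2L)
  xp <- d1(x); yp <- d1(y); xpp <- d2(x); ypp <- d2(y)
  denom <- (xp^2 + yp^2)^1.5
  k <- ifelse(denom > 0, (xp * ypp - yp * xpp) / denom, 0)
  # the filter transients at the path ends carry no tangent information;
  # clamp them to the nearest interior estimate
  h <- min(as.integer(window) + maW - 1L, (n - 1L) %/% 2L)
  if (h > 0L && n > 2L * h) {
    k[seq_len(h)] <- k[h + 1L]
    k[(n - h + 1L):n] <- k[n - h]
  }
  k
}

#' Compute the five indicators of one frame
#'
#' Runs HGD on the enhanced image, RIA on the vesselness response, and the
#' segment extraction plus ANG/DIS/CUR on the skeleton, returning the full
#' \code{\linkS4class{IndicatorSet}}.
#'
#' @param pp a \code{\linkS4class{ProcessedImages}} object.
#' @param nBins,magPercentile see \code{\link{computeHGD}}.
#' @param angles see \code{\link{computeRIA}}.
#' @param minLen see \code{\link{extractSegments}}.
#' @param window see \code{\link{computeCUR}}.
#' @return an \code{\linkS4class{IndicatorSet}}.
#' @export
computeIndicators <- function(pp, nBins = 180L, magPercentile = 0.75,
                              angles = seq(0, 315, by = 45), minLen = 21L,
                              window = 5L) {
  stopifnot(is(pp, "ProcessedImages"))
  segset <- extractSegments(pp@skeleton, minLen = minLen)
  ad <- computeAngDis(segset)
  riab <- computeRIA(pp@filtered, angles = angles)
  curb <- computeCUR(segset, window = window)
  new("IndicatorSet",
      hgd = computeHGD(pp@enhanced, nBins = nBins,
                       magPercentile = magPercentile),
      ria = riab$values, riaLengths = riab$lengths,
      ang = ad$ang, dis = ad$dis,
      cur = curb$values, curLengths = curb$lengths)
}
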