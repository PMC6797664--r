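# The 24 scalar features.  Block layout (fixed, versioned in the CSV
# header): HGD F1-F4, RIA F5-F8, ANG F9-F14, DIS F15-F20, CUR F21-F24.
# Degenerate inputs (blank image, no peaks, no segments) yield 0, never
# NaN, so classifier inputs stay finite.

#' Canonical feature names
#' @return character vector \code{c("F1", ..., "F24")}.
#' @export
featureNames <- function() paste0("F", 1:24)

.peakEnergies <- function(signal, peaks) {
  if (nrow(peaks) == 0L) return(numeric(0))
  vapply(seq_len(nrow(peaks)), function(i)
    sum(signal[peaks$on[i]:peaks$off[i]]^2), numeric(1))
}

#' HGD features F1-F4
#'
#' F1 is the total energy of the normalized histogram, F2 its minimum, F3
#' its max-min range, and F4 the ratio of the summed peak-waveform energies
#' to the total energy.
#'
#' @param hgdSig numeric vector (normalized HGD histogram).
#' @param peaks data.frame from \code{\link{detectPeaks}} run on
#'   \code{hgdSig}; computed when missing.
#' @param prominenceFrac passed to \code{\link{detectPeaks}}.
#' @return named numeric vector \code{F1..F4}.
#' @export
hgdFeatures <- function(hgdSig, peaks = detectPeaks(hgdSig, prominenceFrac),
                        prominenceFrac = 0.1) {
  if (!length(hgdSig)) return(c(F1 = 0, F2 = 0, F3 = 0, F4 = 0))
  f1 <- sum(hgdSig^2)
  f4 <- if (f1 > 0) sum(.peakEnergies(hgdSig, peaks)) / f1 else 0
  c(F1 = f1, F2 = min(hgdSig), F3 = max(hgdSig) - min(hgdSig), F4 = f4)
}

#' RIA features F5-F8
#'
#' F5 is the total energy, F6 the number of significant peaks, F7 the mean
#' peak-waveform energy over the total energy, and F8 the mean
#' amplitude/width ratio of the peak waveforms.
#'
#' @param riaSig numeric vector (concatenated RIA profiles).
#' @inheritParams hgdFeatures
#' @param peaks data.frame from \code{\link{detectPeaks}} on \code{riaSig}.
#' @return named numeric vector \code{F5..F8}.
#' @export
riaFeatures <- function(riaSig, peaks = detectPeaks(riaSig, prominenceFrac),
                        prominenceFrac = 0.1) {
  if (!length(riaSig)) return(c(F5 = 0, F6 = 0, F7 = 0, F8 = 0))
  f5 <- sum(riaSig^2)
  np <- nrow(peaks)
  if (np == 0L || f5 == 0) return(c(F5 = f5, F6 = np, F7 = 0, F8 = 0))
  c(F5 = f5, F6 = np,
    F7 = mean(.peakEnergies(riaSig, peaks)) / f5,
    F8 = mean(peaks$amplitude / peaks$width))
}

# Savitzky-Golay style smoothed first derivative (5-point quadratic).
.smoothDeriv <- function(v) {
  if (length(v) < 5L) return(diff(v))
  signal::sgolayfilt(v, p = 2L, n = 5L, m = 1L)
}

#' Sign changes of the smoothed derivative, per segment
#'
#' @param perSegment list of numeric vectors (one per segment).
#' @param tol dead zone: derivative values with \code{|d| <= tol} are
#'   treated as zero (skipped), so sub-sample rasterization wobble does
#'   not register as direction changes.  Default 0 (strict contract).
#' @return integer vector \code{s_m} of per-segment sign-change counts of
#'   the smoothed derivative (zeros skipped, so a +,0,- pattern counts
#'   once).
#' @export
signChangeCounts <- function(perSegment, tol = 0) {
  vapply(perSegment, function(v) {
    if (length(v) < 3L) return(0L)
    d <- .smoothDeriv(v)
    s <- sign(d)
    s[abs(d) <= tol] <- 0
    s <- s[s != 0]
    if (length(s) < 2L) return(0L)
    sum(diff(s) != 0)
  }, integer(1))
}

#' Sign-change features (mean, total, max, median of s_m)
#'
#' Applied to the ANG profiles this yields F9-F12 and to the DIS profiles
#' F15-F18.
#'
#' @param perSegment list of numeric vectors.
#' @inheritParams signChangeCounts
#' @return numeric vector \code{c(mean, total, max, median)}; all 0 when no
#'   segments are present.
#' @export
signChangeFeatures <- function(perSegment, tol = 0) {
  if (!length(perSegment)) return(c(mean = 0, total = 0, max = 0, median = 0))
  s <- signChangeCounts(perSegment, tol = tol)
  c(mean = mean(s), total = sum(s), max = max(s), median = median(s))
}

#' Cubic-polynomial fit errors (mean, median of e_m)
#'
#' Each per-segment profile is fit by a degree-3 polynomial of the sample
#' index; \code{e_m} is the root-mean-square residual.  Applied to ANG this
#' yields F13-F14 and to DIS F19-F20.  Segments with fewer than 4 samples
#' are excluded.
#'
#' @param perSegment list of numeric vectors.
#' @return numeric vector \code{c(mean, median)}; 0 when nothing is
#'   fittable.
#' @export
polyfitErrorFeatures <- function(perSegment) {
  perSegment <- Filter(function(v) length(v) >= 4L, perSegment)
  if (!length(perSegment)) return(c(mean = 0, median = 0))
  e <- vapply(perSegment, function(v) {
    idx <- seq_along(v)
    fit <- lm(v ~ poly(idx, 3L))
    sqrt(mean(resid(fit)^2))
  }, numeric(1))
  c(mean = mean(e), median = median(e))
}

#' CUR features F21-F24
#'
#' F21 is the total energy of the signed curvature, F22 its variance, F23
#' the number of significant peaks of \code{|CUR|}, and F24 that peak count
#' times the summed peak amplitudes -- loop-rich patterns have both many
#' and high curvature peaks.  A peak only counts as significant when its
#' amplitude reaches \code{curPeakFloor}: the digital curvature estimator
#' resolves straight lines to better than 0.01/px, so peaks below twice
#' that bound are rasterization noise, not vessel curvature.
#'
#' @param curSig numeric vector (concatenated signed curvature).
#' @inheritParams hgdFeatures
#' @param peaks data.frame from \code{\link{detectPeaks}} on
#'   \code{abs(curSig)}.
#' @param curPeakFloor minimum peak amplitude (1/px) for F23/F24
#'   (default 0.02).
#' @return named numeric vector \code{F21..F24}.
#' @export
curFeatures <- function(curSig, peaks = detectPeaks(abs(curSig),
                                                    prominenceFrac),
                        prominenceFrac = 0.1, curPeakFloor = 0.02) {
  if (!length(curSig)) return(c(F21 = 0, F22 = 0, F23 = 0, F24 = 0))
  peaks <- peaks[peaks$amplitude >= curPeakFloor, , drop = FALSE]
  np <- nrow(peaks)
  c(F21 = sum(curSig^2),
    F22 = if (length(curSig) > 1L) var(curSig) else 0,
    F23 = np,
    F24 = if (np > 0L) np * sum(peaks$amplitude) else 0)
}

#' Extract the 24-feature vector of one image
#'
#' Assembles F1-F24 from an \code{\linkS4class{IndicatorSet}} in the fixed
#' documented order: HGD (F1-F4), RIA (F5-F8), ANG (F9-F14), DIS
#' (F15-F20), CUR (F21-F24).
#'
#' @param ind an \code{\linkS4class{IndicatorSet}}.
#' @param prominenceFrac peak-detector threshold shared by the HGD, RIA and
#'   CUR blocks (default 0.1).
#' @param angDerivTol,disDerivTol dead zones (degrees resp. pixels per
#'   sample) for the sign-change counting of the ANG and DIS blocks; the
#'   defaults sit an order of magnitude below the derivative swing of a
#'   genuinely undulating vessel but above the sub-pixel rasterization
#'   wobble of a straight one.
#' @param curPeakFloor see \code{\link{curFeatures}}.
#' @return named numeric vector of length 24, all finite.
#' @examples
#' blank <- new("IndicatorSet", hgd = numeric(0), ria = numeric(0),
#'              riaLengths = integer(0), ang = list(), dis = list(),
#'              cur = numeric(0), curLengths = integer(0))
#' extractFeatures(blank)   # 24 zeros
#' @export
extractFeatures <- function(ind, prominenceFrac = 0.1, angDerivTol = 0.2,
                            disDerivTol = 0.05, curPeakFloor = 0.02) {
  stopifnot(is(ind, "IndicatorSet"))
  fv <- c(hgdFeatures(ind@hgd, prominenceFrac = prominenceFrac),
          riaFeatures(ind@ria, prominenceFrac = prominenceFrac),
          unname(signChangeFeatures(ind@ang, tol = angDerivTol)),
          unname(polyfitErrorFeatures(ind@ang)),
          unname(signChangeFeatures(ind@dis, tol = disDerivTol)),
          unname(polyfitErrorFeatures(ind@dis)),
          curFeatures(ind@cur, prominenceFrac = prominenceFrac,
                      curPeakFloor = curPeakFloor))
  fv <- as.numeric(fv)
  fv[!is.finite(fv)] <- 0
  names(fv) <- featureNames()
  fv
}
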