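# S4 containers for the pipeline stages.  Images are plain numeric matrices
# indexed [row, col] (row 1 = top of the frame); EBImage's (x, y) layout is
# converted at the I/O boundary only.

#' ProcessedImages: the three processed images derived from one frame
#'
#' Holds the enhanced (detrended) image \code{I_H}, the Frangi vesselness
#' response \code{I_F} (values in \code{[0, 1]}) and the one-pixel-wide
#' binary skeleton \code{I_S}, all on the grid of the input frame.
#'
#' @slot enhanced numeric matrix, detrended grayscale image (I_H).
#' @slot filtered numeric matrix in \code{[0, 1]}, vesselness response (I_F).
#' @slot skeleton logical matrix, one-pixel-wide skeleton (I_S).
#'
#' @seealso \code{\link{preprocessFrame}}
#' @exportClass ProcessedImages
setClass("ProcessedImages",
  representation(enhanced = "matrix", filtered = "matrix", skeleton = "matrix"))

setValidity("ProcessedImages", function(object) {
  msg <- character(0)
  dE <- dim(object@enhanced)
  if (!identical(dE, dim(object@filtered)) || !identical(dE, dim(object@skeleton)))
    msg <- c(msg, "enhanced, filtered and skeleton must share dimensions")
  if (!all(is.finite(object@enhanced)))
    msg <- c(msg, "enhanced image contains non-finite values")
  rngF <- range(object@filtered)
  if (rngF[1] < -1e-12 || rngF[2] > 1 + 1e-12)
    msg <- c(msg, "filtered values must lie in [0, 1]")
  if (!is.logical(object@skeleton))
    msg <- c(msg, "skeleton must be a logical matrix")
  else if (.hasFullBlock(object@skeleton))
    msg <- c(msg, "skeleton is not one pixel wide (fully set 2x2 block found)")
  if (length(msg)) msg else TRUE
})

#' VesselSegment: one traced skeleton arc
#'
#' An ordered one-pixel-wide path traced from the skeleton, together with its
#' two reference points: \code{refA}, the first path pixel, and \code{refB},
#' \code{refA} displaced by one pixel along the column axis.  The segment
#' baseline A-B is the common reference against which the per-pixel angle
#' (ANG) and distance (DIS) profiles are measured.
#'
#' @slot path integer matrix with columns \code{row}, \code{col}; consecutive
#'   rows are 8-neighbours.
#' @slot refA integer vector \code{c(row, col)}.
#' @slot refB integer vector \code{c(row, col)}, never equal to \code{refA}.
#'
#' @exportClass VesselSegment
setClass("VesselSegment",
  representation(path = "matrix", refA = "integer", refB = "integer"))

setValidity("VesselSegment", function(object) {
  p <- object@path
  if (ncol(p) != 2) return("path must have two columns (row, col)")
  if (nrow(p) < 2) return("path must contain at least two pixels")
  if (identical(object@refA, object@refB)) return("refA and refB must differ")
  steps <- abs(diff(p))
  if (any(steps > 1) || any(rowSums(steps) == 0))
    return("consecutive path pixels must be distinct 8-neighbours")
  TRUE
})

#' SegmentSet: all vessel segments of one image
#'
#' @slot segments list of \code{\link{VesselSegment}} objects in deterministic
#'   (row-major first-pixel) order.
#' @slot imageDim integer vector, dimensions of the source skeleton.
#'
#' @seealso \code{\link{extractSegments}}
#' @exportClass SegmentSet
setClass("SegmentSet",
  representation(segments = "list", imageDim = "integer"))

setValidity("SegmentSet", function(object) {
  ok <- vapply(object@segments, function(s) is(s, "VesselSegment"), logical(1))
  if (!all(ok)) return("segments must all be VesselSegment objects")
  TRUE
})

#' IndicatorSet: the five per-image indicator signals
#'
#' HGD (normalized histogram of gradient directions) and RIA (concatenated
#' per-rotation row means) are per-image vectors; ANG and DIS (per-pixel
#' angle/distance to the segment reference) are stored per segment; CUR is
#' the concatenation of the per-segment digital curvature profiles.
#'
#' @slot hgd numeric vector summing to 1 (or empty for blank images).
#' @slot ria numeric vector, concatenated row-mean profiles.
#' @slot riaLengths integer vector, profile length contributed by each
#'   rotation angle.
#' @slot ang list of numeric vectors (degrees in \code{[0, 180]}), one per
#'   segment.
#' @slot dis list of numeric vectors (pixels, \code{>= 0}), one per segment.
#' @slot cur numeric vector, concatenated signed curvature (1/px).
#' @slot curLengths integer vector, curvature samples per segment.
#'
#' @seealso \code{\link{computeIndicators}}
#' @exportClass IndicatorSet
setClass("IndicatorSet",
  representation(hgd = "numeric", ria = "numeric", riaLengths = "integer",
                 ang = "list", dis = "list", cur = "numeric",
                 curLengths = "integer"))

setValidity("IndicatorSet", function(object) {
  msg <- character(0)
  if (length(object@hgd) && (any(object@hgd < -1e-12) ||
      abs(sum(object@hgd) - 1) > 1e-8))
    msg <- c(msg, "hgd must be non-negative and sum to 1")
  if (length(object@ang) != length(object@dis))
    msg <- c(msg, "ang and dis must have one entry per segment")
  if (length(object@cur) != sum(object@curLengths))
    msg <- c(msg, "cur length must equal sum(curLengths)")
  if (length(msg)) msg else TRUE
})

#' EvalReport: cross-validated classifier performance
#'
#' Pooled out-of-fold confusion matrix of a stratified tenfold
#' cross-validation together with the derived metrics.  Sensitivity,
#' specificity and AUC are class-frequency-weighted one-vs-rest averages.
#'
#' @slot confusion integer matrix (true class x predicted class).
#' @slot accuracy,sensitivity,specificity,auc numbers in \code{[0, 1]}.
#' @slot bestParams list, classifier kind and hyperparameters used.
#' @slot folds integer, number of CV folds.
#' @slot seed integer, RNG seed used for fold assignment and stochastic fits.
#'
#' @seealso \code{\link{evaluateCV}}
#' @exportClass EvalReport
setClass("EvalReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 auc = "numeric", bestParams = "list", folds = "integer",
                 seed = "integer"))

setValidity("EvalReport", function(object) {
  m <- c(object@accuracy, object@sensitivity, object@specificity, object@auc)
  if (any(m < -1e-12 | m > 1 + 1e-12))
    return("metrics must lie in [0, 1]")
  TRUE
})
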