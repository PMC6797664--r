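# Accessor generics + show methods.

#' @rdname ProcessedImages-class
#' @param object a \code{ProcessedImages} object
#' @export
setGeneric("enhanced", function(object) standardGeneric("enhanced"))
#' @rdname ProcessedImages-class
#' @export
setGeneric("filtered", function(object) standardGeneric("filtered"))
#' @rdname ProcessedImages-class
#' @export
setGeneric("skeleton", function(object) standardGeneric("skeleton"))

#' @rdname ProcessedImages-class
#' @export
setMethod("enhanced", "ProcessedImages", function(object) object@enhanced)
#' @rdname ProcessedImages-class
#' @export
setMethod("filtered", "ProcessedImages", function(object) object@filtered)
#' @rdname ProcessedImages-class
#' @export
setMethod("skeleton", "ProcessedImages", function(object) object@skeleton)

setMethod("show", "ProcessedImages", function(object) {
  d <- dim(object@enhanced)
  cat("ProcessedImages:", d[1], "x", d[2], "px;",
      sum(object@skeleton), "skeleton pixels\n")
})

#' @rdname SegmentSet-class
#' @param object a \code{SegmentSet} object
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname SegmentSet-class
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))

#' @rdname SegmentSet-class
#' @export
setMethod("segments", "SegmentSet", function(object) object@segments)
#' @rdname SegmentSet-class
#' @export
setMethod("nSegments", "SegmentSet", function(object) length(object@segments))

#' @rdname VesselSegment-class
#' @param object a \code{VesselSegment} object
#' @export
setGeneric("segmentPath", function(object) standardGeneric("segmentPath"))
#' @rdname VesselSegment-class
#' @export
setMethod("segmentPath", "VesselSegment", function(object) object@path)

setMethod("show", "VesselSegment", function(object) {
  cat("VesselSegment:", nrow(object@path), "px, A = (",
      object@refA[1], ",", object@refA[2], ")\n")
})

setMethod("show", "SegmentSet", function(object) {
  lens <- vapply(object@segments, function(s) nrow(s@path), integer(1))
  cat("SegmentSet: M =", length(lens), "segments")
  if (length(lens)) cat(", lengths", min(lens), "-", max(lens), "px")
  cat("\n")
})

#' @rdname IndicatorSet-class
#' @param object an \code{IndicatorSet} object
#' @export
setGeneric("hgd", function(object) standardGeneric("hgd"))
#' @rdname IndicatorSet-class
#' @export
setGeneric("ria", function(object) standardGeneric("ria"))
#' @rdname IndicatorSet-class
#' @export
setGeneric("ang", function(object) standardGeneric("ang"))
#' @rdname IndicatorSet-class
#' @export
setGeneric("dis", function(object) standardGeneric("dis"))
#' @rdname IndicatorSet-class
#' @export
setGeneric("cur", function(object) standardGeneric("cur"))

#' @rdname IndicatorSet-class
#' @export
setMethod("hgd", "IndicatorSet", function(object) object@hgd)
#' @rdname IndicatorSet-class
#' @export
setMethod("ria", "IndicatorSet", function(object) object@ria)
#' @rdname IndicatorSet-class
#' @export
setMethod("ang", "IndicatorSet", function(object) object@ang)
#' @rdname IndicatorSet-class
#' @export
setMethod("dis", "IndicatorSet", function(object) object@dis)
#' @rdname IndicatorSet-class
#' @export
setMethod("cur", "IndicatorSet", function(object) object@cur)

setMethod("show", "IndicatorSet", function(object) {
  cat("IndicatorSet: HGD[", length(object@hgd), "], RIA[",
      length(object@ria), "], ANG/DIS over M =", length(object@ang),
      "segments, CUR[", length(object@cur), "]\n")
})

#' @rdname EvalReport-class
#' @param object an \code{EvalReport} object
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))
#' @rdname EvalReport-class
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname EvalReport-class
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))

#' @rdname EvalReport-class
#' @export
setMethod("confusion", "EvalReport", function(object) object@confusion)
#' @rdname EvalReport-class
#' @export
setMethod("accuracy", "EvalReport", function(object) object@accuracy)
#' @rdname EvalReport-class
#' @export
setMethod("metrics", "EvalReport", function(object)
  c(accuracy = object@accuracy, sensitivity = object@sensitivity,
    specificity = object@specificity, auc = object@auc))

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (", object@bestParams$kind, ", ", object@folds,
      "-fold CV, seed ", object@seed, ")\n", sep = "")
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f  auc %.3f\n",
              object@accuracy, object@sensitivity, object@specificity,
              object@auc))
  cat("  confusion matrix (rows = truth):\n")
  print(object@confusion)
})
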