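#' Convert a color frame to a grayscale matrix
#'
#' NBI concentrates vessel contrast in the green band, so the default policy
#' keeps the green channel; \code{"luminance"} uses the Rec. 601 weights.
#' Single-channel input is returned unchanged under either policy.
#'
#' @param frame an \code{EBImage::Image}, or a numeric matrix
#'   (\code{[row, col]}, already gray), or a 3-D numeric array
#'   \code{[row, col, channel]} with 1 or 3 channels.
#' @param policy \code{"green"} (default) or \code{"luminance"}.
#' @return numeric matrix indexed \code{[row, col]}.
#' @export
toGray <- function(frame, policy = c("green", "luminance")) {
  policy <- match.arg(policy)
  if (is(frame, "Image")) {
    a <- EBImage::imageData(frame)
    # EBImage stores (x, y[, channel]); move to [row, col, channel]
    frame <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  }
  d <- dim(frame)
  if (length(d) == 2L) return(frame)
  if (length(d) == 3L) {
    if (d[3] == 1L) return(frame[, , 1L])
    if (d[3] == 3L) {
      if (policy == "green") return(frame[, , 2L])
      return(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] +
             0.114 * frame[, , 3L])
    }
  }
  stop("unsupported channel count: frames must have 1 or 3 channels")
}

#' Read an endoscopic frame from disk
#'
#' Thin wrapper over \code{EBImage::readImage} returning the frame in this
#' package's \code{[row, col(, channel)]} layout.
#'
#' @param path path to a JPEG/PNG/TIFF file.
#' @return numeric matrix or 3-D array with intensities in \code{[0, 1]}.
#' @export
readFrame <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

#' Write a grayscale matrix as a PNG
#'
#' Intensities are clipped to \code{[0, 1]}.  Used for the optional
#' diagnostic dumps of the processed images and by the synthetic generator.
#'
#' @param img numeric or logical matrix \code{[row, col]}.
#' @param path output file path (extension selects the format).
#' @return \code{invisible(path)}
#' @export
writeGray <- function(img, path) {
  img <- pmin(pmax(img + 0, 0), 1)
  EBImage::writeImage(EBImage::Image(t(img)), path)
  invisible(path)
}

#' Preprocess one frame into the three processed images
#'
#' The preprocessing chain of the pipeline: grayscale conversion, wavelet
#' detrending (homogenization) giving the enhanced image \code{I_H},
#' multiscale Frangi filtering of \code{I_H} giving the vesselness response
#' \code{I_F}, and Otsu binarization plus iterative thinning giving the
#' binary skeleton \code{I_S}.
#'
#' @param frame as accepted by \code{\link{toGray}}.
#' @param channelPolicy grayscale policy, see \code{\link{toGray}}.
#' @param waveletLevel detrending depth, see \code{\link{detrendImage}}.
#' @param sigmas Frangi scales, see \code{\link{frangiEnhance}}.
#' @param darkRidges ridge polarity, see \code{\link{frangiEnhance}}.
#' @param responseFloor Otsu histogram floor, see
#'   \code{\link{binarizeSkeletonize}}.
#' @return a \code{\linkS4class{ProcessedImages}} object.
#' @examples
#' syn <- genOrder(synthConfig(seed = 1))
#' pp <- preprocessFrame(synthImage(syn))
#' pp
#' @export
preprocessFrame <- function(frame, channelPolicy = c("green", "luminance"),
                            waveletLevel = 7L, sigmas = 1:8,
                            darkRidges = TRUE, responseFloor = 1e-3) {
  g <- toGray(frame, match.arg(channelPolicy))
  if (min(dim(g)) < 64L)
    stop("frames smaller than 64 px per side are not supported")
  if (!all(is.finite(g))) stop("frame contains non-finite intensities")
  iH <- detrendImage(g, waveletLevel)
  iF <- frangiEnhance(iH, sigmas = sigmas, darkRidges = darkRidges)
  iS <- binarizeSkeletonize(iF, responseFloor = responseFloor)
  new("ProcessedImages", enhanced = iH, filtered = iF, skeleton = iS)
}

#' Write the three processed images as diagnostic PNGs
#'
#' @param pp a \code{\linkS4class{ProcessedImages}} object.
#' @param prefix path prefix; files \code{<prefix>_IH.png},
#'   \code{<prefix>_IF.png}, \code{<prefix>_IS.png} are written.
#' @return invisible character vector of the three paths.
#' @export
writeDiagnostics <- function(pp, prefix) {
  iH <- pp@enhanced
  rng <- range(iH)
  if (diff(rng) > 0) iH <- (iH - rng[1]) / diff(rng)
  paths <- paste0(prefix, c("_IH.png", "_IF.png", "_IS.png"))
  writeGray(iH, paths[1])
  writeGray(pp@filtered, paths[2])
  writeGray(pp@skeleton, paths[3])
  invisible(paths)
}
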