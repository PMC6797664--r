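#' Multiscale Frangi vessel enhancement
#'
#' Hessian-eigenvalue vesselness.  At each scale \code{sigma} the image is
#' convolved with scale-normalized Gaussian second-derivative kernels; from
#' the Hessian eigenvalues \code{|l1| <= |l2|} the tubularity measure
#' \deqn{V = \exp(-R_b^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2 c^2))}
#' is formed with blobness \eqn{R_b = l1/l2} and structureness
#' \eqn{S = \sqrt{l1^2 + l2^2}}, restricted to the requested ridge polarity
#' (\code{l2 > 0} for dark vessels on a bright background, the NBI
#' appearance).  The per-pixel response is the maximum over scales,
#' rescaled to \code{[0, 1]}.
#'
#' @param img numeric matrix, grayscale image.
#' @param sigmas numeric vector of positive scales in pixels; the default
#'   1..8 covers the vessel calibres seen at contact-endoscopy
#'   magnification.
#' @param beta blobness sensitivity (default 0.5, the filter's classical
#'   value).
#' @param darkRidges logical; \code{TRUE} (default) enhances dark vessels on
#'   a bright background.
#' @return numeric matrix in \code{[0, 1]} of the same dimensions.
#' @examples
#' img <- matrix(1, 64, 64)
#' img[30:32, ] <- 0          # one dark horizontal vessel
#' v <- frangiEnhance(img, sigmas = 1:4)
#' which.max(v[, 32])         # response peaks on the centerline
#' @export
frangiEnhance <- function(img, sigmas = 1:8, beta = 0.5, darkRidges = TRUE) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (length(sigmas) == 0 || any(sigmas <= 0))
    stop("sigmas must be a non-empty vector of positive scales")
  best <- matrix(0, nrow(img), ncol(img))
  for (s in sigmas) {
    radius <- min(ceiling(3 * s), min(dim(img)) - 1L)
    g0 <- .gaussKernel(s, 0L, radius)
    g1 <- .gaussKernel(s, 1L, radius)
    g2 <- .gaussKernel(s, 2L, radius)
    # scale-normalized Hessian (gamma = 2)
    Hrr <- s^2 * .sepFilter(img, g2, g0)
    Hcc <- s^2 * .sepFilter(img, g0, g2)
    Hrc <- s^2 * .sepFilter(img, g1, g1)
    disc <- sqrt(((Hrr - Hcc) / 2)^2 + Hrc^2)
    m <- (Hrr + Hcc) / 2
    e1 <- m + disc
    e2 <- m - disc
    swap <- abs(e1) > abs(e2)           # order so |l1| <= |l2|
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    maxS <- sqrt(max(S2))
    # a numerically flat image has no second-order structure; without this
    # floor the final [0, 1] rescaling would amplify float noise
    if (maxS < 1e-8) next
    c2 <- (maxS / 2)^2
    Rb2 <- ifelse(l2 == 0, 0, (l1 / l2)^2)
    V <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    V[if (darkRidges) l2 <= 0 else l2 >= 0] <- 0
    best <- pmax(best, V)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  best
}
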