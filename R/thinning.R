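# Iterative thinning (Zhang-Suen two-subiteration scheme) plus a cleanup
# pass that removes deletable corner pixels of any remaining fully set 2x2
# block, so the one-pixel-wide contract holds exactly.

# 8-neighbour planes of a logical matrix, in the clockwise order
# P2 (N), P3 (NE), P4 (E), P5 (SE), P6 (S), P7 (SW), P8 (W), P9 (NW),
# with implicit FALSE outside the image.
.neighborPlanes <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- M
  core <- function(dr, dc) P[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  list(p2 = core(-1L, 0L), p3 = core(-1L, 1L), p4 = core(0L, 1L),
       p5 = core(1L, 1L),  p6 = core(1L, 0L),  p7 = core(1L, -1L),
       p8 = core(0L, -1L), p9 = core(-1L, -1L))
}

# number of 0 -> 1 transitions around the 8-neighbourhood
.transitionCount <- function(np) {
  seqs <- list(np$p2, np$p3, np$p4, np$p5, np$p6, np$p7, np$p8, np$p9, np$p2)
  A <- matrix(0L, nrow(np$p2), ncol(np$p2))
  for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1L]])
  A
}

.neighborSum <- function(np)
  np$p2 + np$p3 + np$p4 + np$p5 + np$p6 + np$p7 + np$p8 + np$p9

#' Thin a binary mask to one-pixel-wide lines
#'
#' Iterative homotopy-preserving thinning (Zhang-Suen family).  The result
#' is idempotent and contains no fully set 2x2 block.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @return logical matrix of the same dimensions.
#' @export
thinMask <- function(mask) {
  M <- mask != 0
  repeat {
    before <- M
    repeat {
      changed <- FALSE
      for (sub in 1:2) {
        np <- .neighborPlanes(M)
        B <- .neighborSum(np)
        A <- .transitionCount(np)
        if (sub == 1L)
          cond <- !(np$p2 & np$p4 & np$p6) & !(np$p4 & np$p6 & np$p8)
        else
          cond <- !(np$p2 & np$p4 & np$p8) & !(np$p2 & np$p6 & np$p8)
        del <- M & B >= 2L & B <= 6L & A == 1L & cond
        if (any(del)) {
          M[del] <- FALSE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    M <- .breakFullBlocks(M)
    # iterate to a joint fixed point so thinning is idempotent
    if (identical(M, before)) break
  }
  M
}

# TRUE if any 2x2 block is fully set
.hasFullBlock <- function(M) {
  if (nrow(M) < 2L || ncol(M) < 2L) return(FALSE)
  nr <- nrow(M); nc <- ncol(M)
  any(M[-nr, -nc] & M[-1L, -nc] & M[-nr, -1L] & M[-1L, -1L])
}

# Delete one deletable pixel per remaining 2x2 block.  A pixel is deletable
# when its removal keeps the local 8-topology (transition count 1) and it
# is not an endpoint; such a pixel always exists inside a fully set block.
.breakFullBlocks <- function(M) {
  repeat {
    nr <- nrow(M); nc <- ncol(M)
    if (nr < 2L || nc < 2L) return(M)
    blk <- which(M[-nr, -nc] & M[-1L, -nc] & M[-nr, -1L] & M[-1L, -1L],
                 arr.ind = TRUE)
    if (nrow(blk) == 0L) return(M)
    i <- blk[1L, 1L]; j <- blk[1L, 2L]
    cand <- rbind(c(i + 1L, j + 1L), c(i + 1L, j), c(i, j + 1L), c(i, j))
    removed <- FALSE
    for (k in seq_len(nrow(cand))) {
      r <- cand[k, 1L]; cc <- cand[k, 2L]
      sub <- matrix(FALSE, 3L, 3L)
      rr <- max(1L, r - 1L):min(nr, r + 1L)
      ccr <- max(1L, cc - 1L):min(nc, cc + 1L)
      sub[rr - r + 2L, ccr - cc + 2L] <- M[rr, ccr, drop = FALSE]
      ring <- sub[rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 3),
                        c(3, 2), c(3, 1), c(2, 1), c(1, 1))]
      A <- sum(!ring & ring[c(2:8, 1)])
      if (A == 1L && sum(ring) >= 2L) {
        M[r, cc] <- FALSE
        removed <- TRUE
        break
      }
    }
    if (!removed) M[i + 1L, j + 1L] <- FALSE  # cannot occur for simple shapes
  }
}

#' Binarize a vesselness response and reduce it to a skeleton
#'
#' Thresholds the Frangi response with Otsu's method computed over the
#' responding pixels only (response > 1e-3; the flat zero background would
#' otherwise dominate the histogram) and thins the binary image to
#' one-pixel-wide centerlines.
#'
#' @param filteredImg numeric matrix in \code{[0, 1]} (vesselness response).
#' @param responseFloor pixels at or below this response are excluded from
#'   the Otsu histogram (default \code{1e-3}).
#' @return logical skeleton matrix; all-FALSE when nothing responds.
#' @export
binarizeSkeletonize <- function(filteredImg, responseFloor = 1e-3) {
  stopifnot(is.matrix(filteredImg))
  if (min(filteredImg) < -1e-9 || max(filteredImg) > 1 + 1e-9)
    stop("filtered image must lie in [0, 1]")
  nz <- filteredImg[filteredImg > responseFloor]
  if (length(nz) < 2L)
    return(matrix(FALSE, nrow(filteredImg), ncol(filteredImg)))
  th <- EBImage::otsu(EBImage::Image(matrix(nz, ncol = 1L)), range = c(0, 1))
  thinMask(filteredImg > th)
}
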