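# Decomposition of the skeleton into ordered vessel-segment paths.
# Junction pixels (>= 3 skeleton neighbours) are removed first, which
# splits crossing vessels into simple arcs; every remaining pixel then has
# at most two neighbours, so each connected component is an open path or a
# closed loop.  Loops are cut at their lexicographically smallest pixel.

# 8-neighbour count of each set pixel, computed on the full skeleton
.neighborCountMatrix <- function(M) {
  np <- .neighborPlanes(M)
  .neighborSum(np)
}

# crossing number: 0->1 transitions around the 8-ring = number of distinct
# branches leaving the pixel.  Raw neighbour counts overestimate on
# staircase (4-connected diagonal) runs, where diagonal shortcut
# adjacencies are not branches.
.crossingNumberMatrix <- function(M) {
  .transitionCount(.neighborPlanes(M))
}

#' Extract ordered vessel segments from a skeleton
#'
#' Removes junction pixels (pixels from which three or more skeleton
#' branches leave, measured by the crossing number of the 8-ring so that
#' staircase runs of diagonal vessels are not mistaken for junctions),
#' traces every remaining arc endpoint-to-endpoint into an
#' ordered pixel path, and keeps the arcs longer than \code{minLen - 1}
#' pixels (the pipeline follows the "greater than 20 px" rule, i.e. keeps
#' length >= 21 by default).  Each kept segment is given its reference
#' points: A is the first path pixel and B is A shifted by one pixel along
#' the column axis, a fixed baseline shared by all segments.  Segments are
#' ordered by their first pixel in row-major order; with the path start
#' chosen at the lexicographically smaller endpoint the decomposition is
#' fully deterministic.
#'
#' @param skeletonMask logical (or 0/1) matrix, one-pixel-wide skeleton.
#' @param minLen minimum path length in pixels to keep (default 21).
#' @return a \code{\linkS4class{SegmentSet}}.
#' @examples
#' sk <- matrix(FALSE, 64, 64)
#' sk[32, 5:54] <- TRUE
#' nSegments(extractSegments(sk))   # one straight 50 px segment
#' @export
extractSegments <- function(skeletonMask, minLen = 21L) {
  M <- skeletonMask != 0
  minLen <- max(as.integer(minLen), 2L)
  if (!any(M)) return(new("SegmentSet", segments = list(),
                          imageDim = dim(M)))
  cn <- .crossingNumberMatrix(M)
  A <- M & cn < 3L                      # junctions removed
  segs <- list()
  if (any(A)) {
    cnA <- .crossingNumberMatrix(A)
    todo <- A
    # endpoints first (open arcs), then whatever remains (closed loops)
    pickStart <- function(avail, endpointsOnly) {
      cand <- if (endpointsOnly) avail & cnA < 2L else avail
      w <- which(cand)
      if (!length(w)) return(NULL)
      # column-major which(): order by (col, row); re-rank row-major
      ij <- arrayInd(w, dim(avail))
      o <- order(ij[, 1L], ij[, 2L])
      ij[o[1L], ]
    }
    nr <- nrow(A); nc <- ncol(A)
    offs <- cbind(rep(-1:1, 3L), rep(-1:1, each = 3L))
    offs <- offs[!(offs[, 1L] == 0L & offs[, 2L] == 0L), ]
    # a diagonal step is redundant (and must not be taken) when a common
    # 4-neighbour is itself a skeleton pixel: the true path runs through
    # that pixel, or -- if it was a junction -- the two arcs merely brush
    # each other across it
    stepOK <- function(cur, r, c) {
      dr <- r - cur[1L]; dc <- c - cur[2L]
      if (dr == 0L || dc == 0L) return(TRUE)
      !(M[cur[1L], c] || M[r, cur[2L]])
    }
    walk <- function(start) {
      path <- matrix(0L, sum(todo) + 1L, 2L)
      n <- 0L
      cur <- start
      repeat {
        n <- n + 1L
        path[n, ] <- cur
        todo[cur[1L], cur[2L]] <<- FALSE
        nxt <- NULL
        for (k in seq_len(nrow(offs))) {
          r <- cur[1L] + offs[k, 1L]; c <- cur[2L] + offs[k, 2L]
          if (r >= 1L && r <= nr && c >= 1L && c <= nc && todo[r, c] &&
              stepOK(cur, r, c)) {
            # prefer 4-connected steps so staircase corners stay ordered
            if (is.null(nxt) || sum(abs(offs[k, ])) <
                sum(abs(nxt - cur))) nxt <- c(r, c)
          }
        }
        if (is.null(nxt)) break
        cur <- nxt
      }
      path[seq_len(n), , drop = FALSE]
    }
    tracePath <- function(start) {
      fwd <- walk(start)
      # when tracing starts mid-arc, walking again from the start picks up
      # the not-yet-visited other direction; prepend it reversed
      back <- walk(start)
      if (nrow(back) > 1L)
        fwd <- rbind(back[nrow(back):2L, , drop = FALSE], fwd)
      fwd
    }
    for (endpointsOnly in c(TRUE, FALSE)) {
      repeat {
        start <- pickStart(todo, endpointsOnly)
        if (is.null(start)) break
        segs[[length(segs) + 1L]] <- tracePath(start)
      }
    }
  }
  segs <- Filter(function(p) nrow(p) >= minLen, segs)
  if (length(segs)) {
    # orient each path to start at its lexicographically smaller endpoint
    segs <- lapply(segs, function(p) {
      a <- p[1L, ]; b <- p[nrow(p), ]
      if (b[1L] < a[1L] || (b[1L] == a[1L] && b[2L] < a[2L]))
        p[nrow(p):1L, , drop = FALSE] else p
    })
    first <- t(vapply(segs, function(p) p[1L, ], integer(2)))
    segs <- segs[order(first[, 1L], first[, 2L])]
  }
  new("SegmentSet",
      segments = lapply(segs, function(p) assignReference(p)),
      imageDim = dim(M))
}

#' Attach the reference geometry to an ordered path
#'
#' Reference point A is the first path pixel; B is A displaced by one pixel
#' along the column axis, giving every segment the same fixed baseline
#' direction, so the ANG profile is the polar angle of each path pixel
#' about A.
#'
#' @param path integer matrix of ordered \code{(row, col)} pixels.
#' @return a \code{\linkS4class{VesselSegment}}.
#' @export
assignReference <- function(path) {
  path <- matrix(as.integer(path), ncol = 2L,
                 dimnames = list(NULL, c("row", "col")))
  if (nrow(path) < 2L) stop("degenerate single-pixel path")
  refA <- path[1L, ]
  new("VesselSegment", path = path, refA = refA,
      refB = refA + c(0L, 1L))
}

#' Export a SegmentSet as a data frame
#'
#' One row per path pixel: segment id, pixel index along the path, row and
#' column.  Suitable for CSV export.
#'
#' @param segset a \code{\linkS4class{SegmentSet}}.
#' @return data.frame with columns \code{segment}, \code{index},
#'   \code{row}, \code{col}.
#' @export
segmentsAsTable <- function(segset) {
  stopifnot(is(segset, "SegmentSet"))
  if (nSegments(segset) == 0L)
    return(data.frame(segment = integer(0), index = integer(0),
                      row = integer(0), col = integer(0)))
  do.call(rbind, lapply(seq_along(segset@segments), function(m) {
    p <- segset@segments[[m]]@path
    data.frame(segment = m, index = seq_len(nrow(p)),
               row = p[, 1L], col = p[, 2L])
  }))
}
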