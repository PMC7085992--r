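# Slice-wise psoas segmentation: window + equalize -> Canny edges ->
# alpha-shape closure -> tracked region selection -> rasterized label mask.

#' Window and histogram-equalize one axial CT slice
#'
#' HU values are clamped to \code{bodyWindow} and mapped through the
#' empirical CDF of the windowed slice, yielding intensities in \[0, 1\]
#' with voxel ranks preserved. A constant slice has no contrast and maps to
#' constant 0 (with a message).
#'
#' @param ctSlice 2D numeric matrix of HU values.
#' @param bodyWindow HU interval, default \code{c(-200, 300)}.
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
equalizeSlice <- function(ctSlice, bodyWindow = c(-200, 300)) {
  if (any(!is.finite(ctSlice)))
    stop("input error: CT slice contains non-finite values")
  w <- pmin(pmax(ctSlice, bodyWindow[1]), bodyWindow[2])
  if (max(w) == min(w)) {
    message("equalizeSlice: constant slice, no contrast")
    return(array(0, dim(ctSlice)))
  }
  out <- rank(w, ties.method = "max") / length(w)
  array(out, dim(ctSlice))
}

.gaussKernel <- function(sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k / sum(k)
}

.bandMatrix <- function(n, k) {
  # replicate-padded 1D convolution as an n x n matrix
  rad <- (length(k) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (o in seq_along(k)) {
    j <- pmin(pmax(seq_len(n) + (o - 1L - rad), 1L), n)
    B[cbind(seq_len(n), j)] <- B[cbind(seq_len(n), j)] + k[o]
  }
  B
}

.convSep <- function(m, kRow, kCol) {
  .bandMatrix(nrow(m), kRow) %*% m %*% t(.bandMatrix(ncol(m), kCol))
}

.shift <- function(m, dr, dc) {
  # shift with replicate padding
  n1 <- nrow(m); n2 <- ncol(m)
  r <- pmin(pmax(seq_len(n1) + dr, 1L), n1)
  c <- pmin(pmax(seq_len(n2) + dc, 1L), n2)
  m[r, c, drop = FALSE]
}

.signedShift <- function(m, sy, sx) {
  # per-pixel sample m[r + sy, c + sx] with sy, sx matrices in {-1, 0, 1}
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    sel <- (sy == dy) & (sx == dx)
    if (any(sel)) out[sel] <- .shift(m, dy, dx)[sel]
  }
  out
}

#' Canny edge detection on an equalized slice
#'
#' Gaussian smoothing at \code{sigma}, Sobel gradients, non-maximum
#' suppression with a tie-break that keeps the brighter-side pixel of a
#' symmetric ridge, and hysteresis thresholding. Thresholds are relative to
#' the slice's maximum gradient magnitude (the MATLAB convention), so they
#' are invariant to global intensity rescaling.
#'
#' @param eqSlice 2D matrix in \[0, 1\] (see [equalizeSlice()]).
#' @param sigma Gaussian smoothing scale in px.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, \code{0 < low < high}.
#' @return m x 2 integer matrix of edge pixel (row, col) coordinates
#'   (possibly zero rows).
#' @export
detectEdges <- function(eqSlice, sigma = 1.4, low = 0.012, high = 0.03) {
  stopifnot(low > 0, low < high)
  g <- .gaussKernel(sigma)
  sm <- .convSep(eqSlice, g, g)
  # Sobel, scaled to a per-pixel derivative
  dk <- c(-0.5, 0, 0.5)
  ak <- c(0.25, 0.5, 0.25)
  gy <- .convSep(sm, dk, ak)   # along rows
  gx <- .convSep(sm, ak, dk)   # along cols
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx <= 1e-10)   # flat slice up to numerical noise
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("row", "col"))))
  mag <- mag / mx
  # non-maximum suppression along the quantized gradient direction; exact
  # ties (symmetric ridges on ideal steps) resolve to the pixel on the
  # brighter side because the comparison toward the gradient is strict
  t225 <- tan(pi / 8)
  horiz <- abs(gy) <= t225 * abs(gx)
  vert <- abs(gx) <= t225 * abs(gy)
  diag1 <- !horiz & !vert & (gx * gy > 0)   # neighbors (+1,+1) / (-1,-1)
  diag2 <- !horiz & !vert & (gx * gy <= 0)  # neighbors (+1,-1) / (-1,+1)
  sy <- matrix(0, nrow(mag), ncol(mag)); sx <- sy
  sx[horiz] <- 1
  sy[vert] <- 1
  sy[diag1] <- 1; sx[diag1] <- 1
  sy[diag2] <- 1; sx[diag2] <- -1
  # orient (sy, sx) along +gradient so "positive" means uphill
  flip <- (horiz & gx < 0) | (vert & gy < 0) | ((diag1 | diag2) & gy < 0)
  sy[flip] <- -sy[flip]; sx[flip] <- -sx[flip]
  nPos <- .signedShift(mag, sy, sx)
  nNeg <- .signedShift(mag, -sy, -sx)
  ridge <- (mag > nPos) & (mag >= nNeg) & mag > 0
  strong <- ridge & (mag >= high)
  weak <- ridge & (mag >= low)
  # hysteresis: grow strong edges through 8-connected weak pixels
  cur <- strong
  repeat {
    dil <- cur
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0L || dc != 0L) dil <- dil | .shift(cur, dr, dc)
    nxt <- weak & dil
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  idx <- which(cur, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    colnames(idx) <- c("row", "col")
    return(idx)
  }
  # sub-pixel refinement: parabolic interpolation of the magnitude along
  # the (quantized) gradient direction puts the returned point on the
  # underlying boundary rather than on the nearest pixel centre
  m0 <- mag[idx]; mp <- nPos[idx]; mn <- nNeg[idx]
  den <- mn - 2 * m0 + mp
  delta <- ifelse(abs(den) > 1e-12, 0.5 * (mn - mp) / den, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  out <- cbind(row = idx[, 1] + delta * sy[idx],
               col = idx[, 2] + delta * sx[idx])
  out
}

#' Pick the tracked psoas region on one slice, per side
#'
#' Among the candidate closed regions of a side, the admissible ones
#' contain the side's tracking point and (when a previous area is known)
#' have an area ratio to it within \code{areaRatioBounds}; the innermost
#' (smallest-area) admissible region is selected, and the tracking point
#' moves to its centroid.
#'
#' @param candidates list with elements \code{left} and \code{right}, each a
#'   list of regions as returned by [alphaShapeRegions()].
#' @param previous list with \code{left}/\code{right}, each
#'   \code{list(point = c(row, col), area = <px or NA>)}; on the first
#'   slice the points are the configured seeds and areas are NA.
#' @param config a [SegmentationConfig-class] (for
#'   \code{areaRatioBounds}).
#' @return list with \code{left}/\code{right}: either \code{NULL} (side
#'   missing on this slice) or \code{list(polygon, area, centroid,
#'   closedByAlphaShape)}.
#' @export
selectPsoasRegions <- function(candidates, previous, config) {
  pick <- function(cands, prev) {
    if (length(cands) == 0L) return(NULL)
    ok <- vapply(cands, function(g) {
      if (!.pointsInPolygon(prev$point[1], prev$point[2], g$polygon))
        return(FALSE)
      if (!is.na(prev$area)) {
        ratio <- g$area / prev$area
        if (ratio < config@areaRatioBounds[1] ||
            ratio > config@areaRatioBounds[2]) return(FALSE)
      }
      TRUE
    }, logical(1))
    if (!any(ok)) return(NULL)
    cands <- cands[ok]
    g <- cands[[which.min(vapply(cands, `[[`, numeric(1), "area"))]]
    list(polygon = g$polygon, area = g$area, centroid = g$centroid,
         closedByAlphaShape = g$maxEdge > sqrt(2) + 1e-6)
  }
  list(left = pick(candidates$left, previous$left),
       right = pick(candidates$right, previous$right))
}

.insetPolygon <- function(poly, inset) {
  # offset each vertex inward (toward the interior of a positively
  # oriented polygon) along the averaged edge normal
  if (inset <= 0) return(poly)
  n <- nrow(poly)
  if (n < 3L) return(poly)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  unitNormal <- function(d) {
    l <- sqrt(rowSums(d^2)); l[l == 0] <- 1
    cbind(d[, 2], -d[, 1]) / l          # left normal in (row, col) coords
  }
  nn <- unitNormal(poly[nxt, , drop = FALSE] - poly) +
        unitNormal(poly - poly[prv, , drop = FALSE])
  l <- sqrt(rowSums(nn^2)); l[l == 0] <- 1
  poly + inset * nn / l
}

.rasterizePolygon <- function(poly, nrow, ncol) {
  # pixels whose centers fall inside the polygon (even-odd rule)
  rr <- range(poly[, 1]); cc <- range(poly[, 2])
  r0 <- max(1L, floor(rr[1])); r1 <- min(nrow, ceiling(rr[2]))
  c0 <- max(1L, floor(cc[1])); c1 <- min(ncol, ceiling(cc[2]))
  if (r1 < r0 || c1 < c0) return(matrix(integer(0), 0, 2))
  gr <- expand.grid(row = r0:r1, col = c0:c1)
  inside <- .pointsInPolygon(gr$row, gr$col, poly)
  as.matrix(gr[inside, , drop = FALSE])
}

.windowPoints <- function(edges, center, radius) {
  sel <- abs(edges[, 1] - center[1]) <= radius &
         abs(edges[, 2] - center[2]) <= radius
  edges[sel, , drop = FALSE]
}

#' Segment both psoas bodies over a configured slice range
#'
#' Runs the per-slice chain (equalize, Canny, alpha-shape closure, tracked
#' selection) over \code{[sliceStart, sliceStop)} and rasterizes the
#' selected contours into a label mask (1 = left, 2 = right). Slices where
#' a side yields no admissible region are repaired by copying the nearest
#' selected contour of that side, provided no more than \code{kMissing}
#' consecutive slices failed; longer runs are a hard error naming the
#' slices.
#'
#' @param ct a [VolumeGrid-class] with modality \code{"CT_HU"}.
#' @param config a [SegmentationConfig-class].
#' @return A [BinaryMask3D-class] on the CT grid with a \code{"qc"}
#'   attribute: a per-slice, per-side data.frame (slice, side, area_px,
#'   closed_by_alpha_shape, selected, filled_from).
#' @export
buildMask <- function(ct, config) {
  stopifnot(is(ct, "VolumeGrid"))
  validObject(config)
  d <- dim(ct@data)
  if (config@sliceStop > d[1] + 1L)
    stop("input error: slice range exceeds volume (", d[1], " slices)")
  slices <- config@sliceStart:(config@sliceStop - 1L)
  sides <- c("left", "right")
  track <- list(left = list(point = config@seeds["left", ], area = NA_real_),
                right = list(point = config@seeds["right", ], area = NA_real_))
  sel <- list(left = vector("list", length(slices)),
              right = vector("list", length(slices)))
  qc <- list()
  for (i in seq_along(slices)) {
    s <- slices[i]
    eq <- equalizeSlice(ct@data[s, , ], config@bodyWindow)
    edges <- detectEdges(eq, config@cannySigma, config@cannyLow,
                         config@cannyHigh)
    cands <- list()
    for (sd in sides) {
      pts <- .windowPoints(edges, track[[sd]]$point, config@captureRadius)
      cands[[sd]] <- if (nrow(pts) >= 3L && !.allCollinear(pts)) {
        r <- if (is.na(config@alpha))
          .autoAlphaRadius(pts, track[[sd]]$point) else 1 / config@alpha
        if (is.na(r)) list() else alphaShapeRegions(pts, r)
      } else list()
    }
    chosen <- selectPsoasRegions(cands, track, config)
    for (sd in sides) {
      g <- chosen[[sd]]
      if (!is.null(g)) {
        sel[[sd]][[i]] <- g
        track[[sd]] <- list(point = g$centroid, area = g$area)
      }
      qc[[length(qc) + 1L]] <- data.frame(
        slice = s, side = sd,
        area_px = if (is.null(g)) NA_real_ else g$area,
        closed_by_alpha_shape = if (is.null(g)) NA else g$closedByAlphaShape,
        selected = !is.null(g), filled_from = NA_integer_)
    }
  }
  qc <- do.call(rbind, qc)
  # repair missing slices by nearest-neighbor contour copy
  for (sd in sides) {
    found <- which(!vapply(sel[[sd]], is.null, logical(1)))
    if (length(found) == 0L)
      stop("segmentation error: no ", sd, " psoas region found in slices ",
           slices[1], "-", slices[length(slices)])
    missing <- setdiff(seq_along(slices), found)
    if (length(missing)) {
      runs <- split(missing, cumsum(c(1, diff(missing) != 1)))
      for (run in runs) {
        if (length(run) > config@kMissing)
          stop("segmentation error: ", length(run),
               " consecutive failures on ", sd, " side at slices ",
               paste(slices[run], collapse = ", "))
      }
      for (m in missing) {
        src <- found[which.min(abs(found - m))]
        sel[[sd]][[m]] <- sel[[sd]][[src]]
        qc$filled_from[qc$slice == slices[m] & qc$side == sd] <- slices[src]
      }
      warning(sprintf("filled %d missing %s-side slice(s) by contour copy",
                      length(missing), sd), call. = FALSE)
    }
  }
  labels <- array(0L, d)
  for (i in seq_along(slices)) {
    s <- slices[i]
    for (sd in sides) {
      px <- .rasterizePolygon(
        .insetPolygon(sel[[sd]][[i]]$polygon, config@contourInset),
        d[2], d[3])
      if (nrow(px)) {
        lab <- if (sd == "left") 1L else 2L
        cur <- labels[cbind(s, px[, 1], px[, 2])]
        free <- cur == 0L
        labels[cbind(s, px[free, 1], px[free, 2])] <- lab
      }
    }
  }
  mask <- BinaryMask3D(labels, grid = ct, gridId = "ct")
  attr(mask, "qc") <- qc
  mask
}
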