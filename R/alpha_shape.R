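# 2D alpha-shape machinery for contour closure.
#
# Edge detection on an axial CT slice yields a point cloud tracing tissue
# outlines: mostly closed pixel chains with gaps where contrast drops.
# The alpha-shape of the cloud at disc radius r = 1/alpha consists of
#   (i)  every Delaunay edge whose smallest empty circumscribing disc has
#        radius <= r (this includes the "singular" chain edges that
#        reconstruct a sampled curve and the short-cut edges that bridge
#        chain gaps narrower than ~2r), minus
#   (ii) edges interior to the filled complex (shared by two triangles
#        with circumradius <= r).
# The surviving edges form a planar graph; its bounded faces are the
# closed regions. As r grows to infinity the graph degenerates to the
# convex hull boundary and the single face is the hull. Delaunay
# triangulation itself comes from deldir; everything alpha-specific lives
# here.

.delaunayTriangles <- function(points) {
  # points: n x 2 (row, col). Returns points (deduplicated) + m x 3 index
  # matrix of triangles.
  if (nrow(points) < 3L)
    stop("segmentation failure: need at least 3 points for triangulation")
  dup <- duplicated(points)
  if (any(dup)) points <- points[!dup, , drop = FALSE]
  if (nrow(points) < 3L)
    stop("segmentation failure: fewer than 3 distinct points")
  if (.allCollinear(points))
    stop("segmentation failure: points are collinear")
  # tolerance dedup: sub-pixel refined edge points can nearly coincide,
  # which upsets the triangulation numerics
  key <- paste(round(points[, 1] * 128), round(points[, 2] * 128))
  points <- points[!duplicated(key), , drop = FALSE]
  if (nrow(points) < 3L)
    stop("segmentation failure: fewer than 3 distinct points")
  tryTriang <- function(p) {
    dd <- NULL
    # deldir chats about internal retries from C code on near-degenerate
    # input; capture both streams so pipelines stay quiet
    utils::capture.output(utils::capture.output(
      dd <- suppressMessages(suppressWarnings(
        deldir::deldir(p[, 2], p[, 1], suppressMsge = TRUE))),
      type = "message"), type = "output")
    deldir::triMat(dd)
  }
  tri <- try(tryTriang(points), silent = TRUE)
  if (inherits(tri, "try-error")) {
    # deterministic sub-milli-pixel jitter breaks residual degeneracies
    jit <- points + 2e-3 * cbind(sin(seq_len(nrow(points))),
                                 cos(seq_len(nrow(points)) * 1.7))
    tri <- try(tryTriang(jit), silent = TRUE)
    if (inherits(tri, "try-error"))
      stop("segmentation failure: triangulation failed")
    points <- jit
  }
  list(points = points, tri = tri)
}

.allCollinear <- function(points) {
  if (nrow(points) < 3L) return(TRUE)
  p1 <- points[1, ]
  d <- sweep(points[-1, , drop = FALSE], 2, p1)
  ref <- d[which.max(rowSums(d^2)), ]
  cr <- ref[1] * d[, 2] - ref[2] * d[, 1]
  all(abs(cr) < 1e-9)
}

.circumradii <- function(points, tri) {
  a <- sqrt((points[tri[, 1], 1] - points[tri[, 2], 1])^2 +
            (points[tri[, 1], 2] - points[tri[, 2], 2])^2)
  b <- sqrt((points[tri[, 2], 1] - points[tri[, 3], 1])^2 +
            (points[tri[, 2], 2] - points[tri[, 3], 2])^2)
  c <- sqrt((points[tri[, 3], 1] - points[tri[, 1], 1])^2 +
            (points[tri[, 3], 2] - points[tri[, 1], 2])^2)
  k2 <- abs((points[tri[, 2], 2] - points[tri[, 1], 2]) *
              (points[tri[, 3], 1] - points[tri[, 1], 1]) -
            (points[tri[, 3], 2] - points[tri[, 1], 2]) *
              (points[tri[, 2], 1] - points[tri[, 1], 1]))
  a * b * c / (2 * pmax(k2, .Machine$double.eps))
}

.alphaEdges <- function(points, tri) {
  # unique Delaunay edges with: endpoint indices, length, smallest
  # empty-disc radius rho, adjacent triangle circumradii (NA if hull edge)
  R <- .circumradii(points, tri)
  e <- rbind(tri[, c(1, 2, 3)], tri[, c(2, 3, 1)], tri[, c(3, 1, 2)])
  # columns: endpoint1, endpoint2, opposite vertex
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- lo * (nrow(points) + 1) + hi
  triIdx <- rep(seq_len(nrow(tri)), 3L)
  ord <- order(key)
  key <- key[ord]; lo <- lo[ord]; hi <- hi[ord]
  opp <- e[ord, 3]; triIdx <- triIdx[ord]
  first <- !duplicated(key)
  uIdx <- cumsum(first)
  nU <- uIdx[length(uIdx)]
  P1 <- points[lo, , drop = FALSE]; P2 <- points[hi, , drop = FALSE]
  PW <- points[opp, , drop = FALSE]
  len2 <- rowSums((P1 - P2)^2)
  # opposite angle >= 90 deg  <=>  (p1-w).(p2-w) <= 0
  obtuse <- rowSums((P1 - PW) * (P2 - PW)) <= 0
  Rtri <- R[triIdx]
  rho <- rep(Inf, nU); anyObtuse <- rep(FALSE, nU)
  r1 <- rep(NA_real_, nU); r2 <- rep(NA_real_, nU)
  for (i in seq_along(key)) {
    u <- uIdx[i]
    if (obtuse[i]) {
      anyObtuse[u] <- TRUE
      rho[u] <- min(rho[u], Rtri[i])
    }
    if (is.na(r1[u])) r1[u] <- Rtri[i] else r2[u] <- Rtri[i]
  }
  halfLen <- sqrt(len2[first]) / 2
  rho <- ifelse(anyObtuse, rho, halfLen)
  data.frame(v1 = lo[first], v2 = hi[first], length = 2 * halfLen,
             rho = rho, r1 = r1, r2 = r2)
}

.traceFaces <- function(points, edges) {
  # bounded faces of the planar straight-line graph given by `edges`
  # (data.frame with v1, v2). Returns list of vertex-index cycles.
  if (nrow(edges) == 0L) return(list())
  m <- nrow(edges)
  dartFrom <- c(edges$v1, edges$v2)
  dartTo <- c(edges$v2, edges$v1)
  twin <- c(m + seq_len(m), seq_len(m))
  ang <- atan2(points[dartTo, 1] - points[dartFrom, 1],
               points[dartTo, 2] - points[dartFrom, 2])
  # darts grouped by origin vertex, sorted by angle (ccw)
  nxt <- integer(2 * m)
  byFrom <- split(seq_len(2 * m), dartFrom)
  for (ds in byFrom) {
    ds <- ds[order(ang[ds])]
    k <- length(ds)
    # next dart of d = twin(d)'s cw-successor around head(d):
    # precompute, for each dart, its cw predecessor around its origin
    for (j in seq_len(k)) {
      prv <- ds[if (j == 1L) k else j - 1L]
      nxt[twin[ds[j]]] <- prv
    }
  }
  used <- rep(FALSE, 2 * m)
  faces <- list()
  for (d0 in seq_len(2 * m)) {
    if (used[d0]) next
    cyc <- integer(0)
    d <- d0
    repeat {
      used[d] <- TRUE
      cyc <- c(cyc, dartFrom[d])
      d <- nxt[d]
      if (d == d0) break
    }
    faces[[length(faces) + 1L]] <- cyc
  }
  faces
}

.polygonArea <- function(poly) {
  # signed shoelace area; poly: k x 2 (row, col)
  y <- poly[, 1]; x <- poly[, 2]
  j <- c(nrow(poly), seq_len(nrow(poly) - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

.polygonCentroid <- function(poly) {
  y <- poly[, 1]; x <- poly[, 2]
  j <- c(nrow(poly), seq_len(nrow(poly) - 1L))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(poly))
  c(sum((y + y[j]) * cr) / (6 * a), sum((x + x[j]) * cr) / (6 * a))
}

.pointsInPolygon <- function(py, px, poly) {
  # even-odd rule (ray casting); poly: k x 2 (row, col); vectorized in
  # the query points
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    if (yi != yj) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Closed regions of the alpha-shape of a planar point set
#'
#' Builds the Delaunay triangulation, keeps every edge whose smallest
#' empty circumscribing disc has radius at most \code{r} while discarding
#' edges interior to the filled complex, and returns the bounded faces of
#' the resulting planar graph as closed polygons.
#'
#' @param points n x 2 matrix of (row, col) coordinates.
#' @param r alpha-disc radius (same unit as the coordinates);
#'   \code{Inf} gives the convex hull.
#' @return A list of candidate regions; each has \code{polygon} (k x 2,
#'   vertices in order, closed implicitly), \code{area} (absolute, px^2),
#'   \code{centroid} (row, col), and \code{maxEdge} (longest boundary
#'   segment, px).
#' @seealso [closeRegionAlphaShape()]
#' @export
alphaShapeRegions <- function(points, r) {
  dt <- .delaunayTriangles(as.matrix(points))
  .regionsAtRadius(dt$points, .alphaEdges(dt$points, dt$tri), r)
}

.regionsAtRadius <- function(pts, ae, r) {
  interior <- !is.na(ae$r1) & !is.na(ae$r2) &
    ae$r1 <= r + 1e-9 & ae$r2 <= r + 1e-9
  keep <- ae$rho <= r + 1e-9 & !interior
  edges <- ae[keep, , drop = FALSE]
  faces <- .traceFaces(pts, edges)
  out <- list()
  for (cyc in faces) {
    poly <- pts[cyc, , drop = FALSE]
    a <- .polygonArea(poly)
    if (a <= 1e-9) next                      # outer face / degenerate
    nxt <- c(seq_len(nrow(poly))[-1], 1L)
    segLen <- sqrt(rowSums((poly[nxt, , drop = FALSE] - poly)^2))
    out[[length(out) + 1L]] <- list(polygon = poly, area = a,
                                    centroid = .polygonCentroid(poly),
                                    maxEdge = max(segLen))
  }
  out
}

.autoAlphaRadius <- function(points, seedPoint) {
  # smallest alpha-disc radius whose alpha-shape has a bounded face
  # containing the seed; NA when even the convex hull misses it
  dt <- try(.delaunayTriangles(as.matrix(points)), silent = TRUE)
  if (inherits(dt, "try-error")) return(NA_real_)
  ae <- .alphaEdges(dt$points, dt$tri)
  cand <- sort(unique(ae$rho))
  cand <- cand[is.finite(cand)]
  containsSeed <- function(r) {
    regs <- .regionsAtRadius(dt$points, ae, r)
    any(vapply(regs, function(g)
      .pointsInPolygon(seedPoint[1], seedPoint[2], g$polygon), logical(1)))
  }
  if (!containsSeed(Inf)) return(NA_real_)
  lo <- 1L; hi <- length(cand)
  if (hi == 0L) return(NA_real_)
  if (!containsSeed(cand[hi])) return(Inf)
  while (lo < hi) {           # containment is monotone in r
    mid <- (lo + hi) %/% 2L
    if (containsSeed(cand[mid])) hi <- mid else lo <- mid + 1L
  }
  cand[lo]
}

#' Close a gappy edge chain around a seed with an alpha-shape
#'
#' Returns the boundary polygon of the alpha-shape face containing the
#' seed point. With \code{alpha = NA} the disc radius is auto-tuned per
#' call: the smallest radius at which a closed face contains the seed
#' (gaps in the chain are therefore bridged by the smallest discs able to
#' close them). As \code{alpha} tends to 0 (disc radius to infinity) the
#' region tends to the convex hull of the points.
#'
#' @param points n x 2 matrix (row, col) of edge points (>= 3 distinct,
#'   not all collinear).
#' @param seed numeric(2) (row, col) point that must end up inside.
#' @param alpha inverse disc radius (1/px); \code{NA} auto-tunes.
#' @return k x 2 polygon matrix with attributes \code{closedByAlphaShape}
#'   (TRUE when the chain was not already pixel-connected and a gap was
#'   bridged), \code{area}, \code{centroid}, and \code{radius} (the disc
#'   radius used).
#' @examples
#' sq <- cbind(c(0, 0, 10, 10), c(0, 10, 0, 10))
#' p <- closeRegionAlphaShape(sq, seed = c(5, 5), alpha = 1e-9)
#' attr(p, "area")  # 100: convex-hull limit
#' @export
closeRegionAlphaShape <- function(points, seed, alpha = NA_real_) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("segmentation failure: fewer than 3 edge points")
  r <- if (is.na(alpha)) .autoAlphaRadius(points, seed) else 1 / alpha
  if (is.na(r))
    stop("segmentation failure: no closed region contains the seed")
  regs <- alphaShapeRegions(points, r)
  cont <- vapply(regs, function(g)
    .pointsInPolygon(seed[1], seed[2], g$polygon), logical(1))
  if (!any(cont))
    stop("segmentation failure: no closed region contains the seed")
  regs <- regs[cont]
  g <- regs[[which.min(vapply(regs, `[[`, numeric(1), "area"))]]
  poly <- g$polygon
  attr(poly, "closedByAlphaShape") <- g$maxEdge > sqrt(2) + 1e-6
  attr(poly, "area") <- g$area
  attr(poly, "centroid") <- g$centroid
  attr(poly, "radius") <- r
  poly
}
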