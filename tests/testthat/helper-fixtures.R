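# Shared fixtures: reduced phantoms (fewer slices than the calibration
# phantom, same in-plane anatomy) and small analytic grids. All fixtures
# are generated in code at test time.

smallPhantomSpec <- function(...) {
  phantomSpec(ctDim = c(12L, 256L, 256L), petDim = c(12L, 64L, 64L),
              muscleSliceRange = c(2L, 11L),
              liverCenter = c(15, 100, 70), liverAxes = c(12, 28, 36),
              ...)
}

smallSegConfig <- function(spec, ...) {
  phantomSegmentationConfig(spec, margin = 2L)
}

diceCoefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# truth restricted to a half-open slice range, as segmented masks are
truthInRange <- function(truthMask, sliceStart, sliceStop) {
  lab <- maskLabels(truthMask)
  out <- array(0L, dim(lab))
  sl <- sliceStart:(sliceStop - 1L)
  out[sl, , ] <- lab[sl, , ]
  out
}

# independent log-rank oracle: explicit hypergeometric sums over the
# distinct event times (sum(O - E))^2 / sum(V)
logrankOracle <- function(t1, e1, t2, e2) {
  tt <- c(t1, t2); ee <- c(e1, e2)
  gg <- rep(1:2, c(length(t1), length(t2)))
  OminusE <- 0; V <- 0
  for (tau in sort(unique(tt[ee == 1]))) {
    atRisk <- tt >= tau
    n <- sum(atRisk); n1 <- sum(atRisk & gg == 1)
    d <- sum(tt == tau & ee == 1)
    d1 <- sum(tt == tau & ee == 1 & gg == 1)
    OminusE <- OminusE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(NA_real_)
  OminusE^2 / V
}

# brute-force smallest empty-disc radius through a pair of points, by a
# fine scan of disc centres along the perpendicular bisector (both sides);
# Inf when no empty disc exists (not a Delaunay edge)
bruteEmptyDiscRadius <- function(points, i, j, tMax = 50, nT = 4000) {
  p <- points[i, ]; q <- points[j, ]
  mid <- (p + q) / 2
  d <- q - p
  len <- sqrt(sum(d^2))
  perp <- c(-d[2], d[1]) / len
  others <- points[-c(i, j), , drop = FALSE]
  best <- Inf
  for (t in seq(-tMax, tMax, length.out = nT)) {
    ctr <- mid + t * perp
    r <- sqrt((len / 2)^2 + t^2)
    if (r >= best) next
    d2 <- (others[, 1] - ctr[1])^2 + (others[, 2] - ctr[2])^2
    if (nrow(others) == 0L || all(d2 > r^2 - 1e-12)) best <- r
  }
  best
}

# brute-force box-overlap downsampling oracle: per target voxel, loop
# over all source voxels and accumulate exact interval intersections
bruteDownsample <- function(lab, sSp, sOr, dDim, dSp, dOr, frac = 0.5) {
  out <- array(0L, dDim)
  sDim <- dim(lab)
  for (i in seq_len(dDim[1])) for (j in seq_len(dDim[2]))
    for (k in seq_len(dDim[3])) {
      lo <- dOr + (c(i, j, k) - 1) * dSp - dSp / 2
      hi <- lo + dSp
      cov <- c(0, 0)
      for (a in seq_len(sDim[1])) {
        zl <- sOr[1] + (a - 1) * sSp[1] - sSp[1] / 2
        oz <- max(0, min(hi[1], zl + sSp[1]) - max(lo[1], zl))
        if (oz == 0) next
        for (b in seq_len(sDim[2])) {
          yl <- sOr[2] + (b - 1) * sSp[2] - sSp[2] / 2
          oy <- max(0, min(hi[2], yl + sSp[2]) - max(lo[2], yl))
          if (oy == 0) next
          for (cc in seq_len(sDim[3])) {
            l <- lab[a, b, cc]
            if (l == 0L) next
            xl <- sOr[3] + (cc - 1) * sSp[3] - sSp[3] / 2
            ox <- max(0, min(hi[3], xl + sSp[3]) - max(lo[3], xl))
            cov[l] <- cov[l] + oz * oy * ox
          }
        }
      }
      tot <- sum(cov) / prod(dSp)
      if (tot >= frac - 1e-12)
        out[i, j, k] <- if (cov[1] >= cov[2]) 1L else 2L
    }
  out
}
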