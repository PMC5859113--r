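# 2D binary morphology on a single slice. Structuring element: the
# 4-connected disc of radius 1 (EBImage "diamond" brush), applied
# iteratively so that iteration counts are meaningful; n iterations of
# dilation with this element equal a city-block distance transform
# thresholded at n.

kern4 <- function() EBImage::makeBrush(3L, shape = "diamond")

# erode with outside-of-image treated as background: pad, erode, crop
morph_erode <- function(m, n = 1L) {
  x <- (m != 0) * 1
  if (n < 1L) return(x > 0)
  d <- dim(x)
  pad <- matrix(0, d[1] + 2L * n, d[2] + 2L * n)
  pad[n + seq_len(d[1]), n + seq_len(d[2])] <- x
  k <- kern4()
  for (i in seq_len(n)) pad <- EBImage::erode(pad, k)
  pad[n + seq_len(d[1]), n + seq_len(d[2])] > 0.5
}

morph_dilate <- function(m, n = 1L) {
  x <- (m != 0) * 1
  if (n < 1L) return(x > 0)
  k <- kern4()
  for (i in seq_len(n)) x <- EBImage::dilate(x, k)
  x > 0.5
}

shift2d <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Morphological (Lantuejoul) skeleton over max_iter erosion levels:
# union over k = 0..max_iter of erode^k(X) minus its opening. Each level
# contributes the voxels of the k-fold eroded set that an opening cannot
# recover, giving a medial stroke set that follows the region's lobes.
morph_skeleton <- function(m, max_iter) {
  m <- m != 0
  ek <- m
  skel <- matrix(FALSE, nrow(m), ncol(m))
  for (k in 0:max(0L, max_iter)) {
    if (!any(ek)) break
    opened <- morph_dilate(morph_erode(ek, 1L), 1L)
    skel <- skel | (ek & !opened)
    ek <- morph_erode(ek, 1L)
  }
  if (!any(skel)) skel <- m  # degenerate: keep the region itself
  skel
}

region_centroid <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  colMeans(idx)
}

# minor axis length of the area-equivalent ellipse (4 * sqrt of the smaller
# eigenvalue of the coordinate covariance), the standard regionprops value
region_minor_axis <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(1)
  cv <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  4 * sqrt(max(min(ev), 0))
}

# fill of the convex hull of a 2D region (half-plane test against the
# hull's edges, vectorized over the voxel grid)
convex_fill <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) <= 2L) return(m != 0)
  h <- grDevices::chull(idx)
  hull <- idx[h, , drop = FALSE]  # counterclockwise or clockwise
  nh <- nrow(hull)
  nxt <- c(seq_len(nh)[-1], 1L)
  # polygon orientation from the shoelace sum so the half-plane test is
  # consistent whichever way chull ordered the vertices
  sgn <- sign(sum(hull[, 1] * hull[nxt, 2] - hull[nxt, 1] * hull[, 2]))
  if (sgn == 0) sgn <- 1
  gr <- as.matrix(expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m))))
  inside <- rep(TRUE, nrow(gr))
  for (i in seq_len(nh)) {
    a <- hull[i, ]
    b <- hull[nxt[i], ]
    cr <- (b[1] - a[1]) * (gr[, 2] - a[2]) - (b[2] - a[2]) * (gr[, 1] - a[1])
    inside <- inside & (sgn * cr >= -1e-9)
  }
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[gr[inside, , drop = FALSE]] <- TRUE
  out
}
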