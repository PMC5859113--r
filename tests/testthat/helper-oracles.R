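# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with literal loops and textbook formulas, kept
# free of the package's own code paths.

# literal synchronous GrowCut automaton (triple loop), matching the
# documented rule: neighbour q captures p iff (1 - |c_p - c_q|) * s_q > s_p,
# 26-connectivity, ties keep the incumbent. Records per-iteration strengths.
growcut_reference <- function(image, labels, max_iters) {
  d <- dim(image)
  rng <- range(image)
  if (rng[2] > rng[1]) image <- (image - rng[1]) / (rng[2] - rng[1])
  else image <- array(0, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lab <- labels
  str <- array(as.numeric(labels != 0), d)
  history <- list()
  iter <- 0L
  while (iter < max_iters) {
    nlab <- lab
    nstr <- str
    changed <- FALSE
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      bl <- lab[x, y, z]
      bs <- str[x, y, z]
      cp <- image[x, y, z]
      for (k in seq_len(nrow(offs))) {
        qx <- x + offs[k, 1]; qy <- y + offs[k, 2]; qz <- z + offs[k, 3]
        if (qx < 1 || qx > d[1] || qy < 1 || qy > d[2] ||
            qz < 1 || qz > d[3]) next
        if (lab[qx, qy, qz] == 0) next
        attack <- (1 - abs(cp - image[qx, qy, qz])) * str[qx, qy, qz]
        if (attack > bs) {
          bs <- attack
          bl <- lab[qx, qy, qz]
        }
      }
      nlab[x, y, z] <- bl
      nstr[x, y, z] <- bs
      if (bl != lab[x, y, z] || bs != str[x, y, z]) changed <- TRUE
    }
    lab <- nlab
    str <- nstr
    iter <- iter + 1L
    history[[iter]] <- str
    if (!changed) break
  }
  list(labels = lab, strengths = str, iterations = iter, history = history)
}

# brute-force GLCM: enumerate every voxel pair under every offset
glcm_reference <- function(image, mask, n_bins = 24L, offsets = NULL) {
  if (is.null(offsets)) {
    offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
    offsets <- offsets[apply(offsets, 1, function(o) o[o != 0][1] > 0), ,
                       drop = FALSE]
  }
  d <- dim(image)
  rng <- range(image)
  scaled <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) * 255
            else image * 0
  bin <- pmin(floor(scaled / (255 / n_bins)) + 1, n_bins)
  counts <- matrix(0, n_bins, n_bins)
  vox <- which(mask != 0, arr.ind = TRUE)
  for (v in seq_len(nrow(vox))) {
    for (r in seq_len(nrow(offsets))) {
      for (s in c(1, -1)) {
        q <- vox[v, ] + s * offsets[r, ]
        if (any(q < 1) || any(q > d)) next
        if (!mask[q[1], q[2], q[3]]) next
        a <- bin[vox[v, 1], vox[v, 2], vox[v, 3]]
        b <- bin[q[1], q[2], q[3]]
        counts[a, b] <- counts[a, b] + 1
      }
    }
  }
  if (sum(counts) == 0) stop("no pairs")
  p <- counts / sum(counts)
  i <- matrix(seq_len(n_bins), n_bins, n_bins)
  j <- t(i)
  nz <- p > 0
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
  c(energy = sum(p^2),
    entropy = -sum(p[nz] * log2(p[nz])),
    correlation = if (s_i == 0 || s_j == 0) 0 else
      sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j),
    homogeneity = sum(p / (1 + (i - j)^2)),
    contrast = sum(p * (i - j)^2))
}

# exhaustive directed surface distances: surface voxels by 6-neighbour
# loop, all point-pair distances in mm
surface_reference <- function(mask, spacing) {
  d <- dim(mask)
  surf <- NULL
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    nb_out <- FALSE
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      q <- c(x, y, z) + o
      if (any(q < 1) || any(q > d) || !mask[q[1], q[2], q[3]]) {
        nb_out <- TRUE
        break
      }
    }
    if (nb_out) surf <- rbind(surf, c(x, y, z))
  }
  sweep(surf, 2, spacing, `*`)
}

directed_distances_reference <- function(A, G, spacing) {
  sa <- surface_reference(A, spacing)
  sg <- surface_reference(G, spacing)
  apply(sa, 1, function(p) min(sqrt(colSums((t(sg) - p)^2))))
}

# simple seeded test volume: two-intensity lesion/background block
two_region_image <- function(d = c(10, 10, 8), lesion = 200, bg = 0) {
  img <- array(bg, d)
  img[4:7, 4:7, 3:6] <- lesion
  img
}

make_seeds <- function(d, fg_at, bg_at) {
  s <- array(0L, d)
  s[matrix(fg_at, ncol = 3)] <- 1L
  s[matrix(bg_at, ncol = 3)] <- 2L
  s
}

# quick series builder: four volumes from a function of timepoint
series_from <- function(f, d = c(8, 8, 6), spacing = c(1, 1, 1)) {
  dce_series(lapply(0:3, function(t) array(f(t), d)), spacing)
}
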