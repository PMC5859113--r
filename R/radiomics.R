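#' First-order texture statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), skewness (moment
#' coefficient g1) and excess kurtosis (normal = 0) of the raw intensities
#' inside a mask. Degenerate regions (a single voxel, or zero variance)
#' return 0 for SD/skewness/kurtosis with a flag.
#'
#' @param image numeric 3D array.
#' @param mask nonempty logical mask, same shape.
#' @return named numeric vector `mean`, `sd`, `kurtosis`, `skewness`, with
#'   attribute `flag` when degenerate.
#' @export
first_order <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) stop("image/mask shapes differ")
  v <- image[mask != 0]
  if (length(v) == 0L) stop("empty mask")
  mu <- mean(v)
  flag <- NULL
  if (length(v) == 1L) {
    out <- c(mean = mu, sd = 0, kurtosis = 0, skewness = 0)
    attr(out, "flag") <- "single-voxel mask"
    return(out)
  }
  s <- stats::sd(v)
  m2 <- mean((v - mu)^2)
  if (m2 == 0) {
    out <- c(mean = mu, sd = 0, kurtosis = 0, skewness = 0)
    attr(out, "flag") <- "constant region"
    return(out)
  }
  skew <- mean((v - mu)^3) / m2^1.5
  kurt <- mean((v - mu)^4) / m2^2 - 3
  out <- c(mean = mu, sd = s, kurtosis = kurt, skewness = skew)
  if (!is.null(flag)) attr(out, "flag") <- flag
  out
}

# the 13 symmetric unit displacement vectors of the 26-neighbourhood
glcm_offsets_13 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- apply(offs, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  unname(offs[keep, , drop = FALSE])
}

# quantize a volume: linear rescale of the whole volume to [0, 255], then
# n_bins equal-width bins
glcm_quantize <- function(image, n_bins, rescale_range = NULL) {
  if (is.null(rescale_range)) rescale_range <- range(image)
  lo <- rescale_range[1]
  hi <- rescale_range[2]
  scaled <- if (hi > lo) (image - lo) / (hi - lo) * 255 else image * 0
  width <- 255 / n_bins
  b <- floor(scaled / width) + 1L
  array(pmin(as.integer(b), n_bins), dim(image))
}

#' Haralick texture features from a gray-level co-occurrence matrix
#'
#' The image is linearly rescaled to 0-255 over the whole volume, quantized
#' into `n_bins` equal-width bins, and co-occurrence counts are pooled over
#' the offsets (by default the 13 symmetric unit displacements of the 3D
#' 26-neighbourhood) for voxel pairs lying entirely inside the mask;
#' symmetric pairs are counted in both directions and the matrix is
#' normalized to sum 1. Returns the five Haralick measures: energy
#' `sum p^2`, entropy `-sum p log2 p`, correlation, homogeneity
#' `sum p / (1 + (i - j)^2)` and contrast `sum p (i - j)^2`. A zero-variance
#' matrix yields correlation 0 with a flag.
#'
#' @param image numeric 3D array.
#' @param mask logical mask with at least one in-mask voxel pair under some
#'   offset.
#' @param n_bins number of gray-level bins.
#' @param rescale_range optional fixed rescale range; default is the full
#'   volume's intensity range.
#' @param offsets integer matrix of displacement vectors (rows), default
#'   the 13 symmetric 3D unit offsets.
#' @return named numeric vector `energy`, `entropy`, `correlation`,
#'   `homogeneity`, `contrast`; attribute `glcm` holds the normalized
#'   matrix.
#' @export
glcm_features <- function(image, mask, n_bins = 24L, rescale_range = NULL,
                          offsets = glcm_offsets_13()) {
  if (!identical(dim(image), dim(mask))) stop("image/mask shapes differ")
  mask <- mask != 0
  d <- dim(image)
  B <- glcm_quantize(image, n_bins, rescale_range)
  counts <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    xr <- seq_len(max(0L, d[1] - abs(o[1])))
    yr <- seq_len(max(0L, d[2] - abs(o[2])))
    zr <- seq_len(max(0L, d[3] - abs(o[3])))
    if (!length(xr) || !length(yr) || !length(zr)) next
    x1 <- xr + max(0L, -o[1]); x2 <- xr + max(0L, o[1])
    y1 <- yr + max(0L, -o[2]); y2 <- yr + max(0L, o[2])
    z1 <- zr + max(0L, -o[3]); z2 <- zr + max(0L, o[3])
    ok <- mask[x1, y1, z1, drop = FALSE] & mask[x2, y2, z2, drop = FALSE]
    if (!any(ok)) next
    a <- B[x1, y1, z1, drop = FALSE][ok]
    b <- B[x2, y2, z2, drop = FALSE][ok]
    tab <- matrix(tabulate((a - 1L) * n_bins + b, nbins = n_bins * n_bins),
                  n_bins, n_bins, byrow = TRUE)
    counts <- counts + tab + t(tab)
  }
  tot <- sum(counts)
  if (tot == 0) stop("no in-mask voxel pairs under the given offsets")
  p <- counts / tot
  i <- matrix(seq_len(n_bins), n_bins, n_bins)
  j <- t(i)
  energy <- sum(p^2)
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  contrast <- sum(p * (i - j)^2)
  homogeneity <- sum(p / (1 + (i - j)^2))
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p))
  s_j <- sqrt(sum((j - mu_j)^2 * p))
  flag <- NULL
  if (s_i == 0 || s_j == 0) {
    correlation <- 0
    flag <- "zero-variance co-occurrence matrix"
  } else {
    correlation <- sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
  }
  out <- c(energy = energy, entropy = entropy, correlation = correlation,
           homogeneity = homogeneity, contrast = contrast)
  attr(out, "glcm") <- p
  if (!is.null(flag)) attr(out, "flag") <- flag
  out
}

#' Extract the 36-feature radiomics vector
#'
#' Nine texture values (mean, SD, kurtosis, skewness, energy, entropy,
#' correlation, homogeneity, contrast) per MR sequence (pre, post1, post2,
#' post3) computed inside a segmented tumour mask: 36 named values in a
#' fixed order.
#'
#' @param series a [dce_series()].
#' @param mask nonempty logical tumour mask.
#' @return named numeric vector of length 36 (e.g. `pre_mean`, ...,
#'   `post3_contrast`).
#' @export
extract_feature_vector <- function(series, mask) {
  stopifnot(inherits(series, "dce_series"))
  if (!any(mask != 0)) stop("empty mask")
  out <- numeric(0)
  for (seq_name in names(series$volumes)) {
    img <- series$volumes[[seq_name]]
    fo <- first_order(img, mask)
    gl <- glcm_features(img, mask)
    v <- c(fo[c("mean", "sd", "kurtosis", "skewness")],
           gl[c("energy", "entropy", "correlation", "homogeneity",
                "contrast")])
    names(v) <- paste(seq_name, names(v), sep = "_")
    out <- c(out, v)
  }
  out
}
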