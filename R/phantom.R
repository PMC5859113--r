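#' Specification of a synthetic DCE phantom
#'
#' Describes one synthetic case: an enhancing lesion (ellipsoidal mass or a
#' non-mass union of small blobs) embedded in parenchymal background with
#' mild or marked background parenchymal enhancement (BPE), imaged at one
#' pre-contrast and three post-contrast timepoints with additive Gaussian
#' noise.
#'
#' @param grid_shape voxels per axis (all >= 8).
#' @param spacing_mm voxel size in mm per axis.
#' @param lesion_kind `"mass"` (ellipsoid) or `"non-mass"` (6-12
#'   overlapping 2-4 mm spheres along a random arc).
#' @param lesion_center lesion centre in voxel indices (defaults to the
#'   grid centre).
#' @param lesion_radii_mm per-axis semi-axes of the lesion envelope, mm.
#' @param uptake_curve 4 lesion intensities (pre, post1..post3); the lesion
#'   must enhance (`uptake_curve[2] > uptake_curve[1]`).
#' @param bpe_level `"mild"` or `"marked"`; scales the background
#'   post-contrast gain (amplitudes 0.15 and 0.45 of baseline).
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   raw intensity units.
#' @param heterogeneity relative amplitude of the smooth within-lesion
#'   intensity texture (0 gives an exactly uniform lesion).
#' @param lobulation relative amplitude of the smooth angular modulation of
#'   the mass boundary (0 gives an exact ellipsoid). Real masses are
#'   lobulated rather than perfectly round; the default adds a mild
#'   irregularity that leaves the volume within a few percent of the
#'   ellipsoid's.
#' @param rng_seed integer seed; simulation is bit-reproducible given it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 16),
                         spacing_mm = c(1, 1, 1),
                         lesion_kind = c("mass", "non-mass"),
                         lesion_center = NULL,
                         lesion_radii_mm = c(6, 6, 5),
                         uptake_curve = c(100, 300, 280, 260),
                         bpe_level = c("mild", "marked"),
                         noise_sd = 5,
                         heterogeneity = 0,
                         lobulation = 0.15,
                         rng_seed = 1L) {
  lesion_kind <- match.arg(lesion_kind)
  bpe_level <- match.arg(bpe_level)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("'grid_shape' must be 3 sizes, all >= 8")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive numbers")
  if (is.null(lesion_center)) lesion_center <- (grid_shape + 1) / 2
  if (length(lesion_center) != 3L) stop("'lesion_center' must have length 3")
  if (length(lesion_radii_mm) != 3L || any(lesion_radii_mm <= 0))
    stop("'lesion_radii_mm' must be 3 positive semi-axes")
  if (length(uptake_curve) != 4L || any(!is.finite(uptake_curve)))
    stop("'uptake_curve' must give 4 finite intensities")
  if (uptake_curve[2] <= uptake_curve[1])
    stop("lesion must enhance: uptake_curve[2] must exceed uptake_curve[1]")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (heterogeneity < 0) stop("'heterogeneity' must be >= 0")
  if (lobulation < 0 || lobulation > 0.5)
    stop("'lobulation' must lie in [0, 0.5]")
  r_vox <- lesion_radii_mm * (1 + lobulation) / spacing_mm
  if (any(lesion_center - r_vox < 1) || any(lesion_center + r_vox > grid_shape))
    stop("lesion extends outside the grid; shrink the radii or move the centre")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 lesion_kind = lesion_kind,
                 lesion_center = as.numeric(lesion_center),
                 lesion_radii_mm = as.numeric(lesion_radii_mm),
                 uptake_curve = as.numeric(uptake_curve),
                 bpe_level = bpe_level, noise_sd = noise_sd,
                 heterogeneity = heterogeneity, lobulation = lobulation,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

bpe_amplitude <- function(level) switch(level, mild = 0.15, marked = 0.45)

# smooth random field in [0, 1]: uniform noise box-blurred along each axis
smooth_field <- function(d, passes = 3L) {
  f <- array(stats::runif(prod(d)), d)
  blur1 <- function(a, axis) {
    idx <- seq_len(dim(a)[axis])
    lo <- pmax(idx - 1L, 1L)
    hi <- pmin(idx + 1L, dim(a)[axis])
    pick <- function(i) switch(axis,
                               a[i, , , drop = FALSE],
                               a[, i, , drop = FALSE],
                               a[, , i, drop = FALSE])
    (pick(lo) + pick(idx) + pick(hi)) / 3
  }
  for (p in seq_len(passes)) for (ax in 1:3) f <- blur1(f, ax)
  rng <- range(f)
  if (rng[2] > rng[1]) (f - rng[1]) / (rng[2] - rng[1]) else f * 0
}

lesion_indicator <- function(spec) {
  d <- spec$grid_shape
  ax <- lapply(1:3, function(i) seq_len(d[i]))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  cen <- spec$lesion_center
  sp <- spec$spacing_mm
  if (spec$lesion_kind == "mass") {
    rr <- spec$lesion_radii_mm
    ux <- (g$x - cen[1]) * sp[1] / rr[1]
    uy <- (g$y - cen[2]) * sp[2] / rr[2]
    uz <- (g$z - cen[3]) * sp[3] / rr[3]
    rho <- sqrt(ux^2 + uy^2 + uz^2)
    if (spec$lobulation > 0) {
      # smooth zero-mean angular modulation: lobulated rather than round
      ph <- stats::runif(3, 0, 2 * pi)
      az <- atan2(uy, ux)
      el <- asin(ifelse(rho > 0, pmin(pmax(uz / rho, -1), 1), 0))
      h <- 0.6 * sin(2 * az + ph[1]) * cos(el) +
        0.4 * sin(3 * az + ph[2]) * cos(el) +
        0.3 * sin(2 * el + ph[3])
      ind <- rho <= 1 + spec$lobulation * h
    } else {
      ind <- rho <= 1
    }
  } else {
    n_blob <- sample(6:12, 1L)
    t <- seq(-1, 1, length.out = n_blob)
    dir1 <- stats::rnorm(3)
    dir1 <- dir1 / sqrt(sum(dir1^2))
    dir2 <- stats::rnorm(3)
    dir2 <- dir2 - sum(dir2 * dir1) * dir1
    dir2 <- dir2 / sqrt(sum(dir2^2))
    reach <- 0.7 * spec$lesion_radii_mm
    ind <- rep(FALSE, nrow(g))
    for (i in seq_len(n_blob)) {
      centre_mm <- t[i] * reach * dir1 + 0.5 * (1 - t[i]^2) * reach * dir2
      centre <- cen + centre_mm / sp
      rad <- stats::runif(1, 2.5, 4)
      # keep each blob fully inside the grid
      centre <- pmin(pmax(centre, 1 + rad / sp), d - rad / sp)
      v <- ((g$x - centre[1]) * sp[1])^2 + ((g$y - centre[2]) * sp[2])^2 +
        ((g$z - centre[3]) * sp[3])^2
      ind <- ind | (v <= rad^2)
    }
  }
  array(ind, d)
}

#' Simulate one synthetic DCE case
#'
#' Builds the DCE series, the ground-truth lesion mask, and the three
#' rater-style inputs (careful contour, loose convex-hull ROI dilated by 3
#' voxels, and tumour + background strokes), all derived from the truth
#' mask on the slice with the largest lesion cross-section. The background
#' is iso-intense with the lesion pre-contrast and gains
#' `amplitude * field * w_t` post-contrast (`w = (0.6, 0.8, 1.0)`, field a
#' smooth random map), emulating mild or marked BPE. Lesion voxels follow
#' `uptake_curve` exactly when `heterogeneity = 0` and `noise_sd = 0`.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_case`: `series` ([dce_series()]),
#'   `truth_mask` (logical volume), `inputs` (list of three
#'   [seed_input()]s named `contour`, `roi`, `strokes`), and `spec`.
#' @export
simulate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$rng_seed)

  d <- spec$grid_shape
  # redraw (deterministically) until the largest lesion cross-section is big
  # enough to admit the contour/ROI seed extraction rules
  truth <- NULL
  for (try in 0:19) {
    if (try > 0) set.seed(spec$rng_seed + 100003L * try)
    cand_truth <- lesion_indicator(spec)
    if (!any(cand_truth)) next
    zmax <- which.max(apply(cand_truth, 3, sum))
    if (sum(morph_erode(cand_truth[, , zmax], 1L)) >= 9L) {
      truth <- cand_truth
      break
    }
  }
  if (is.null(truth))
    stop("lesion indicator is empty or too small; enlarge the radii")

  base <- spec$uptake_curve[1]
  amp <- bpe_amplitude(spec$bpe_level)
  field <- smooth_field(d)
  wt <- c(0.6, 0.8, 1.0)
  tex <- if (spec$heterogeneity > 0) 2 * smooth_field(d) - 1 else array(0, d)

  vols <- vector("list", 4L)
  for (t in 0:3) {
    bgv <- if (t == 0) array(base, d) else base * (1 + amp * field * wt[t])
    lesion_val <- spec$uptake_curve[t + 1] * (1 + spec$heterogeneity * tex)
    v <- bgv
    v[truth] <- lesion_val[truth]
    if (spec$noise_sd > 0)
      v <- v + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
    vols[[t + 1L]] <- v
  }
  series <- dce_series(vols, spec$spacing_mm)

  z <- which.max(apply(truth, 3, sum))
  sl <- truth[, , z]

  roi_region <- morph_dilate(convex_fill(sl), 3L)
  er <- morph_erode(sl, 1L)
  if (!any(er)) er <- sl
  cen <- round(region_centroid(er))
  fg <- matrix(FALSE, d[1], d[2])
  rows <- which(er[, cen[2]])
  cols <- which(er[cen[1], ])
  if (length(rows)) fg[rows, cen[2]] <- TRUE
  if (length(cols)) fg[cen[1], cols] <- TRUE
  if (!any(fg)) fg[which(er, arr.ind = TRUE)[1, , drop = FALSE]] <- TRUE
  bg_ring <- morph_dilate(sl, 4L) & !morph_dilate(sl, 3L)

  inputs <- list(
    contour = seed_input("contour", z, sl),
    roi = seed_input("roi", z, roi_region),
    strokes = seed_input("strokes", z, fg, bg_ring)
  )
  for (inp in inputs)
    if (!any(inp$tumour_marks & sl))
      stop("internal error: input tumour marks miss the truth mask")

  structure(list(series = series, truth_mask = truth, inputs = inputs,
                 spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("Synthetic DCE case (", x$spec$lesion_kind, ", ", x$spec$bpe_level,
      " BPE): lesion ", sum(x$truth_mask), " voxels (",
      format(sum(x$truth_mask) * voxel_volume(x$spec$spacing_mm),
             digits = 4), " mm^3)\n", sep = "")
  invisible(x)
}

#' Simulate a cohort of phantom cases with synthetic subtype labels
#'
#' Draws `n_cases` phantoms whose subtype label controls the lesion
#' appearance: class `i` of `K` gets within-lesion heterogeneity
#' `0.05 + 0.25 * (i - 1) / (K - 1)` and a progressively stronger washout
#' tail, so classes are separable by construction. Class counts follow
#' `subtype_mix` under largest-remainder rounding; lesion size, centre,
#' BPE level and lesion kind vary across cases; per-case seeds derive
#' deterministically from `master_seed`.
#'
#' @param n_cases number of cases (>= 2).
#' @param subtype_mix named or unnamed proportions summing to 1; every
#'   class must receive at least one case.
#' @param master_seed integer master seed.
#' @param nonmass_frac fraction of cases drawn as non-mass lesions.
#' @param noise_sd per-case additive noise SD.
#' @return list of `phantom_case` objects, each with an extra `$subtype`
#'   label; the list carries attribute `subtypes`.
#' @export
simulate_cohort <- function(n_cases, subtype_mix = c(A = 0.5, B = 0.5),
                            master_seed = 1L, nonmass_frac = 0.2,
                            noise_sd = 5) {
  if (n_cases < 2L) stop("'n_cases' must be >= 2")
  p <- as.numeric(subtype_mix)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("'subtype_mix' must be non-negative proportions summing to 1")
  K <- length(p)
  labels <- names(subtype_mix)
  if (is.null(labels)) labels <- LETTERS[seq_len(K)]
  counts <- floor(n_cases * p)
  rem <- n_cases - sum(counts)
  if (rem > 0) {
    frac <- n_cases * p - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  if (any(counts == 0L))
    stop("degenerate proportions: a subtype would receive no cases")
  class_of <- rep(seq_len(K), counts)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)

  het <- if (K == 1L) 0.15 else 0.05 + 0.25 * (seq_len(K) - 1) / (K - 1)
  washout <- if (K == 1L) 0.9 else seq(0.95, 0.75, length.out = K)

  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    ci <- class_of[i]
    seed_i <- (master_seed + 7919L * i) %% .Machine$integer.max
    set.seed(seed_i)
    rad <- stats::runif(3, 4.5, 7)
    rad[3] <- min(rad[3], 4.8)
    jit <- stats::runif(3, -1.5, 1.5)
    kind <- if (stats::runif(1) < nonmass_frac) "non-mass" else "mass"
    bpe <- if (i %% 2L == 0L) "marked" else "mild"
    peak <- stats::runif(1, 280, 330)
    curve <- c(100, peak, peak * (washout[ci] + 0.05),
               peak * washout[ci])
    spec <- phantom_spec(lesion_kind = kind,
                         lesion_center = c(16.5, 16.5, 8.5) + jit,
                         lesion_radii_mm = rad,
                         uptake_curve = curve,
                         bpe_level = bpe,
                         noise_sd = noise_sd,
                         heterogeneity = het[ci],
                         rng_seed = seed_i)
    case <- simulate_case(spec)
    case$subtype <- labels[ci]
    cases[[i]] <- case
  }
  attr(cases, "subtypes") <- labels[class_of]
  cases
}
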