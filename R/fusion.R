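#' Precision-weighted F-measure weight for the GMM term
#'
#' The fusion weight `gamma` is the F-measure with `beta = 0.5` (precision
#' weighted over recall, reflecting the large imbalance between tumour and
#' normal voxels) of the binary volume `G` scored against `reference`:
#' `gamma = (1 + beta^2) P R / (beta^2 P + R)`, 0 when precision and recall
#' are both 0.
#'
#' @param G logical volume being scored (the GMM labeling).
#' @param reference nonempty logical reference volume.
#' @param beta F-measure weight.
#' @return `gamma` in \[0, 1\].
#' @export
compute_gamma <- function(G, reference, beta = 0.5) {
  if (!any(reference)) stop("empty reference volume")
  if (!identical(dim(G), dim(reference))) stop("volume shapes differ")
  tp <- sum(G & reference)
  P <- if (sum(G) > 0) tp / sum(G) else 0
  R <- tp / sum(reference)
  if (P == 0 && R == 0) return(0)
  den <- beta^2 * P + R
  if (den == 0) return(0)
  (1 + beta^2) * P * R / den
}

#' Fuse per-feature GrowCut masks with the GMM labeling
#'
#' Per-voxel confidence `L(x) = (1/N) sum_i S_i(x) (1 - gamma) + G(x) gamma`
#' over the `N` GrowCut masks `S_i` and the GMM label volume `G`; the final
#' mask is `L > omega`.
#'
#' @param S_list list of logical GrowCut masks (one per feature image).
#' @param G logical GMM label volume.
#' @param gamma GMM weight in \[0, 1\].
#' @param omega confidence threshold in (0, 1\].
#' @return object of class `confidence_map`: `L` (numeric volume in
#'   \[0, 1\]), `gamma_used`, `omega`, and `mask` (`L > omega`).
#' @export
fuse <- function(S_list, G, gamma, omega = 0.6) {
  if (length(S_list) < 1L) stop("need at least one GrowCut mask")
  d <- dim(G)
  for (S in S_list)
    if (!identical(dim(S), d)) stop("mask shapes differ")
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("'gamma' must lie in [0, 1]")
  if (omega <= 0 || omega > 1) stop("'omega' must lie in (0, 1]")
  N <- length(S_list)
  Ssum <- Reduce(`+`, lapply(S_list, function(m) m * 1))
  L <- (Ssum / N) * (1 - gamma) + (G * 1) * gamma
  structure(list(L = L, gamma_used = gamma, omega = omega, mask = L > omega),
            class = "confidence_map")
}

#' @export
print.confidence_map <- function(x, ...) {
  cat(sprintf("Confidence map: gamma = %.3f, omega = %.2f, %d voxels above threshold\n",
              x$gamma_used, x$omega, sum(x$mask)))
  invisible(x)
}

# keep only mask components (26-connectivity) that touch foreground seeds
keep_seeded_components <- function(mask, seeds) {
  start <- array(seeds == 1L, dim = dim(mask))
  out <- flood_reach(as.logical(mask), as.logical(start),
                     as.integer(dim(mask)))
  array(out, dim = dim(mask))
}

#' Appearance-constrained GrowCut segmentation (GCGMM)
#'
#' The main fitting function. From a DCE series and a single user input it
#' (i) builds the eight feature images, (ii) extracts foreground/background
#' seed strokes, (iii) runs GrowCut once per feature image, (iv) fits one
#' tumour and one background Gaussian mixture (AIC-selected size) on the
#' 8-feature vectors at the seed voxels and labels every voxel, (v) sets
#' the fusion weight `gamma` to the F(beta = 0.5) measure of the GMM volume
#' against the GrowCut consensus (mean of the 8 masks >= 0.5) unless
#' overridden, and (vi) fuses everything into a confidence map thresholded
#' at `omega`. Components of the thresholded mask not connected to the
#' foreground seeds are discarded.
#'
#' @param series a [dce_series()].
#' @param input a [seed_input()].
#' @param omega confidence threshold (default 0.6).
#' @param tau GMM tumour-probability threshold (default 0.75).
#' @param beta F-measure weight for `gamma` (default 0.5).
#' @param gamma optional manual override of the fusion weight.
#' @param max_iters GrowCut iteration cap (default: sum of grid dims).
#' @param seed integer seed for the GMM initializations.
#' @return an object of class `gcgmm` with, among others, elements `mask`
#'   (the final logical volume), `confidence` (the [fuse()] result),
#'   `gc_masks`, `gc_consensus`, `gmm` (models and labeling), `seeds`,
#'   `gamma_used` and `spacing_mm`. See [predict.gcgmm()] to re-threshold.
#' @seealso [fcm_segment()] for the fuzzy c-means baseline.
#' @export
gcgmm <- function(series, input, omega = 0.6, tau = 0.75, beta = 0.5,
                  gamma = NULL, max_iters = NULL, seed = 1L) {
  stopifnot(inherits(series, "dce_series"), inherits(input, "seed_input"))
  cl <- match.call()
  stack <- with_stage("features", build_feature_stack(series))
  seeds <- with_stage("seeds", extract_seeds(input, dim(series)))

  gc_masks <- with_stage("growcut", lapply(stack$images, function(img)
    growcut_segment(img, seeds, max_iters = max_iters)))
  N <- length(gc_masks)
  gc_mean <- Reduce(`+`, lapply(gc_masks, function(m) m * 1)) / N
  gc_consensus <- gc_mean >= 0.5

  X <- stack_matrix(stack)
  fg <- which(seeds == 1L)
  bg <- which(seeds == 2L)
  gmm_fit <- with_stage("gmm", {
    model_T <- fit_gmm(X[fg, , drop = FALSE], seed = seed)
    model_B <- fit_gmm(X[bg, , drop = FALSE], seed = seed + 1L)
    labeling <- gmm_label(stack, model_T, model_B, tau = tau)
    list(model_T = model_T, model_B = model_B, labeling = labeling)
  })

  gamma_used <- if (is.null(gamma)) {
    if (any(gc_consensus))
      compute_gamma(gmm_fit$labeling$G, gc_consensus, beta = beta)
    else 0
  } else gamma
  conf <- with_stage("fusion",
                     fuse(gc_masks, gmm_fit$labeling$G, gamma_used, omega))
  mask <- keep_seeded_components(conf$mask, seeds)

  structure(list(mask = mask, confidence = conf, gc_masks = gc_masks,
                 gc_consensus = gc_consensus, gmm = gmm_fit, seeds = seeds,
                 gamma_used = gamma_used, omega = omega, tau = tau,
                 beta = beta, spacing_mm = series$spacing_mm,
                 input_kind = input$kind, call = cl),
            class = "gcgmm")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' @export
print.gcgmm <- function(x, ...) {
  cat("GCGMM segmentation\n")
  cat(sprintf("  input: %s; gamma = %.3f, omega = %.2f, tau = %.2f\n",
              x$input_kind, x$gamma_used, x$omega, x$tau))
  cat(sprintf("  mask: %d voxels (%.1f mm^3)\n", sum(x$mask),
              sum(x$mask) * voxel_volume(x$spacing_mm)))
  invisible(x)
}

#' @export
summary.gcgmm <- function(object, ...) {
  vv <- voxel_volume(object$spacing_mm)
  out <- list(
    gamma_used = object$gamma_used, omega = object$omega, tau = object$tau,
    volume_mm3 = sum(object$mask) * vv,
    gc_consensus_mm3 = sum(object$gc_consensus) * vv,
    gmm_mm3 = sum(object$gmm$labeling$G) * vv,
    n_components = c(tumour = object$gmm$model_T$n_components,
                     background = object$gmm$model_B$n_components),
    gc_iterations = vapply(object$gc_masks,
                           function(m) attr(m, "iterations"), numeric(1)))
  class(out) <- "summary.gcgmm"
  out
}

#' @export
print.summary.gcgmm <- function(x, ...) {
  cat("GCGMM segmentation summary\n")
  cat(sprintf("  gamma = %.3f (omega = %.2f, tau = %.2f)\n",
              x$gamma_used, x$omega, x$tau))
  cat(sprintf("  volumes (mm^3): fused %.1f, GC consensus %.1f, GMM %.1f\n",
              x$volume_mm3, x$gc_consensus_mm3, x$gmm_mm3))
  cat(sprintf("  mixture sizes: tumour %d, background %d\n",
              x$n_components["tumour"], x$n_components["background"]))
  cat("  GrowCut sweeps per feature image: ",
      paste(x$gc_iterations, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Re-threshold a fitted GCGMM confidence map
#'
#' Recomputes the final mask `L > omega` from the stored confidence map
#' (the dynamic-threshold operation of the interactive workflow), keeping
#' only components connected to the foreground seeds.
#'
#' @param object a fitted [gcgmm()] object.
#' @param omega confidence threshold; defaults to the fitted one.
#' @param ... unused.
#' @return logical 3D mask.
#' @export
predict.gcgmm <- function(object, omega = object$omega, ...) {
  if (omega <= 0 || omega > 1) stop("'omega' must lie in (0, 1]")
  keep_seeded_components(object$confidence$L > omega, object$seeds)
}

#' Plot a GCGMM confidence map slice
#'
#' Displays the confidence map on one axial slice with the final mask
#' outlined.
#'
#' @param x a fitted [gcgmm()] object.
#' @param slice axial slice; defaults to the input slice.
#' @param ... passed to [graphics::image()].
#' @export
plot.gcgmm <- function(x, slice = NULL, ...) {
  if (is.null(slice)) {
    per_slice <- apply(x$mask, 3, sum)
    slice <- if (any(per_slice > 0)) which.max(per_slice) else 1L
  }
  L <- x$confidence$L[, , slice]
  graphics::image(seq_len(nrow(L)), seq_len(ncol(L)), L,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (voxel)", ylab = "y (voxel)",
                  main = sprintf("GCGMM confidence, slice %d", slice), ...)
  m <- x$mask[, , slice]
  if (any(m))
    graphics::contour(seq_len(nrow(m)), seq_len(ncol(m)), m * 1,
                      levels = 0.5, add = TRUE, drawlabels = FALSE,
                      col = "white", lwd = 2)
  invisible(x)
}

#' Fuzzy c-means baseline segmentation
#'
#' Fuzzy c-means clustering (c = 2, fuzziness m = 2) of the 8-feature
#' vectors inside a rectangular region of interest. The tumour cluster is
#' the one whose centre has the highest first-post-contrast intensity; the
#' mask keeps ROI voxels with tumour membership above 0.5. Initial centres
#' are the feature rows of the ROI voxels with the lowest and highest
#' `post1` value, making the fit deterministic.
#'
#' @param stack a [build_feature_stack()] result.
#' @param roi 3x2 integer matrix of inclusive index ranges (rows = axes),
#'   e.g. from [fcm_roi()].
#' @param c number of clusters.
#' @param m fuzziness exponent.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @return logical 3D mask (FALSE outside the ROI) with attribute
#'   `membership_range`.
#' @export
fcm_segment <- function(stack, roi, c = 2L, m = 2, tol = 1e-5,
                        max_iter = 200L) {
  stopifnot(inherits(stack, "feature_stack"))
  d <- dim(stack$images[[1]])
  roi <- matrix(as.integer(roi), 3L, 2L)
  if (any(roi[, 1] < 1L) || any(roi[, 2] > d) || any(roi[, 1] > roi[, 2]))
    stop("ROI outside the volume")
  sel <- array(FALSE, d)
  sel[roi[1, 1]:roi[1, 2], roi[2, 1]:roi[2, 2], roi[3, 1]:roi[3, 2]] <- TRUE
  idx <- which(sel)
  if (length(idx) < c) stop("ROI smaller than the number of clusters")
  X <- stack_matrix(stack)[idx, , drop = FALSE]
  post1 <- X[, "post1"]
  centers <- X[c(which.min(post1)[1], which.max(post1)[1]), , drop = FALSE]
  if (c > 2L) {
    qs <- stats::quantile(post1, probs = seq(0, 1, length.out = c))
    centers <- X[vapply(qs, function(q) which.min(abs(post1 - q)), 1L), ,
                 drop = FALSE]
  }
  if (nrow(unique(centers)) < c) {
    # degenerate (e.g. constant ROI): fall back to uniform memberships
    mem <- matrix(1 / c, length(idx), c)
    fit <- list(membership = mem, centers = centers)
  } else {
    fit <- e1071::cmeans(X, centers = centers, iter.max = max_iter, m = m,
                         control = list(reltol = tol))
  }
  tumour <- which.max(fit$centers[, "post1"])
  mask <- array(FALSE, d)
  mask[idx] <- fit$membership[, tumour] > 0.5
  attr(mask, "membership_range") <- range(fit$membership)
  mask
}

#' Rectangular ROI from background strokes
#'
#' The in-plane bounding box enclosing the background seed strokes,
#' extended across all slices; the input handed to the FCM baseline.
#'
#' @param seeds a `seed_labels` volume.
#' @return 3x2 integer matrix of inclusive index ranges.
#' @export
fcm_roi <- function(seeds) {
  idx <- which(seeds == 2L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no background strokes to enclose")
  d <- dim(seeds)
  rbind(range(idx[, 1]), range(idx[, 2]), c(1L, d[3]))
}
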