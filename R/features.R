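#' Temporal difference image
#'
#' Squared voxel-wise enhancement at a post-contrast timepoint:
#' `(I_t(x) - I_0(x))^2`, where `I_0` is the pre-contrast volume. The square
#' makes the image independent of the sign of the change and emphasises
#' strongly enhancing voxels.
#'
#' @param series a [dce_series()].
#' @param t post-contrast timepoint, one of 1, 2, 3.
#' @return a numeric 3D array, non-negative everywhere.
#' @export
temporal_difference <- function(series, t) {
  stopifnot(inherits(series, "dce_series"))
  if (!t %in% 1:3) stop("'t' must be 1, 2 or 3")
  (series$volumes[[t + 1L]] - series$volumes$pre)^2
}

#' Temporal tensor trace image
#'
#' At each voxel the four timepoint intensities `i_0..i_3` are assembled into
#' a 4x4 symmetric matrix with diagonal entries `i_t^2` and off-diagonal
#' `(a, b)` entries `(i_a - i_b)^2`. The matrix is eigendecomposed and the
#' sum of the three largest eigenvalues is returned, summarising the
#' magnitude and temporal variation of contrast uptake in a single scalar.
#' Entries of the matrix are non-negative but its eigenvalues need not be;
#' the three largest are taken literally (descending by value).
#'
#' @param series a [dce_series()].
#' @return a numeric 3D array, non-negative everywhere.
#' @export
tensor_trace <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  X <- do.call(cbind, lapply(series$volumes, as.vector))
  bad <- which(!is.finite(rowSums(X)))
  if (length(bad))
    stop(sprintf("non-finite intensity at voxel %d", bad[1]))
  out <- tensor_trace_core(X)
  dim(out) <- dim(series$volumes$pre)
  out
}

#' Build the eight feature images
#'
#' The segmentation operates on eight scalar volumes derived from the DCE
#' series: the four raw timepoints (passed through unchanged), the three
#' squared temporal difference images and the temporal tensor trace image,
#' in that fixed order.
#'
#' @param series a [dce_series()].
#' @return an object of class `feature_stack`: a named list `images` with
#'   elements `pre`, `post1`, `post2`, `post3`, `diff1`, `diff2`, `diff3`,
#'   `trace`, plus `spacing_mm`.
#' @export
build_feature_stack <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  images <- c(
    series$volumes,
    list(diff1 = temporal_difference(series, 1),
         diff2 = temporal_difference(series, 2),
         diff3 = temporal_difference(series, 3),
         trace = tensor_trace(series))
  )
  structure(list(images = images, spacing_mm = series$spacing_mm),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat("Feature stack: 8 images (", paste(names(x$images), collapse = ", "),
      "), grid ", paste(dim(x$images[[1]]), collapse = " x "), "\n", sep = "")
  invisible(x)
}
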