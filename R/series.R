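#' Dynamic contrast-enhanced series
#'
#' Container for an aligned DCE acquisition: one pre-contrast and three
#' post-contrast 3D volumes on a common grid, plus the voxel spacing in mm.
#' All downstream stages (feature images, GrowCut, GMM, radiomics) consume
#' this object.
#'
#' @param volumes list of exactly 4 numeric 3D arrays (pre, post1, post2,
#'   post3), all with identical dimensions and finite intensities.
#' @param spacing_mm positive numeric vector of length 3, voxel size in mm
#'   along each axis.
#' @return an object of class `dce_series` with elements `volumes` (named
#'   list `pre`, `post1`, `post2`, `post3`) and `spacing_mm`.
#' @export
dce_series <- function(volumes, spacing_mm = c(1, 1, 1)) {
  if (!is.list(volumes) || length(volumes) != 4L)
    stop("'volumes' must be a list of 4 arrays (pre + 3 post-contrast)")
  volumes <- lapply(volumes, function(v) {
    if (is.matrix(v)) dim(v) <- c(dim(v), 1L)
    v
  })
  d <- dim(volumes[[1]])
  if (length(d) != 3L) stop("volumes must be 3D arrays")
  for (i in seq_along(volumes)) {
    if (!identical(dim(volumes[[i]]), d))
      stop(sprintf("volume %d has mismatched dimensions", i))
    if (!all(is.finite(volumes[[i]])))
      stop(sprintf("volume %d contains non-finite intensities", i))
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive numbers")
  names(volumes) <- c("pre", "post1", "post2", "post3")
  structure(list(volumes = volumes, spacing_mm = spacing_mm),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$volumes$pre)
  cat("DCE series: 4 timepoints, grid ", paste(d, collapse = " x "),
      ", spacing ", paste(signif(x$spacing_mm, 3), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.dce_series <- function(x) dim(x$volumes$pre)

# voxel volume in mm^3
voxel_volume <- function(spacing_mm) prod(spacing_mm)

# stack voxels of a feature stack into an n_voxels x 8 matrix
stack_matrix <- function(stack) {
  do.call(cbind, lapply(stack$images, as.vector))
}
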