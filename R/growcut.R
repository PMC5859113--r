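#' GrowCut cellular-automaton segmentation
#'
#' Competitive region growing on one scalar volume from foreground and
#' background seed labels. Each labeled voxel carries a strength in (0, 1];
#' at every synchronous iteration a neighbour `q` captures voxel `p` iff
#' `g(|C_p - C_q|) * theta_q > theta_p`, with `g(d) = 1 - d / maxC` and
#' `maxC` the image intensity range (the image is normalized to \[0, 1\]
#' internally so `g(d) = 1 - d`). Ties keep the incumbent label; seed voxels
#' start at strength 1 and are never captured. The automaton uses
#' 26-connectivity and stops at a fixpoint or after `max_iters` sweeps.
#'
#' @param image numeric 3D array with finite values.
#' @param seeds integer 3D array with values 0 (unlabeled), 1 (foreground),
#'   2 (background), e.g. from [extract_seeds()].
#' @param max_iters maximum synchronous sweeps; default is the sum of the
#'   grid dimensions (enough for a label to cross the volume).
#' @param require_background error when no background seeds are present
#'   (without opposition every connected voxel eventually turns foreground);
#'   set `FALSE` to permit unopposed growth.
#' @return logical 3D array, the foreground mask, with attributes `labels`,
#'   `strengths`, `iterations` and `converged`. A `FALSE` `converged` flag
#'   (with a warning) means the automaton was stopped at `max_iters`.
#' @export
growcut_segment <- function(image, seeds, max_iters = NULL,
                            require_background = TRUE) {
  d <- dim(image)
  if (length(d) != 3L) stop("'image' must be a 3D array")
  if (!all(is.finite(image))) stop("'image' contains non-finite values")
  if (!identical(dim(seeds), d)) stop("seed grid does not match the image")
  if (is.null(max_iters)) max_iters <- sum(d)
  lab0 <- as.integer(seeds)
  if (!any(lab0 == 1L)) stop("no foreground seeds")
  if (require_background && !any(lab0 == 2L))
    stop("no background seeds: every voxel would become foreground")

  rng <- range(image)
  img <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
         else array(0, d)
  str0 <- as.numeric(lab0 != 0L)
  res <- growcut_core(as.numeric(img), lab0, str0, as.integer(d),
                      as.integer(max_iters))
  if (!res$converged)
    warning(sprintf("GrowCut stopped at max_iters = %d before convergence",
                    max_iters))
  mask <- array(res$labels == 1L, dim = d)
  attr(mask, "labels") <- array(res$labels, dim = d)
  attr(mask, "strengths") <- array(res$strengths, dim = d)
  attr(mask, "iterations") <- res$iterations
  attr(mask, "converged") <- res$converged
  mask
}
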