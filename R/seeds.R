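#' User input for a segmentation
#'
#' One of the three input styles a rater can provide on a single axial
#' slice: a carefully traced closed contour (`"contour"`, the enclosed
#' region), a rough polygonal/rectangular region of interest (`"roi"`), or
#' explicit tumour plus background strokes (`"strokes"`).
#'
#' @param kind one of `"contour"`, `"roi"`, `"strokes"`.
#' @param slice_index axial (third-axis) slice the input was drawn on.
#' @param tumour_marks logical matrix (in-plane grid): the enclosed region
#'   for contour/roi inputs, or the tumour stroke voxels for strokes.
#' @param background_marks logical matrix of background stroke voxels;
#'   required for (and only for) `kind = "strokes"`.
#' @return an object of class `seed_input`.
#' @export
seed_input <- function(kind, slice_index, tumour_marks,
                       background_marks = NULL) {
  kind <- match.arg(kind, c("contour", "roi", "strokes"))
  tumour_marks <- tumour_marks != 0
  if (!any(tumour_marks)) stop("tumour marks are empty")
  if (kind == "strokes") {
    if (is.null(background_marks))
      stop("strokes input requires background marks")
    background_marks <- background_marks != 0
    if (!identical(dim(background_marks), dim(tumour_marks)))
      stop("tumour and background marks must share the slice grid")
    if (any(tumour_marks & background_marks))
      stop("tumour and background strokes overlap")
  } else if (!is.null(background_marks)) {
    stop("background marks are only valid for kind = 'strokes'")
  }
  structure(list(kind = kind, slice_index = as.integer(slice_index),
                 tumour_marks = tumour_marks,
                 background_marks = background_marks),
            class = "seed_input")
}

#' @export
print.seed_input <- function(x, ...) {
  cat("Seed input (", x$kind, ") on slice ", x$slice_index, ": ",
      sum(x$tumour_marks), " tumour-side voxels",
      if (!is.null(x$background_marks))
        paste0(", ", sum(x$background_marks), " background voxels"),
      "\n", sep = "")
  invisible(x)
}

#' Extract foreground/background seed strokes from a user input
#'
#' Converts a contour or ROI input into GrowCut-style stroke labels. The
#' enclosed region is first eroded once so the foreground stays inside the
#' tumour. With `r` = round(half the area-equivalent contour diameter,
#' `2*sqrt(area/pi)`), the foreground is the morphological (Lantuejoul)
#' skeleton of the eroded region over `r - 1` erosion levels (contour
#' input), or two
#' perpendicular line strokes through the eroded region's centroid, each
#' extending to the region's minor-axis length (ROI input). Background
#' strokes are the ring `dilate(region, d1) \ dilate(region, d2)` with
#' `d1 = r` and `d2 = max(2, r - 2)` dilation iterations of the original
#' region. Stroke inputs pass through unchanged. All morphology is 2D on
#' the input slice; GrowCut later propagates the labels in 3D.
#'
#' @param input a [seed_input()].
#' @param grid_shape integer vector of length 3, the volume grid the labels
#'   live on.
#' @return an object of class `seed_labels`: integer 3D array with values 0
#'   (unlabeled), 1 (foreground), 2 (background), with attributes
#'   `provenance` and `r`.
#' @export
extract_seeds <- function(input, grid_shape) {
  stopifnot(inherits(input, "seed_input"))
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L) stop("'grid_shape' must have length 3")
  if (!identical(dim(input$tumour_marks), grid_shape[1:2]))
    stop("input slice grid does not match 'grid_shape'")
  if (input$slice_index < 1L || input$slice_index > grid_shape[3])
    stop("slice index outside the volume")

  labels <- array(0L, dim = grid_shape)
  z <- input$slice_index

  if (input$kind == "strokes") {
    sl <- matrix(0L, grid_shape[1], grid_shape[2])
    sl[input$tumour_marks] <- 1L
    sl[input$background_marks] <- 2L
    labels[, , z] <- sl
    attr(labels, "provenance") <- c(foreground = "user strokes",
                                    background = "user strokes")
    attr(labels, "r") <- NA_integer_
    class(labels) <- c("seed_labels", class(labels))
    return(labels)
  }

  region <- input$tumour_marks
  eroded <- morph_erode(region, 1L)
  idx <- which(eroded, arr.ind = TRUE)
  if (nrow(idx) < 9L ||
      diff(range(idx[, 1])) < 2L || diff(range(idx[, 2])) < 2L)
    stop("input too small: region under 3x3 voxels after erosion")

  area <- sum(region)
  r <- max(1L, as.integer(round(sqrt(area / pi))))
  if (r < 2L)
    warning("equivalent radius below 2; background ring clamped to d2 = 2")
  d1 <- r
  d2 <- max(2L, r - 2L)

  if (input$kind == "contour") {
    fg <- morph_skeleton(eroded, r - 1L)
    prov_fg <- sprintf("morphological skeleton of eroded contour region (%d erosion levels)",
                       r - 1L)
  } else {
    cen <- round(region_centroid(eroded))
    len <- region_minor_axis(eroded)
    half <- max(1L, as.integer(round(len / 2)))
    fg <- matrix(FALSE, nrow(region), ncol(region))
    rows <- pmax(1L, cen[1] - half):pmin(nrow(region), cen[1] + half)
    cols <- pmax(1L, cen[2] - half):pmin(ncol(region), cen[2] + half)
    fg[rows, cen[2]] <- TRUE
    fg[cen[1], cols] <- TRUE
    fg <- fg & eroded
    if (!any(fg)) fg[cen[1], cen[2]] <- eroded[cen[1], cen[2]]
    prov_fg <- "perpendicular centroid lines clipped to eroded ROI"
  }
  if (!any(fg)) stop("foreground stroke extraction produced no voxels")

  bg <- morph_dilate(region, d1) & !morph_dilate(region, d2)
  if (!any(bg)) stop("background ring extraction produced no voxels")

  sl <- matrix(0L, grid_shape[1], grid_shape[2])
  sl[fg] <- 1L
  sl[bg] <- 2L
  labels[, , z] <- sl
  attr(labels, "provenance") <- c(
    foreground = prov_fg,
    background = sprintf("dilate(region, %d) minus dilate(region, %d)", d1, d2))
  attr(labels, "r") <- r
  class(labels) <- c("seed_labels", class(labels))
  labels
}
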