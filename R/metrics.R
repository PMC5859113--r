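#' Segmentation accuracy scores
#'
#' Compares an algorithm mask `A` with a reference mask `G`:
#' * Dice coefficient `DSC = 2|A n G| / (|A| + |G|)`;
#' * signed and absolute volume-difference ratio
#'   `VR = (v(A) - v(G)) / (0.5 (v(A) + v(G)))`;
#' * directed mean surface distance `mSD = mean_x min_y d(x, y)` and the
#'   95th-percentile Hausdorff distance `HD95 = 95%(min_y d(x, y))`, taken
#'   from `A`'s surface to `G`'s surface, in mm.
#'
#' A surface voxel is a mask voxel with at least one face-adjacent outside
#' voxel (the volume border counts as outside); distances are between voxel
#' centres. An empty `A` yields DSC 0 and missing distances with a flag.
#'
#' @param A logical algorithm mask.
#' @param G logical nonempty reference mask, same shape.
#' @param spacing_mm voxel size in mm per axis.
#' @param symmetric also average the distances taken in the reverse
#'   direction (practical variant; the default is the directed definition).
#' @return object of class `seg_scores`: `dsc`, `msd_mm`, `hd95_mm`,
#'   `vr_signed`, `vr_abs`, `flags`.
#' @export
seg_scores <- function(A, G, spacing_mm = c(1, 1, 1), symmetric = FALSE) {
  if (!identical(dim(A), dim(G))) stop("mask shapes differ")
  A <- A != 0
  G <- G != 0
  if (!any(G)) stop("reference mask is empty")
  flags <- character(0)
  nA <- sum(A)
  nG <- sum(G)
  dsc <- 2 * sum(A & G) / (nA + nG)
  vv <- voxel_volume(spacing_mm)
  vA <- nA * vv
  vG <- nG * vv
  vr_signed <- (vA - vG) / (0.5 * (vA + vG))
  if (nA == 0L) {
    flags <- c(flags, "empty algorithm mask: distances undefined")
    out <- list(dsc = 0, msd_mm = NA_real_, hd95_mm = NA_real_,
                vr_signed = vr_signed, vr_abs = abs(vr_signed),
                flags = flags)
    class(out) <- "seg_scores"
    return(out)
  }
  sA <- surface_coords(A, spacing_mm)
  sG <- surface_coords(G, spacing_mm)
  dAG <- nn_dist(sA, sG)
  if (symmetric) {
    dGA <- nn_dist(sG, sA)
    msd <- mean(c(dAG, dGA))
    hd95 <- stats::quantile(c(dAG, dGA), 0.95, names = FALSE)
  } else {
    msd <- mean(dAG)
    hd95 <- stats::quantile(dAG, 0.95, names = FALSE)
  }
  out <- list(dsc = dsc, msd_mm = msd, hd95_mm = hd95,
              vr_signed = vr_signed, vr_abs = abs(vr_signed), flags = flags)
  class(out) <- "seg_scores"
  out
}

#' @export
print.seg_scores <- function(x, ...) {
  cat(sprintf("DSC %.3f | mSD %.2f mm | HD95 %.2f mm | |VR| %.3f\n",
              x$dsc, x$msd_mm, x$hd95_mm, x$vr_abs))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# surface voxel centres (mm): mask voxels with a face-adjacent background
# voxel; out-of-volume counts as background
surface_coords <- function(mask, spacing_mm) {
  d <- dim(mask)
  inside <- array(TRUE, d)
  for (ax in 1:3) {
    shift_ok <- function(off) {
      idx <- lapply(d, seq_len)
      src <- idx
      src[[ax]] <- idx[[ax]] + off
      valid <- src[[ax]] >= 1L & src[[ax]] <= d[ax]
      out <- array(FALSE, d)
      dst <- idx
      dst[[ax]] <- idx[[ax]][valid]
      src[[ax]] <- src[[ax]][valid]
      out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
      out
    }
    inside <- inside & shift_ok(1L) & shift_ok(-1L)
  }
  surf <- mask & !inside
  idx <- which(surf, arr.ind = TRUE)
  sweep(idx, 2, spacing_mm, `*`)
}

# for each row of a, distance to nearest row of b (small point sets)
nn_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Reproducibility report: RMS coefficient of variation and RMS SD
#'
#' Precision-error summary over repeated segmentation trials. For each
#' patient `p` and metric, `%CV_p = 100 * SD_p / mean_p` across that
#' patient's trials; then `%CV_RMS = sqrt(mean_p(%CV_p^2))` and
#' `SD_RMS = sqrt(mean_p(SD_p^2))`. Identical trials give exact zeros; a
#' patient with zero mean but nonzero SD has an undefined %CV and is
#' excluded from `%CV_RMS` with a warning.
#'
#' @param values data frame with columns `case`, `trial`, and one or more
#'   numeric metric columns (every case needs >= 2 trials).
#' @return object of class `repro_report`: data frame `summary` (metric,
#'   sd_rms, pct_cv_rms, n_cases) and `per_case` (case, metric, sd, mean,
#'   pct_cv).
#' @export
repro_report <- function(values) {
  values <- as.data.frame(values)
  if (!all(c("case", "trial") %in% names(values)))
    stop("'values' needs 'case' and 'trial' columns")
  metrics <- setdiff(names(values), c("case", "trial"))
  if (length(metrics) == 0L) stop("no metric columns found")
  counts <- table(values$case)
  if (any(counts < 2L)) stop("every case needs at least 2 trials")

  per_case <- do.call(rbind, lapply(metrics, function(m) {
    sd_p <- tapply(values[[m]], values$case, stats::sd)
    mean_p <- tapply(values[[m]], values$case, mean)
    cv <- ifelse(sd_p == 0, 0, 100 * sd_p / mean_p)
    data.frame(case = names(sd_p), metric = m, sd = as.numeric(sd_p),
               mean = as.numeric(mean_p), pct_cv = as.numeric(cv),
               row.names = NULL)
  }))
  undef <- per_case$mean == 0 & per_case$sd > 0
  if (any(undef)) {
    warning(sprintf("%d case/metric pairs with zero mean excluded from %%CV_RMS",
                    sum(undef)))
    per_case$pct_cv[undef] <- NA_real_
  }
  summary <- do.call(rbind, lapply(metrics, function(m) {
    pc <- per_case[per_case$metric == m, ]
    data.frame(metric = m,
               sd_rms = sqrt(mean(pc$sd^2)),
               pct_cv_rms = sqrt(mean(pc$pct_cv^2, na.rm = TRUE)),
               n_cases = sum(!is.na(pc$pct_cv)),
               row.names = NULL)
  }))
  structure(list(summary = summary, per_case = per_case),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat("Reproducibility (RMS over cases):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# ICC(2,1): two-way random effects, absolute agreement, single measurement
icc21 <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2L || k < 2L) stop("need >= 2 cases and >= 2 trials")
  grand <- mean(mat)
  rowm <- rowMeans(mat)
  colm <- colMeans(mat)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((mat - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (den <= 0 || (msr <= mse && msc <= mse && mse == 0))
    return(structure(0, flag = "degenerate variance decomposition"))
  val <- (msr - mse) / den
  if (msr <= mse && abs(msr - mse) < 1e-12)
    attr(val, "flag") <- "no between-case variance"
  val
}

#' Intraclass correlation of features across segmentation trials
#'
#' Test-retest reliability of each feature across repeated segmentation
#' trials, as ICC(2,1) (two-way random effects, absolute agreement, single
#' measurement). Identical trials with between-case spread give ICC 1.
#'
#' @param feature_table data frame with columns `case`, `trial`, and one
#'   or more numeric feature columns; every case must have every trial.
#' @return object of class `icc_report`: named vector `icc` per feature and
#'   `summary` (median and IQR).
#' @export
icc_features <- function(feature_table) {
  ft <- as.data.frame(feature_table)
  if (!all(c("case", "trial") %in% names(ft)))
    stop("'feature_table' needs 'case' and 'trial' columns")
  feats <- setdiff(names(ft), c("case", "trial"))
  cases <- sort(unique(ft$case))
  trials <- sort(unique(ft$trial))
  icc <- vapply(feats, function(f) {
    mat <- matrix(NA_real_, length(cases), length(trials),
                  dimnames = list(cases, trials))
    mat[cbind(match(ft$case, cases), match(ft$trial, trials))] <- ft[[f]]
    if (anyNA(mat)) stop("unbalanced case x trial table for feature ", f)
    as.numeric(icc21(mat))
  }, numeric(1))
  qs <- stats::quantile(icc, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(icc = icc,
                 summary = c(median = qs[2], iqr_lo = qs[1], iqr_hi = qs[3])),
            class = "icc_report")
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf("ICC(2,1) over %d features: median %.3f (IQR %.3f-%.3f)\n",
              length(x$icc), x$summary["median"], x$summary["iqr_lo"],
              x$summary["iqr_hi"]))
  invisible(x)
}

#' Wilcoxon rank-sum tests with Bonferroni-Holm correction
#'
#' One two-sample rank-sum test per feature between two groups, with Holm
#' step-down adjustment across the tested set. Features constant across
#' both groups get p = 1 with a flag.
#'
#' @param x,y data frames or matrices of feature values (samples in rows)
#'   for the two groups, with matching columns.
#' @param features optional subset of column names to test.
#' @return data frame with columns `feature`, `p_raw`, `p_adjusted`,
#'   `flag`.
#' @export
wilcoxon_holm <- function(x, y, features = NULL) {
  x <- as.data.frame(x)
  y <- as.data.frame(y)
  if (nrow(x) == 0L || nrow(y) == 0L) stop("both groups must be nonempty")
  if (is.null(features)) features <- intersect(names(x), names(y))
  if (length(features) == 0L) stop("no common features to test")
  res <- lapply(features, function(f) {
    a <- x[[f]]
    b <- y[[f]]
    if (length(unique(c(a, b))) == 1L)
      return(data.frame(feature = f, p_raw = 1, flag = "constant data"))
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    data.frame(feature = f, p_raw = p, flag = "")
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "holm")
  res[, c("feature", "p_raw", "p_adjusted", "flag")]
}
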