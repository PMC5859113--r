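#' Read and write DCE volumes as NIfTI
#'
#' A series is stored either as one 4D NIfTI file or four 3D files
#' (pre, post1..post3); voxel spacing is taken from the header. Masks and
#' seed-label volumes are stored as integer NIfTI volumes.
#'
#' @param paths one 4D NIfTI path or a character vector of four 3D paths.
#' @return [read_dce_series()] returns a [dce_series()].
#' @export
read_dce_series <- function(paths) {
  if (length(paths) == 1L) {
    img <- RNifti::readNifti(paths)
    if (length(dim(img)) != 4L || dim(img)[4] != 4L)
      stop(sprintf("'%s' is not a 4-timepoint 4D volume", paths))
    sp <- RNifti::pixdim(img)[1:3]
    vols <- lapply(1:4, function(t) array(img[, , , t], dim(img)[1:3]))
    return(dce_series(vols, sp))
  }
  if (length(paths) != 4L) stop("need one 4D file or four 3D files")
  imgs <- lapply(paths, RNifti::readNifti)
  d <- dim(imgs[[1]])
  sp <- RNifti::pixdim(imgs[[1]])[1:3]
  for (i in 2:4) {
    if (!identical(dim(imgs[[i]]), d))
      stop(sprintf("geometry mismatch between '%s' and '%s'",
                   paths[1], paths[i]))
    if (max(abs(RNifti::pixdim(imgs[[i]])[1:3] - sp)) > 1e-6)
      stop(sprintf("voxel spacing mismatch between '%s' and '%s'",
                   paths[1], paths[i]))
  }
  dce_series(lapply(imgs, function(x) array(as.numeric(x), d)), sp)
}

#' @rdname read_dce_series
#' @param series a [dce_series()].
#' @param path output path (`.nii` or `.nii.gz`); the series is written as
#'   a single 4D file.
#' @export
write_dce_series <- function(series, path) {
  stopifnot(inherits(series, "dce_series"))
  d <- dim(series)
  arr <- array(0, c(d, 4L))
  for (t in 1:4) arr[, , , t] <- series$volumes[[t]]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$spacing_mm, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_dce_series
#' @param mask logical or integer 3D volume.
#' @param spacing_mm voxel spacing to record in the header.
#' @export
write_mask <- function(mask, path, spacing_mm = c(1, 1, 1)) {
  arr <- array(as.integer(mask), dim(mask))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname read_dce_series
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop(sprintf("'%s' is not a 3D volume", path))
  out <- array(as.integer(img), dim(img))
  attr(out, "spacing_mm") <- RNifti::pixdim(img)[1:3]
  out
}

#' Write a phantom case to disk
#'
#' Writes the 4D series, the truth mask, the three input label volumes
#' (tumour marks 1, background marks 2, on the input slice) and a JSON
#' sidecar with the generating spec.
#'
#' @param case a [simulate_case()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- case$spec$spacing_mm
  write_dce_series(case$series, file.path(dir, "series.nii.gz"))
  write_mask(case$truth_mask, file.path(dir, "truth.nii.gz"), sp)
  for (nm in names(case$inputs)) {
    inp <- case$inputs[[nm]]
    lab <- array(0L, dim(case$truth_mask))
    sl <- matrix(0L, nrow(inp$tumour_marks), ncol(inp$tumour_marks))
    sl[inp$tumour_marks] <- 1L
    if (!is.null(inp$background_marks)) sl[inp$background_marks] <- 2L
    lab[, , inp$slice_index] <- sl
    write_mask(lab, file.path(dir, paste0("input_", nm, ".nii.gz")), sp)
  }
  spec <- case$spec
  class(spec) <- NULL
  jsonlite::write_json(spec, file.path(dir, "spec.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Study configuration
#'
#' @param n_cases number of simulated cases.
#' @param subtype_mix subtype proportions, passed to [simulate_cohort()].
#' @param methods segmentation methods to run, subset of
#'   `c("gc", "fcm", "gcgmm")`.
#' @param trials input variants to use, subset of
#'   `c("contour", "roi", "strokes")`.
#' @param omega,tau,beta GCGMM fusion parameters.
#' @param noise_sd,nonmass_frac phantom generation parameters.
#' @param master_seed master seed; every random stage derives its own seed
#'   from it.
#' @param out_dir optional output directory for CSV/JSON reports.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_cases = 10L, subtype_mix = c(A = 0.5, B = 0.5),
                         methods = c("gc", "fcm", "gcgmm"),
                         trials = c("contour", "roi", "strokes"),
                         omega = 0.6, tau = 0.75, beta = 0.5,
                         noise_sd = 5, nonmass_frac = 0.2,
                         master_seed = 1L, out_dir = NULL) {
  methods <- match.arg(methods, c("gc", "fcm", "gcgmm"), several.ok = TRUE)
  trials <- match.arg(trials, c("contour", "roi", "strokes"),
                      several.ok = TRUE)
  if (length(methods) < 1L) stop("need at least one method")
  structure(list(n_cases = as.integer(n_cases), subtype_mix = subtype_mix,
                 methods = methods, trials = trials, omega = omega,
                 tau = tau, beta = beta, noise_sd = noise_sd,
                 nonmass_frac = nonmass_frac,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "study_config")
}

#' Run a full simulated segmentation study
#'
#' Drives the complete workflow on a synthetic cohort: for every case x
#' input trial the GCGMM fit is computed (its GrowCut consensus doubles as
#' the standalone GC method) along with the FCM baseline; each mask is
#' scored against the ground truth and its 36-feature radiomics vector is
#' extracted (the truth mask's vector once per case). The study then
#' aggregates reproducibility (per-metric %CV_RMS / SD_RMS and pairwise
#' inter-trial Dice), per-feature ICC across trials, and - when the cohort
#' has two subtype classes - a SMOTE-balanced LOOCV random-forest
#' classification per method using the stroke-trial features.
#'
#' @param config a [study_config()]; or pass its arguments via `...`.
#' @param cohort optionally, a pre-simulated cohort (list of
#'   `phantom_case`); otherwise one is simulated from the config.
#' @param ... used to build a config when `config` is missing.
#' @return object of class `gcgmm_study` with elements `scores`,
#'   `features`, `repro` (per method), `pairwise_dsc`, `icc` (per method),
#'   `classification` (per method, possibly empty), `failed_cases`,
#'   `config`.
#' @export
run_study <- function(config = NULL, cohort = NULL, ...) {
  if (is.null(config)) config <- study_config(...)
  stopifnot(inherits(config, "study_config"))
  if (is.null(cohort))
    cohort <- simulate_cohort(config$n_cases,
                              subtype_mix = config$subtype_mix,
                              master_seed = config$master_seed,
                              nonmass_frac = config$nonmass_frac,
                              noise_sd = config$noise_sd)
  n <- length(cohort)
  scores <- list()
  feats <- list()
  pw <- list()
  failed <- character(0)

  for (ci in seq_len(n)) {
    case <- cohort[[ci]]
    case_id <- sprintf("case%03d", ci)
    res <- tryCatch(
      run_case(case, case_id, config),
      error = function(e) {
        message(sprintf("%s failed: %s", case_id, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) {
      failed <- c(failed, case_id)
      next
    }
    scores[[ci]] <- res$scores
    feats[[ci]] <- res$features
    pw[[ci]] <- res$pairwise
  }
  if (length(failed) > n / 10)
    stop(sprintf("%d of %d cases failed", length(failed), n))

  scores <- do.call(rbind, scores)
  feats <- do.call(rbind, feats)
  pw <- do.call(rbind, pw)

  repro <- lapply(stats::setNames(config$methods, config$methods), function(m) {
    sub <- scores[scores$method == m,
                  c("case", "trial", "dsc", "msd_mm", "hd95_mm", "vr_abs",
                    "volume_mm3")]
    if (length(unique(sub$trial)) < 2L) return(NULL)
    repro_report(sub)
  })

  icc <- lapply(stats::setNames(config$methods, config$methods), function(m) {
    sub <- feats[feats$method == m, , drop = FALSE]
    if (length(unique(sub$trial)) < 2L) return(NULL)
    icc_features(sub[, !(names(sub) %in% c("method", "subtype"))])
  })

  classification <- list()
  subtypes <- vapply(cohort, function(x)
    if (is.null(x$subtype)) NA_character_ else x$subtype, character(1))
  if (length(unique(stats::na.omit(subtypes))) == 2L &&
      "strokes" %in% config$trials) {
    for (m in config$methods) {
      sub <- feats[feats$method == m & feats$trial == "strokes", ,
                   drop = FALSE]
      keep <- !is.na(sub$subtype)
      sub <- sub[keep, , drop = FALSE]
      if (min(table(sub$subtype)) >= 3L) {
        fx <- sub[, !(names(sub) %in% c("case", "trial", "method",
                                        "subtype"))]
        classification[[m]] <- loocv_rf(fx, sub$subtype,
                                        seed = config$master_seed)
      }
    }
  }

  out <- list(scores = scores, features = feats, pairwise_dsc = pw,
              repro = repro, icc = icc, classification = classification,
              failed_cases = failed, config = config)
  class(out) <- "gcgmm_study"
  if (!is.null(config$out_dir)) write_study(out, config$out_dir)
  out
}

run_case <- function(case, case_id, config) {
  series <- case$series
  sp <- series$spacing_mm
  vv <- voxel_volume(sp)
  stack <- build_feature_stack(series)
  truth <- case$truth_mask
  sc_rows <- list()
  ft_rows <- list()
  masks <- list()

  for (tr in config$trials) {
    input <- case$inputs[[tr]]
    need_gcgmm <- any(c("gc", "gcgmm") %in% config$methods)
    fit <- if (need_gcgmm)
      gcgmm(series, input, omega = config$omega, tau = config$tau,
            beta = config$beta, seed = config$master_seed)
    else NULL
    if ("gcgmm" %in% config$methods)
      masks[[paste("gcgmm", tr, sep = ".")]] <- fit$mask
    if ("gc" %in% config$methods)
      masks[[paste("gc", tr, sep = ".")]] <-
        keep_seeded_components(fit$gc_consensus, fit$seeds)
    if ("fcm" %in% config$methods) {
      seeds <- if (!is.null(fit)) fit$seeds
               else extract_seeds(input, dim(series))
      masks[[paste("fcm", tr, sep = ".")]] <-
        fcm_segment(stack, fcm_roi(seeds))
    }
  }

  for (nm in names(masks)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    m <- masks[[nm]]
    ss <- seg_scores(m, truth, sp)
    sc_rows[[nm]] <- data.frame(
      case = case_id, subtype = if (is.null(case$subtype)) NA else
        case$subtype,
      method = parts[1], trial = parts[2], dsc = ss$dsc,
      msd_mm = ss$msd_mm, hd95_mm = ss$hd95_mm, vr_abs = ss$vr_abs,
      volume_mm3 = sum(m) * vv)
    fv <- if (any(m)) extract_feature_vector(series, m) else
      stop(sprintf("empty %s mask", nm))
    ft_rows[[nm]] <- data.frame(case = case_id, method = parts[1],
                                trial = parts[2],
                                subtype = if (is.null(case$subtype)) NA
                                else case$subtype,
                                as.list(fv), check.names = FALSE)
  }
  fv_truth <- extract_feature_vector(series, truth)
  ft_rows[["truth"]] <- data.frame(case = case_id, method = "truth",
                                   trial = "none",
                                   subtype = if (is.null(case$subtype)) NA
                                   else case$subtype,
                                   as.list(fv_truth), check.names = FALSE)

  # inter-trial pairwise Dice per method (segmentation reproducibility)
  pairwise <- list()
  for (m in config$methods) {
    mm <- masks[grep(paste0("^", m, "\\."), names(masks))]
    if (length(mm) >= 2L) {
      pairs <- utils::combn(length(mm), 2)
      dscs <- apply(pairs, 2, function(pr) {
        a <- mm[[pr[1]]]
        b <- mm[[pr[2]]]
        s <- sum(a) + sum(b)
        if (s == 0) 1 else 2 * sum(a & b) / s
      })
      pairwise[[m]] <- data.frame(case = case_id, method = m,
                                  mean_pairwise_dsc = mean(dscs))
    }
  }

  list(scores = do.call(rbind, sc_rows),
       features = do.call(rbind, ft_rows),
       pairwise = do.call(rbind, pairwise))
}

write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(study$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(study$pairwise_dsc, file.path(dir, "pairwise_dsc.csv"),
                   row.names = FALSE)
  repro <- do.call(rbind, lapply(names(study$repro), function(m) {
    r <- study$repro[[m]]
    if (is.null(r)) return(NULL)
    cbind(method = m, r$summary)
  }))
  if (!is.null(repro))
    utils::write.csv(repro, file.path(dir, "repro.csv"), row.names = FALSE)
  icc <- do.call(rbind, lapply(names(study$icc), function(m) {
    r <- study$icc[[m]]
    if (is.null(r)) return(NULL)
    data.frame(method = m, feature = names(r$icc), icc = as.numeric(r$icc))
  }))
  if (!is.null(icc))
    utils::write.csv(icc, file.path(dir, "icc.csv"), row.names = FALSE)
  if (length(study$classification)) {
    cls <- lapply(study$classification, function(cv)
      list(auc = cv$auc, auc_ci = cv$auc_ci, tpr = cv$tpr, tnr = cv$tnr,
           fpr = cv$fpr, fnr = cv$fnr,
           top_features = rank_features(cv, 5L)))
    jsonlite::write_json(cls, file.path(dir, "classification.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @export
print.gcgmm_study <- function(x, ...) {
  cat("GCGMM study:", length(unique(x$scores$case)), "cases,",
      nrow(x$scores), "segmentations\n")
  agg <- stats::aggregate(dsc ~ method, data = x$scores, FUN = mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-6s mean DSC %.3f\n", agg$method[i], agg$dsc[i]))
  if (length(x$failed_cases))
    cat("  failed cases:", paste(x$failed_cases, collapse = ", "), "\n")
  invisible(x)
}
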