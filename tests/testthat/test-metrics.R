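cube_mask <- function(d, from, to) {
  m <- array(FALSE, d)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}

test_that("identical masks score perfectly", {
  d <- c(10, 10, 8)
  A <- cube_mask(d, c(3, 3, 3), c(7, 7, 6))
  s <- seg_scores(A, A)
  expect_equal(s$dsc, 1)
  expect_equal(s$msd_mm, 0)
  expect_equal(s$hd95_mm, 0)
  expect_equal(s$vr_signed, 0)
  expect_equal(s$vr_abs, 0)
})

test_that("the volume ratio follows the printed normalization", {
  # |A| = 150, |G| = 100 -> |VR| = 50 / 125 = 0.4
  d <- c(12, 12, 6)
  A <- cube_mask(d, c(1, 1, 1), c(10, 5, 3))    # 150 voxels
  G <- cube_mask(d, c(1, 1, 1), c(10, 5, 2))    # 100 voxels
  s <- seg_scores(A, G)
  expect_equal(s$vr_abs, 0.4, tolerance = 1e-12)
  expect_equal(s$vr_signed, 0.4, tolerance = 1e-12)
  # antisymmetric under swapping, Dice symmetric
  s2 <- seg_scores(G, A)
  expect_equal(s2$vr_signed, -0.4, tolerance = 1e-12)
  expect_equal(s$dsc, s2$dsc)
})

test_that("surface distances match the exhaustive point-pair oracle", {
  spacing <- c(1, 1, 2.5)
  cases <- list(
    list(A = cube_mask(c(12, 12, 8), c(3, 3, 3), c(6, 6, 5)),
         G = cube_mask(c(12, 12, 8), c(5, 5, 3), c(8, 8, 5))),
    list(A = cube_mask(c(10, 10, 10), c(2, 2, 2), c(8, 8, 8)),
         G = cube_mask(c(10, 10, 10), c(4, 4, 4), c(6, 6, 6)))
  )
  for (cs in cases) {
    s <- seg_scores(cs$A, cs$G, spacing)
    dd <- directed_distances_reference(cs$A, cs$G, spacing)
    expect_equal(s$msd_mm, mean(dd), tolerance = 1e-12)
    expect_equal(s$hd95_mm, stats::quantile(dd, 0.95, names = FALSE),
                 tolerance = 1e-12)
    nA <- sum(cs$A); nG <- sum(cs$G)
    expect_equal(s$dsc, 2 * sum(cs$A & cs$G) / (nA + nG), tolerance = 1e-12)
  }
})

test_that("an empty algorithm mask is flagged with DSC 0", {
  d <- c(8, 8, 4)
  G <- cube_mask(d, c(2, 2, 2), c(5, 5, 3))
  s <- seg_scores(array(FALSE, d), G)
  expect_equal(s$dsc, 0)
  expect_true(is.na(s$msd_mm))
  expect_match(s$flags, "empty")
  expect_error(seg_scores(G, array(FALSE, d)), "empty")
})

test_that("reproducibility follows the %CV and RMS arithmetic", {
  # one case, values {0.8, 1.0, 1.2}: SD = 0.2, mean = 1 -> %CV = 20
  v <- data.frame(case = "p1", trial = 1:3, m = c(0.8, 1.0, 1.2))
  r <- repro_report(v)
  expect_equal(r$summary$pct_cv_rms, 20, tolerance = 1e-10)
  expect_equal(r$summary$sd_rms, 0.2, tolerance = 1e-10)
  # two cases with %CV 10 and 30 -> RMS = sqrt((100 + 900)/2)
  v2 <- data.frame(case = rep(c("a", "b"), each = 2), trial = rep(1:2, 2),
                   m = c(10, 10 * (1 + 0.1 * sqrt(2)),
                         10, 10 * (1 + 0.3 * sqrt(2))))
  # constructed so SD/mean isn't exactly 10/30; compute directly instead
  sd_a <- sd(v2$m[1:2]); mn_a <- mean(v2$m[1:2])
  sd_b <- sd(v2$m[3:4]); mn_b <- mean(v2$m[3:4])
  cvs <- 100 * c(sd_a / mn_a, sd_b / mn_b)
  r2 <- repro_report(v2)
  expect_equal(r2$summary$pct_cv_rms, sqrt(mean(cvs^2)), tolerance = 1e-10)
  expect_equal(sqrt(mean((c(100, 900)))), 22.36, tolerance = 1e-2)
  # identical trials give exact zeros
  v3 <- data.frame(case = rep(c("a", "b"), each = 3), trial = rep(1:3, 2),
                   m = rep(c(2, 5), each = 3))
  r3 <- repro_report(v3)
  expect_equal(r3$summary$sd_rms, 0)
  expect_equal(r3$summary$pct_cv_rms, 0)
})

test_that("%CV_RMS is scale-invariant while SD_RMS scales linearly", {
  set.seed(30)
  v <- data.frame(case = rep(letters[1:4], each = 3), trial = rep(1:3, 4),
                  m = runif(12, 1, 5))
  r1 <- repro_report(v)
  v2 <- v; v2$m <- v$m * 3.7
  r2 <- repro_report(v2)
  expect_equal(r2$summary$pct_cv_rms, r1$summary$pct_cv_rms,
               tolerance = 1e-10)
  expect_equal(r2$summary$sd_rms, 3.7 * r1$summary$sd_rms, tolerance = 1e-10)
})

test_that("ICC(2,1) matches a from-scratch ANOVA mean-squares computation", {
  mat <- matrix(c(9, 2, 5, 8,
                  6, 1, 3, 2,
                  8, 4, 6, 9), nrow = 4)  # 4 cases x 3 trials
  ft <- data.frame(case = rep(1:4, 3), trial = rep(1:3, each = 4),
                   f = as.vector(mat))
  got <- icc_features(ft)$icc[["f"]]
  # oracle: mean squares from aov
  a <- summary(stats::aov(f ~ factor(case) + factor(trial), data = ft))[[1]]
  msr <- a["factor(case)", "Mean Sq"]
  msc <- a["factor(trial)", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  n <- 4; k <- 3
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(got, icc_oracle, tolerance = 1e-10)
})

test_that("ICC is 1 for identical trials and near 0 for pure noise", {
  base <- c(1, 4, 9, 2, 7)
  ft <- data.frame(case = rep(1:5, 3), trial = rep(1:3, each = 5),
                   f = rep(base, 3))
  expect_equal(icc_features(ft)$icc[["f"]], 1)
  set.seed(31)
  reps <- replicate(40, {
    ftn <- data.frame(case = rep(1:10, 3), trial = rep(1:3, each = 10),
                      f = rnorm(30))
    icc_features(ftn)$icc[["f"]]
  })
  expect_lt(abs(mean(reps)), 0.15)
})

test_that("Holm adjustment follows the step-down arithmetic", {
  # two features engineered to give small rank-sum p-values, then checked
  # against a literal Holm computation
  set.seed(32)
  x <- data.frame(f1 = rnorm(12, 0), f2 = rnorm(12, 0))
  y <- data.frame(f1 = rnorm(12, 3), f2 = rnorm(12, 1))
  res <- wilcoxon_holm(x, y)
  p <- res$p_raw
  o <- order(p)
  holm <- pmin(1, cummax(p[o] * (length(p) - seq_along(p) + 1)))
  expect_equal(res$p_adjusted[o], holm, tolerance = 1e-12)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  # printed example: raw (0.01, 0.04) -> adjusted (0.02, 0.04)
  expect_equal(pmin(1, cummax(c(0.01, 0.04) * c(2, 1))), c(0.02, 0.04))
  # identical constant groups
  cz <- data.frame(f1 = rep(1, 5))
  res2 <- wilcoxon_holm(cz, cz)
  expect_equal(res2$p_adjusted, 1)
  expect_match(res2$flag, "constant")
})
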