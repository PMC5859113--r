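ball_mask <- function(d, centre, radius) {
  m <- array(FALSE, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1]))
    if (sum((c(x, y, z) - centre)^2) <= radius^2) m[x, y, z] <- TRUE
  m
}

test_that("first-order moments match direct arithmetic", {
  d <- c(5, 1, 1)
  img <- array(c(1, 2, 3, 4, 10), d)
  mask <- array(TRUE, d)
  fo <- first_order(img, mask)
  v <- c(1, 2, 3, 4, 10)
  m2 <- mean((v - mean(v))^2)
  expect_equal(fo[["mean"]], 4)
  expect_equal(fo[["sd"]], sd(v))
  expect_equal(fo[["skewness"]], mean((v - mean(v))^3) / m2^1.5)
  expect_equal(fo[["kurtosis"]], mean((v - mean(v))^4) / m2^2 - 3)
})

test_that("degenerate and symmetric regions follow the stated conventions", {
  d <- c(4, 4, 2)
  img <- array(7, d)
  fo <- first_order(img, array(TRUE, d))
  expect_equal(unname(fo), c(7, 0, 0, 0), ignore_attr = TRUE)
  expect_match(attr(fo, "flag"), "constant")
  # symmetric values about the mean -> zero skewness
  img2 <- array(c(1, 2, 2, 3, 1, 2, 2, 3), c(8, 1, 1))
  fo2 <- first_order(img2, array(TRUE, c(8, 1, 1)))
  expect_equal(fo2[["skewness"]], 0)
  # single voxel
  one <- array(FALSE, d); one[1, 1, 1] <- TRUE
  fo3 <- first_order(img, one)
  expect_match(attr(fo3, "flag"), "single")
})

test_that("a constant region gives the single-cell GLCM limits", {
  d <- c(6, 6, 3)
  img <- array(0, d)
  img[2:5, 2:5, 1:2] <- 42
  mask <- img == 42
  gl <- glcm_features(img, mask)
  expect_equal(gl[["energy"]], 1)
  expect_equal(gl[["entropy"]], 0)
  expect_equal(gl[["contrast"]], 0)
  expect_equal(gl[["homogeneity"]], 1)
  expect_equal(gl[["correlation"]], 0)  # degenerate convention
  expect_match(attr(gl, "flag"), "zero-variance")
})

test_that("a striped region yields contrast k^2 under the along-stripe offset", {
  # stripes alternate between two intensities k bins apart along x
  n_bins <- 24L
  d <- c(12, 6, 1)
  img <- array(0, d)
  # values chosen so rescaled bins are exactly b and b + k
  img[] <- rep(c(0, 255), length.out = d[1])  # bins 1 and 24 -> k = 23
  for (x in seq_len(d[1])) img[x, , ] <- if (x %% 2 == 1) 0 else 255
  mask <- array(TRUE, d)
  gl <- glcm_features(img, mask, offsets = matrix(c(1L, 0L, 0L), 1))
  expect_equal(gl[["contrast"]], 23^2)
})

test_that("pooled-offset GLCM features equal the brute-force pair enumeration", {
  set.seed(40)
  d <- c(7, 6, 5)
  img <- array(runif(prod(d), 0, 100), d)
  mask <- ball_mask(d, c(4, 3, 3), 2.6)
  got <- glcm_features(img, mask)
  oracle <- glcm_reference(img, mask)
  expect_equal(unname(got[names(oracle)]), unname(oracle), tolerance = 1e-10)
  # normalization and range invariants
  p <- attr(got, "glcm")
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(got[["energy"]] > 0 && got[["energy"]] <= 1)
  expect_true(got[["entropy"]] >= 0)
  expect_true(got[["homogeneity"]] > 0 && got[["homogeneity"]] <= 1)
  expect_true(got[["contrast"]] >= 0)
  expect_true(abs(got[["correlation"]]) <= 1)
})

test_that("the radiomics vector has 36 named values in fixed order", {
  case <- simulate_case(phantom_spec(noise_sd = 2, heterogeneity = 0.1,
                                     rng_seed = 41L))
  fv <- extract_feature_vector(case$series, case$truth_mask)
  expect_length(fv, 36)
  expect_false(any(duplicated(names(fv))))
  expect_true(all(is.finite(fv)))
  seqs <- c("pre", "post1", "post2", "post3")
  stats9 <- c("mean", "sd", "kurtosis", "skewness", "energy", "entropy",
              "correlation", "homogeneity", "contrast")
  expect_identical(names(fv),
                   as.vector(t(outer(seqs, stats9, paste, sep = "_"))))
  expect_error(extract_feature_vector(case$series,
                                      array(FALSE, dim(case$series))),
               "empty")
})

test_that("shifting one sequence moves only its mean; GLCM features absorb the shift", {
  case <- simulate_case(phantom_spec(noise_sd = 2, heterogeneity = 0.1,
                                     rng_seed = 42L))
  fv <- extract_feature_vector(case$series, case$truth_mask)
  shifted <- case$series
  shifted$volumes$post2 <- shifted$volumes$post2 + 50
  fv2 <- extract_feature_vector(shifted, case$truth_mask)
  expect_equal(fv2[["post2_mean"]], fv[["post2_mean"]] + 50)
  same <- setdiff(names(fv), "post2_mean")
  expect_equal(fv2[same], fv[same], tolerance = 1e-10)
})
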