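test_that("gamma follows the F(0.5) arithmetic", {
  d <- c(6, 6, 4)
  ref <- array(FALSE, d); ref[2:5, 2:5, 2:3] <- TRUE
  expect_equal(compute_gamma(ref, ref), 1)
  disjoint <- array(FALSE, d); disjoint[1, 1, 1] <- TRUE
  expect_equal(compute_gamma(disjoint, ref), 0)
  # P = 0.5, R = 1.0 -> 1.25 * 0.5 / (0.25 * 0.5 + 1) = 0.5556
  G <- array(FALSE, d)
  G[ref] <- TRUE
  extra <- which(!ref)[seq_len(sum(ref))]
  G[extra] <- TRUE  # |G| = 2|ref|, all of ref covered
  expect_equal(compute_gamma(G, ref), 1.25 * 0.5 / (0.25 * 0.5 + 1),
               tolerance = 1e-12)
  expect_error(compute_gamma(G, array(FALSE, d)), "empty reference")
})

test_that("fusion reproduces the per-voxel weighted sum exactly", {
  # printed arithmetic: 6 of 8 masks on, G on, gamma 0.4 -> L = 0.85
  d <- c(3, 3, 2)
  S <- lapply(1:8, function(i) array(i <= 6, d))
  G <- array(TRUE, d)
  cm <- fuse(S, G, gamma = 0.4, omega = 0.6)
  expect_equal(cm$L[1], 0.75 * 0.6 + 0.4)
  expect_true(all(cm$mask))

  # random masks vs a brute-force per-voxel loop
  set.seed(20)
  S <- lapply(1:5, function(i) array(runif(prod(d)) > 0.5, d))
  G <- array(runif(prod(d)) > 0.5, d)
  gamma <- 0.3
  cm <- fuse(S, G, gamma, omega = 0.6)
  for (i in seq_len(prod(d))) {
    l <- mean(vapply(S, function(m) m[i], logical(1))) * (1 - gamma) +
      G[i] * gamma
    expect_equal(cm$L[i], l, tolerance = 1e-12)
  }
  expect_identical(cm$mask, cm$L > 0.6)
  # all-off voxels stay background
  S0 <- lapply(1:4, function(i) array(FALSE, d))
  expect_true(all(fuse(S0, array(FALSE, d), 0.5)$L == 0))
  expect_error(fuse(S, G, gamma = 1.2), "gamma")
})

test_that("gamma = 1 and gamma = 0 reduce to the GMM and mean-GC limits", {
  case <- simulate_case(phantom_spec(noise_sd = 3, rng_seed = 21L))
  fit <- suppressWarnings(gcgmm(case$series, case$inputs$strokes))
  f1 <- suppressWarnings(gcgmm(case$series, case$inputs$strokes, gamma = 1))
  G <- f1$gmm$labeling$G
  expect_identical(f1$confidence$mask, G & TRUE)
  # final mask = seed-connected components of G
  expect_true(all(f1$mask[f1$mask] & G[f1$mask]))
  f0 <- suppressWarnings(gcgmm(case$series, case$inputs$strokes, gamma = 0))
  mean_gc <- Reduce(`+`, lapply(f0$gc_masks, function(m) m * 1)) / 8
  expect_identical(f0$confidence$mask, mean_gc > f0$omega)
})

test_that("raising omega never grows the fused mask", {
  case <- simulate_case(phantom_spec(noise_sd = 3, rng_seed = 22L))
  fit <- suppressWarnings(gcgmm(case$series, case$inputs$roi))
  prev <- predict(fit, omega = 0.3)
  for (om in c(0.5, 0.7, 0.9)) {
    cur <- predict(fit, omega = om)
    expect_true(all(prev[cur]))
    prev <- cur
  }
})

test_that("noise-free high-contrast phantoms segment almost perfectly", {
  case <- simulate_case(phantom_spec(noise_sd = 0, rng_seed = 23L))
  fit <- suppressWarnings(gcgmm(case$series, case$inputs$contour))
  ss <- seg_scores(fit$mask, case$truth_mask, case$spec$spacing_mm)
  expect_gte(ss$dsc, 0.9)
})

test_that("FCM separates two well-separated feature populations exactly", {
  d <- c(10, 10, 4)
  img <- array(0, d)
  img[3:6, 3:6, 2:3] <- 500
  series <- dce_series(list(img * 0 + 10, img + 10, img + 10, img + 10))
  stack <- build_feature_stack(series)
  roi <- rbind(c(1, 10), c(1, 10), c(1, 4))
  mask <- fcm_segment(stack, roi)
  # exact 2-means partition on this bimodal data = the enhancing block
  expect_identical(array(as.logical(mask), d), img == 500)
})

test_that("a uniform ROI gives indifferent memberships and no tumour voxels", {
  d <- c(6, 6, 3)
  series <- dce_series(lapply(1:4, function(i) array(5, d)))
  stack <- build_feature_stack(series)
  mask <- fcm_segment(stack, rbind(c(1, 6), c(1, 6), c(1, 3)))
  expect_false(any(mask))
  expect_equal(attr(mask, "membership_range"), c(0.5, 0.5))
})

test_that("FCM converges to an objective no worse than its initialization", {
  set.seed(24)
  d <- c(8, 8, 4)
  vols <- lapply(1:4, function(i) array(runif(prod(d), 0, 100), d))
  stack <- build_feature_stack(dce_series(vols))
  roi <- rbind(c(1, 8), c(1, 8), c(1, 4))
  X <- do.call(cbind, lapply(stack$images, as.vector))
  post1 <- X[, "post1"]
  centers <- X[c(which.min(post1), which.max(post1)), ]
  obj <- function(U, cen, m = 2) {
    d2 <- outer(seq_len(nrow(X)), seq_len(nrow(cen)),
                function(i, j) rowSums((X[i, , drop = FALSE] -
                                          cen[j, , drop = FALSE])^2))
    sum(U^m * d2)
  }
  fit <- e1071::cmeans(X, centers = centers, iter.max = 200, m = 2)
  # initial memberships from initial centers
  d2i <- t(apply(X, 1, function(r) c(sum((r - centers[1, ])^2),
                                     sum((r - centers[2, ])^2))))
  d2i <- pmax(d2i, 1e-12)
  Ui <- (1 / d2i) / rowSums(1 / d2i)
  expect_lte(obj(fit$membership, fit$centers), obj(Ui, centers))
})

test_that("stage errors are reported with the failing stage's name", {
  case <- simulate_case(phantom_spec(noise_sd = 0, rng_seed = 25L))
  bad_input <- case$inputs$contour
  bad_input$tumour_marks <- matrix(TRUE, 4, 4)  # wrong slice grid
  expect_error(gcgmm(case$series, bad_input), "\\[seeds\\]")
})
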