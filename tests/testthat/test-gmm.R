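make_stack <- function(images) {
  structure(list(images = images, spacing_mm = c(1, 1, 1)),
            class = "feature_stack")
}

# a 1-component unit-variance model on 8 identical features
flat_model <- function(mu) {
  structure(list(n_components = 1L, means = matrix(mu, 1, 8),
                 covariances = array(diag(8), c(8, 8, 1)), weights = 1,
                 loglik = NA_real_, aic = NA_real_,
                 loglik_trace = numeric(0)),
            class = "gmm_model")
}

test_that("a tight single Gaussian yields near-coincident component means", {
  set.seed(10)
  x <- matrix(rnorm(200 * 3, mean = 5, sd = 0.5), ncol = 3)
  fit <- fit_gmm(x, seed = 3L)
  mu <- fit$means
  if (nrow(mu) > 1) {
    dmax <- max(dist(mu))
    expect_lt(dmax, 3 * 0.5)
  }
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
})

test_that("EM log-likelihood is non-decreasing on every fit", {
  set.seed(11)
  x <- rbind(matrix(rnorm(120, 0, 1), ncol = 2),
             matrix(rnorm(120, 6, 1), ncol = 2))
  fit <- fit_gmm(x, seed = 5L)
  tr <- fit$loglik_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) >= -1e-6 * (abs(tr[-length(tr)]) + 1)))
})

test_that("AIC recovers a well-separated 3-component mixture", {
  set.seed(12)
  mu <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(167, mu[k, 1]), rnorm(167, mu[k, 2]))))
  fit <- fit_gmm(x, seed = 7L)
  expect_equal(fit$n_components, 3L)
  # match recovered means to truth
  err <- apply(mu, 1, function(m)
    min(sqrt(rowSums(sweep(fit$means, 2, m)^2))))
  expect_true(all(err < 1))  # 10% of the 10-unit separation
})

test_that("empty or undersized sample sets are rejected", {
  expect_error(fit_gmm(matrix(numeric(0), 0, 8)), "no samples")
  expect_error(suppressWarnings(fit_gmm(matrix(1:4, 2, 2))),
               "too few samples")
})

test_that("the fitted log-likelihood agrees with an independent EM (mclust)", {
  set.seed(13)
  x <- rbind(matrix(rnorm(300, 0, 1), ncol = 2),
             matrix(rnorm(300, 5, 1.5), ncol = 2))
  fit <- fit_gmm(x, n_components = 2L, seed = 1L)
  suppressPackageStartupMessages(library(mclust))
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 0.01)
})

test_that("similarity maps are complementary and tau = 1 empties G", {
  img <- array(seq(0, 10, length.out = 4 * 4 * 2), c(4, 4, 2))
  stack <- make_stack(stats::setNames(rep(list(img), 8),
                                      c("pre", "post1", "post2", "post3",
                                        "diff1", "diff2", "diff3", "trace")))
  lab <- gmm_label(stack, flat_model(8), flat_model(2), tau = 0.75)
  expect_equal(lab$k_T + lab$k_B, array(1, dim(img)), tolerance = 1e-12)
  lab1 <- gmm_label(stack, flat_model(8), flat_model(2), tau = 1)
  expect_false(any(lab1$G))
})

test_that("the tumour/background boundary matches the closed-form posterior", {
  # 8 identical features, unit variance, means 2 vs 8 per feature:
  # logit k_T(x) = 8 * (muT - muB) * (x - (muT + muB)/2) = 48 (x - 5)
  img <- array(seq(0, 10, length.out = 64), c(4, 4, 4))
  stack <- make_stack(stats::setNames(rep(list(img), 8),
                                      c("pre", "post1", "post2", "post3",
                                        "diff1", "diff2", "diff3", "trace")))
  tau <- 0.75
  lab <- gmm_label(stack, flat_model(8), flat_model(2), tau = tau)
  boundary <- 5 + log(tau / (1 - tau)) / 48
  expect_identical(lab$G, img > boundary)
  expect_equal(lab$k_T, array(stats::plogis(48 * (img - 5)), dim(img)),
               tolerance = 1e-4)
})

test_that("tau = 0.5 with these maps is maximum-likelihood labeling and raising tau shrinks G", {
  img <- array(seq(0, 10, length.out = 64), c(4, 4, 4))
  stack <- make_stack(stats::setNames(rep(list(img), 8),
                                      c("pre", "post1", "post2", "post3",
                                        "diff1", "diff2", "diff3", "trace")))
  mT <- flat_model(7)
  mB <- flat_model(3)
  lab05 <- gmm_label(stack, mT, mB, tau = 0.5)
  # brute-force density comparison per voxel
  X <- do.call(cbind, rep(list(as.vector(img)), 8))
  dT <- apply(X, 1, function(r) prod(stats::dnorm(r, 7, 1)))
  dB <- apply(X, 1, function(r) prod(stats::dnorm(r, 3, 1)))
  expect_identical(as.vector(lab05$G), dT > dB)
  prev <- lab05$G
  for (tau in c(0.6, 0.8, 0.95)) {
    cur <- gmm_label(stack, mT, mB, tau = tau)$G
    expect_true(all(prev[cur]))  # cur subset of prev
    prev <- cur
  }
})

test_that("a fitted mixture survives a JSON round trip", {
  set.seed(14)
  x <- matrix(rnorm(240, 2, 1), ncol = 2)
  fit <- fit_gmm(x, n_components = 2L, seed = 2L)
  path <- tempfile(fileext = ".json")
  write_gmm(fit, path)
  back <- read_gmm(path)
  expect_equal(back$means, fit$means, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_equal(back$covariances, fit$covariances, tolerance = 1e-12)
  expect_equal(back$aic, fit$aic, tolerance = 1e-12)
})
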