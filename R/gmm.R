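#' Fit a multivariate Gaussian mixture with AIC model selection
#'
#' Full-covariance Gaussian mixtures are fitted by expectation maximization
#' for each candidate number of components (default 2, 3, 4) and the model
#' minimising the Akaike Information Criterion is returned. Initialization
#' is k-means++ seeding with hard assignment, repeated for `restarts`
#' restarts per candidate (best likelihood kept), so the fit is
#' deterministic for a fixed `seed`. Component covariances are ridge
#' regularized by `1e-6 * trace(S)/d` (plus a tiny absolute floor, escalated
#' if the Cholesky factorization still fails) to survive near-constant
#' features.
#'
#' @param x numeric matrix, samples in rows (typically 8 feature columns).
#' @param n_components integer candidates for the number of components.
#'   Candidates with fewer samples than components are dropped with a
#'   warning; if all are dropped an error is raised.
#' @param seed integer seed controlling the k-means++ initializations.
#' @param restarts EM restarts per candidate.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   change per sample falls below `tol` (the convention of standard
#'   mixture libraries).
#' @return object of class `gmm_model`: `n_components`, `means` (n x d),
#'   `covariances` (d x d x n), `weights`, `loglik`, `loglik_trace`, `aic`,
#'   and `candidates` (the per-candidate AIC table).
#' @export
fit_gmm <- function(x, n_components = 2:4, seed = 1L, restarts = 5L,
                    max_iter = 200L, tol = 1e-3) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("no samples to fit")
  if (!all(is.finite(x))) stop("samples contain non-finite values")
  n <- nrow(x)
  # a candidate needs more samples than components; smaller candidates stay
  keep <- n_components[n > n_components]
  if (length(keep) < length(n_components))
    warning(sprintf("dropped mixture sizes with fewer than %d samples: %s",
                    n, paste(setdiff(n_components, keep), collapse = ", ")))
  if (length(keep) == 0L)
    stop(sprintf("too few samples (%d) for any candidate mixture size", n))

  best <- NULL
  cand <- data.frame(n_components = integer(), loglik = numeric(),
                     aic = numeric())
  for (k in keep) {
    fit_k <- NULL
    for (r in seq_len(restarts)) {
      f <- tryCatch(
        em_gmm(x, k, seed = seed + 1009L * (r - 1L) + 31L * k,
               max_iter = max_iter, tol = tol),
        error = function(e) NULL)
      if (!is.null(f) && (is.null(fit_k) || f$loglik > fit_k$loglik))
        fit_k <- f
    }
    if (is.null(fit_k)) next
    d <- ncol(x)
    npar <- (k - 1) + k * d + k * d * (d + 1) / 2
    aic <- 2 * npar - 2 * fit_k$loglik
    cand <- rbind(cand, data.frame(n_components = k, loglik = fit_k$loglik,
                                   aic = aic))
    if (is.null(best) || aic < best$aic) {
      best <- fit_k
      best$aic <- aic
    }
  }
  if (is.null(best)) stop("EM failed for all candidate mixture sizes")
  best$candidates <- cand
  class(best) <- "gmm_model"
  best
}

#' @export
print.gmm_model <- function(x, ...) {
  cat("Gaussian mixture:", x$n_components, "components,",
      ncol(x$means), "features; AIC", format(x$aic, digits = 6), "\n")
  invisible(x)
}

# k-means++ center seeding
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# log density of N(mu, sigma) at rows of x, via Cholesky with escalating
# ridge when sigma is numerically singular
chol_safe <- function(sigma) {
  d <- ncol(sigma)
  ridge <- 1e-6 * sum(diag(sigma)) / d + 1e-10
  for (i in 0:6) {
    R <- tryCatch(chol(sigma + diag(ridge * 100^i, d)), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("covariance not positive definite after regularization")
}

mvn_logdens <- function(x, mu, R) {
  d <- ncol(x)
  z <- forwardsolve(t(R), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}

em_gmm <- function(x, k, seed, max_iter = 200L, tol = 1e-3) {
  n <- nrow(x)
  d <- ncol(x)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)

  centers <- kmeanspp_centers(x, k)
  # hard assignment to the seeded centers -> initial responsibilities
  dists <- sapply(seq_len(k), function(j) rowSums(sweep(x, 2, centers[j, ])^2))
  assign0 <- max.col(-matrix(dists, n, k), ties.method = "first")
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), assign0)] <- 1

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  w <- mu <- sig <- NULL
  for (it in seq_len(max_iter)) {
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    w <- nk / n
    mu <- crossprod(resp, x) / nk
    sig <- array(0, c(d, d, k))
    Rs <- vector("list", k)
    for (j in seq_len(k)) {
      xc <- sweep(x, 2, mu[j, ])
      S <- crossprod(xc * resp[, j], xc) / nk[j]
      S <- S + diag(1e-6 * sum(diag(S)) / d + 1e-10, d)
      sig[, , j] <- S
      Rs[[j]] <- chol_safe(S)
    }
    # E step
    lp <- sapply(seq_len(k), function(j)
      log(w[j]) + mvn_logdens(x, mu[j, ], Rs[[j]]))
    lp <- matrix(lp, n, k)
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(lp - lse)
    # stopping rule on the per-sample averaged log-likelihood change (the
    # convention of standard mixture libraries); the raw likelihood of a
    # full-covariance mixture is unbounded, so early stopping doubles as
    # regularization against degenerate component spikes
    if (is.finite(ll) && is.finite(ll_old) && abs(ll - ll_old) / n <= tol)
      break
    ll_old <- ll
  }
  list(n_components = k, means = mu, covariances = sig, weights = w,
       loglik = ll, loglik_trace = loglik_trace)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# log mixture density of a gmm_model at rows of x
gmm_logdens <- function(model, x) {
  k <- model$n_components
  lp <- sapply(seq_len(k), function(j)
    log(model$weights[j]) +
      mvn_logdens(x, model$means[j, ], chol_safe(model$covariances[, , j])))
  lp <- matrix(lp, nrow(x), k)
  m <- apply(lp, 1, max)
  out <- m + log(rowSums(exp(lp - m)))
  out[!is.finite(m)] <- -Inf
  out
}

#' Voxel-wise GMM tumour/background labeling
#'
#' Evaluates the tumour and background mixture densities at every voxel of
#' the 8-image feature stack and normalizes them into similarity maps
#' `k_T = p_T / (p_T + p_B)` and `k_B = 1 - k_T`. A voxel is labeled tumour
#' iff `k_T > k_B` and, to limit false positives, `k_T > tau` (default
#' 0.75).
#'
#' @param stack a [build_feature_stack()] result.
#' @param model_T,model_B fitted [fit_gmm()] models for tumour and
#'   background (trained on the same 8 features).
#' @param tau tumour-probability threshold in \[0, 1\].
#' @return object of class `gmm_labeling`: logical array `G`, similarity
#'   arrays `k_T` and `k_B`, `tau`, and `n_underflow` (voxels where both
#'   densities underflowed; labeled background with a warning).
#' @export
gmm_label <- function(stack, model_T, model_B, tau = 0.75) {
  stopifnot(inherits(stack, "feature_stack"),
            inherits(model_T, "gmm_model"), inherits(model_B, "gmm_model"))
  if (tau < 0 || tau > 1) stop("'tau' must lie in [0, 1]")
  X <- stack_matrix(stack)
  if (ncol(model_T$means) != ncol(X) || ncol(model_B$means) != ncol(X))
    stop("models were not fitted on the stack's features")
  lt <- gmm_logdens(model_T, X)
  lb <- gmm_logdens(model_B, X)
  kT <- stats::plogis(lt - lb)
  under <- !is.finite(lt) & !is.finite(lb)
  n_under <- sum(under)
  if (n_under > 0) {
    warning(sprintf("%d voxels with vanishing densities labeled background",
                    n_under))
    kT[under] <- 0
  }
  d <- dim(stack$images[[1]])
  kT <- array(kT, d)
  G <- kT > 0.5 & kT > tau
  structure(list(G = G, k_T = kT, k_B = 1 - kT, tau = tau,
                 n_underflow = n_under),
            class = "gmm_labeling")
}

#' Write or read a fitted mixture as JSON
#'
#' @param model a `gmm_model`.
#' @param path file path.
#' @return `read_gmm` returns a `gmm_model`; `write_gmm` its path,
#'   invisibly.
#' @export
write_gmm <- function(model, path) {
  stopifnot(inherits(model, "gmm_model"))
  obj <- list(n_components = model$n_components,
              means = model$means,
              covariances = lapply(seq_len(model$n_components),
                                   function(j) model$covariances[, , j]),
              weights = model$weights,
              loglik = model$loglik,
              aic = model$aic)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  k <- obj$n_components
  means <- do.call(rbind, lapply(obj$means, function(r) unlist(r)))
  d <- ncol(means)
  sig <- array(0, c(d, d, k))
  for (j in seq_len(k))
    sig[, , j] <- do.call(rbind, lapply(obj$covariances[[j]],
                                        function(r) unlist(r)))
  structure(list(n_components = k, means = means, covariances = sig,
                 weights = unlist(obj$weights),
                 loglik = obj$loglik, aic = obj$aic,
                 loglik_trace = numeric(0)),
            class = "gmm_model")
}
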