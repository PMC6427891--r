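#' Gaussian mixture clustering by Classification EM (CEM)
#'
#' Second-stage splitter of the iterative engine, used when the rotation
#' search finds no dominant gap. Multivariate Gaussian mixtures with full
#' covariance are fitted to the PC scores for k = 1..`maxK` by CEM: the
#' E-step hard-assigns every point to its maximum-posterior component, the
#' M-step re-estimates weights, means and covariances from the resulting
#' partition. Each k is fitted from `nStarts` k-means++-style seedings and
#' the best classification likelihood wins; k is then selected by the
#' Bayesian Information Criterion on the classification likelihood, ties
#' broken towards smaller k. `k = 1` means "no substructure".
#'
#' Near-singular component covariances are regularized by adding
#' `1e-6 x mean(diag)` to the diagonal; a component that still degenerates
#' (or empties) invalidates that start, and a k with no valid start is
#' skipped.
#'
#' @param x numeric matrix of scores (N x D, N > D >= 1).
#' @param maxK maximum number of components (default 3).
#' @param nStarts random initializations per k.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @return list with elements `k`, `labels` (1..k, relabeled in order of
#'   first appearance), `means`, `covariances`, `weights`, `bic` (named
#'   vector over candidate k), `logLik` (classification log-likelihood of
#'   the chosen fit) and `clTrace` (per-iteration classification
#'   log-likelihood of the winning start, non-decreasing).
#' @export
cemCluster <- function(x, maxK = 3L, nStarts = 10L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- ncol(x)
  if (n <= d) .argError("need more points than dimensions")
  if (maxK < 1L) .argError("maxK must be >= 1")
  fits <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(min(maxK, n - 1L)), function(k) .cemFitK(x, k, nStarts))
  })
  ok <- !vapply(fits, is.null, TRUE)
  fits <- fits[ok]
  if (!length(fits)) .stopf("all mixture fits degenerated")
  bics <- vapply(fits, `[[`, 0, "bic")
  names(bics) <- vapply(fits, `[[`, 0L, "k")
  best <- fits[[which.min(bics)]] # which.min -> first, i.e. smallest k on ties
  labs <- best$labels
  # relabel components in order of first appearance
  u <- unique(labs)
  relab <- integer(max(labs))
  relab[u] <- seq_along(u)
  list(k = best$k,
       labels = relab[labs],
       means = best$means[u, , drop = FALSE],
       covariances = best$covariances[u],
       weights = best$weights[u],
       bic = bics,
       logLik = best$cl,
       clTrace = best$clTrace)
}

.cemFitK <- function(x, k, nStarts) {
  n <- nrow(x)
  d <- ncol(x)
  if (k == 1L) {
    par <- .cemMStep(x, rep(1L, n), 1L)
    if (is.null(par)) return(NULL)
    ll <- .cemLogLik(x, par)
    cl <- sum(ll)
    nu <- d + d * (d + 1) / 2
    return(list(k = 1L, labels = rep(1L, n), means = par$means,
                covariances = par$covs, weights = par$weights,
                cl = cl, bic = -2 * cl + nu * log(n), clTrace = cl))
  }
  best <- NULL
  for (s in seq_len(nStarts)) {
    centers <- .kmeansppCenters(x, k)
    z <- max.col(-.sqDistToCenters(x, centers), ties.method = "first")
    fit <- .cemRun(x, z, k)
    if (!is.null(fit) && (is.null(best) || fit$cl > best$cl)) best <- fit
  }
  if (is.null(best)) return(NULL)
  nu <- (k - 1) + k * d + k * d * (d + 1) / 2
  best$k <- k
  best$bic <- -2 * best$cl + nu * log(n)
  best
}

.cemRun <- function(x, z, k, maxIter = 100L) {
  n <- nrow(x)
  trace <- numeric(0)
  for (iter in seq_len(maxIter)) {
    par <- .cemMStep(x, z, k)
    if (is.null(par)) return(NULL)
    ll <- .cemLogLikMat(x, par) # n x k: log(pi_g) + log phi
    if (is.null(ll)) return(NULL)
    zNew <- max.col(ll, ties.method = "first")
    cl <- sum(ll[cbind(seq_len(n), zNew)])
    trace <- c(trace, cl)
    if (identical(zNew, z)) {
      z <- zNew
      break
    }
    z <- zNew
  }
  if (length(unique(z)) < k) return(NULL)
  list(labels = z, means = par$means, covariances = par$covs,
       weights = par$weights, cl = trace[length(trace)], clTrace = trace)
}

.cemMStep <- function(x, z, k) {
  n <- nrow(x)
  d <- ncol(x)
  counts <- tabulate(z, nbins = k)
  if (any(counts == 0L)) return(NULL)
  means <- matrix(0, k, d)
  covs <- vector("list", k)
  for (g in seq_len(k)) {
    xg <- x[z == g, , drop = FALSE]
    mu <- colMeans(xg)
    means[g, ] <- mu
    cc <- crossprod(sweep(xg, 2L, mu, "-")) / counts[g] # ML covariance
    eps <- 1e-6 * mean(diag(cc))
    if (!is.finite(eps) || eps <= 0) eps <- 1e-12
    covs[[g]] <- cc + diag(eps, d)
  }
  list(means = means, covs = covs, weights = counts / n)
}

# per-point, per-component log(weight * gaussian density); NULL on failure
.cemLogLikMat <- function(x, par) {
  k <- nrow(par$means)
  n <- nrow(x)
  d <- ncol(x)
  out <- matrix(NA_real_, n, k)
  for (g in seq_len(k)) {
    ch <- tryCatch(chol(par$covs[[g]]), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    xc <- sweep(x, 2L, par$means[g, ], "-")
    q <- colSums(forwardsolve(t(ch), t(xc))^2)
    out[, g] <- log(par$weights[g]) - sum(log(diag(ch))) -
      0.5 * d * log(2 * pi) - 0.5 * q
  }
  out
}

.cemLogLik <- function(x, par) {
  ll <- .cemLogLikMat(x, par)
  if (is.null(ll)) return(rep(-Inf, nrow(x)))
  ll[, 1L]
}

.kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(.sqDistToCenters(x, centers), 1L, min)
    tot <- sum(d2)
    i <- if (tot > 0) sample.int(n, 1L, prob = d2 / tot) else sample.int(n, 1L)
    centers <- rbind(centers, x[i, , drop = FALSE])
  }
  centers
}

.sqDistToCenters <- function(x, centers) {
  n <- nrow(x)
  k <- nrow(centers)
  d2 <- matrix(0, n, k)
  for (g in seq_len(k)) {
    d2[, g] <- rowSums(sweep(x, 2L, centers[g, ], "-")^2)
  }
  d2
}
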