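#' Normalize a genotype matrix for PCA
#'
#' Columns are mean-centered; with `scaleMode = "eigenstrat"` each column j
#' is additionally divided by `sqrt(p_j (1 - p_j))`, where
#' `p_j = (1 + sum_i g_ij) / (2 + 2N)` is the shrunk counted-allele
#' frequency estimate, putting every SNP on the scale of its binomial
#' standard deviation. The shrinkage keeps the denominator strictly
#' positive, so constant columns simply remain all-zero after centering and
#' are never divided by zero.
#'
#' @param x numeric genotype matrix (individuals x SNPs), no missing values.
#' @param scaleMode `"eigenstrat"` (default) or `"center"`.
#' @return normalized numeric matrix of the same shape.
#' @export
normalizeGenotypes <- function(x, scaleMode = c("eigenstrat", "center")) {
  scaleMode <- match.arg(scaleMode)
  x <- .asGenoMatrix(x)
  if (anyNA(x)) .valueError("normalization requires imputed genotypes")
  n <- nrow(x)
  mu <- colMeans(x)
  x <- sweep(x, 2L, mu, "-")
  if (scaleMode == "eigenstrat") {
    p <- (1 + n * mu) / (2 + 2 * n)
    x <- sweep(x, 2L, sqrt(p * (1 - p)), "/")
  }
  x
}

#' Top principal components of a normalized genotype matrix
#'
#' Eigendecomposition of the N x N covariance-like matrix X X' / M (the
#' EIGENSTRAT orientation, efficient when N << M as in genotype panels).
#' Scores are the principal-component projections U S (equal to X V of the
#' singular value decomposition X = U S V'); eigenvalues are the singular
#' values squared over M. The sign of each component is fixed by making its
#' largest-magnitude score entry positive, so results are reproducible.
#'
#' @param x numeric matrix (individuals x SNPs), already normalized, no
#'   missing values.
#' @param k number of components to keep; must satisfy
#'   `k <= min(nrow(x), ncol(x))`.
#' @return a [PCResult-class] object.
#' @export
topPCs <- function(x, k = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (k < 1L || k > min(n, m)) {
    .argError("k = %d out of range; must be in [1, %d]", k, min(n, m))
  }
  if (anyNA(x)) .valueError("PCA requires imputed genotypes")
  cv <- tcrossprod(x) / m
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  keep <- seq_len(k)
  scores <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(vals[keep] * m), nrow = k)
  # deterministic sign: largest-|score| entry of each component positive
  for (j in keep) {
    i <- which.max(abs(scores[, j]))
    if (length(i) && scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  new("PCResult",
      scores = scores,
      eigenvalues = vals[keep],
      explained = if (total > 0) vals[keep] / total else rep(0, k),
      totalVariance = total)
}

#' EigenFit substructure statistic
#'
#' Differences between the natural logarithms of consecutive eigenvalues
#' sorted from high to low; the statistic is the largest such gap. A large
#' gap indicates that the leading eigenvalues stand out from the bulk of the
#' spectrum, i.e. that axes of genuine substructure exist. Non-positive
#' eigenvalues (and everything below the first one encountered) are dropped
#' before taking logs; with fewer than two eigenvalues left the statistic is
#' `NA`, read as "no evidence of structure". The statistic is invariant to
#' rescaling the data by any positive constant.
#'
#' @param eigenvalues numeric vector of eigenvalues (a [PCResult-class] is
#'   also accepted).
#' @return list with `gaps` (length K-1) and `statistic` (max gap, or `NA`).
#' @export
eigenFit <- function(eigenvalues) {
  if (is(eigenvalues, "PCResult")) eigenvalues <- eigenvalues(eigenvalues)
  ev <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  ev <- ev[ev > 0]
  if (length(ev) < 2L) {
    return(list(gaps = numeric(0), statistic = NA_real_))
  }
  gaps <- -diff(log(ev))
  list(gaps = gaps, statistic = max(gaps))
}
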