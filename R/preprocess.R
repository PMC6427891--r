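#' @rdname imputeMedian
#' @export
setMethod("imputeMedian", "matrix", function(x) {
  bad <- which(colSums(!is.na(x)) == 0L)
  if (length(bad)) {
    .valueError("SNP(s) with no non-missing genotype: column %s",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  needs <- which(colSums(is.na(x)) > 0L)
  for (j in needs) {
    col <- x[, j]
    col[is.na(col)] <- stats::median(col, na.rm = TRUE)
    x[, j] <- col
  }
  x
})

#' @rdname imputeMedian
#' @export
setMethod("imputeMedian", "GenotypeData", function(x) {
  g <- genotypes(x)
  ids <- snpIds(x)
  bad <- which(colSums(!is.na(g)) == 0L)
  if (length(bad)) {
    .valueError("SNP(s) with no non-missing genotype: %s",
                paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  x@genotypes <- imputeMedian(g)
  x
})

#' Regress per-individual covariates out of every SNP column
#'
#' For patient samples, broad ancestry should be removed before clustering:
#' each SNP column is replaced by the residuals of an ordinary least-squares
#' fit on an intercept plus the supplied covariates (e.g. reference ancestry
#' PCs or ancestry-informative-marker dosages). Residual columns have mean
#' zero, are orthogonal to the covariates, and are invariant to affine
#' rescaling of covariate columns.
#'
#' @param x a [GenotypeData-class] object or numeric genotype matrix with no
#'   missing values (impute first).
#' @param covariates numeric matrix/data.frame, one row per individual, no
#'   missing values.
#' @return numeric residual matrix (individuals x SNPs). Rank-deficient
#'   covariate sets trigger a warning and a pseudoinverse fit.
#' @export
regressOutCovariates <- function(x, covariates) {
  g <- .asGenoMatrix(x)
  cv <- as.matrix(covariates)
  storage.mode(cv) <- "double"
  if (nrow(cv) != nrow(g)) {
    .argError("covariates have %d rows but genotypes have %d individuals",
              nrow(cv), nrow(g))
  }
  if (anyNA(cv)) .valueError("covariates must not contain missing values")
  if (anyNA(g)) .valueError("genotypes must be imputed before regression")
  if (ncol(cv) >= nrow(g) - 1L) {
    .argError("need fewer covariates than individuals")
  }
  X <- cbind(1, cv)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient covariates; using pseudoinverse fit")
    beta <- MASS::ginv(X) %*% g
    res <- g - X %*% beta
  } else {
    res <- qr.resid(qrX, g)
  }
  unname(res)
}
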