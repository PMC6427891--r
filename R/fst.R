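#' Hudson F_ST between two sample groups (per SNP and average)
#'
#' Hudson-type estimator in the ratio-of-averages form. With `p_i` the
#' sample counted-allele frequency and `n_i` the allele count (2 x number of
#' individuals with a non-missing call) in group i at SNP j:
#' \deqn{N_j = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1} -
#'             \frac{p_2(1-p_2)}{n_2 - 1}}
#' \deqn{D_j = p_1(1 - p_2) + p_2(1 - p_1)}
#' The per-SNP estimate is `N_j / D_j` and the genome-wide average is the
#' ratio of averages `sum(N_j) / sum(D_j)` over retained SNPs - never the
#' average of per-SNP ratios. The finite-sample correction terms make the
#' estimator unbiased at zero differentiation, so slightly negative values
#' are meaningful and are never clipped.
#'
#' SNPs are excluded when `D_j = 0` (monomorphic for the same allele in both
#' groups) or when a group has no non-missing call (allele count < 2).
#' Missing genotypes are simply dropped from the frequency estimates, never
#' re-imputed here.
#'
#' @param group1,group2 genotype subsets: [GenotypeData-class] objects or
#'   numeric matrices (individuals x SNPs, additive coding, NA = missing)
#'   over the same SNPs in the same order.
#' @return `hudsonFst`: an [FstResult-class]; `hudsonFstAverage`: the scalar
#'   ratio-of-averages (error if every SNP is excluded).
#' @export
hudsonFst <- function(group1, group2) {
  ids <- if (is(group1, "GenotypeData")) snpIds(group1) else NULL
  g1 <- .asGenoMatrix(group1)
  g2 <- .asGenoMatrix(group2)
  if (ncol(g1) != ncol(g2)) {
    .argError("groups cover different numbers of SNPs (%d vs %d)",
              ncol(g1), ncol(g2))
  }
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(g1)))
  n1 <- 2 * colSums(!is.na(g1))
  n2 <- 2 * colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / n1
  p2 <- colSums(g2, na.rm = TRUE) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  excluded <- n1 < 2 | n2 < 2 | !is.finite(den) | den == 0
  fst <- ifelse(excluded, NA_real_, num / den)
  avg <- if (all(excluded)) NaN else
    sum(num[!excluded]) / sum(den[!excluded])
  new("FstResult",
      numerator = ifelse(n1 < 2 | n2 < 2, NA_real_, num),
      denominator = ifelse(n1 < 2 | n2 < 2, NA_real_, den),
      fst = fst, average = avg, excluded = excluded,
      snpIds = as.character(ids))
}

#' @rdname hudsonFst
#' @export
hudsonFstAverage <- function(group1, group2) {
  res <- hudsonFst(group1, group2)
  if (!is.finite(res@average)) {
    .valueError("average Hudson FST undefined: every SNP excluded")
  }
  res@average
}

#' @describeIn topDiscriminators genotype matrix/GenotypeData plus an
#'   explicit group assignment vector.
#' @param groups vector of group ids, one per individual.
#' @param groupA,groupB the two group ids to contrast.
#' @param snpAnnotation optional data.frame in the [GenotypeData-class]
#'   `snpInfo` layout (e.g. read from a bim file); defaults to the object's
#'   own annotation.
#' @param nTop number of top-ranked SNPs to return (default 100). If fewer
#'   valid SNPs exist, all are returned with a warning.
#' @export
setMethod("topDiscriminators", "GenotypeData",
  function(x, groups, groupA, groupB, snpAnnotation = NULL, nTop = 100L) {
    .topDiscImpl(genotypes(x), groups, groupA, groupB,
                 if (is.null(snpAnnotation)) snpInfo(x) else snpAnnotation,
                 nTop)
  })

#' @describeIn topDiscriminators plain genotype matrix input.
#' @export
setMethod("topDiscriminators", "matrix",
  function(x, groups, groupA, groupB, snpAnnotation = NULL, nTop = 100L) {
    if (is.null(snpAnnotation)) {
      snpAnnotation <- defaultSnpInfo(paste0("snp", seq_len(ncol(x))))
    }
    .topDiscImpl(x, groups, groupA, groupB, snpAnnotation, nTop)
  })

.topDiscImpl <- function(g, groups, groupA, groupB, snpAnnotation, nTop) {
  if (nTop < 1L) .argError("nTop must be >= 1")
  if (length(groups) != nrow(g)) {
    .argError("groups must have one entry per individual")
  }
  for (gr in c(groupA, groupB)) {
    if (!any(groups == gr, na.rm = TRUE)) .argError("unknown group id: %s", gr)
  }
  if (nrow(snpAnnotation) != ncol(g)) {
    .argError("SNP annotation has %d rows but panel has %d SNPs",
              nrow(snpAnnotation), ncol(g))
  }
  inA <- which(groups == groupA)
  inB <- which(groups == groupB)
  res <- hudsonFst(g[inA, , drop = FALSE], g[inB, , drop = FALSE])
  valid <- which(!res@excluded)
  if (!length(valid)) .valueError("no SNP with a defined FST between the groups")
  if (nTop > length(valid)) {
    warning(sprintf("only %d valid SNPs; returning all of them", length(valid)))
    nTop <- length(valid)
  }
  ord <- valid[order(res@fst[valid], decreasing = TRUE)][seq_len(nTop)]
  out <- snpAnnotation[ord, , drop = FALSE]
  out$fst <- res@fst[ord]
  out$rank <- seq_len(nTop)
  rownames(out) <- NULL
  out
}

#' @describeIn topDiscriminators contrast two final/outlier groups of a
#'   finished [iterativePrune()] run; `x` is the [ClusterTree-class] and the
#'   genotypes must be supplied via `genotypeData`.
#' @param genotypeData the [GenotypeData-class] the tree was built from.
#' @export
setMethod("topDiscriminators", "ClusterTree",
  function(x, genotypeData, groupA, groupB, snpAnnotation = NULL,
           nTop = 100L) {
    asg <- groupAssignments(x)
    topDiscriminators(genotypeData, asg$group, groupA, groupB,
                      snpAnnotation = snpAnnotation, nTop = nTop)
  })
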