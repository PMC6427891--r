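#' @rdname GenotypeData-class
#' @param x object to extract from.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeData-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypeData-class
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname PCResult-class
#' @param x object to extract from.
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' @rdname PCResult-class
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname PCResult-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname FstResult-class
#' @param x object to extract from.
#' @export
setGeneric("perSnpFst", function(x) standardGeneric("perSnpFst"))

#' @rdname FstResult-class
#' @export
setGeneric("fstAverage", function(x) standardGeneric("fstAverage"))

#' @rdname ClusterTree-class
#' @param x object to extract from.
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' @rdname ClusterTree-class
#' @export
setGeneric("groupAssignments", function(x) standardGeneric("groupAssignments"))

#' @rdname ClusterTree-class
#' @export
setGeneric("finalGroups", function(x) standardGeneric("finalGroups"))

#' @rdname ClusterTree-class
#' @export
setGeneric("outlierGroups", function(x) standardGeneric("outlierGroups"))

#' Median imputation of residual missing genotypes
#'
#' Replaces each missing genotype by the SNP-wise median of the non-missing
#' values of that SNP (even counts: mean of the two central order statistics,
#' so fractional dosages such as 1 for \{0, 2\} or 0.5 for \{0, 1\} can
#' arise). Non-missing entries are never changed, so the operation is
#' idempotent. A SNP with no non-missing value is an error.
#'
#' @param x a [GenotypeData-class] object or a numeric genotype matrix
#'   (individuals x SNPs).
#' @return object of the same kind as `x`, with no missing values.
#' @export
setGeneric("imputeMedian", function(x) standardGeneric("imputeMedian"))

#' Rank SNPs by per-SNP Hudson F_ST between two groups
#'
#' Computes per-SNP Hudson F_ST between two groups of samples and returns
#' the `nTop` SNPs with the largest values, with their annotation. SNPs with
#' an undefined denominator are never returned.
#'
#' @param x a [ClusterTree-class] (groups are final/outlier group numbers)
#'   or a [GenotypeData-class] object.
#' @param ... further arguments, see methods.
#' @return data.frame with columns `snpId`, `chromosome`, `position`,
#'   `allele1`, `allele2`, `fst`, `rank`.
#' @export
setGeneric("topDiscriminators", function(x, ...) standardGeneric("topDiscriminators"))
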