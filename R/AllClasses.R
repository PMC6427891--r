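#' @import methods
NULL

#' GenotypeData: additive-coded SNP genotypes with sample and SNP annotation
#'
#' The central container of the package: an N x M numeric matrix of genotypes
#' in additive coding (count of `allele2` copies, 0/1/2, `NA` for missing),
#' with N individuals as rows and M SNPs as columns, plus per-SNP annotation
#' (chromosome, position, alleles) and per-sample annotation (id, optional
#' population/phenotype label).
#'
#' Genotype values read from files are validated to lie in \{0, 1, 2, NA\};
#' after median imputation ([imputeMedian()]) fractional dosages in \[0, 2\]
#' can occur (the even-count median of \{0, 1\} is 0.5), so validity checks
#' the range rather than integrality.
#'
#' @slot genotypes numeric matrix, individuals x SNPs, values in \[0, 2\] or NA.
#' @slot snpInfo data.frame with columns `chromosome`, `snpId`, `position`,
#'   `allele1`, `allele2`; one row per genotype column, same order.
#' @slot sampleInfo data.frame with columns `sampleId`, `label`; one row per
#'   genotype row, same order.
#'
#' @seealso [GenotypeData()] for the constructor, [readPlinkBinary()],
#'   [readTextGenotypes()].
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(
    genotypes = "matrix",
    snpInfo = "data.frame",
    sampleInfo = "data.frame"
  )
)

setValidity("GenotypeData", function(object) {
  g <- object@genotypes
  msg <- character(0)
  if (!is.numeric(g)) {
    msg <- c(msg, "genotypes must be a numeric matrix")
  }
  if (nrow(g) < 2L) msg <- c(msg, "need at least 2 individuals")
  if (ncol(g) < 1L) msg <- c(msg, "need at least 1 SNP")
  v <- g[!is.na(g)]
  if (length(v) && (min(v) < 0 || max(v) > 2)) {
    msg <- c(msg, "non-missing genotypes must lie in [0, 2]")
  }
  si <- object@sampleInfo
  if (!identical(names(si), c("sampleId", "label"))) {
    msg <- c(msg, "sampleInfo must have columns sampleId, label")
  } else {
    if (nrow(si) != nrow(g)) msg <- c(msg, "sampleInfo rows must match individuals")
    if (anyDuplicated(si$sampleId)) msg <- c(msg, "sample ids must be unique")
  }
  vi <- object@snpInfo
  if (!identical(names(vi),
                 c("chromosome", "snpId", "position", "allele1", "allele2"))) {
    msg <- c(msg, "snpInfo must have columns chromosome, snpId, position, allele1, allele2")
  } else {
    if (nrow(vi) != ncol(g)) msg <- c(msg, "snpInfo rows must match SNPs")
    if (anyDuplicated(vi$snpId)) msg <- c(msg, "snp ids must be unique")
    if (any(vi$position < 0)) msg <- c(msg, "positions must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Principal-component decomposition of a genotype subset
#'
#' Scores are principal-component projections of the (normalized) genotype
#' matrix; eigenvalues are those of the individuals-by-individuals
#' covariance-like matrix X X' / M, sorted in decreasing order.
#'
#' @slot scores numeric matrix, individuals x components.
#' @slot eigenvalues numeric, decreasing, length = number of components kept.
#' @slot explained fraction of total variance per kept component.
#' @slot totalVariance sum of all eigenvalues of the full decomposition.
#'
#' @seealso [topPCs()]
#' @exportClass PCResult
setClass("PCResult",
  representation(
    scores = "matrix",
    eigenvalues = "numeric",
    explained = "numeric",
    totalVariance = "numeric"
  )
)

setValidity("PCResult", function(object) {
  msg <- character(0)
  ev <- object@eigenvalues
  if (ncol(object@scores) != length(ev)) {
    msg <- c(msg, "scores columns must match eigenvalues")
  }
  if (length(ev) > 1 && any(diff(ev) > 1e-8 * max(abs(ev), 1))) {
    msg <- c(msg, "eigenvalues must be sorted in decreasing order")
  }
  if (any(ev < -1e-8 * max(abs(ev), 1))) msg <- c(msg, "eigenvalues must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Hudson F_ST between two sample groups
#'
#' Per-SNP numerator/denominator of the Hudson estimator plus their ratio,
#' and the ratio-of-averages summary sum(N_j) / sum(D_j) over retained SNPs.
#' SNPs whose denominator is zero (monomorphic for the same allele in both
#' groups) or with insufficient non-missing calls are flagged `excluded` and
#' contribute to neither sum.
#'
#' @slot numerator per-SNP Hudson numerator N_j.
#' @slot denominator per-SNP Hudson denominator D_j.
#' @slot fst per-SNP ratio N_j / D_j (NA where excluded).
#' @slot average ratio of averages sum(N) / sum(D) over retained SNPs.
#' @slot excluded logical flag per SNP.
#' @slot snpIds SNP identifiers, same order as the input columns.
#'
#' @seealso [hudsonFst()], [hudsonFstAverage()]
#' @exportClass FstResult
setClass("FstResult",
  representation(
    numerator = "numeric",
    denominator = "numeric",
    fst = "numeric",
    average = "numeric",
    excluded = "logical",
    snpIds = "character"
  )
)

#' Result tree of the iterative-pruning engine
#'
#' A rooted tree of nested sample subsets. Each node carries the indices of
#' its members, a status (`intermediate`, `terminal`, or `outlier`) and, for
#' stopped nodes, the stopping reason. Terminal nodes smaller than the
#' minimum group size are reclassified as outlier groups; every sample ends
#' up in exactly one final or outlier group.
#'
#' @slot nodes data.frame with columns `nodeId`, `parentId`, `depth`, `size`,
#'   `status`, `stopReason`, `method` (splitter that produced the children).
#' @slot members list of integer index vectors, one per node.
#' @slot pcs list of [PCResult-class] objects (NULL where PCA was not run).
#' @slot assignments data.frame with `sampleId`, `label`, `group`, `nodeId`.
#' @slot finalGroups node ids of the final (non-outlier) groups, in group order.
#' @slot outlierGroups node ids of outlier groups.
#' @slot config list of engine parameters used for the run.
#'
#' @seealso [iterativePrune()], [classifyOutliers()], [exportResults()]
#' @exportClass ClusterTree
setClass("ClusterTree",
  representation(
    nodes = "data.frame",
    members = "list",
    pcs = "list",
    assignments = "data.frame",
    finalGroups = "integer",
    outlierGroups = "integer",
    config = "list"
  )
)

#' Configuration of the Balding-Nichols benchmark simulator
#'
#' @slot nSnps number of independent SNPs.
#' @slot popSizes diploid individuals per population.
#' @slot fst Balding-Nichols differentiation parameter in [0, 1); this is
#'   the intra-class correlation of per-population allele frequencies around
#'   the ancestral frequency, and (for independently drifted populations)
#'   the expected pairwise Hudson F_ST.
#' @slot nOutliers number of planted outlying individuals.
#' @slot outlierScale multiple of the observed PC score range at which
#'   outlier scores are planted.
#' @slot mafRange range from which ancestral counted-allele frequencies are
#'   drawn uniformly.
#' @slot seed RNG seed for the generator.
#'
#' @seealso [SimConfig()], [simulatePopulations()], [benchmarkDataset()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nSnps = "integer",
    popSizes = "integer",
    fst = "numeric",
    nOutliers = "integer",
    outlierScale = "numeric",
    mafRange = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (any(object@popSizes < 1L)) msg <- c(msg, "all popSizes must be >= 1")
  if (object@fst < 0 || object@fst >= 1) msg <- c(msg, "fst must lie in [0, 1)")
  if (object@nOutliers < 0L) msg <- c(msg, "nOutliers must be >= 0")
  if (object@outlierScale <= 0) msg <- c(msg, "outlierScale must be > 0")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange >= 1) || diff(object@mafRange) < 0) {
    msg <- c(msg, "mafRange must be an increasing interval within (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated genotype panel with truth labels
#'
#' @slot genotypes a [GenotypeData-class] object (populations first, planted
#'   outliers appended last).
#' @slot truthLabels generating population of each individual, `"OUTLIER"`
#'   for planted outliers.
#' @slot ancestralFreqs per-SNP ancestral counted-allele frequencies.
#' @slot popFreqs per-population per-SNP frequencies (populations x SNPs).
#' @slot outlierIndex row indices of planted outliers (integer(0) if none).
#' @slot config the [SimConfig-class] used.
#'
#' @seealso [simulatePopulations()], [injectOutliers()]
#' @exportClass SimResult
setClass("SimResult",
  representation(
    genotypes = "GenotypeData",
    truthLabels = "character",
    ancestralFreqs = "numeric",
    popFreqs = "matrix",
    outlierIndex = "integer",
    config = "SimConfig"
  )
)
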