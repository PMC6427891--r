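#' Construct a GenotypeData object
#'
#' @param genotypes numeric matrix, individuals x SNPs, additive coding
#'   (0/1/2 copies of `allele2`), `NA` for missing.
#' @param sampleIds character vector of unique sample identifiers; defaults
#'   to rownames of `genotypes` or `sample1..N`.
#' @param snpIds character vector of unique SNP identifiers; defaults to
#'   colnames of `genotypes` or `snp1..M`.
#' @param snpInfo optional data.frame with columns `chromosome`, `snpId`,
#'   `position`, `allele1`, `allele2`; a default synthetic map (chromosome 1,
#'   positions 1..M x 1000, alleles A/B) is used when absent.
#' @param labels optional per-sample labels (annotation only; never used by
#'   the clustering itself).
#' @return a [GenotypeData-class] object.
#' @examples
#' g <- GenotypeData(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3))
#' dim(g)
#' @export
GenotypeData <- function(genotypes, sampleIds = NULL, snpIds = NULL,
                         snpInfo = NULL, labels = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (is.null(sampleIds)) {
    sampleIds <- if (!is.null(rownames(genotypes))) rownames(genotypes)
                 else paste0("sample", seq_len(n))
  }
  if (is.null(snpIds)) {
    snpIds <- if (!is.null(colnames(genotypes))) colnames(genotypes)
              else paste0("snp", seq_len(m))
  }
  if (is.null(snpInfo)) {
    snpInfo <- defaultSnpInfo(snpIds)
  }
  if (is.null(labels)) labels <- rep(NA_character_, n)
  dimnames(genotypes) <- NULL
  new("GenotypeData",
      genotypes = genotypes,
      snpInfo = as.data.frame(snpInfo, stringsAsFactors = FALSE),
      sampleInfo = data.frame(sampleId = as.character(sampleIds),
                              label = as.character(labels),
                              stringsAsFactors = FALSE))
}

# synthetic map: chromosome 1, positions 1..M x 1000, alleles A/B
defaultSnpInfo <- function(snpIds) {
  m <- length(snpIds)
  data.frame(chromosome = rep("1", m),
             snpId = as.character(snpIds),
             position = seq_len(m) * 1000L,
             allele1 = rep("A", m),
             allele2 = rep("B", m),
             stringsAsFactors = FALSE)
}

#' @rdname GenotypeData-class
#' @aliases genotypes,GenotypeData-method
#' @export
setMethod("genotypes", "GenotypeData", function(x) x@genotypes)

#' @rdname GenotypeData-class
#' @export
setMethod("sampleIds", "GenotypeData", function(x) x@sampleInfo$sampleId)

#' @rdname GenotypeData-class
#' @export
setMethod("snpIds", "GenotypeData", function(x) x@snpInfo$snpId)

#' @rdname GenotypeData-class
#' @export
setMethod("snpInfo", "GenotypeData", function(x) x@snpInfo)

#' @rdname GenotypeData-class
#' @export
setMethod("sampleLabels", "GenotypeData", function(x) x@sampleInfo$label)

#' @rdname GenotypeData-class
#' @export
setMethod("dim", "GenotypeData", function(x) dim(x@genotypes))

#' Subset samples (rows) and/or SNPs (columns) of a GenotypeData object
#' @param x a [GenotypeData-class] object.
#' @param i sample indices.
#' @param j SNP indices.
#' @param ... ignored.
#' @param drop ignored; a GenotypeData is always returned.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@genotypes))
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  new("GenotypeData",
      genotypes = x@genotypes[i, j, drop = FALSE],
      snpInfo = x@snpInfo[j, , drop = FALSE],
      sampleInfo = x@sampleInfo[i, , drop = FALSE])
})

setMethod("show", "GenotypeData", function(object) {
  d <- dim(object@genotypes)
  nmiss <- sum(is.na(object@genotypes))
  cat("GenotypeData:", d[1], "individuals x", d[2], "SNPs\n")
  cat("  missing genotypes:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / prod(d)))
  labs <- object@sampleInfo$label
  if (!all(is.na(labs))) {
    tab <- table(labs, useNA = "no")
    cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
})

setMethod("show", "PCResult", function(object) {
  cat("PCResult:", nrow(object@scores), "samples,",
      ncol(object@scores), "components\n")
  cat("  eigenvalues:", paste(signif(utils::head(object@eigenvalues, 5), 4),
                              collapse = ", "),
      if (length(object@eigenvalues) > 5) "...\n" else "\n")
  cat("  explained:", paste(sprintf("%.1f%%",
                                    100 * utils::head(object@explained, 5)),
                            collapse = ", "),
      if (length(object@explained) > 5) "...\n" else "\n")
})

setMethod("show", "FstResult", function(object) {
  cat("FstResult over", length(object@fst), "SNPs (",
      sum(object@excluded), "excluded )\n")
  cat("  average Hudson FST (ratio of averages):",
      signif(object@average, 6), "\n")
})

#' @rdname PCResult-class
#' @export
setMethod("pcaScores", "PCResult", function(x) x@scores)

#' @rdname PCResult-class
#' @export
setMethod("eigenvalues", "PCResult", function(x) x@eigenvalues)

#' @rdname PCResult-class
#' @export
setMethod("explainedVariance", "PCResult", function(x) x@explained)

#' @rdname FstResult-class
#' @export
setMethod("perSnpFst", "FstResult", function(x) {
  data.frame(snpId = x@snpIds, numerator = x@numerator,
             denominator = x@denominator, fst = x@fst,
             excluded = x@excluded, stringsAsFactors = FALSE)
})

#' @rdname FstResult-class
#' @export
setMethod("fstAverage", "FstResult", function(x) x@average)
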