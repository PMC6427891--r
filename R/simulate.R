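#' Configure the Balding-Nichols benchmark simulator
#'
#' Defaults reproduce the package's benchmark design: 10,000 independent
#' SNPs, three populations of 250 diploid individuals at pairwise
#' F_ST = 0.005, and 10 planted outliers created by eigenvector replacement
#' and SVD reconstruction.
#'
#' @param nSnps number of independent SNPs (default 10000).
#' @param popSizes individuals per population (default `c(250, 250, 250)`).
#' @param fst Balding-Nichols differentiation parameter (default 0.005).
#' @param nOutliers planted outliers (default 10).
#' @param outlierScale outlier scores are planted at plus/minus this
#'   multiple of the observed score range (default 3).
#' @param mafRange ancestral counted-allele frequency range (default
#'   `c(0.1, 0.9)`, avoiding near-monomorphic SNPs).
#' @param seed generator seed.
#' @return a [SimConfig-class] object.
#' @export
SimConfig <- function(nSnps = 10000L, popSizes = c(250L, 250L, 250L),
                      fst = 0.005, nOutliers = 10L, outlierScale = 3,
                      mafRange = c(0.1, 0.9), seed = 1L) {
  new("SimConfig", nSnps = as.integer(nSnps),
      popSizes = as.integer(popSizes), fst = as.numeric(fst),
      nOutliers = as.integer(nOutliers),
      outlierScale = as.numeric(outlierScale),
      mafRange = as.numeric(mafRange), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d SNPs, pops [%s], FST = %g, %d outliers, seed %d\n",
              object@nSnps, paste(object@popSizes, collapse = ", "),
              object@fst, object@nOutliers, object@seed))
})

#' Simulate independent SNPs for differentiated populations
#'
#' Balding-Nichols construction: per SNP j an ancestral counted-allele
#' frequency `p_j ~ Uniform(mafRange)`; per population i a frequency
#' `p_ij ~ Beta(p_j (1-F)/F, (1-p_j)(1-F)/F)` with `F = config@fst` (for
#' F = 0 the ancestral frequency is used exactly). The Beta's intra-class
#' correlation equals F, so for populations drifted independently from the
#' common ancestor the expected pairwise Hudson F_ST is the nominal F.
#' Genotypes are drawn `Binomial(2, p_ij)` independently across SNPs.
#' Identical seeds give bit-identical output.
#'
#' @param config a [SimConfig-class] object (`nOutliers` is ignored here;
#'   see [injectOutliers()]).
#' @return a [SimResult-class]; individuals are labeled `POP1..POPK`.
#' @export
simulatePopulations <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  m <- config@nSnps
  sizes <- config@popSizes
  fst <- config@fst
  withr::with_seed(config@seed, {
    pAnc <- stats::runif(m, config@mafRange[1L], config@mafRange[2L])
    popFreqs <- matrix(0, nrow = length(sizes), ncol = m)
    for (i in seq_along(sizes)) {
      popFreqs[i, ] <- if (fst == 0) pAnc else
        stats::rbeta(m, pAnc * (1 - fst) / fst, (1 - pAnc) * (1 - fst) / fst)
    }
    blocks <- lapply(seq_along(sizes), function(i) {
      matrix(stats::rbinom(sizes[i] * m, 2L, rep(popFreqs[i, ], each = sizes[i])),
             nrow = sizes[i])
    })
  })
  g <- do.call(rbind, blocks)
  labs <- rep(paste0("POP", seq_along(sizes)), sizes)
  geno <- GenotypeData(g,
                       sampleIds = paste0("ind", seq_len(nrow(g))),
                       labels = labs)
  new("SimResult", genotypes = geno, truthLabels = labs,
      ancestralFreqs = pAnc, popFreqs = popFreqs,
      outlierIndex = integer(0), config = config)
}

#' Plant outlying individuals by eigenvector replacement
#'
#' The base genotype matrix is column-centered and decomposed as
#' X = U S V'. For each planted outlier a score row is created whose PC1 and
#' PC2 coordinates are placed at a random sign times
#' `outlierScale x (observed score range)` and whose remaining coordinates
#' are small noise (5% of the corresponding score standard deviation); the
#' row is mapped back to genotype space through V', un-centered, rounded to
#' the nearest of \{0, 1, 2\} and clipped. The resulting individuals are
#' extreme along the leading axes of variation but carry legal genotypes.
#' Base individuals are never altered.
#'
#' @param sim a [SimResult-class] from [simulatePopulations()].
#' @param nOutliers number of outliers to append (default from the config).
#' @param outlierScale score multiple for "extreme values" (default from
#'   the config).
#' @param seed RNG seed for signs and noise (default `config@seed + 1`).
#' @return the augmented [SimResult-class]; outliers are labeled
#'   `"OUTLIER"` and recorded in `outlierIndex`.
#' @export
injectOutliers <- function(sim, nOutliers = NULL, outlierScale = NULL,
                           seed = NULL) {
  stopifnot(is(sim, "SimResult"))
  cfg <- sim@config
  if (is.null(nOutliers)) nOutliers <- cfg@nOutliers
  if (is.null(outlierScale)) outlierScale <- cfg@outlierScale
  if (is.null(seed)) seed <- cfg@seed + 1L
  if (outlierScale <= 0) .argError("outlierScale must be > 0")
  if (nOutliers == 0L) return(sim)
  base <- genotypes(sim@genotypes)
  mu <- colMeans(base)
  xc <- sweep(base, 2L, mu, "-")
  sv <- svd(xc)
  scores <- sv$u %*% diag(sv$d)
  nComp <- ncol(scores)
  rngs <- apply(scores[, 1:2, drop = FALSE], 2L, function(s) diff(range(s)))
  sds <- apply(scores, 2L, stats::sd)
  outScores <- withr::with_seed(as.integer(seed), {
    o <- matrix(stats::rnorm(nOutliers * nComp, 0, rep(0.05 * sds, each = nOutliers)),
                nrow = nOutliers)
    signs <- matrix(sample(c(-1, 1), nOutliers * 2L, replace = TRUE),
                    ncol = 2L)
    o[, 1L] <- signs[, 1L] * outlierScale * rngs[1L]
    o[, 2L] <- signs[, 2L] * outlierScale * rngs[2L]
    o
  })
  rows <- outScores %*% t(sv$v)
  rows <- sweep(rows, 2L, mu, "+")
  rows <- pmin(pmax(round(rows), 0), 2)
  g <- rbind(base, rows)
  n0 <- nrow(base)
  labs <- c(sim@truthLabels, rep("OUTLIER", nOutliers))
  geno <- GenotypeData(g,
                       sampleIds = c(sampleIds(sim@genotypes),
                                     paste0("outlier", seq_len(nOutliers))),
                       snpIds = snpIds(sim@genotypes),
                       snpInfo = snpInfo(sim@genotypes),
                       labels = labs)
  new("SimResult", genotypes = geno, truthLabels = labs,
      ancestralFreqs = sim@ancestralFreqs, popFreqs = sim@popFreqs,
      outlierIndex = seq.int(n0 + 1L, n0 + nOutliers), config = cfg)
}

#' Generate the full benchmark dataset
#'
#' Runs [simulatePopulations()] plus [injectOutliers()] with the default
#' benchmark configuration (10,000 SNPs; populations 250/250/250 at
#' F_ST = 0.005; 10 outliers) and optionally writes the panel as a PLINK
#' binary trio (`simSNP.bed/.bim/.fam`) plus a two-column label file
#' (`simSNP_individuals.txt`: sample id, truth label) readable by
#' [readPlinkBinary()] and [readLabels()].
#'
#' @param seed generator seed.
#' @param dir optional output directory for the PLINK trio and label file.
#' @param config optional [SimConfig-class] overriding the benchmark
#'   defaults (its seed is replaced by `seed`).
#' @return a [SimResult-class].
#' @export
benchmarkDataset <- function(seed = 1L, dir = NULL, config = NULL) {
  if (is.null(config)) config <- SimConfig(seed = seed)
  config@seed <- as.integer(seed)
  validObject(config)
  sim <- simulatePopulations(config)
  sim <- injectOutliers(sim)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writePlinkBinary(sim@genotypes, file.path(dir, "simSNP"))
    utils::write.table(
      data.frame(sampleIds(sim@genotypes), sim@truthLabels),
      file.path(dir, "simSNP_individuals.txt"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  sim
}
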