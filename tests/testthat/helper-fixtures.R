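# shared fixture builders; everything is generated in code at test time

# isotropic 3-D Gaussian blob around `center`
blob3 <- function(n, center = c(0, 0, 0), sd = 1) {
  sweep(matrix(rnorm(n * 3, 0, sd), ncol = 3), 2, center, "+")
}

# oblique unit direction used by the splitter fixtures
obliqueDir <- c(1, 1, 1) / sqrt(3)

# random genotype matrix with optional missingness
randomGenotypes <- function(n, m, naFrac = 0) {
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (naFrac > 0) {
    miss <- sample(length(g), round(naFrac * length(g)))
    g[miss] <- NA
  }
  storage.mode(g) <- "double"
  g
}

# two-population panel: `mNeutral` SNPs at shared frequencies plus
# `mDiv` SNPs with frequency offset `delta` between the groups
twoGroupPanel <- function(n1, n2, mNeutral, mDiv = 0, delta = 0.5) {
  pa <- runif(mNeutral + mDiv, 0.2, 0.8)
  pb <- pa
  if (mDiv > 0) {
    divIdx <- seq_len(mDiv)
    pb[divIdx] <- pmin(pmax(pa[divIdx] + delta, 0.02), 0.98)
  }
  g1 <- sapply(pa, function(p) rbinom(n1, 2, p))
  g2 <- sapply(pb, function(p) rbinom(n2, 2, p))
  list(g1 = g1, g2 = g2,
       divIdx = if (mDiv > 0) seq_len(mDiv) else integer(0))
}

# independent brute-force Hudson estimator: explicit per-SNP loops
bruteForceHudson <- function(g1, g2) {
  m <- ncol(g1)
  num <- den <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    a <- g1[, j][!is.na(g1[, j])]
    b <- g2[, j][!is.na(g2[, j])]
    n1 <- 2 * length(a)
    n2 <- 2 * length(b)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(a) / n1
    p2 <- sum(b) / n2
    num[j] <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den[j] <- p1 * (1 - p2) + p2 * (1 - p1)
  }
  keep <- !is.na(den) & den > 0
  list(num = num, den = den,
       average = sum(num[keep]) / sum(den[keep]))
}

# adjusted Rand index between two partitions (mclust's reference metric)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
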