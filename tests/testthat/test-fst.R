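test_that("Hudson closed forms: fixed difference and equal frequencies", {
  # opposite fixation: correction terms vanish, FST = 1 exactly
  g1 <- matrix(2, 4, 3)
  g2 <- matrix(0, 5, 3)
  res <- hudsonFst(g1, g2)
  expect_identical(res@fst, rep(1, 3))
  expect_identical(fstAverage(res), 1)
  expect_identical(hudsonFstAverage(g1, g2), 1)

  # equal frequencies 0.5 with n1 = n2 = 102 alleles: exact negative value
  a <- matrix(rep(c(0, 2), length.out = 51), ncol = 1)
  res2 <- hudsonFst(a, a)
  handValue <- (-0.25 / 101 - 0.25 / 101) / 0.5
  expect_equal(res2@fst[1], handValue, tolerance = 1e-12)
  expect_lt(res2@fst[1], 0)
})

test_that("identical groups give a non-positive average", {
  withr::local_seed(61)
  g <- randomGenotypes(20, 80)
  expect_lte(hudsonFstAverage(g, g), 0)
})

test_that("estimator matches a brute-force implementation to 1e-12", {
  withr::local_seed(62)
  for (rep in 1:3) {
    g1 <- randomGenotypes(15, 100, naFrac = 0.05)
    g2 <- randomGenotypes(12, 100, naFrac = 0.05)
    ours <- hudsonFst(g1, g2)
    ref <- bruteForceHudson(g1, g2)
    keep <- !ours@excluded
    expect_equal(ours@numerator[keep], ref$num[keep], tolerance = 1e-12)
    expect_equal(ours@denominator[keep], ref$den[keep], tolerance = 1e-12)
    expect_equal(fstAverage(ours), ref$average, tolerance = 1e-12)
    # the average is the ratio of sums of the per-SNP output
    expect_equal(fstAverage(ours),
                 sum(ours@numerator[keep]) / sum(ours@denominator[keep]),
                 tolerance = 1e-15)
  }
})

test_that("estimator is symmetric and excludes undefined SNPs", {
  withr::local_seed(63)
  g1 <- randomGenotypes(10, 50)
  g2 <- randomGenotypes(10, 50)
  # plant a SNP monomorphic for the same allele in both groups
  g1[, 7] <- 0; g2[, 7] <- 0
  a <- hudsonFst(g1, g2)
  b <- hudsonFst(g2, g1)
  expect_equal(a@fst, b@fst, tolerance = 1e-15)
  expect_equal(fstAverage(a), fstAverage(b), tolerance = 1e-15)
  expect_true(a@excluded[7])
  expect_true(is.na(a@fst[7]))
  # all SNPs monomorphic: undefined-result error for the average
  z <- matrix(0, 5, 4)
  expect_error(hudsonFstAverage(z, z), class = "ipclust_value_error")
})

test_that("duplicating individuals drives FST to the no-correction limit", {
  withr::local_seed(64)
  g1 <- randomGenotypes(8, 60)
  g2 <- randomGenotypes(8, 60)
  p1 <- colMeans(g1) / 2
  p2 <- colMeans(g2) / 2
  limitNum <- (p1 - p2)^2
  limitDen <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- limitDen > 0
  limit <- sum(limitNum[keep]) / sum(limitDen[keep])
  errAt <- function(r) {
    abs(hudsonFstAverage(g1[rep(1:8, r), ], g2[rep(1:8, r), ]) - limit)
  }
  expect_lt(errAt(64), errAt(4))
  expect_lt(errAt(64), 1e-2)
})

test_that("topDiscriminators ranks planted high-divergence SNPs first", {
  withr::local_seed(65)
  panel <- twoGroupPanel(n1 = 60, n2 = 60, mNeutral = 200, mDiv = 10,
                         delta = 0.5)
  g <- rbind(panel$g1, panel$g2)
  groups <- rep(c(1, 2), each = 60)
  top <- topDiscriminators(g, groups, 1, 2, nTop = 10)
  planted <- paste0("snp", panel$divIdx)
  expect_gte(sum(top$snpId %in% planted), 9)
  expect_identical(top$rank, 1:10)
  expect_true(all(diff(top$fst) <= 0))
})

test_that("topDiscriminators edge cases: single signal, boundaries, bad ids", {
  # exactly one fixed-difference SNP among identical-frequency SNPs
  g <- cbind(c(2, 2, 2, 0, 0, 0),
             c(1, 0, 1, 1, 0, 1),
             c(2, 0, 2, 2, 0, 2))
  groups <- rep(c("x", "y"), each = 3)
  top <- topDiscriminators(g, groups, "x", "y", nTop = 1)
  expect_identical(top$snpId, "snp1")
  expect_identical(top$fst, 1)
  expect_warning(all3 <- topDiscriminators(g, groups, "x", "y", nTop = 50),
                 regexp = "valid SNPs")
  expect_lte(nrow(all3), 3L)
  expect_error(topDiscriminators(g, groups, "x", "z"),
               class = "ipclust_argument_error")
  # bim-style annotation is carried through
  ann <- data.frame(chromosome = "7", snpId = paste0("rs", 1:3),
                    position = c(10L, 20L, 30L), allele1 = "A", allele2 = "B",
                    stringsAsFactors = FALSE)
  top2 <- topDiscriminators(g, groups, "x", "y", snpAnnotation = ann, nTop = 1)
  expect_identical(top2$snpId, "rs1")
  expect_identical(top2$chromosome, "7")
})
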