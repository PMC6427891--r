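test_that("bed decoding matches a hand-encoded SNP-major fixture", {
  td <- withr::local_tempdir()
  # 2 individuals, 1 SNP: ind1 hom allele1 (bits 00), ind2 het (bits 10)
  # -> payload byte 0b00001000 = 8
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x08)), file.path(td, "hand.bed"))
  writeLines(c("f1 s1 0 0 0 -9", "f2 s2 0 0 0 -9"), file.path(td, "hand.fam"))
  writeLines("1 rs1 0 100 A B", file.path(td, "hand.bim"))
  gd <- readPlinkBinary(file.path(td, "hand.bed"))
  expect_identical(genotypes(gd)[, 1], c(0, 1))
  expect_identical(sampleIds(gd), c("s1", "s2"))
  expect_identical(snpInfo(gd)$allele2, "B")

  # all four 2-bit codes in one byte: 00, 01 (missing), 10, 11
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00 + 4 * 1 + 16 * 2 + 64 * 3)),
           file.path(td, "all.bed"))
  writeLines(sprintf("f%d s%d 0 0 0 -9", 1:4, 1:4), file.path(td, "all.fam"))
  writeLines("1 rs1 0 100 A B", file.path(td, "all.bim"))
  gd4 <- readPlinkBinary(file.path(td, "all.bed"))
  expect_identical(genotypes(gd4)[, 1], c(0, NA, 1, 2))
})

test_that("malformed bed files are rejected with format errors", {
  td <- withr::local_tempdir()
  writeLines("f1 s1 0 0 0 -9", file.path(td, "x.fam"))
  writeLines("1 rs1 0 100 A B", file.path(td, "x.bim"))
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x00)), file.path(td, "x.bed"))
  expect_error(readPlinkBinary(file.path(td, "x.bed")),
               class = "ipclust_format_error")
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0x00)), file.path(td, "x.bed"))
  expect_error(readPlinkBinary(file.path(td, "x.bed")), regexp = "SNP-major")
  # payload truncated: 2 SNPs declared, bytes for 1
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00)), file.path(td, "x.bed"))
  writeLines(c("1 rs1 0 100 A B", "1 rs2 0 200 A B"), file.path(td, "x.bim"))
  expect_error(readPlinkBinary(file.path(td, "x.bed")),
               regexp = "inconsistent")
})

test_that("plink writer/reader round-trip preserves genotypes and metadata", {
  withr::local_seed(3)
  td <- withr::local_tempdir()
  g <- randomGenotypes(7, 13, naFrac = 0.1)
  gd <- GenotypeData(g, labels = paste0("L", 1:7))
  writePlinkBinary(gd, file.path(td, "rt"))
  back <- readPlinkBinary(file.path(td, "rt.bed"))
  expect_identical(genotypes(back), genotypes(gd))
  expect_identical(sampleIds(back), sampleIds(gd))
  expect_identical(snpIds(back), snpIds(gd))
  expect_identical(sampleLabels(back), sampleLabels(gd))
})

test_that("the same cohort in text and PLINK form yields identical genotypes", {
  withr::local_seed(4)
  td <- withr::local_tempdir()
  g <- randomGenotypes(6, 9)
  gd <- GenotypeData(g)
  writePlinkBinary(gd, file.path(td, "eq"))
  # text format: SNPs as rows, individuals as columns
  writeLines(apply(t(g), 1, paste, collapse = " "), file.path(td, "eq.txt"))
  fromText <- readTextGenotypes(file.path(td, "eq.txt"))
  fromBed <- readPlinkBinary(file.path(td, "eq.bed"))
  expect_identical(genotypes(fromText), genotypes(fromBed))
})

test_that("text input transposes, merges files in order, and validates", {
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a.txt")
  writeLines(c("0 1 2", "2 2 0"), f1)
  gd <- readTextGenotypes(f1)
  expect_identical(genotypes(gd), matrix(c(0, 1, 2, 2, 2, 0), nrow = 3))

  f2 <- file.path(td, "b.txt")
  writeLines("1 NA -9", f2)
  both <- readTextGenotypes(c(f1, f2))
  expect_identical(dim(both), c(3L, 3L))
  expect_identical(genotypes(both)[, 3], c(1, NA, NA))
  # merge associativity: concat(A,B) then C == concat(A,B,C)
  f3 <- file.path(td, "c.txt")
  writeLines("9 0 1", f3)
  abc <- readTextGenotypes(c(f1, f2, f3))
  ab <- cbind(genotypes(both), genotypes(readTextGenotypes(f3)))
  expect_identical(genotypes(abc), ab)

  ragged <- file.path(td, "ragged.txt")
  writeLines(c("0 1 2", "1 2"), ragged)
  expect_error(readTextGenotypes(ragged), class = "ipclust_format_error")
  wide <- file.path(td, "wide.txt")
  writeLines("0 1 2 2", wide)
  expect_error(readTextGenotypes(c(f1, wide)),
               class = "ipclust_format_error")
  badTok <- file.path(td, "bad.txt")
  writeLines("0 3 1", badTok)
  expect_error(readTextGenotypes(badTok), class = "ipclust_value_error")
})

test_that("label files honor the 1-based column index and preserve order", {
  td <- withr::local_tempdir()
  f <- file.path(td, "labs.txt")
  writeLines(c("id1 POP1", "id2 POP2"), f)
  labs <- readLabels(f, column = 2)
  expect_identical(labs$label, c("POP1", "POP2"))
  expect_identical(labs$sampleId, c("id1", "id2"))
  expect_error(readLabels(f, column = 3), class = "ipclust_argument_error")

  big <- file.path(td, "big.txt")
  writeLines(sprintf("ind%d POP%d", 1:760, rep(1:4, length.out = 760)), big)
  expect_identical(nrow(readLabels(big, column = 2)), 760L)
})

test_that("cache round-trips exactly, including the missing mask", {
  withr::local_seed(5)
  td <- withr::local_tempdir()
  g <- randomGenotypes(5, 8, naFrac = 0.15)
  gd <- GenotypeData(g, labels = c("a", "b", "a", "b", "a"))
  p <- file.path(td, "rawdata.tsv.gz")
  saveGenotypeCache(gd, p)
  back <- loadGenotypeCache(p)
  expect_identical(genotypes(back), genotypes(gd))
  expect_identical(sampleIds(back), sampleIds(gd))
  expect_identical(sampleLabels(back), sampleLabels(gd))
  expect_identical(snpIds(back), snpIds(gd))

  raw <- readBin(p, "raw", file.size(p))
  trunc <- file.path(td, "trunc.tsv.gz")
  writeBin(raw[1:15], trunc)
  expect_error(loadGenotypeCache(trunc), class = "ipclust_format_error")
  notCache <- file.path(td, "not.tsv.gz")
  con <- gzfile(notCache, "wt"); writeLines(c("x\ty", "1\t2"), con); close(con)
  expect_error(loadGenotypeCache(notCache), class = "ipclust_format_error")
})

test_that("GenotypeData validity rejects malformed containers", {
  expect_error(GenotypeData(matrix(c(0, 5), 2, 1)), regexp = "0, 2")
  expect_error(GenotypeData(matrix(0:1, 2, 2),
                            sampleIds = c("a", "a")),
               regexp = "unique")
  expect_error(GenotypeData(matrix(1, 1, 2)), regexp = "2 individuals")
})
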