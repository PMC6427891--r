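#' Read a PLINK binary genotype trio (bed/bim/fam)
#'
#' Bit-exact reader for PLINK 1 binary files in SNP-major mode. Each SNP is
#' stored as ceiling(N/4) bytes of 2-bit codes, first individual in the two
#' lowest-order bits. Codes are decoded to counts of `allele2` (bim column
#' 6): `00` -> 0, `10` -> 1, `11` -> 2, `01` -> missing. Row order follows
#' the fam file, column order the bim file.
#'
#' @param bedPath,bimPath,famPath paths to the three files. `bimPath` and
#'   `famPath` default to the bed path with the extension swapped.
#' @return a [GenotypeData-class] object; fam individual ids become sample
#'   ids, fam column 6 (phenotype) is kept as the label.
#' @export
readPlinkBinary <- function(bedPath,
                            bimPath = sub("\\.bed$", ".bim", bedPath),
                            famPath = sub("\\.bed$", ".fam", bedPath)) {
  for (p in c(bedPath, bimPath, famPath)) {
    if (!file.exists(p)) .argError("file not found: %s", p)
  }
  fam <- data.table::fread(famPath, header = FALSE, data.table = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 6L) .formatError("fam file must have 6 columns")
  bim <- data.table::fread(bimPath, header = FALSE, data.table = FALSE,
                           colClasses = "character")
  if (ncol(bim) < 6L) .formatError("bim file must have 6 columns")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bedPath, what = "raw", n = file.size(bedPath))
  if (length(raw) < 3L ||
      raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    .formatError("not a PLINK bed file (bad magic bytes)")
  }
  if (raw[3L] != as.raw(0x01)) {
    .formatError("only SNP-major bed files (mode byte 0x01) are supported")
  }
  bytesPerSnp <- ceiling(n / 4)
  if (length(raw) - 3L != bytesPerSnp * m) {
    .formatError("bed payload size %d inconsistent with %d individuals x %d SNPs",
                 length(raw) - 3L, n, m)
  }
  geno <- .decodeBedPayload(raw[-(1:3)], n, m)
  info <- data.frame(chromosome = bim[[1L]], snpId = bim[[2L]],
                     position = as.integer(bim[[4L]]),
                     allele1 = bim[[5L]], allele2 = bim[[6L]],
                     stringsAsFactors = FALSE)
  GenotypeData(geno, sampleIds = fam[[2L]], snpIds = bim[[2L]],
               snpInfo = info, labels = fam[[6L]])
}

# payload -> N x M matrix of 0/1/2/NA (counts of allele2)
.decodeBedPayload <- function(payload, n, m) {
  b <- as.integer(payload)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  dim(codes) <- c(4L * ceiling(n / 4), m)
  codes <- codes[seq_len(n), , drop = FALSE]
  map <- c(0, NA_real_, 1, 2) # codes 0b00, 0b01, 0b10, 0b11
  out <- map[codes + 1L]
  dim(out) <- c(n, m)
  out
}

#' Write a PLINK binary genotype trio (bed/bim/fam)
#'
#' Inverse of [readPlinkBinary()]; genotypes must be integral 0/1/2 or
#' missing. fam is written with FID = IID = sample id, phenotype = label
#' (`-9` when absent).
#'
#' @param x a [GenotypeData-class] object.
#' @param prefix output path prefix; `prefix.bed`, `prefix.bim`,
#'   `prefix.fam` are written.
#' @return the prefix, invisibly.
#' @export
writePlinkBinary <- function(x, prefix) {
  g <- genotypes(x)
  v <- g[!is.na(g)]
  if (any(v != round(v))) {
    .valueError("PLINK output requires integral genotypes (impute/round first)")
  }
  info <- snpInfo(x)
  fam <- data.frame(sampleIds(x), sampleIds(x), 0L, 0L, 0L,
                    ifelse(is.na(sampleLabels(x)), "-9", sampleLabels(x)))
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  bim <- data.frame(info$chromosome, info$snpId, 0L, info$position,
                    info$allele1, info$allele2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(.encodeBedPayload(g), con)
  invisible(prefix)
}

.encodeBedPayload <- function(g) {
  n <- nrow(g)
  m <- ncol(g)
  # additive count -> 2-bit code (0->00, 1->10, 2->11, NA->01)
  codeOf <- c(0L, 2L, 3L)
  codes <- matrix(1L, nrow = 4L * ceiling(n / 4), ncol = m)
  gi <- g
  gi[is.na(gi)] <- -1
  sel <- gi >= 0
  codesTop <- matrix(1L, nrow = n, ncol = m)
  codesTop[sel] <- codeOf[gi[sel] + 1L]
  codes[seq_len(n), ] <- codesTop
  # NA-fill rows beyond n are padding; PLINK pads with zero bits
  if (nrow(codes) > n) codes[(n + 1L):nrow(codes), ] <- 0L
  dim(codes) <- c(4L, length(codes) / 4L)
  bytes <- codes[1L, ] + 4L * codes[2L, ] + 16L * codes[3L, ] + 64L * codes[4L, ]
  as.raw(bytes)
}

#' Read additive-coded genotypes from delimited text files
#'
#' Text layout: one row per SNP, one column per individual, fields separated
#' by spaces or tabs. Several files (a large panel split for loading) are
#' row-concatenated in the order given, so all files must have the same
#' number of columns. The result is transposed to the package's internal
#' individuals x SNPs orientation.
#'
#' Missing genotypes may be written `NA`, `-9`, or `9`; any other token
#' outside \{0, 1, 2\} is an error. Which allele the count refers to is the
#' caller's convention; the package treats it as the `allele2` count.
#'
#' @param paths character vector of file paths, in concatenation order.
#' @param sampleIds,labels optional per-individual annotation.
#' @return a [GenotypeData-class] object.
#' @export
readTextGenotypes <- function(paths, sampleIds = NULL, labels = NULL) {
  blocks <- lapply(paths, .readTextBlock)
  ncols <- vapply(blocks, ncol, 1L)
  if (length(unique(ncols)) != 1L) {
    .formatError("all genotype files must have the same number of individuals (got %s)",
                 paste(ncols, collapse = ", "))
  }
  snpBySample <- do.call(rbind, blocks)
  GenotypeData(t(snpBySample), sampleIds = sampleIds, labels = labels)
}

.readTextBlock <- function(path) {
  if (!file.exists(path)) .argError("file not found: %s", path)
  nf <- unique(utils::count.fields(path))
  if (length(nf) != 1L) {
    .formatError("ragged rows in %s (field counts: %s)", path,
                 paste(nf, collapse = ", "))
  }
  x <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "character"))
  x[x %in% c("NA", "-9", "9")] <- NA_character_
  bad <- !is.na(x) & !(x %in% c("0", "1", "2"))
  if (any(bad)) {
    .valueError("invalid genotype token(s) in %s: %s", path,
                paste(unique(x[bad])[1:min(3, sum(bad))], collapse = ", "))
  }
  storage.mode(x) <- "double"
  unname(x)
}

#' Read a sample-label sidecar file
#'
#' One line per individual, whitespace-delimited; the label is taken from
#' the given 1-based column. Column 1 is used as the sample id.
#'
#' @param path path to the label file.
#' @param column 1-based index of the label column.
#' @param header logical; does the file start with a header line?
#' @return data.frame with columns `sampleId` and `label`, file order
#'   preserved.
#' @export
readLabels <- function(path, column = 2L, header = FALSE) {
  if (!file.exists(path)) .argError("file not found: %s", path)
  if (column < 1L) .argError("column must be >= 1")
  x <- utils::read.table(path, header = header, colClasses = "character")
  if (column > ncol(x)) {
    .argError("label column %d out of range (file has %d columns)",
              column, ncol(x))
  }
  data.frame(sampleId = x[[1L]], label = x[[column]],
             stringsAsFactors = FALSE)
}

#' Save / load a genotype run cache
#'
#' The cache is a gzip-compressed tab-separated table: columns `sample_id`,
#' `label`, then one column per SNP (named by SNP id), one row per
#' individual, missing genotypes written as `NA`. It is a documented,
#' language-neutral format intended for fast re-analysis; a round trip
#' reproduces the genotype matrix, the missing mask, and sample order
#' exactly. SNP annotation beyond the id is not cached.
#'
#' @param x a [GenotypeData-class] object.
#' @param path output file (conventionally `rawdata.tsv.gz`).
#' @return `saveGenotypeCache`: the path, invisibly. `loadGenotypeCache`: a
#'   [GenotypeData-class] object.
#' @export
saveGenotypeCache <- function(x, path) {
  g <- genotypes(x)
  colnames(g) <- snpIds(x)
  dt <- data.table::data.table(sample_id = sampleIds(x),
                               label = sampleLabels(x))
  dt <- cbind(dt, data.table::as.data.table(g))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA",
                     compress = "gzip")
  invisible(path)
}

#' @rdname saveGenotypeCache
#' @export
loadGenotypeCache <- function(path) {
  if (!file.exists(path)) .argError("file not found: %s", path)
  dt <- tryCatch({
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) < 2L) .formatError("cache %s is empty or truncated", path)
    data.table::fread(text = lines, sep = "\t", header = TRUE,
                      data.table = FALSE)
  },
    error = function(e) .formatError("corrupt cache %s: %s", path,
                                     conditionMessage(e)),
    warning = function(w) .formatError("corrupt cache %s: %s", path,
                                       conditionMessage(w)))
  if (ncol(dt) < 3L ||
      !identical(names(dt)[1:2], c("sample_id", "label"))) {
    .formatError("not an ipclust cache: %s", path)
  }
  g <- as.matrix(dt[, -(1:2), drop = FALSE])
  storage.mode(g) <- "double"
  v <- g[!is.na(g)]
  if (length(v) && any(!(v %in% c(0, 1, 2)))) {
    .formatError("cache %s contains invalid genotype values", path)
  }
  labs <- as.character(dt[[2L]])
  GenotypeData(g, sampleIds = as.character(dt[[1L]]),
               snpIds = colnames(dt)[-(1:2)], labels = labs)
}
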