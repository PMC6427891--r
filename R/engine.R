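#' Iterative pruning of a genotype panel into genetically similar subgroups
#'
#' The driver of the package. Starting from the full sample, each node of a
#' recursion tree is processed as follows:
#'
#' 1. nodes smaller than `2 * minGroupSize`, or at `maxDepth`, stop
#'    (reasons `min_size` / `max_depth`);
#' 2. the node's genotype sub-matrix is re-normalized within the node
#'    (allele frequencies recomputed on the subset) and its top PCs
#'    computed;
#' 3. if the [eigenFit()] statistic of the eigenvalue spectrum is below
#'    `eigenfitCutoff` the node stops (reason `eigenfit`): the spectrum
#'    carries no evidence of further substructure;
#' 4. [rubikSplit()] is attempted on PC1-PC3; if it finds no split,
#'    [cemCluster()] (Gaussian mixture, up to 3 components) is attempted on
#'    the same scores; if neither proposes >= 2 groups the node stops
#'    (reason `no_split`);
#' 5. the proposed children are vetted with [hudsonFstAverage()]: if the
#'    largest pairwise F_ST among children is below `fstThreshold` the split
#'    is rejected and the node stops (reason `fst`); otherwise the engine
#'    recurses into every child.
#'
#' After the recursion, terminal nodes smaller than `minGroupSize` are
#' reclassified as outlier groups ([classifyOutliers()]): clusters
#' containing few members are reported as outlying individuals rather than
#' populations. Every sample ends up in exactly one final or outlier group.
#'
#' The only stochastic step is the mixture initialization, which is seeded
#' per node from `seed`, so a run is fully reproducible.
#'
#' @param x a [GenotypeData-class] object or numeric genotype matrix.
#'   Residual missing genotypes are imputed with [imputeMedian()].
#' @param labels optional per-sample annotation labels (reporting only);
#'   defaults to the labels carried by `x`.
#' @param minGroupSize minimum size of a final group; smaller terminal
#'   groups become outlier groups (default 20).
#' @param fstThreshold minimum largest pairwise Hudson F_ST between proposed
#'   children for a split to be retained (default 8e-4).
#' @param eigenfitCutoff stop when the maximum eigenvalue log-gap falls
#'   below this value (default 0.15).
#' @param maxDepth recursion safety bound (default 10).
#' @param scaleMode normalization mode used at every node (default
#'   `"eigenstrat"`).
#' @param nPCs number of components computed per node (default 10; the
#'   splitters consume the first 3).
#' @param angleStep,gapFactor,minGapPoints,maxGroups parameters of
#'   [rubikSplit()].
#' @param mixtureStarts random initializations per mixture fit.
#' @param covariates optional covariate table; when supplied, clustering
#'   runs on [regressOutCovariates()] residuals (patient-sample mode) while
#'   F_ST vetting still uses the raw imputed genotypes.
#' @param seed run-level seed (default 1).
#' @return a [ClusterTree-class] object.
#' @examples
#' sim <- simulatePopulations(SimConfig(nSnps = 600, popSizes = c(60, 60),
#'                                      fst = 0.05, seed = 7))
#' tree <- iterativePrune(sim@genotypes, minGroupSize = 10, seed = 7)
#' table(groupAssignments(tree)$group, sim@truthLabels)
#' @export
iterativePrune <- function(x, labels = NULL,
                           minGroupSize = 20L, fstThreshold = 8e-4,
                           eigenfitCutoff = 0.15, maxDepth = 10L,
                           scaleMode = c("eigenstrat", "center"),
                           nPCs = 10L, angleStep = 10, gapFactor = 3,
                           minGapPoints = 1L, maxGroups = 5L,
                           mixtureStarts = 10L, covariates = NULL,
                           seed = 1L) {
  scaleMode <- match.arg(scaleMode)
  if (is(x, "GenotypeData")) {
    if (is.null(labels)) labels <- sampleLabels(x)
    ids <- sampleIds(x)
  } else {
    ids <- rownames(x)
  }
  g <- .asGenoMatrix(x)
  if (nrow(g) < 2L) .argError("need at least 2 individuals")
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(g)))
  if (is.null(labels)) labels <- rep(NA_character_, nrow(g))
  if (anyNA(g)) g <- imputeMedian(g)
  clusterMat <- if (!is.null(covariates)) {
    regressOutCovariates(g, covariates)
  } else g
  cfg <- list(minGroupSize = as.integer(minGroupSize),
              fstThreshold = fstThreshold,
              eigenfitCutoff = eigenfitCutoff,
              maxDepth = as.integer(maxDepth), scaleMode = scaleMode,
              nPCs = as.integer(nPCs), angleStep = angleStep,
              gapFactor = gapFactor, minGapPoints = as.integer(minGapPoints),
              maxGroups = as.integer(maxGroups),
              mixtureStarts = as.integer(mixtureStarts),
              covariatesUsed = !is.null(covariates),
              seed = as.integer(seed))

  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$members <- list()
  env$pcs <- list()
  env$nextId <- 1L

  record <- function(parentId, depth, idx) {
    id <- env$nextId
    env$nextId <- id + 1L
    env$members[[id]] <- idx
    env$pcs[id] <- list(NULL)
    env$rows[[id]] <- data.frame(nodeId = id, parentId = parentId,
                                 depth = depth, size = length(idx),
                                 status = "terminal",
                                 stopReason = NA_character_,
                                 method = NA_character_,
                                 stringsAsFactors = FALSE)
    id
  }
  setNode <- function(id, status = NULL, reason = NULL, method = NULL) {
    if (!is.null(status)) env$rows[[id]]$status <- status
    if (!is.null(reason)) env$rows[[id]]$stopReason <- reason
    if (!is.null(method)) env$rows[[id]]$method <- method
  }

  recurse <- function(idx, parentId, depth) {
    id <- record(parentId, depth, idx)
    size <- length(idx)
    if (size < 2L * cfg$minGroupSize) {
      setNode(id, reason = "min_size")
      return(invisible(NULL))
    }
    if (depth >= cfg$maxDepth) {
      setNode(id, reason = "max_depth")
      return(invisible(NULL))
    }
    sub <- clusterMat[idx, , drop = FALSE]
    k <- min(cfg$nPCs, size - 1L, ncol(sub))
    pc <- topPCs(normalizeGenotypes(sub, cfg$scaleMode), k)
    env$pcs[[id]] <- pc
    ef <- eigenFit(eigenvalues(pc))
    if (is.na(ef$statistic) || ef$statistic < cfg$eigenfitCutoff) {
      setNode(id, reason = "eigenfit")
      return(invisible(NULL))
    }
    d <- min(3L, k)
    s3 <- pcaScores(pc)[, seq_len(d), drop = FALSE]
    labs <- if (d >= 3L) {
      rubikSplit(s3, angleStep = cfg$angleStep, gapFactor = cfg$gapFactor,
                 minGapPoints = cfg$minGapPoints, maxGroups = cfg$maxGroups)
    } else rep(1L, size)
    method <- "rubik"
    if (max(labs) == 1L) {
      mix <- cemCluster(s3, maxK = 3L, nStarts = cfg$mixtureStarts,
                        seed = cfg$seed + id)
      labs <- mix$labels
      method <- "cem"
    }
    if (max(labs) == 1L) {
      setNode(id, reason = "no_split")
      return(invisible(NULL))
    }
    parts <- split(idx, labs)
    maxFst <- -Inf
    for (a in seq_along(parts)) {
      for (b in seq_len(a - 1L)) {
        f <- tryCatch(
          hudsonFstAverage(g[parts[[a]], , drop = FALSE],
                           g[parts[[b]], , drop = FALSE]),
          error = function(e) -Inf)
        if (is.finite(f) && f > maxFst) maxFst <- f
      }
    }
    if (maxFst < cfg$fstThreshold) {
      setNode(id, reason = "fst", method = method)
      return(invisible(NULL))
    }
    setNode(id, status = "intermediate", method = method)
    for (p in parts) recurse(p, id, depth + 1L)
    invisible(NULL)
  }

  recurse(seq_len(nrow(g)), NA_integer_, 0L)

  tree <- new("ClusterTree",
              nodes = do.call(rbind, env$rows),
              members = env$members,
              pcs = env$pcs,
              assignments = data.frame(sampleId = ids,
                                       label = as.character(labels),
                                       group = NA_integer_,
                                       nodeId = NA_integer_,
                                       stringsAsFactors = FALSE),
              finalGroups = integer(0),
              outlierGroups = integer(0),
              config = cfg)
  classifyOutliers(tree, cfg$minGroupSize)
}

#' Reclassify small terminal groups as outliers and number the groups
#'
#' Terminal nodes with fewer than `minGroupSize` members get status
#' `outlier`; the remaining terminal nodes are the final groups. Final
#' groups are numbered first (1..G, in tree order), outlier groups after
#' them (G+1..), and the per-sample assignment table is rebuilt.
#'
#' @param tree a [ClusterTree-class] object.
#' @param minGroupSize the outlier cutoff; defaults to the value used for
#'   the run.
#' @return the updated [ClusterTree-class].
#' @export
classifyOutliers <- function(tree, minGroupSize = NULL) {
  if (is.null(minGroupSize)) minGroupSize <- tree@config$minGroupSize
  nodes <- tree@nodes
  leaf <- nodes$status != "intermediate"
  nodes$status[leaf] <- ifelse(nodes$size[leaf] < minGroupSize,
                               "outlier", "terminal")
  finals <- nodes$nodeId[leaf & nodes$status == "terminal"]
  outs <- nodes$nodeId[leaf & nodes$status == "outlier"]
  asg <- tree@assignments
  groupNo <- 0L
  for (nid in c(finals, outs)) {
    groupNo <- groupNo + 1L
    idx <- tree@members[[nid]]
    asg$group[idx] <- groupNo
    asg$nodeId[idx] <- nid
  }
  tree@nodes <- nodes
  tree@assignments <- asg
  tree@finalGroups <- as.integer(finals)
  tree@outlierGroups <- as.integer(outs)
  tree
}

#' @rdname ClusterTree-class
#' @export
setMethod("treeNodes", "ClusterTree", function(x) x@nodes)

#' @rdname ClusterTree-class
#' @export
setMethod("groupAssignments", "ClusterTree", function(x) x@assignments)

#' @rdname ClusterTree-class
#' @export
setMethod("finalGroups", "ClusterTree", function(x) x@finalGroups)

#' @rdname ClusterTree-class
#' @export
setMethod("outlierGroups", "ClusterTree", function(x) x@outlierGroups)

setMethod("show", "ClusterTree", function(object) {
  nodes <- object@nodes
  cat("ClusterTree:", nrow(nodes), "nodes,",
      length(object@finalGroups), "final group(s),",
      length(object@outlierGroups), "outlier group(s)\n")
  finalSizes <- nodes$size[match(object@finalGroups, nodes$nodeId)]
  if (length(finalSizes)) {
    cat("  final group sizes:", paste(finalSizes, collapse = ", "), "\n")
  }
  nOut <- sum(nodes$size[match(object@outlierGroups, nodes$nodeId)])
  if (length(object@outlierGroups)) {
    cat("  outlying individuals:", nOut, "\n")
  }
})

#' Write the results of a pruning run to a directory
#'
#' Writes `groups.txt` (sample_id, label, group, node_id; one row per
#' sample), `tree.txt` (the node table), `run_log.txt` (configuration and
#' per-node decisions) and, for every intermediate node with >= 3 computed
#' components, a three-view PC scatter plot (`node_<id>_3views.pdf`)
#' colored by the eventual group membership of the node's samples.
#' `groups.txt` and `tree.txt` are plain deterministic text: re-running the
#' engine on identical input with the same seed reproduces them
#' byte-identically.
#'
#' @param tree a [ClusterTree-class] object.
#' @param outDir output directory (created recursively if needed).
#' @param plots logical; write the per-node PC plots (default TRUE)?
#' @return `outDir`, invisibly.
#' @export
exportResults <- function(tree, outDir, plots = TRUE) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || !dir.exists(outDir)) .stopf("cannot create directory %s", outDir)
  probe <- file.path(outDir, ".write_probe")
  okw <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                  error = function(e) FALSE)
  if (!isTRUE(okw)) .stopf("directory %s is not writable", outDir)
  unlink(probe)

  asg <- tree@assignments
  names(asg) <- c("sample_id", "label", "group", "node_id")
  utils::write.table(asg, file.path(outDir, "groups.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  nodes <- tree@nodes
  names(nodes) <- c("node_id", "parent_id", "depth", "size", "status",
                    "stop_reason", "method")
  utils::write.table(nodes, file.path(outDir, "tree.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")

  logLines <- c("ipclust run log",
                paste0("config: ",
                       paste(names(tree@config), unlist(tree@config),
                             sep = "=", collapse = " ")),
                sprintf("final groups: %s",
                        paste(tree@finalGroups, collapse = ", ")),
                sprintf("outlier groups: %s",
                        paste(tree@outlierGroups, collapse = ", ")),
                "per-node decisions:",
                sprintf("  node %d (size %d, depth %d): %s%s%s",
                        nodes$node_id, nodes$size, nodes$depth, nodes$status,
                        ifelse(is.na(nodes$stop_reason), "",
                               paste0(", stop=", nodes$stop_reason)),
                        ifelse(is.na(nodes$method), "",
                               paste0(", split=", nodes$method))))
  writeLines(logLines, file.path(outDir, "run_log.txt"))

  if (plots) {
    for (nid in nodes$node_id[nodes$status == "intermediate"]) {
      pc <- tree@pcs[[nid]]
      if (is.null(pc) || ncol(pcaScores(pc)) < 3L) next
      idx <- tree@members[[nid]]
      grp <- tree@assignments$group[idx]
      grDevices::pdf(file.path(outDir, sprintf("node_%d_3views.pdf", nid)),
                     width = 10.5, height = 3.8)
      plot3Views(pcaScores(pc), grp,
                 main = sprintf("node %d", nid))
      grDevices::dev.off()
    }
  }
  invisible(outDir)
}
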