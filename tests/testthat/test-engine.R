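# small structured panel used across engine tests: two populations at a
# comfortably detectable divergence plus a couple of planted outliers
engineFixture <- function(seed = 81) {
  cfg <- SimConfig(nSnps = 1200, popSizes = c(60L, 60L), fst = 0.05,
                   nOutliers = 2L, seed = seed)
  injectOutliers(simulatePopulations(cfg))
}

test_that("a homogeneous sample is left as a single final group", {
  sim <- simulatePopulations(SimConfig(nSnps = 3000, popSizes = 150L,
                                       fst = 0, nOutliers = 0, seed = 82))
  tree <- iterativePrune(sim@genotypes, seed = 82)
  expect_identical(length(finalGroups(tree)), 1L)
  expect_identical(length(outlierGroups(tree)), 0L)
  expect_identical(treeNodes(tree)$stopReason[1], "eigenfit")
})

test_that("structured data are split into the generating populations", {
  sim <- engineFixture()
  tree <- iterativePrune(sim@genotypes, minGroupSize = 10L, seed = 81)
  expect_identical(length(finalGroups(tree)), 2L)
  asg <- groupAssignments(tree)
  nonout <- setdiff(seq_len(nrow(asg)), sim@outlierIndex)
  expect_gte(ari(asg$group[nonout], sim@truthLabels[nonout]), 0.99)
  expect_true(all(asg$nodeId[sim@outlierIndex] %in% outlierGroups(tree)))
  # partition invariant: every sample in exactly one final/outlier group
  expect_false(anyNA(asg$group))
  nodes <- treeNodes(tree)
  leafIds <- c(finalGroups(tree), outlierGroups(tree))
  expect_identical(sum(nodes$size[match(leafIds, nodes$nodeId)]),
                   nrow(asg))
})

test_that("stopping bookkeeping is sound across the tree", {
  sim <- engineFixture()
  tree <- iterativePrune(sim@genotypes, minGroupSize = 10L, seed = 81)
  nodes <- treeNodes(tree)
  leaves <- nodes[nodes$status != "intermediate", ]
  inner <- nodes[nodes$status == "intermediate", ]
  # every stopped node records exactly one reason; inner nodes none
  expect_false(anyNA(leaves$stopReason))
  expect_true(all(is.na(inner$stopReason)))
  # every intermediate node has >= 2 children
  kids <- table(nodes$parentId)
  expect_true(all(kids[as.character(inner$nodeId)] >= 2))
  # children partition the parent
  for (pid in inner$nodeId) {
    cids <- nodes$nodeId[!is.na(nodes$parentId) & nodes$parentId == pid]
    expect_identical(sort(unlist(tree@members[cids])),
                     sort(tree@members[[pid]]))
  }
})

test_that("an unattainable FST threshold vetoes any split of the root", {
  sim <- engineFixture()
  tree <- iterativePrune(sim@genotypes, fstThreshold = 10, seed = 81)
  nodes <- treeNodes(tree)
  expect_identical(nrow(nodes), 1L)
  expect_identical(nodes$stopReason[1], "fst")
  expect_identical(length(finalGroups(tree)), 1L)
})

test_that("classifyOutliers relabels small terminal groups", {
  # hand-built tree with terminal sizes 250/250/250/6/4
  sizes <- c(250L, 250L, 250L, 6L, 4L)
  bounds <- cumsum(c(0L, sizes))
  members <- c(list(seq_len(760L)),
               lapply(1:5, function(i) seq.int(bounds[i] + 1L, bounds[i + 1L])))
  nodes <- data.frame(nodeId = 1:6, parentId = c(NA, rep(1L, 5)),
                      depth = c(0L, rep(1L, 5)), size = c(760L, sizes),
                      status = c("intermediate", rep("terminal", 5)),
                      stopReason = c(NA, rep("eigenfit", 5)),
                      method = c("rubik", rep(NA, 5)),
                      stringsAsFactors = FALSE)
  tree <- new("ClusterTree", nodes = nodes, members = members,
              pcs = rep(list(NULL), 6),
              assignments = data.frame(sampleId = paste0("s", 1:760),
                                       label = NA_character_,
                                       group = NA_integer_,
                                       nodeId = NA_integer_,
                                       stringsAsFactors = FALSE),
              finalGroups = integer(0), outlierGroups = integer(0),
              config = list(minGroupSize = 20L))
  out <- classifyOutliers(tree, 20L)
  expect_identical(length(finalGroups(out)), 3L)
  expect_identical(length(outlierGroups(out)), 2L)
  expect_identical(sum(treeNodes(out)$size[match(outlierGroups(out),
                                                 treeNodes(out)$nodeId)]), 10L)
  # all groups at or above the cutoff: no outliers
  allBig <- classifyOutliers(tree, 4L)
  expect_identical(length(outlierGroups(allBig)), 0L)
  # cutoff 1: no group can ever be an outlier
  expect_identical(length(outlierGroups(classifyOutliers(tree, 1L))), 0L)
  # final groups numbered before outlier groups
  asg <- groupAssignments(out)
  expect_identical(sort(unique(asg$group)), 1:5)
  expect_true(all(asg$group[bounds[4] + 1:10] %in% 4:5))
})

test_that("identical input and seed reproduce exports byte-identically", {
  sim <- engineFixture()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  t1 <- iterativePrune(sim@genotypes, labels = sim@truthLabels,
                       minGroupSize = 10L, seed = 7)
  t2 <- iterativePrune(sim@genotypes, labels = sim@truthLabels,
                       minGroupSize = 10L, seed = 7)
  exportResults(t1, d1, plots = FALSE)
  exportResults(t2, d2, plots = FALSE)
  for (f in c("groups.txt", "tree.txt")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})

test_that("exports reproduce the in-memory tables and draw the PC plots", {
  sim <- engineFixture()
  tree <- iterativePrune(sim@genotypes, labels = sim@truthLabels,
                         minGroupSize = 10L, seed = 7)
  td <- withr::local_tempdir()
  exportResults(tree, td)
  groups <- read.table(file.path(td, "groups.txt"), header = TRUE, sep = "\t")
  expect_identical(nrow(groups), nrow(genotypes(sim@genotypes)))
  # cross-tabulating the written file reproduces the in-memory table
  asg <- groupAssignments(tree)
  expect_identical(table(groups$label, groups$group),
                   table(asg$label, asg$group))
  nodes <- read.table(file.path(td, "tree.txt"), header = TRUE, sep = "\t")
  expect_identical(nrow(nodes), nrow(treeNodes(tree)))
  expect_true(file.exists(file.path(td, "run_log.txt")))
  inner <- treeNodes(tree)$nodeId[treeNodes(tree)$status == "intermediate"]
  expect_true(all(file.exists(
    file.path(td, sprintf("node_%d_3views.pdf", inner)))))
})

test_that("plot3Views validates its input and handles a single group", {
  expect_error(plot3Views(matrix(0, 5, 2)), class = "ipclust_argument_error")
  expect_error(plot3Views(matrix(0, 5, 3), groups = 1:2),
               class = "ipclust_argument_error")
  td <- withr::local_tempdir()
  f <- file.path(td, "p.pdf")
  grDevices::pdf(f)
  expect_no_error(plot3Views(matrix(rnorm(60), 20, 3)))
  expect_no_error(plot3Views(matrix(rnorm(60), 20, 3),
                             groups = rep(1:2, each = 10)))
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
})

test_that("covariate regression mode removes a known confounder axis", {
  withr::local_seed(83)
  # two 'ancestry' groups whose separation is fully explained by a covariate
  sim <- simulatePopulations(SimConfig(nSnps = 1500, popSizes = c(60L, 60L),
                                       fst = 0.08, nOutliers = 0, seed = 83))
  g <- genotypes(sim@genotypes)
  anc <- as.numeric(sim@truthLabels == "POP2")
  tree <- iterativePrune(g, covariates = cbind(anc), seed = 83)
  # with the ancestry axis regressed out, no residual structure remains
  expect_identical(length(finalGroups(tree)), 1L)
  # without regression the same data split into the two populations
  tree2 <- iterativePrune(g, seed = 83)
  expect_identical(length(finalGroups(tree2)), 2L)
})
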