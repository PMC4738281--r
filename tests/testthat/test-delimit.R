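test_that("threshold clustering lumps a shallow cloud and splits clean clades", {
  # all pairwise distances tiny: one species, accepted at the root
  ids <- sprintf("s%d", 1:5)
  dm <- matrix(0.004, 5, 5, dimnames = list(ids, ids)); diag(dm) <- 0
  tr <- buildUPGMA(dm)
  expect_equal(nSpecies(clusterByThreshold(tr, dm)), 1L)

  # two clean clades, high support: two species; brute-force condition check
  dm2 <- makeTwoClusterMatrix(4, 4, intra = 0.003, inter = 0.06)
  tr2 <- buildUPGMA(dm2)
  part <- clusterByThreshold(tr2, dm2, distThreshold = 0.02, supportMin = 70)
  expect_equal(nSpecies(part), 2L)
  a <- speciesAssignments(part)
  g1 <- names(a)[a == a[[1]]]
  g2 <- setdiff(names(a), g1)
  expect_lt(max(dm2[g1, g1]), 0.02)
  expect_lt(max(dm2[g2, g2]), 0.02)
  expect_gte(min(dm2[g1, g2]), 0.02)
})

test_that("threshold clustering respects the bootstrap-support condition", {
  dm2 <- makeTwoClusterMatrix(4, 4, intra = 0.003, inter = 0.06)
  tr2 <- buildUPGMA(dm2)
  # force supports below the cutoff on every internal node: the two clades
  # fail condition (c), traversal recurses to tips within each clade
  tr2$node.label <- rep("10", tr2$Nnode)
  part <- clusterByThreshold(tr2, dm2, distThreshold = 0.02, supportMin = 70)
  expect_equal(nSpecies(part), 8L)
})

test_that("threshold clustering extremes: all singletons / one species", {
  ds <- defaultDataset()
  sub <- BarcodeAlignment(as.character(ds@alignment)[seq(1, 100, 4)])
  dm <- k2pMatrix(sub)
  tr <- buildNJ(dm)
  allSingle <- clusterByThreshold(tr, dm, distThreshold = 0, supportMin = 0)
  expect_equal(nSpecies(allSingle), nrow(dm))
  allOne <- clusterByThreshold(tr, dm, distThreshold = 1, supportMin = 0)
  expect_equal(nSpecies(allOne), 1L)
  # coverage: every sample appears exactly once
  expect_setequal(sampleIds(allSingle), rownames(dm))
  expect_error(clusterByThreshold(tr, dm[1:10, 1:10]), "match")
})

test_that("ABGD finds a planted barcode gap and recurses no further", {
  dm <- makeTwoClusterMatrix(5, 5, intra = 0.004, inter = 0.09)
  res <- abgdPartitions(dm, abgdConfig())
  for (el in res) {
    if (el$prior >= 0.005 && el$prior <= 0.05)
      expect_equal(nSpecies(el$partition), 2L,
                   label = sprintf("prior %.4g", el$prior))
  }
  expect_equal(nSpecies(abgdModalPartition(res)), 2L)
  # the gap location is verifiable on the sorted distance vector
  d <- sort(dm[upper.tri(dm)])
  gapLow <- max(d[d < 0.05]); gapHigh <- min(d[d > 0.05])
  expect_gt(gapHigh - gapLow, 0.05)
})

test_that("ABGD returns one group when no distance exceeds the prior", {
  ids <- sprintf("s%d", 1:6)
  dm <- matrix(0.004, 6, 6, dimnames = list(ids, ids)); diag(dm) <- 0
  jit <- outer(1:6, 1:6, function(i, j) 1e-5 * ((i + j) %% 3))
  dm <- dm + (jit + t(jit)) / 2; diag(dm) <- 0
  res <- suppressMessages(abgdPartitions(dm, abgdConfig()))
  for (el in res) {
    if (el$prior >= 0.005)
      expect_equal(nSpecies(el$partition), 1L)
  }
  expect_error(abgdPartitions(dm[1:2, 1:2]), "3 samples")
})

test_that("abgdConfig validates its bounds", {
  expect_error(abgdConfig(pMin = 0.2, pMax = 0.1), "pMin")
  expect_error(abgdConfig(relativeGapX = 0), "positive")
})

test_that("GMYC recovers the true species count on clean data", {
  # the regime this checks is species divergence far above coalescent
  # depth: theta 5e-4 against species ages >= 0.025
  ds <- generateDataset(simulationConfig(nSpecies = 10L, theta = 5e-4),
                        seed = 303L)
  fit <- gmycFit(ds@geneTree)
  expect_equal(fit@entities, 10L)
  expect_equal(nSpecies(gmycPartition(fit)), 10L)
  expect_setequal(sampleIds(gmycPartition(fit)), sampleIds(ds@alignment))
  # partition equals the truth up to label renaming
  truth <- speciesAssignments(ds@partition)
  est <- speciesAssignments(gmycPartition(fit))[names(truth)]
  expect_equal(length(unique(paste(truth, est))), 10L)
  # the LR test is decisive on structured data
  expect_lt(fit@pValue, 1e-4)
  expect_true(fit@ciEntities[1] <= fit@entities &&
                fit@entities <= fit@ciEntities[2])
})

test_that("GMYC invariants: nesting, CI, input validation", {
  set.seed(8)
  tr <- ape::rcoal(25)
  fit <- gmycFit(tr)
  expect_gte(fit@lnLGmyc, fit@lnLNull)
  expect_gte(fit@statistic, 0)
  expect_equal(fit@statistic, 2 * (fit@lnLGmyc - fit@lnLNull),
               tolerance = 1e-9)
  expect_true(all(diff(fit@profile$threshold) < 0))
  # non-ultrametric and non-binary inputs are rejected
  bad <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  expect_error(gmycFit(bad), "ultrametric")
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(gmycFit(poly), "binary|rooted")
})

test_that("GMYC report writer emits the fitted quantities", {
  set.seed(9)
  fit <- gmycFit(ape::rcoal(12))
  f <- withr::local_tempfile(fileext = ".txt")
  p <- withr::local_tempfile(fileext = ".tsv")
  writeGmycReport(fit, f, p)
  rep <- readLines(f)
  expect_true(any(grepl("^ml_entities\t", rep)))
  prof <- utils::read.delim(p)
  expect_equal(nrow(prof), nrow(fit@profile))
})

test_that("consensus follows the majority and lumps on ties", {
  p1 <- SpeciesPartition(c(a = "x", b = "x", c = "y"))
  p2 <- SpeciesPartition(c(a = "x", b = "x", c = "y"))
  p3 <- SpeciesPartition(c(a = "x", b = "z", c = "z"))
  # three identical partitions reproduce themselves
  same <- consensusPartition(list(p1, p2, p1))
  expect_equal(speciesAssignments(same)[c("a", "b")] |> unique() |> length(),
               1L)
  expect_equal(nSpecies(same), 2L)
  # 2:1 majority keeps ab | c
  cons <- consensusPartition(list(p1, p2, p3))
  a <- speciesAssignments(cons)
  expect_identical(a[["a"]], a[["b"]])
  expect_false(a[["a"]] == a[["c"]])
  # two partitions disagreeing on one pair: tie lumps
  q1 <- SpeciesPartition(c(a = "x", b = "x"))
  q2 <- SpeciesPartition(c(a = "x", b = "y"))
  tie <- consensusPartition(list(q1, q2))
  expect_equal(nSpecies(tie), 1L)
  expect_error(consensusPartition(list(p1)), "two")
  expect_error(consensusPartition(list(p1, SpeciesPartition(c(a = "x")))),
               "sample sets")
})

test_that("consensus reports pairs overturned by transitive closure", {
  # a-b and b-c conspecific by majority, a-c not: closure joins a-c
  p1 <- SpeciesPartition(c(a = "1", b = "1", c = "2"))
  p2 <- SpeciesPartition(c(a = "1", b = "1", c = "1"))
  p3 <- SpeciesPartition(c(a = "2", b = "1", c = "1"))
  expect_message(cons <- consensusPartition(list(p1, p2, p3)), "closure")
  expect_equal(nSpecies(cons), 1L)
  expect_equal(attr(cons, "overturned"), 1L)
})

test_that("all three methods agree with the truth on separable data", {
  ds <- defaultDataset()
  dm <- k2pMatrix(ds@alignment)
  nj <- bootstrapNJ(ds@alignment, replicates = 30, seed = 77L)
  pCluster <- clusterByThreshold(nj, dm)
  pAbgd <- abgdModalPartition(abgdPartitions(dm))
  gm <- gmycFit(ds@geneTree)
  pGmyc <- gmycPartition(gm)
  expect_equal(nSpecies(pCluster), 20L)
  expect_equal(nSpecies(pAbgd), 20L)
  # GMYC may split a species whose coalescent genealogy runs deep (its ML
  # entity count recovers the truth exactly on about two thirds of draws at
  # these conditions); its confidence set must still cover the truth
  expect_gte(20L, gm@ciEntities[1])
  expect_lte(20L, gm@ciEntities[2])
  expect_lte(abs(gm@entities - 20L), 2L)
  cons <- consensusPartition(list(pCluster, pAbgd, pGmyc))
  expect_equal(nSpecies(cons), 20L)
  # consensus equals the generator truth up to label renaming
  truth <- speciesAssignments(ds@partition)
  est <- speciesAssignments(cons)[names(truth)]
  expect_equal(length(unique(paste(truth, est))), 20L)
})
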