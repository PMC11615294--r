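test_that("negative binomial sampling matches the stated mean/dispersion moments", {
  set.seed(81)
  mu <- 5; phi <- 0.1
  x <- rnbinom(1e5, mu = mu, size = 1 / phi)
  expect_equal(mean(x), mu, tolerance = 0.02)
  expect_equal(var(x), mu + phi * mu^2, tolerance = 0.05)
})

test_that("builtin reference profile is reproducible and stratified", {
  p1 <- referenceParams("builtin", nGenes = 2000, nMarkers = 200, seed = 4)
  p2 <- referenceParams("builtin", nGenes = 2000, nMarkers = 200, seed = 4)
  expect_identical(p1, p2)
  # markers all come from the top-20% stratum of the mean pool
  expect_gte(min(p1$markerMeans), max(p1$nonMarkerMeans))
  expect_equal(length(p1$markerMeans), 200)
  expect_equal(length(p1$nonMarkerMeans), 1800)
  expect_equal(p1$foldChanges, c(3, 4, 5))
})

test_that("pbmc3k mode without the local matrix raises an instructive error", {
  expect_error(referenceParams("pbmc3k", path = withr::local_tempdir()),
               "10xgenomics")
})

test_that("hierarchy simulation is reproducible with nested labels and planted fold changes", {
  sim <- smallHierSim(seed = 3)
  sim2 <- smallHierSim(seed = 3)
  expect_identical(as.matrix(exprValues(sim$em)),
                   as.matrix(exprValues(sim2$em)))
  lab <- sim$truth$labels
  # perfect nesting: finer labels refine coarser ones
  for (s in 2:3) {
    tab <- table(lab[, s], lab[, s - 1])
    expect_true(all(rowSums(tab > 0) == 1))
  }
  expect_equal(length(unique(lab[, 1])), 2)
  expect_equal(length(unique(lab[, 3])), 8)
  # marker counts per scale follow the 2:2:1 totals of the three scales
  expect_equal(as.numeric(table(sim$truth$markers$scale)), c(40, 40, 32))
  # in-cluster vs out-cluster sample means approximate the fold change
  cfg <- sim$truth$config
  bigger <- simulateHierarchy(hierSimConfig(
    nCells = 2000, nGenes = 60, markersPerCluster = c(10, 0, 0),
    clustersPerScale = c(2, 4, 8), seed = 11,
    params = referenceParams("builtin", nGenes = 60, nMarkers = 20,
                             seed = 12)))
  m <- bigger$truth$markers[1, ]
  x <- as.numeric(exprValues(bigger$em)[, m$gene])
  inC <- bigger$truth$labels[, m$scale] == m$cluster
  expect_equal(mean(x[inC]) / mean(x[!inC]),
               bigger$truth$config$params$foldChanges[m$scale],
               tolerance = 0.15)
})

test_that("tree simulation plants laminar supports and exact background sizes", {
  cfg <- treeSimConfig(seed = 5)
  sim <- simulateTrees(cfg)
  expect_equal(dim(sim$em), c(1000L, 100L))
  v <- as.matrix(exprValues(sim$em))
  expect_true(all(v %in% c(0L, 1L)))
  # background genes: exactly 500 cells each
  expect_true(all(colSums(v[, 16:100]) == 500))
  # planted supports are pairwise disjoint-or-inclusive within each tree
  for (tr in sim$truth$trees) {
    k <- length(tr$supports)
    for (i in seq_len(k)) for (j in seq_len(i - 1)) {
      rel <- supportRelation(tr$supports[[i]], tr$supports[[j]])
      expect_true(rel %in% c("disjoint", "inclusive"))
    }
  }
  expect_equal(length(sim$truth$trees), 5)
  expect_equal(sum(lengths(lapply(sim$truth$trees, `[[`, "entities"))), 15)
})

test_that("adjusted Rand index matches the mclust oracle and its analytic anchors", {
  skip_if_not_installed("mclust")
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  set.seed(82)
  for (rep in 1:25) {
    n <- sample(6:40, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
  # one swapped element between balanced 2-block labelings, n = 10
  a <- rep(1:2, each = 5)
  b <- a; b[5] <- 2; b[6] <- 1
  expect_equal(adjustedRandIndex(a, b),
               unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  # independent labels: near zero
  set.seed(83)
  a <- sample(1:5, 1000, replace = TRUE)
  b <- sample(1:5, 1000, replace = TRUE)
  expect_lt(abs(adjustedRandIndex(a, b)), 0.05)
  expect_error(adjustedRandIndex(1:3, 1:4), "same cell set")
})

test_that("marker recovery rate is 1 for a perfect detector and 0 for a useless one", {
  sim <- smallHierSim(seed = 6)
  truth <- sim$truth
  hier <- new("HierarchicalClustering",
              scaleIndex = 1:3, times = c(100, 10, 1),
              memberships = truth$labels,
              cellIds = cellIds(sim$em), diagnostics = data.frame())
  nM <- nrow(truth$markers)
  perfect <- data.frame(unit = truth$markers$gene,
                        scale = truth$markers$scale,
                        cluster = truth$markers$cluster,
                        p_value = seq(1e-20, 1e-10, length.out = nM))
  r <- markerRecoveryRate(perfect, truth, hier, topN = nM)
  expect_equal(r$overall, 1)
  expect_equal(unname(r$perScale), c(1, 1, 1))
  useless <- data.frame(unit = paste0("nm", 1:50), scale = 1, cluster = 1,
                        p_value = seq(1e-30, 1e-20, length.out = 50))
  expect_equal(suppressWarnings(
    markerRecoveryRate(useless, truth, hier, topN = 50))$overall, 0)
})

test_that("detected markers on simulated data recover planted assignments", {
  sim <- smallHierSim(seed = 7, nCells = 160, nGenes = 250)
  ln <- logNormalize(dropEmptyCells(sim$em))
  hier <- new("HierarchicalClustering",
              scaleIndex = 1:3, times = c(100, 10, 1),
              memberships = sim$truth$labels[match(cellIds(ln),
                                                   cellIds(sim$em)), ],
              cellIds = cellIds(ln), diagnostics = data.frame())
  asn <- suppressWarnings(assignMarkers(ln, hier, geneIds(ln)))
  r <- markerRecoveryRate(asn, sim$truth, hier,
                          topN = nrow(sim$truth$markers))
  # with the true partitions given, most planted markers are recovered
  expect_gt(r$overall, 0.7)
})
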