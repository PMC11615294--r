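test_that("K2 operator has closed-form stationary distribution and kernel", {
  g <- graphFromMatrix(matrix(c(0, 0.7, 0.7, 0), 2))
  op <- buildOperator(g)
  expect_equal(stationaryDistribution(op), c(0.5, 0.5))
  for (t in c(0, 0.5, 2)) {
    P <- transitionMatrix(op, t)
    expect_equal(P[1, 1], (1 + exp(-2 * t)) / 2, tolerance = 1e-12)
    expect_equal(P[1, 2], (1 - exp(-2 * t)) / 2, tolerance = 1e-12)
    expect_equal(rowSums(P), c(1, 1), tolerance = 1e-10)
  }
})

test_that("spectral P(t) equals the dense matrix-exponential oracle", {
  # 5-node path graph
  A <- matrix(0, 5, 5)
  for (i in 1:4) A[i, i + 1] <- A[i + 1, i] <- 1
  op <- buildOperator(graphFromMatrix(A))
  L <- diag(5) - diag(1 / rowSums(A)) %*% A
  oracle <- as.matrix(Matrix::expm(-1 * Matrix::Matrix(L)))
  expect_equal(transitionMatrix(op, 1), oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(transitionMatrix(op, 0), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # stationarity: pi' P(t) = pi'
  pi_ <- stationaryDistribution(op)
  expect_equal(as.numeric(pi_ %*% transitionMatrix(op, 3)), pi_,
               tolerance = 1e-10)
  expect_error(buildOperator(graphFromMatrix(diag(0, 4) + rbind(
    cbind(matrix(c(0, 1, 1, 0), 2), matrix(0, 2, 2)),
    cbind(matrix(0, 2, 2), matrix(c(0, 1, 1, 0), 2))))), "disconnected")
})

test_that("Markov stability identities hold exactly", {
  set.seed(5)
  A <- matrix(runif(64), 8, 8)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  op <- buildOperator(graphFromMatrix(A))
  for (t in c(0, 0.3, 2, 50))
    expect_lt(abs(markovStability(op, rep(1, 8), t)), 1e-9)
  expect_equal(markovStability(op, 1:8, 0), 7, tolerance = 1e-10)
})

test_that("MS is non-increasing in t for fixed partitions", {
  op <- buildOperator(twoCliqueGraph(5))
  part <- rep(1:2, each = 5)
  tgrid <- c(0.1, 0.5, 1, 3, 10, 100)
  ms <- vapply(tgrid, function(t) markovStability(op, part, t), numeric(1))
  expect_true(all(diff(ms) <= 1e-10))
  # also for a random partition
  set.seed(9)
  part2 <- sample(1:3, 10, replace = TRUE)
  ms2 <- vapply(tgrid, function(t) markovStability(op, part2, t), numeric(1))
  expect_true(all(diff(ms2) <= 1e-10))
})

test_that("variation of information matches analytic values and the entropy oracle", {
  expect_equal(variationOfInformation(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(variationOfInformation(rep(1, 4), 1:4), log(4),
               tolerance = 1e-12)
  x <- c(1, 1, 1, 2, 2, 2)
  y <- c(1, 1, 2, 2, 3, 3)
  expect_equal(variationOfInformation(x, y), unname(viEntropyOracle(x, y)),
               tolerance = 1e-12)
  expect_equal(variationOfInformation(x, y), log(3) - log(2) / 3,
               tolerance = 1e-12)
  expect_error(variationOfInformation(1:3, 1:4), "same cell set")
})

test_that("VI is a metric: symmetry, identity, triangle inequality (random triples)", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    z <- sample(1:2, n, replace = TRUE)
    vxy <- variationOfInformation(x, y)
    vyx <- variationOfInformation(y, x)
    expect_equal(vxy, vyx, tolerance = 1e-12)
    expect_gte(vxy, 0)
    expect_equal(variationOfInformation(x, x), 0, tolerance = 1e-12)
    vyz <- variationOfInformation(y, z)
    vxz <- variationOfInformation(x, z)
    expect_lte(vxz, vxy + vyz + 1e-10)
    # C++ path agrees with the R implementation
    expect_equal(hierCCC:::.viCpp(x, y), vxy, tolerance = 1e-12)
  }
})

test_that("Louvain recovers two bridged cliques and respects trivial bounds", {
  op <- buildOperator(twoCliqueGraph(5, bridge = 0.1))
  fit <- louvainStability(op, t = 1, nRuns = 20, seed = 3)
  expect_equal(length(unique(fit$representative)), 2)
  expect_equal(fit$representative[1:5], rep(fit$representative[1], 5))
  expect_lt(fit$viG, 1e-12)
  # exhaustive check: the 2-block partition beats all other merges of <= 3 blocks
  Q <- hierCCC:::stabilityQuality(op, 1)
  msOf <- function(m) sum(vapply(split(1:10, m), function(ix)
    sum(Q[ix, ix]), numeric(1)))
  expect_equal(fit$ms, msOf(rep(1:2, each = 5)), tolerance = 1e-10)
  set.seed(2)
  for (i in 1:50) {
    m <- sample(1:3, 10, replace = TRUE)
    expect_lte(msOf(m), fit$ms + 1e-9)
  }
  # never below the trivial partitions
  expect_gte(fit$ms, msOf(rep(1, 10)) - 1e-9)
  expect_gte(fit$ms, msOf(1:10) - 1e-9)
})

test_that("very large Markov time collapses to a single community", {
  op <- buildOperator(twoCliqueGraph(5))
  fit <- louvainStability(op, t = 1e4, nRuns = 5, seed = 0)
  expect_equal(unique(fit$representative), 1L)
})

test_that("same seed gives a bitwise-identical Louvain ensemble", {
  op <- buildOperator(twoCliqueGraph(4, bridge = 0.4))
  a <- louvainStability(op, t = 2, nRuns = 15, seed = 7)
  b <- louvainStability(op, t = 2, nRuns = 15, seed = 7)
  expect_identical(a$ensemble, b$ensemble)
  expect_identical(a$representative, b$representative)
})

test_that("scale selection picks one scale per VI basin and falls back gracefully", {
  # synthetic ScaleScan: three zero blocks of widths 30/30/40; the
  # finest partition sits at the smallest Markov times
  ng <- 100
  memb <- matrix(1L, 10, ng)            # coarsest block: scales 61-100
  memb[, 1:30] <- rep(1:5, each = 2)    # finest block
  memb[, 31:60] <- rep(1:2, each = 5)
  viP <- matrix(0, ng, ng)
  for (i in 1:ng) for (j in 1:ng) {
    bi <- findInterval(i, c(1, 31, 61))
    bj <- findInterval(j, c(1, 31, 61))
    if (bi != bj) viP[i, j] <- 1
  }
  scan <- new("ScaleScan", logGrid = seq(-1, 4, length.out = ng),
              times = 10^seq(-1, 4, length.out = ng), memberships = memb,
              msValues = rep(1, ng), viG = rep(0.01, ng), viP = viP,
              nCommunities = apply(memb, 2, function(m) length(unique(m))),
              cellIds = paste0("c", 1:10))
  hier <- selectScales(scan, basinTheta = 0.1, basinMinWidth = 5)
  expect_equal(length(markovTimes(hier)), 3)
  expect_equal(unname(scanDiagnostics(hier)$nCommunities), c(1, 2, 5))
  # coarse -> fine ordering by decreasing Markov time
  expect_true(all(diff(markovTimes(hier)) < 0))
  # basinMinWidth larger than every run: fallback with warning
  expect_warning(h2 <- selectScales(scan, basinTheta = 0.1,
                                    basinMinWidth = 200), "fallback|falling back")
  expect_equal(length(markovTimes(h2)), 1)
})

test_that("cluster TSV export is tidy and rerun-identical", {
  op <- buildOperator(twoCliqueGraph(5))
  scan <- scanScales(op, gridPoints = 12, nRuns = 5, seed = 1)
  hier <- selectScales(scan, basinTheta = 0.1, basinMinWidth = 2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeClusterAssignments(hier, p1)
  scan2 <- scanScales(op, gridPoints = 12, nRuns = 5, seed = 1)
  hier2 <- selectScales(scan2, basinTheta = 0.1, basinMinWidth = 2)
  writeClusterAssignments(hier2, p2)
  expect_identical(readLines(p1), readLines(p2))
  df <- read.delim(p1)
  expect_equal(nrow(df), 10 * length(markovTimes(hier)))
})
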