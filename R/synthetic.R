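#' Reference parameters for the hierarchical count simulator
#'
#' The simulator draws marker-gene base means from the top-20% stratum of a
#' reference mean-expression distribution and non-marker means from the
#' lower 80%, with per-scale fold changes.
#'
#' Two sources are supported. `"builtin"` is a self-contained profile: a
#' log-normal(meanlog = 1, sdlog = 1) mean distribution, markers drawn from
#' its top-20% stratum, and fold changes (3, 4, 5) from coarsest to finest
#' scale; it is NOT derived from any real dataset. `"pbmc3k"` derives the
#' profile from a local copy of the 10x PBMC-3k filtered matrix (2700 cells,
#' 13714 genes): median-total normalization, 1000 marker means drawn from
#' the top-20% expression stratum, and per-scale fold changes set to the
#' median one-vs-rest fold change of the top 400/400/200 differentially
#' expressed genes among the chosen 1000 (requires a cell-label CSV for the
#' one-vs-rest comparison).
#'
#' @param source "builtin" or "pbmc3k".
#' @param path for pbmc3k: directory containing matrix.mtx, genes.tsv,
#'   barcodes.tsv.
#' @param labelsPath for pbmc3k: CSV (cell_id,label) of cell annotations.
#' @param nMarkers number of marker genes (1000).
#' @param nGenes total genes to parameterize (10000).
#' @param foldChanges builtin fold changes, coarsest to finest.
#' @param seed RNG seed.
#' @return list: markerMeans (length nMarkers), nonMarkerMeans (length
#'   nGenes - nMarkers), foldChanges (length 3), source.
#' @export
referenceParams <- function(source = c("builtin", "pbmc3k"), path = NULL,
                            labelsPath = NULL, nMarkers = 1000,
                            nGenes = 10000, foldChanges = c(3, 4, 5),
                            seed = 0) {
  source <- match.arg(source)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (source == "builtin") {
    poolSize <- max(nGenes * 2, nMarkers * 10)
    pool <- stats::rlnorm(poolSize, meanlog = 1, sdlog = 1)
    cut80 <- stats::quantile(pool, 0.8)
    top <- pool[pool >= cut80]
    low <- pool[pool < cut80]
    return(list(markerMeans = sample(top, nMarkers),
                nonMarkerMeans = sample(low, nGenes - nMarkers),
                foldChanges = foldChanges, source = "builtin"))
  }
  mtx <- file.path(path %||% ".", "matrix.mtx")
  gen <- file.path(path %||% ".", "genes.tsv")
  bar <- file.path(path %||% ".", "barcodes.tsv")
  if (is.null(path) || !all(file.exists(c(mtx, gen, bar))))
    stop("pbmc3k mode needs a local copy of the 10x PBMC-3k filtered matrix ",
         "(matrix.mtx, genes.tsv, barcodes.tsv), available at ",
         "https://cf.10xgenomics.com/samples/cell/pbmc3k/",
         "pbmc3k_filtered_gene_bc_matrices.tar.gz; pass its directory as `path`")
  em <- readExpressionTriplet(mtx, gen, bar, layerTag = "raw_counts")
  em <- dropEmptyCells(em)
  # median-total normalization (linear scale) for mean ranking
  v <- exprValues(em)
  tot <- Matrix::rowSums(v)
  normed <- Matrix::Diagonal(x = stats::median(tot) / tot) %*% v
  mu <- Matrix::colSums(normed) / nrow(normed)
  cut80 <- stats::quantile(mu, 0.8)
  topIdx <- which(mu >= cut80)
  chosen <- sample(topIdx, nMarkers)
  lowPool <- mu[mu < cut80]
  nonMarkerMeans <- sample(lowPool, nGenes - nMarkers, replace = TRUE)
  if (is.null(labelsPath) || !file.exists(labelsPath %||% ""))
    stop("pbmc3k mode needs a cell-label CSV (cell_id,label) for the ",
         "one-vs-rest fold-change calibration; pass it as `labelsPath`")
  lab <- readCellLabels(labelsPath)
  lab <- lab$label[match(cellIds(em), lab$cell_id)]
  if (anyNA(lab)) stop("labels do not cover all cells in the matrix")
  # one-vs-rest fold change per chosen gene: best label's mean ratio
  nm <- as.matrix(normed[, chosen, drop = FALSE])
  fc <- vapply(seq_along(chosen), function(j) {
    x <- nm[, j]
    best <- 1
    for (l in unique(lab)) {
      inG <- lab == l
      r <- (mean(x[inG]) + 1e-9) / (mean(x[!inG]) + 1e-9)
      if (r > best) best <- r
    }
    best
  }, numeric(1))
  o <- order(fc, decreasing = TRUE)
  foldChanges <- c(stats::median(fc[o[seq_len(400)]]),
                   stats::median(fc[o[401:800]]),
                   stats::median(fc[o[801:1000]]))
  list(markerMeans = as.numeric(mu[chosen]),
       nonMarkerMeans = as.numeric(nonMarkerMeans),
       foldChanges = foldChanges, source = "pbmc3k")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration for the hierarchical count simulation
#'
#' Three perfectly nested scales with 2/4/8 equally sized clusters and
#' 1000 marker genes: 200 per cluster at the coarsest scale, 100 at the
#' middle scale and 25 at the finest (scale totals 400/400/200). Counts are
#' negative binomial with variance mu + dispersion * mu^2.
#'
#' @param nCells,nGenes dataset size.
#' @param markersPerCluster markers assigned per cluster, coarsest to finest.
#' @param clustersPerScale communities per scale, coarsest to finest.
#' @param dispersion NB dispersion (0.1).
#' @param params a [referenceParams()] profile (defaults to builtin, seeded
#'   by `seed`).
#' @param seed RNG seed.
#' @return config list for [simulateHierarchy()].
#' @export
hierSimConfig <- function(nCells = 1000, nGenes = 10000,
                          markersPerCluster = c(200, 100, 25),
                          clustersPerScale = c(2, 4, 8), dispersion = 0.1,
                          params = NULL, seed = 0) {
  if (is.null(params))
    params <- referenceParams("builtin", nGenes = nGenes,
                              nMarkers = sum(markersPerCluster * clustersPerScale),
                              seed = seed + 10000)
  list(nCells = nCells, nGenes = nGenes,
       markersPerCluster = markersPerCluster,
       clustersPerScale = clustersPerScale, dispersion = dispersion,
       params = params, seed = seed)
}

#' Simulate a hierarchical negative-binomial count dataset
#'
#' Cells are split evenly into nested clusters at each scale. Every marker
#' gene belongs to one (scale, cluster): its in-cluster mean is fold-change
#' times its out-cluster mean, with the two tied to the gene's base mean m
#' via rho*muIn + (1-rho)*muOut = m (rho = cluster fraction). Non-marker
#' genes use means from the lower-80% reference pool. All counts are NB with
#' the configured dispersion. Bit-reproducible given the config.
#'
#' @param cfg a [hierSimConfig()].
#' @return list: `em` (raw-count [ExpressionMatrix-class]), `truth` (list
#'   with `labels` cells x scales matrix, `markers` data.frame
#'   gene/scale/cluster, `config`).
#' @export
simulateHierarchy <- function(cfg) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  n <- cfg$nCells
  S <- length(cfg$clustersPerScale)
  labels <- sapply(cfg$clustersPerScale, function(k) ceiling(seq_len(n) / (n / k)))
  nMarkersScale <- cfg$markersPerCluster * cfg$clustersPerScale
  nMarkers <- sum(nMarkersScale)
  stopifnot(length(cfg$params$markerMeans) >= nMarkers)
  counts <- matrix(0L, n, cfg$nGenes)
  markerRows <- list()
  g <- 0L
  phi <- cfg$dispersion
  for (s in seq_len(S)) {
    k <- cfg$clustersPerScale[s]
    rho <- 1 / k
    f <- cfg$params$foldChanges[s]
    for (cl in seq_len(k)) {
      inCells <- labels[, s] == cl
      for (m_ in seq_len(cfg$markersPerCluster[s])) {
        g <- g + 1L
        base <- cfg$params$markerMeans[g]
        muOut <- base / (rho * f + 1 - rho)
        muIn <- f * muOut
        counts[inCells, g] <- stats::rnbinom(sum(inCells), mu = muIn, size = 1 / phi)
        counts[!inCells, g] <- stats::rnbinom(sum(!inCells), mu = muOut, size = 1 / phi)
        markerRows[[g]] <- c(g, s, cl)
      }
    }
  }
  nonMu <- sample(cfg$params$nonMarkerMeans, cfg$nGenes - nMarkers,
                  replace = length(cfg$params$nonMarkerMeans) < cfg$nGenes - nMarkers)
  if (any(nonMu <= 0)) stop("non-positive mean expression in reference pool")
  for (j in seq_len(cfg$nGenes - nMarkers)) {
    counts[, nMarkers + j] <- stats::rnbinom(n, mu = nonMu[j], size = 1 / phi)
  }
  geneIds <- paste0("gene", seq_len(cfg$nGenes))
  cellIds <- paste0("cell", seq_len(n))
  mk <- do.call(rbind, markerRows)
  truth <- list(
    labels = labels,
    markers = data.frame(gene = geneIds[mk[, 1]], scale = mk[, 2],
                         cluster = mk[, 3]),
    config = cfg)
  list(em = ExpressionMatrix(counts, geneIds = geneIds, cellIds = cellIds,
                             layerTag = "raw_counts"),
       truth = truth)
}

#' Default planted-tree topologies for the support simulation
#'
#' Five laminar trees over 15 genes (3 per tree), mixing chains and
#' root-with-disjoint-children shapes. Each entry gives the parent vector
#' (NA = root) and support sizes; children of a common parent are disjoint.
#'
#' @return list of 5 topology specs.
#' @export
defaultTreeTopologies <- function() {
  list(
    list(parent = c(NA, 1L, 2L), sizes = c(200, 100, 50)),    # chain
    list(parent = c(NA, 1L, 1L), sizes = c(200, 80, 80)),     # two disjoint kids
    list(parent = c(NA, 1L, 2L), sizes = c(200, 120, 40)),    # chain
    list(parent = c(NA, 1L, 1L), sizes = c(200, 70, 100)),    # two disjoint kids
    list(parent = c(NA, 1L, 2L), sizes = c(200, 100, 30))     # chain
  )
}

#' Configuration for the planted-tree support simulation
#' @param nCells,nGenes dataset size (1000 cells, 100 genes).
#' @param topologies planted tree shapes (see [defaultTreeTopologies()]).
#' @param backgroundSize cells expressing each background gene (500).
#' @param seed RNG seed.
#' @return config list for [simulateTrees()].
#' @export
treeSimConfig <- function(nCells = 1000, nGenes = 100,
                          topologies = defaultTreeTopologies(),
                          backgroundSize = 500, seed = 0) {
  list(nCells = nCells, nGenes = nGenes, topologies = topologies,
       backgroundSize = backgroundSize, seed = seed)
}

#' Simulate binary expression realizing planted signaling trees
#'
#' The structured genes receive supports realizing the planted laminar
#' trees on disjoint cell blocks (so the trees are mutually disjoint);
#' every remaining background gene is expressed in `backgroundSize`
#' uniformly chosen cells, re-drawn per call.
#'
#' @param cfg a [treeSimConfig()].
#' @return list: `em` (binary raw-count ExpressionMatrix), `truth` (list
#'   with `trees` in TreeSet format and `db` a self-paired LRDatabase over
#'   all genes for pipeline use).
#' @export
simulateTrees <- function(cfg) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  n <- cfg$nCells
  nT <- length(cfg$topologies)
  nStruct <- sum(vapply(cfg$topologies, function(t) length(t$sizes), 1L))
  stopifnot(cfg$nGenes > nStruct)
  blockSize <- floor(n / nT)
  counts <- matrix(0L, n, cfg$nGenes)
  geneIds <- paste0("g", seq_len(cfg$nGenes))
  planted <- list()
  g <- 0L
  for (ti in seq_len(nT)) {
    topo <- cfg$topologies[[ti]]
    block <- seq((ti - 1) * blockSize + 1, ti * blockSize)
    stopifnot(topo$sizes[1] <= length(block))
    k <- length(topo$sizes)
    sup <- vector("list", k)
    sup[[1]] <- block[seq_len(topo$sizes[1])]
    for (i in seq(2, k)) {
      par <- topo$parent[i]
      # carve the child out of the parent's cells not yet used by siblings
      sibs <- which(topo$parent == par & seq_len(k) < i)
      used <- unlist(sup[sibs])
      avail <- setdiff(sup[[par]], used)
      stopifnot(length(avail) >= topo$sizes[i])
      sup[[i]] <- avail[seq_len(topo$sizes[i])]
    }
    ents <- geneIds[g + seq_len(k)]
    for (i in seq_len(k)) counts[sup[[i]], g + i] <- 1L
    planted[[ti]] <- list(entities = ents, parent = topo$parent,
                          supports = sup)
    g <- g + k
  }
  for (j in seq(g + 1, cfg$nGenes))
    counts[sample(n, cfg$backgroundSize), j] <- 1L
  em <- ExpressionMatrix(counts, geneIds = geneIds,
                         cellIds = paste0("cell", seq_len(n)),
                         layerTag = "raw_counts")
  db <- LRDatabase(geneIds, geneIds, rep("sim", cfg$nGenes))
  list(em = em, truth = list(trees = planted, config = cfg, db = db))
}

#' Does a TreeSet contain a given tree?
#'
#' A planted tree counts as present when some detected tree has exactly the
#' same entities and parent relations (merged equal-support labels are
#' unpacked before comparison).
#'
#' @param ts a TreeSet.
#' @param tree a tree (entities, parent, supports).
#' @return logical.
#' @export
containsTree <- function(ts, tree) {
  want <- treeKey(tree)
  any(vapply(ts@trees, function(tr) treeKey(tr) == want, logical(1)))
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-model chance-corrected pair-counting agreement: 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors over the same cells.
#' @return scalar ARI.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must cover the same cell set")
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nPairs <- choose(length(a), 2)
  expected <- ai * bj / nPairs
  maxIdx <- (ai + bj) / 2
  if (maxIdx == expected) return(ifelse(sumij == expected, 1, 0))
  (sumij - expected) / (maxIdx - expected)
}

#' Best-ARI alignment of detected scales to planted scales
#' @param hier a HierarchicalClustering.
#' @param truthLabels cells x planted-scales label matrix.
#' @return data.frame: planted scale, matched detected scale, ARI.
#' @export
matchScales <- function(hier, truthLabels) {
  S <- ncol(truthLabels)
  out <- data.frame(planted = seq_len(S), detected = NA_integer_,
                    ari = NA_real_)
  for (s in seq_len(S)) {
    aris <- vapply(seq_len(ncol(hier@memberships)), function(d)
      adjustedRandIndex(truthLabels[, s], hier@memberships[, d]), numeric(1))
    out$detected[s] <- which.max(aris)
    out$ari[s] <- max(aris)
  }
  out
}

#' Marker recovery rate against planted ground truth
#'
#' Ranks units by assigned p-value, takes the top `topN`, and counts a
#' planted marker as recovered when it appears there and its assigned
#' (scale, cluster) maps onto its planted (scale, cluster). Detected scales
#' are aligned to planted scales by best ARI and detected clusters to
#' planted clusters by majority overlap. The overall rate divides by the
#' number of planted markers; per-scale rates divide by the planted markers
#' of that scale.
#'
#' @param assignments output of [assignMarkers()] over all genes.
#' @param truth ground truth from [simulateHierarchy()].
#' @param hier the HierarchicalClustering the assignments were made against.
#' @param topN size of the ranked list.
#' @return list: overall, perScale (named numeric), nCorrect, topN.
#' @export
markerRecoveryRate <- function(assignments, truth, hier, topN = 1000) {
  if (topN > nrow(assignments)) {
    warning("topN exceeds ranked genes; clamped")
    topN <- nrow(assignments)
  }
  sc <- matchScales(hier, truth$labels)
  # per planted scale: detected-cluster -> planted-cluster majority map
  clusterMap <- lapply(seq_len(nrow(sc)), function(s) {
    d <- sc$detected[s]
    tab <- table(hier@memberships[, d], truth$labels[, s])
    stats::setNames(colnames(tab)[apply(tab, 1, which.max)], rownames(tab))
  })
  top <- assignments[order(assignments$p_value,
                           assignments$scale)[seq_len(topN)], ]
  truthIdx <- match(top$unit, truth$markers$gene)
  correct <- logical(nrow(top))
  for (r in seq_len(nrow(top))) {
    ti <- truthIdx[r]
    if (is.na(ti)) next
    ps <- truth$markers$scale[ti]
    if (top$scale[r] != sc$detected[ps]) next
    mapped <- clusterMap[[ps]][as.character(top$cluster[r])]
    correct[r] <- !is.na(mapped) && mapped == as.character(truth$markers$cluster[ti])
  }
  nMarkers <- nrow(truth$markers)
  perScale <- vapply(seq_len(nrow(sc)), function(s) {
    inS <- !is.na(truthIdx) & truth$markers$scale[truthIdx] == s
    sum(correct & inS) / sum(truth$markers$scale == s)
  }, numeric(1))
  list(overall = sum(correct) / min(topN, nMarkers),
       perScale = stats::setNames(perScale, paste0("scale", seq_len(nrow(sc)))),
       nCorrect = sum(correct), topN = topN)
}
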