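test_that("binarize yields hand-listed supports and merges equal sets", {
  m <- matrix(c(1, 0, 2, 0, 0, 3,    # gA: cells 1,3,6
                0, 5, 0, 1, 0, 0,    # gB: cells 2,4
                1, 0, 2, 0, 0, 3),   # gC: same support as gA
              nrow = 6)
  em <- ExpressionMatrix(m, geneIds = c("gA", "gB", "gC"),
                         cellIds = paste0("c", 1:6), layerTag = "raw_counts")
  sm <- binarizeSupports(em, c("gA", "gB", "gC"), tau = 0, minCells = 1)
  sup <- supports(sm)
  expect_equal(sup[["gA=gC"]], c(1L, 3L, 6L))
  expect_equal(sup[["gB"]], c(2L, 4L))
  # raising tau never enlarges a support
  sm2 <- binarizeSupports(em, c("gA", "gB", "gC"), tau = 1, minCells = 1)
  for (e in entities(sm2)) {
    lab <- strsplit(e, "=", fixed = TRUE)[[1]][1]
    old <- sup[[grep(lab, names(sup), value = TRUE)[1]]]
    expect_true(all(supports(sm2)[[e]] %in% old))
  }
  # minCells filters small supports
  sm3 <- binarizeSupports(em, c("gA", "gB"), tau = 0, minCells = 3)
  expect_equal(entities(sm3), "gA")
})

test_that("support relations classify disjoint/inclusive/overlap/equal", {
  expect_equal(supportRelation(c(1, 2, 3), c(2, 3)), "inclusive")
  expect_equal(supportRelation(c(1, 2), c(3, 4)), "disjoint")
  expect_equal(supportRelation(c(1, 2), c(2, 3)), "overlap")
  expect_equal(supportRelation(c(1, 2), c(1, 2)), "equal")
  # with tolerance: 1 shared of min 10 is within eps = 0.15
  expect_equal(supportRelation(1:10, c(10, 21:29), eps = 0.15), "disjoint")
  expect_equal(supportRelation(1:10, c(1:9, 21, 22), eps = 0.15), "inclusive")
})

test_that("Bron-Kerbosch enumerates the same maximal cliques as igraph", {
  skip_if_not_installed("igraph")
  # hand cases: triangle; path
  tri <- matrix(TRUE, 3, 3); diag(tri) <- FALSE
  expect_equal(maximalCliques(tri), list(1:3))
  path <- matrix(FALSE, 3, 3); path[1, 2] <- path[2, 1] <- TRUE
  path[2, 3] <- path[3, 2] <- TRUE
  expect_equal(maximalCliques(path), list(c(1L, 2L), c(2L, 3L)))
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    adj <- matrix(runif(n * n) < 0.4, n, n)
    adj <- adj | t(adj)
    diag(adj) <- FALSE
    mine <- maximalCliques(adj)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    ref <- lapply(igraph::max_cliques(ig), function(v) sort(as.integer(v)))
    key <- function(l) sort(vapply(l, paste, character(1), collapse = ","))
    expect_equal(key(mine), key(ref))
  }
})

test_that("forest extraction builds the Hasse tree of a laminar family", {
  ents <- c("A", "B", "C", "D")
  sup <- list(1:6, 1:2, 3:4, 1)
  ts <- forestFromClique(ents, sup, minNodes = 2)
  expect_equal(length(ts), 1)
  tr <- ts[[1]]
  expect_equal(tr$entities, ents)
  expect_equal(tr$parent, c(NA, 1L, 1L, 2L))   # A -> (B -> D, C)
  # four mutually disjoint sets: all singleton components filtered
  ts2 <- forestFromClique(letters[1:4], list(1:2, 3:4, 5:6, 7:8),
                          minNodes = 2)
  expect_equal(length(ts2), 0)
  ts3 <- forestFromClique(letters[1:4], list(1:2, 3:4, 5:6, 7:8),
                          minNodes = 1)
  expect_equal(length(ts3), 4)
})

test_that("sibling supports in emitted trees are pairwise disjoint at eps = 0", {
  set.seed(52)
  for (rep in 1:30) {
    sm <- randomSupportMatrix(sample(4:10, 1), 25, seed = rep + 500)
    ts <- detectTreesFromSupports(sm, minNodes = 2)
    for (tr in trees(ts)) {
      for (p in which(!is.na(tr$parent))) {
        expect_true(all(tr$supports[[p]] %in% tr$supports[[tr$parent[p]]]))
      }
      for (par in unique(tr$parent[!is.na(tr$parent)])) {
        sib <- which(!is.na(tr$parent) & tr$parent == par)
        if (length(sib) > 1) {
          for (i in seq_along(sib)) for (j in seq_len(i - 1)) {
            expect_equal(length(intersect(tr$supports[[sib[i]]],
                                          tr$supports[[sib[j]]])), 0)
          }
        }
      }
    }
  }
})

test_that("pipeline trees equal brute-force maximal laminar subfamilies", {
  set.seed(53)
  for (rep in 1:60) {
    sm <- randomSupportMatrix(sample(4:9, 1), sample(10:30, 1), seed = rep)
    ts <- detectTreesFromSupports(sm, minNodes = 1)
    sigMine <- sort(vapply(trees(ts), treeSig, character(1)))
    fams <- bruteLaminarFamilies(sm@supports)
    sigRef <- character()
    for (fam in fams) {
      forest <- bruteHasseForest(sm@entities[fam], sm@supports[fam])
      sigRef <- c(sigRef, vapply(forest, treeSig, character(1)))
    }
    expect_equal(sigMine, sort(unique(sigRef)))
  }
})

test_that("tree output is invariant under relabeling of cells and entity order", {
  sm <- randomSupportMatrix(8, 20, seed = 99)
  ts <- detectTreesFromSupports(sm, minNodes = 2)
  perm <- sample(20)
  inv <- order(perm)
  sm2 <- new("SupportMatrix", entities = rev(sm@entities),
             supports = rev(lapply(sm@supports, function(s) sort(inv[s]))),
             nCells = sm@nCells, cellIds = sm@cellIds[perm], tau = 0)
  ts2 <- detectTreesFromSupports(sm2, minNodes = 2)
  expect_equal(sort(vapply(trees(ts), treeSig, character(1))),
               sort(vapply(trees(ts2), treeSig, character(1))))
})

test_that("detectTrees wires kinds correctly and lr_union unions supports", {
  em <- toyExpression()
  db <- toyDb()
  tsL <- detectTrees(em, db, kind = "ligand", minCells = 1)
  expect_equal(tsL@kind, "ligand")
  ts <- detectTrees(em, db, kind = "lr_union", minCells = 1, minNodes = 1)
  supIgf2 <- which(unitExpression(em, "Igf2") > 0)
  supItg <- which(unitExpression(em, "Itga6_Itgb4") > 0)
  want <- sort(union(supIgf2, supItg))
  allSup <- unlist(lapply(trees(ts), function(tr) tr$supports),
                   recursive = FALSE)
  allEnt <- unlist(lapply(trees(ts), function(tr) tr$entities))
  expect_true(any(vapply(seq_along(allEnt), function(i)
    grepl("Igf2->Itga6_Itgb4", allEnt[i]) && identical(allSup[[i]], want),
    logical(1))))
  # receptor run on a ligand-only toy: empty TreeSet, not an error
  emL <- ExpressionMatrix(matrix(c(1, 1, 1), 3), geneIds = "OnlyLigand",
                          cellIds = paste0("c", 1:3), layerTag = "raw_counts")
  ts0 <- suppressWarnings(detectTrees(emL, db, kind = "receptor", minCells = 1))
  expect_equal(length(trees(ts0)), 0)
})

test_that("ligand-tree count is non-increasing in the binarization threshold", {
  topo <- list(list(parent = c(NA, 1L, 2L), sizes = c(80, 40, 15)),
               list(parent = c(NA, 1L, 1L), sizes = c(80, 30, 30)),
               list(parent = c(NA, 1L, 2L), sizes = c(80, 40, 20)))
  sim <- simulateTrees(treeSimConfig(nCells = 300, nGenes = 40,
                                     backgroundSize = 150, seed = 8,
                                     topologies = topo))
  counts <- vapply(c(0, 0.5, 1), function(tau)
    length(trees(detectTrees(sim$em, sim$truth$db, kind = "ligand",
                             tau = tau, minCells = 5))), 1L)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("frequency ranking counts tree membership with alphabetical ties", {
  ts <- new("TreeSet", trees = list(
    list(entities = c("A", "B"), parent = c(NA, 1L), supports = list(1:4, 1:2)),
    list(entities = c("A", "C"), parent = c(NA, 1L), supports = list(1:4, 3:4))),
    kind = "ligand", tau = 0, eps = 0, nCells = 4L)
  fr <- frequencyRanking(ts)
  expect_equal(fr$entity, c("A", "B", "C"))
  expect_equal(fr$count, c(2L, 1L, 1L))
})

test_that("tree pairing matches an exhaustive oracle on a toy tree set", {
  mk <- function(ents) list(entities = ents,
                            parent = c(NA, rep(1L, length(ents) - 1)),
                            supports = rep(list(1:2), length(ents)))
  lts <- new("TreeSet", trees = list(mk(c("L1", "L2")), mk(c("L3", "L4")),
                                     mk(c("L1", "L5"))),
             kind = "ligand", tau = 0, eps = 0, nCells = 2L)
  rts <- new("TreeSet", trees = list(mk(c("R1", "R2")), mk(c("R3", "R9")),
                                     mk(c("R4", "R5"))),
             kind = "receptor", tau = 0, eps = 0, nCells = 2L)
  db <- LRDatabase(ligand = c("L1", "L3", "L9"),
                   receptor = c("R1", "R3", "R9"),
                   pathway = c("p", "p", "q"))
  pt <- pairTrees(lts, rts, db)
  # oracle: brute-force all 9 combinations
  ia <- interactions(db)
  ref <- list()
  for (i in 1:3) for (j in 1:3) {
    hit <- ia$ligand %in% lts@trees[[i]]$entities &
      ia$receptor %in% rts@trees[[j]]$entities
    if (any(hit)) ref[[length(ref) + 1]] <- c(i, j, sum(hit))
  }
  expect_equal(nrow(pt), length(ref))
  for (k in seq_along(ref)) {
    row <- pt[pt$ligand_tree == ref[[k]][1] & pt$receptor_tree == ref[[k]][2], ]
    expect_equal(nrow(row), 1)
  }
  # no DB match -> empty pairing
  db0 <- LRDatabase("Lx", "Rx", "p")
  expect_equal(nrow(pairTrees(lts, rts, db0)), 0)
})

test_that("Newick and JSON serializations are well-formed", {
  skip_if_not_installed("ape")
  tree <- list(entities = c("root", "kidA", "kidB", "grand"),
               parent = c(NA, 1L, 1L, 2L),
               supports = list(1:8, 1:4, 5:8, 1:2))
  nwk <- treeToNewick(tree)
  ph <- ape::read.tree(text = nwk)
  expect_equal(sort(c(ph$tip.label, ph$node.label)),
               sort(c("root", "kidA", "kidB", "grand")))
  ts <- new("TreeSet", trees = list(tree), kind = "ligand", tau = 0,
            eps = 0, nCells = 8L)
  js <- jsonlite::fromJSON(treesToJSON(ts), simplifyVector = FALSE)
  expect_equal(js$n_trees, 1)
  expect_equal(js$trees[[1]]$entity, "root")
  expect_equal(length(js$trees[[1]]$children), 2)
})
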