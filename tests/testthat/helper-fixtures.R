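# Shared fixtures, built in code.

# tiny raw-count matrix with named genes
toyExpression <- function() {
  m <- matrix(c(4, 0, 9, 1,
                1, 2, 4, 0,
                0, 5, 1, 3,
                2, 1, 0, 2,
                3, 3, 2, 1,
                0, 4, 0, 5), nrow = 6, byrow = TRUE)
  ExpressionMatrix(m, geneIds = c("Igf2", "Ocln", "Itga6", "Itgb4"),
                   cellIds = paste0("c", 1:6), layerTag = "raw_counts")
}

toyDb <- function() {
  LRDatabase(ligand   = c("Igf2",        "Ocln"),
             receptor = c("Itga6_Itgb4", "Ocln"),
             pathway  = c("IGF",         "TJ"))
}

# CellGraph from a dense symmetric adjacency
graphFromMatrix <- function(A, ids = paste0("n", seq_len(nrow(A)))) {
  new("CellGraph", adjacency = Matrix::Matrix(A, sparse = TRUE), cellIds = ids)
}

# two weakly bridged cliques of size k
twoCliqueGraph <- function(k = 5, bridge = 0.1) {
  n <- 2 * k
  A <- matrix(0, n, n)
  A[1:k, 1:k] <- 1
  A[(k + 1):n, (k + 1):n] <- 1
  diag(A) <- 0
  A[k, k + 1] <- A[k + 1, k] <- bridge
  graphFromMatrix(A)
}

# random SupportMatrix over nCells cells; sets drawn to make disjoint /
# nested relations reasonably frequent
randomSupportMatrix <- function(nEntities, nCells, seed) {
  set.seed(seed)
  sup <- list()
  for (i in seq_len(nEntities)) {
    if (length(sup) && stats::runif(1) < 0.45) {
      base <- sup[[sample(length(sup), 1)]]
      sz <- sample(length(base), 1)
      sup[[i]] <- sort(sample(base, sz))            # nested inside existing
    } else {
      sz <- sample(2:max(3, nCells %/% 2), 1)
      sup[[i]] <- sort(sample(nCells, sz))          # arbitrary
    }
  }
  # drop duplicate supports (equal-set merging is tested separately)
  key <- vapply(sup, paste, character(1), collapse = ",")
  sup <- sup[!duplicated(key)]
  new("SupportMatrix", entities = paste0("e", seq_along(sup)), supports = sup,
      nCells = as.integer(nCells), cellIds = paste0("c", seq_len(nCells)),
      tau = 0)
}

# independent oracle: maximal laminar subfamilies by subset enumeration
bruteLaminarFamilies <- function(sup) {
  k <- length(sup)
  compat <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { compat[i, j] <- TRUE; next }
    inter <- length(intersect(sup[[i]], sup[[j]]))
    disjoint <- inter == 0
    nested <- inter == min(length(sup[[i]]), length(sup[[j]])) &&
      length(sup[[i]]) != length(sup[[j]])
    compat[i, j] <- disjoint || nested
  }
  fams <- list()
  for (mask in seq_len(2^k - 1)) {
    mem <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    ok <- TRUE
    for (a in mem) {
      if (!all(compat[a, mem])) { ok <- FALSE; break }
    }
    if (ok) fams[[length(fams) + 1]] <- mem
  }
  # keep maximal ones
  keep <- rep(TRUE, length(fams))
  for (i in seq_along(fams)) for (j in seq_along(fams)) {
    if (i != j && keep[i] && all(fams[[i]] %in% fams[[j]]) &&
        length(fams[[j]]) > length(fams[[i]])) keep[i] <- FALSE
  }
  unique(fams[keep])
}

# independent oracle: Hasse forest of a laminar family by direct subset tests
bruteHasseForest <- function(entities, sup) {
  k <- length(sup)
  parent <- rep(NA_integer_, k)
  for (i in seq_len(k)) {
    supersets <- which(vapply(seq_len(k), function(j)
      j != i && length(sup[[j]]) > length(sup[[i]]) &&
        all(sup[[i]] %in% sup[[j]]), logical(1)))
    if (length(supersets))
      parent[i] <- supersets[which.min(lengths(sup)[supersets])]
  }
  root <- vapply(seq_len(k), function(i) {
    while (!is.na(parent[i])) i <- parent[i]
    i
  }, 1L)
  comps <- split(seq_len(k), root)
  lapply(unname(comps), function(id) {
    remap <- match(seq_len(k), id)
    list(entities = entities[id], parent = remap[parent[id]],
         supports = sup[id])
  })
}

# canonical signature of a tree for set comparison
treeSig <- function(tree) {
  o <- order(tree$entities)
  pe <- ifelse(is.na(tree$parent[o]), "", tree$entities[tree$parent[o]])
  paste(tree$entities[o], pe, sep = "<", collapse = "|")
}

# entropy-based VI oracle: H(X) + H(Y) - 2 I(X, Y)
viEntropyOracle <- function(x, y) {
  n <- length(x)
  H <- function(l) {
    p <- table(l) / n
    -sum(p * log(p))
  }
  joint <- table(x, y) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  I <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    r <- joint[i, j]
    if (r > 0) I <- I + r * log(r / (px[i] * py[j]))
  }
  H(x) + H(y) - 2 * I
}

# fast small hierarchical simulation for pipeline tests
smallHierSim <- function(seed = 1, nCells = 120, nGenes = 300) {
  cfg <- hierSimConfig(
    nCells = nCells, nGenes = nGenes,
    markersPerCluster = c(20, 10, 4),
    clustersPerScale = c(2, 4, 8),
    seed = seed,
    params = referenceParams("builtin", nGenes = nGenes,
                             nMarkers = sum(c(20, 10, 4) * c(2, 4, 8)),
                             seed = seed + 99))
  simulateHierarchy(cfg)
}
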