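#' Select highly variable genes by variance of log-normalized expression
#' @param em lognorm ExpressionMatrix.
#' @param n number of genes to keep.
#' @return character vector of gene ids.
#' @export
highlyVariableGenes <- function(em, n = 2000) {
  v <- exprValues(em)
  mu <- Matrix::colSums(v) / nrow(v)
  ex2 <- Matrix::colSums(v^2) / nrow(v)
  vars <- pmax(ex2 - mu^2, 0)
  geneIds(em)[order(vars, decreasing = TRUE)[seq_len(min(n, ncol(v)))]]
}

#' PCA embedding of cells
#'
#' Runs PCA on the (optionally unit-variance scaled) log-normalized values of
#' a gene subset. For all-genes mode the subset defaults to the top
#' highly-variable genes; ligand-only/receptor-only runs pass the expanded
#' subunit gene lists explicitly.
#'
#' @param em lognorm ExpressionMatrix.
#' @param geneSubset "all" or a character vector of gene ids.
#' @param nComponents number of principal components (capped at
#'   min(cells, genes) - 1).
#' @param scale unit-variance scale genes before PCA (constant genes are
#'   left unscaled).
#' @param nHVG number of highly variable genes used when geneSubset = "all".
#' @param provenance provenance tag recorded on the embedding.
#' @return An [Embedding-class].
#' @export
embedCells <- function(em, geneSubset = "all", nComponents = 50, scale = TRUE,
                       nHVG = 2000, provenance = "pca_all_genes") {
  if (layerTag(em) != "lognorm")
    stop("embedCells expects log-normalized input; call logNormalize() first")
  if (identical(geneSubset, "all")) {
    genes <- if (ncol(em) > nHVG) highlyVariableGenes(em, nHVG) else geneIds(em)
  } else {
    genes <- intersect(geneSubset, geneIds(em))
    if (!length(genes)) stop("none of the requested genes are present")
  }
  x <- as.matrix(exprValues(em)[, genes, drop = FALSE])
  maxComp <- min(nrow(x) - 1L, ncol(x))   # rank bound of centered PCA
  if (nComponents > maxComp) {
    if (maxComp < 2L) stop("too few cells/genes for a >= 2D embedding")
    nComponents <- maxComp
  }
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- sweep(x, 2, sds, "/")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = nComponents)
  vec <- pc$x[, seq_len(max(2L, min(nComponents, ncol(pc$x)))), drop = FALSE]
  new("Embedding", cellIds = cellIds(em), vectors = unname(vec),
      provenance = provenance)
}

cosineSimilarityMatrix <- function(v) {
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0))
    stop("all-zero embedding row for cell index ", which(nrm == 0)[1])
  s <- tcrossprod(v / nrm)
  pmin(pmax(s, -1), 1)
}

#' Build a weighted KNN cell graph from an embedding
#'
#' Each cell is linked to its k most cosine-similar neighbors; the directed
#' graph is symmetrized by union (weight = cosine similarity, shared edges
#' keep the common value), negative similarities are clipped to zero, and
#' the diagonal is zero. Ties between equal similarities are broken by lower
#' cell index. If clipping disconnects the graph, components are reconnected
#' by adding the single highest-similarity inter-component edge along a
#' maximum-similarity spanning structure (with a tiny positive floor weight
#' if that similarity is non-positive), and a message is emitted.
#'
#' @param emb an Embedding.
#' @param k neighbors per cell (1 <= k < n).
#' @return A [CellGraph-class].
#' @export
knnGraph <- function(emb, k = 15) {
  v <- embeddingVectors(emb)
  n <- nrow(v)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  s <- cosineSimilarityMatrix(v)
  diag(s) <- -Inf
  # neighbor selection: order by similarity desc, index asc for ties
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(s[i, ], seq_len(n) * -1, decreasing = TRUE)
    idx[i, ] <- o[seq_len(k)]
  }
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(idx))
  ww <- s[cbind(ii, jj)]
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  A <- pmaxSparse(A, Matrix::t(A))          # union symmetrization
  A@x <- pmax(A@x, 0)                       # clip negative cosine weights
  A <- Matrix::drop0(A)
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  A <- repairConnectivity(A, s)
  new("CellGraph", adjacency = A, cellIds = cellIds(emb))
}

# elementwise max of two sparse matrices with identical dims
pmaxSparse <- function(a, b) {
  a <- as(as(a, "CsparseMatrix"), "generalMatrix")
  b <- as(as(b, "CsparseMatrix"), "generalMatrix")
  u <- (a + b + abs(a - b)) / 2
  Matrix::drop0(u)
}

# connected components of a sparse symmetric adjacency (BFS)
graphComponents <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  Al <- Matrix::summary(as(A, "TsparseMatrix"))
  adj <- split(Al$j, Al$i)
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[as.character(u)]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

repairConnectivity <- function(A, s) {
  comp <- graphComponents(A)
  nc <- max(comp)
  if (nc == 1L) return(A)
  message("graph disconnected (", nc, " components); adding ",
          nc * (nc - 1) / 2, " bridging edge(s)")
  diag(s) <- -Inf
  groups <- split(seq_along(comp), comp)
  # best edge for every component pair, so the coarse similarity structure
  # between well-separated blocks survives in the random walk
  for (a in seq_len(nc - 1)) for (b in seq((a + 1), nc)) {
    sub <- s[groups[[a]], groups[[b]], drop = FALSE]
    m <- which.max(sub)
    ri <- ((m - 1) %% nrow(sub)) + 1
    ci <- ((m - 1) %/% nrow(sub)) + 1
    w <- if (sub[m] > 0) sub[m] else 1e-6
    i <- groups[[a]][ri]
    j <- groups[[b]][ci]
    A[i, j] <- w
    A[j, i] <- w
  }
  A
}

#' Export a cell graph as a weighted edge list TSV
#' @param g a CellGraph.
#' @param path output TSV (cell_i, cell_j, weight), each undirected edge once.
#' @export
writeGraphEdges <- function(g, path) {
  tr <- Matrix::summary(as(adjacency(g), "TsparseMatrix"))
  tr <- tr[tr$i < tr$j, , drop = FALSE]
  ids <- cellIds(g)
  utils::write.table(
    data.frame(cell_i = ids[tr$i], cell_j = ids[tr$j], weight = tr$x),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
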