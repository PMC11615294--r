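#' @import methods
#' @importFrom Matrix Matrix rowSums colSums t readMM writeMM sparseMatrix
#' @importClassesFrom Matrix Matrix sparseMatrix generalMatrix CsparseMatrix
NULL

setClassUnion("matrixOrSparse", c("matrix", "Matrix"))

#' ExpressionMatrix: cells x genes expression values
#'
#' Container for a cells-by-genes matrix of non-negative expression values,
#' either raw counts or log-normalized values, together with cell and gene
#' identifiers. Sparse input is kept sparse.
#'
#' @slot values cells x genes matrix (base or Matrix sparse), non-negative.
#' @slot geneIds character vector of unique gene symbols (columns).
#' @slot cellIds character vector of unique cell barcodes (rows).
#' @slot layerTag "raw_counts" or "lognorm".
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  slots = c(values = "matrixOrSparse", geneIds = "character",
            cellIds = "character", layerTag = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != length(object@cellIds))
    msg <- c(msg, "number of rows must equal length of cellIds")
  if (ncol(v) != length(object@geneIds))
    msg <- c(msg, "number of columns must equal length of geneIds")
  if (anyDuplicated(object@cellIds)) msg <- c(msg, "duplicate cellIds")
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicate geneIds")
  mn <- if (inherits(v, "Matrix")) min(v@x, 0) else min(v, 0)
  if (is.finite(mn) && mn < 0) msg <- c(msg, "negative expression entries")
  if (length(object@layerTag) != 1L ||
      !object@layerTag %in% c("raw_counts", "lognorm"))
    msg <- c(msg, "layerTag must be 'raw_counts' or 'lognorm'")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values cells x genes matrix (dense or sparse).
#' @param geneIds,cellIds identifiers; taken from dimnames when missing.
#' @param layerTag "raw_counts" or "lognorm".
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, geneIds = colnames(values),
                             cellIds = rownames(values),
                             layerTag = c("raw_counts", "lognorm")) {
  layerTag <- match.arg(layerTag)
  if (is.null(geneIds)) geneIds <- paste0("gene", seq_len(ncol(values)))
  if (is.null(cellIds)) cellIds <- paste0("cell", seq_len(nrow(values)))
  dimnames(values) <- list(cellIds, geneIds)
  new("ExpressionMatrix", values = values, geneIds = as.character(geneIds),
      cellIds = as.character(cellIds), layerTag = layerTag)
}

#' LRDatabase: ligand-receptor interaction database
#'
#' Ligand and receptor units are gene symbols; multi-subunit complexes join
#' their subunits with "_" (e.g. "Itga6_Itgb4").
#'
#' @slot interactions data.frame with columns ligand, receptor, pathway.
#' @exportClass LRDatabase
setClass("LRDatabase", slots = c(interactions = "data.frame"))

setValidity("LRDatabase", function(object) {
  df <- object@interactions
  msg <- character()
  if (!all(c("ligand", "receptor", "pathway") %in% names(df)))
    msg <- c(msg, "interactions needs columns ligand, receptor, pathway")
  else {
    if (anyDuplicated(df[, c("ligand", "receptor")]))
      msg <- c(msg, "duplicate (ligand, receptor) pairs")
    sub <- unlist(strsplit(c(df$ligand, df$receptor), "_", fixed = TRUE))
    if (length(df$ligand) && (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor)) ||
        any(!nzchar(sub))))
      msg <- c(msg, "empty ligand/receptor unit or subunit symbol")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an LRDatabase
#' @param ligand,receptor,pathway character vectors of equal length.
#' @return An [LRDatabase-class] object.
#' @export
LRDatabase <- function(ligand, receptor, pathway) {
  new("LRDatabase", interactions = data.frame(
    ligand = as.character(ligand), receptor = as.character(receptor),
    pathway = as.character(pathway), stringsAsFactors = FALSE))
}

#' SpatialCoords: 2D coordinates per cell/spot
#' @slot cellIds character vector.
#' @slot xy numeric matrix with two columns.
#' @exportClass SpatialCoords
setClass("SpatialCoords", slots = c(cellIds = "character", xy = "matrix"))

setValidity("SpatialCoords", function(object) {
  msg <- character()
  if (ncol(object@xy) != 2L) msg <- c(msg, "xy must have two columns")
  if (nrow(object@xy) != length(object@cellIds))
    msg <- c(msg, "one coordinate pair per cell required")
  if (any(!is.finite(object@xy))) msg <- c(msg, "non-finite coordinates")
  if (length(msg)) msg else TRUE
})

#' Construct SpatialCoords
#' @param cellIds character vector.
#' @param xy two-column numeric matrix of positions.
#' @export
SpatialCoords <- function(cellIds, xy) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  new("SpatialCoords", cellIds = as.character(cellIds), xy = xy)
}

#' Embedding: low-dimensional cell coordinates
#' @slot cellIds character.
#' @slot vectors cells x d numeric matrix.
#' @slot provenance one of pca_all_genes, pca_ligands, pca_receptors,
#'   pca_plus_spatial.
#' @exportClass Embedding
setClass("Embedding",
  slots = c(cellIds = "character", vectors = "matrix", provenance = "character"))

setValidity("Embedding", function(object) {
  msg <- character()
  if (nrow(object@vectors) != length(object@cellIds))
    msg <- c(msg, "rows of vectors must match cellIds")
  if (ncol(object@vectors) < 2L) msg <- c(msg, "embedding dimension must be >= 2")
  if (any(!is.finite(object@vectors))) msg <- c(msg, "non-finite embedding values")
  if (length(msg)) msg else TRUE
})

#' CellGraph: weighted undirected KNN cell graph
#' @slot adjacency symmetric sparse weight matrix, zero diagonal.
#' @slot cellIds character.
#' @exportClass CellGraph
setClass("CellGraph", slots = c(adjacency = "Matrix", cellIds = "character"))

setValidity("CellGraph", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (nrow(A) != length(object@cellIds))
    msg <- c(msg, "adjacency dimension must match cellIds")
  if (length(A@x) && min(A@x) < 0) msg <- c(msg, "negative edge weights")
  if (any(Matrix::diag(A) != 0)) msg <- c(msg, "nonzero diagonal")
  if (max(abs(A - Matrix::t(A))) > 1e-12)
    msg <- c(msg, "adjacency must be symmetric")
  if (any(Matrix::rowSums(A) <= 0)) msg <- c(msg, "isolated node (zero degree)")
  if (length(msg)) msg else TRUE
})

#' RandomWalkOperator: spectral factors of the random-walk Laplacian
#'
#' Holds the eigendecomposition of the symmetric conjugate
#' D^{1/2} (D^{-1} A) D^{-1/2}, sufficient to evaluate P(t) = exp(-t L)
#' exactly for any Markov time t, plus the closed-form stationary
#' distribution pi = d / sum(d).
#'
#' @slot evectors eigenvectors of the symmetric conjugate.
#' @slot evalues its eigenvalues (of D^{-1/2} A D^{-1/2}).
#' @slot degrees node degree vector.
#' @slot pi stationary distribution.
#' @slot cellIds character.
#' @exportClass RandomWalkOperator
setClass("RandomWalkOperator",
  slots = c(evectors = "matrix", evalues = "numeric", degrees = "numeric",
            pi = "numeric", cellIds = "character"))

#' ScaleScan: Markov-time scan diagnostics
#' @slot logGrid log10 Markov-time grid.
#' @slot times Markov times 10^logGrid.
#' @slot memberships cells x scales matrix of representative partitions.
#' @slot msValues Markov stability of the representative partition per scale.
#' @slot viG mean pairwise VI of the Louvain ensemble per scale.
#' @slot viP scales x scales VI matrix between representative partitions.
#' @slot nCommunities communities per representative partition.
#' @slot cellIds character.
#' @exportClass ScaleScan
setClass("ScaleScan",
  slots = c(logGrid = "numeric", times = "numeric", memberships = "matrix",
            msValues = "numeric", viG = "numeric", viP = "matrix",
            nCommunities = "integer", cellIds = "character"))

setValidity("ScaleScan", function(object) {
  msg <- character()
  if (is.unsorted(object@logGrid, strictly = TRUE))
    msg <- c(msg, "grid must be strictly increasing")
  if (any(object@viG < -1e-12)) msg <- c(msg, "negative VI_g")
  if (!isSymmetric(object@viP, tol = 1e-8)) msg <- c(msg, "viP must be symmetric")
  if (any(abs(diag(object@viP)) > 1e-10)) msg <- c(msg, "viP diagonal must be zero")
  if (length(msg)) msg else TRUE
})

#' HierarchicalClustering: partitions at the selected Markov scales
#' @slot scaleIndex indices into the scan grid, ordered coarse to fine.
#' @slot times Markov times of the selected scales.
#' @slot memberships cells x selected-scales integer matrix (1-based labels,
#'   relabeled by decreasing community size).
#' @slot cellIds character.
#' @slot diagnostics data.frame (scale index, time, n communities, MS, VI_g).
#' @exportClass HierarchicalClustering
setClass("HierarchicalClustering",
  slots = c(scaleIndex = "integer", times = "numeric", memberships = "matrix",
            cellIds = "character", diagnostics = "data.frame"))

setValidity("HierarchicalClustering", function(object) {
  msg <- character()
  if (length(object@times) < 1L) msg <- c(msg, "at least one selected scale required")
  if (ncol(object@memberships) != length(object@times))
    msg <- c(msg, "memberships columns must match selected scales")
  if (length(msg)) msg else TRUE
})

#' SupportMatrix: binarized expression supports
#' @slot entities entity names (units or per-pair unions).
#' @slot supports list of integer vectors of supporting cell indices.
#' @slot nCells total number of cells.
#' @slot cellIds character.
#' @slot tau binarization threshold used.
#' @exportClass SupportMatrix
setClass("SupportMatrix",
  slots = c(entities = "character", supports = "list", nCells = "integer",
            cellIds = "character", tau = "numeric"))

setValidity("SupportMatrix", function(object) {
  msg <- character()
  if (length(object@entities) != length(object@supports))
    msg <- c(msg, "one support per entity required")
  if (length(object@supports) && any(vapply(object@supports, length, 1L) == 0L))
    msg <- c(msg, "entities with empty support must be removed")
  if (length(msg)) msg else TRUE
})

#' TreeSet: rooted signaling trees over expression supports
#'
#' Each tree is a list with elements `entities` (character), `parent`
#' (integer, NA at the root) and `supports` (list of integer cell-index
#' vectors), satisfying child-support inclusion and sibling disjointness.
#'
#' @slot trees list of trees.
#' @slot kind "ligand", "receptor" or "lr_union".
#' @slot tau,eps binarization threshold and relation tolerance used.
#' @slot nCells integer.
#' @exportClass TreeSet
setClass("TreeSet",
  slots = c(trees = "list", kind = "character", tau = "numeric",
            eps = "numeric", nCells = "integer"))
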