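#' @name accessors
#' @title Accessors for hierCCC classes
#' @param x an object.
#' @description Slot accessors; user code should use these rather than `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setMethod("cellIds", "ExpressionMatrix", function(x) x@cellIds)
#' @rdname accessors
#' @export
setMethod("cellIds", "SpatialCoords", function(x) x@cellIds)
#' @rdname accessors
#' @export
setMethod("cellIds", "Embedding", function(x) x@cellIds)
#' @rdname accessors
#' @export
setMethod("cellIds", "CellGraph", function(x) x@cellIds)
#' @rdname accessors
#' @export
setMethod("cellIds", "HierarchicalClustering", function(x) x@cellIds)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) x@geneIds)

#' @rdname accessors
#' @export
setGeneric("layerTag", function(x) standardGeneric("layerTag"))
#' @rdname accessors
#' @export
setMethod("layerTag", "ExpressionMatrix", function(x) x@layerTag)

#' @rdname accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))
#' @rdname accessors
#' @export
setMethod("interactions", "LRDatabase", function(x) x@interactions)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "CellGraph", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))
#' @rdname accessors
#' @export
setMethod("embeddingVectors", "Embedding", function(x) x@vectors)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "Embedding", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("stationaryDistribution", function(x) standardGeneric("stationaryDistribution"))
#' @rdname accessors
#' @export
setMethod("stationaryDistribution", "RandomWalkOperator", function(x) x@pi)

#' @rdname accessors
#' @export
setGeneric("markovTimes", function(x) standardGeneric("markovTimes"))
#' @rdname accessors
#' @export
setMethod("markovTimes", "ScaleScan", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("markovTimes", "HierarchicalClustering", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))
#' @rdname accessors
#' @export
setMethod("memberships", "ScaleScan", function(x) x@memberships)
#' @rdname accessors
#' @export
setMethod("memberships", "HierarchicalClustering", function(x) x@memberships)

#' @rdname accessors
#' @export
setGeneric("scanDiagnostics", function(x) standardGeneric("scanDiagnostics"))
#' @rdname accessors
#' @export
setMethod("scanDiagnostics", "ScaleScan", function(x)
  data.frame(logTime = x@logGrid, time = x@times,
             nCommunities = x@nCommunities, ms = x@msValues, viG = x@viG))
#' @rdname accessors
#' @export
setMethod("scanDiagnostics", "HierarchicalClustering", function(x) x@diagnostics)

#' @rdname accessors
#' @export
setGeneric("viMatrix", function(x) standardGeneric("viMatrix"))
#' @rdname accessors
#' @export
setMethod("viMatrix", "ScaleScan", function(x) x@viP)

#' @rdname accessors
#' @export
setGeneric("trees", function(x) standardGeneric("trees"))
#' @rdname accessors
#' @export
setMethod("trees", "TreeSet", function(x) x@trees)

#' @rdname accessors
#' @export
setGeneric("supports", function(x) standardGeneric("supports"))
#' @rdname accessors
#' @export
setMethod("supports", "SupportMatrix", function(x) {
  names(x@supports) <- x@entities
  x@supports
})

#' @rdname accessors
#' @export
setGeneric("entities", function(x) standardGeneric("entities"))
#' @rdname accessors
#' @export
setMethod("entities", "SupportMatrix", function(x) x@entities)

#' Number of cells and genes
#' @param x an ExpressionMatrix.
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]%s\n",
              nrow(object@values), ncol(object@values), object@layerTag,
              if (inherits(object@values, "sparseMatrix")) " (sparse)" else ""))
})

setMethod("show", "LRDatabase", function(object) {
  df <- object@interactions
  cat(sprintf("LRDatabase: %d interactions, %d pathways\n",
              nrow(df), length(unique(df$pathway))))
})

setMethod("show", "CellGraph", function(object) {
  cat(sprintf("CellGraph: %d cells, %d undirected edges\n",
              length(object@cellIds),
              as.integer(Matrix::nnzero(object@adjacency) / 2)))
})

setMethod("show", "Embedding", function(object) {
  cat(sprintf("Embedding: %d cells x %d dims [%s]\n",
              nrow(object@vectors), ncol(object@vectors), object@provenance))
})

setMethod("show", "ScaleScan", function(object) {
  cat(sprintf("ScaleScan: %d Markov times in [%.3g, %.3g], %d-%d communities\n",
              length(object@times), min(object@times), max(object@times),
              min(object@nCommunities), max(object@nCommunities)))
})

setMethod("show", "HierarchicalClustering", function(object) {
  k <- apply(object@memberships, 2, function(m) length(unique(m)))
  cat(sprintf("HierarchicalClustering: %d scales (coarse to fine), communities: %s\n",
              length(object@times), paste(k, collapse = "/")))
})

setMethod("show", "TreeSet", function(object) {
  cat(sprintf("TreeSet [%s]: %d trees (tau=%g, eps=%g)\n", object@kind,
              length(object@trees), object@tau, object@eps))
})

setMethod("show", "SupportMatrix", function(object) {
  cat(sprintf("SupportMatrix: %d entities over %d cells (tau=%g)\n",
              length(object@entities), object@nCells, object@tau))
})
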