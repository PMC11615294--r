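#' Default pipeline configuration
#'
#' One declarative list of every tunable parameter with the package
#' defaults. [validateRunConfig()] rejects unknown keys.
#'
#' @return named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(
    k = 15, nComponents = 50, nHVG = 2000, scaleGenes = TRUE,
    mode = "all",                      # all | ligands | receptors
    gridMin = -1, gridMax = 4, gridPoints = 100, louvainRuns = 100,
    basinTheta = 0.1, basinMinWidth = 5,
    tau = 0, eps = 0, minCells = 10, minNodes = 2,
    kind = "ligand",                   # ligand | receptor | lr_union
    spatialWeight = 1, radius = NULL,
    pThreshold = 1e-3, Kh = 0.5,
    seed = 0)
}

#' Validate and merge a pipeline configuration
#' @param config partial named list overriding defaults.
#' @return full config list.
#' @export
validateRunConfig <- function(config = list()) {
  def <- defaultRunConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(def, config)
}

#' Global hierarchical clustering pipeline
#'
#' Log-normalizes raw counts if needed, embeds (all genes / ligands only /
#' receptors only, optionally with scaled spatial coordinates appended),
#' builds the KNN graph, scans Markov times, and selects robust scales.
#'
#' @param em an ExpressionMatrix.
#' @param config config list (see [defaultRunConfig()]).
#' @param db LRDatabase (required for ligand/receptor modes).
#' @param coords optional SpatialCoords (spatial variant).
#' @param verbose print scan progress.
#' @return list: hier ([HierarchicalClustering-class]), scan, graph,
#'   embedding, em (log-normalized).
#' @export
multiscaleCluster <- function(em, config = list(), db = NULL, coords = NULL,
                              verbose = FALSE) {
  cfg <- validateRunConfig(config)
  if (cfg$mode != "all" && is.null(db))
    stop("mode '", cfg$mode, "' requires an LR database")
  if (layerTag(em) == "raw_counts") {
    em <- dropEmptyCells(em)
    em <- logNormalize(em)
  }
  subset <- switch(cfg$mode,
    all = "all",
    ligands = dbGenes(db, "ligand"),
    receptors = dbGenes(db, "receptor"))
  prov <- switch(cfg$mode, all = "pca_all_genes", ligands = "pca_ligands",
                 receptors = "pca_receptors")
  emb <- embedCells(em, geneSubset = subset, nComponents = cfg$nComponents,
                    scale = cfg$scaleGenes, nHVG = cfg$nHVG, provenance = prov)
  if (!is.null(coords))
    emb <- augmentEmbedding(emb, coords, weight = cfg$spatialWeight)
  g <- knnGraph(emb, k = cfg$k)
  op <- buildOperator(g)
  scan <- scanScales(op, gridMin = cfg$gridMin, gridMax = cfg$gridMax,
                     gridPoints = cfg$gridPoints, nRuns = cfg$louvainRuns,
                     seed = cfg$seed, verbose = verbose)
  hier <- selectScales(scan, basinTheta = cfg$basinTheta,
                       basinMinWidth = cfg$basinMinWidth)
  list(hier = hier, scan = scan, graph = g, embedding = emb, em = em,
       config = cfg)
}

#' Full global-hierarchy analysis with file outputs
#'
#' Runs [multiscaleCluster()], assigns ligand/receptor units to clusters,
#' derives the ordered specific-pair list, and scores interactions at the
#' finest selected scale; writes cluster TSV, diagnostics TSV, VI matrix
#' CSV, specific-pairs TSV, interactions TSV, and a reproducibility
#' manifest.
#'
#' @param em an ExpressionMatrix.
#' @param db an LRDatabase.
#' @param outDir output directory (created).
#' @param config config list overrides.
#' @param coords optional SpatialCoords.
#' @param verbose print progress.
#' @return (invisibly) list of in-memory results.
#' @export
runHierarchicalPipeline <- function(em, db, outDir, config = list(),
                                    coords = NULL, verbose = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- multiscaleCluster(em, config, db = db, coords = coords,
                           verbose = verbose)
  cfg <- res$config
  units <- unique(c(dbUnits(db, "ligand"), dbUnits(db, "receptor")))
  assignments <- suppressWarnings(assignMarkers(res$em, res$hier, units))
  pairs <- specificPairs(assignments, db, pThreshold = cfg$pThreshold)
  groups <- hierarchyGroups(res$hier)
  ints <- if (nrow(pairs)) hierarchyInteractions(res$em, groups, pairs,
                                                 Kh = cfg$Kh) else NULL
  writeClusterAssignments(res$hier, file.path(outDir, "clusters.tsv"))
  utils::write.table(scanDiagnostics(res$scan),
                     file.path(outDir, "scan_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(viMatrix(res$scan), file.path(outDir, "vi_matrix.csv"),
                   row.names = FALSE)
  utils::write.table(pairs, file.path(outDir, "specific_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ints))
    utils::write.table(ints, file.path(outDir, "interactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeManifest(file.path(outDir, "manifest.json"), cfg,
                stage = "hierarchical",
                nCells = nrow(exprValues(res$em)), nGenes = ncol(exprValues(res$em)))
  invisible(c(res, list(assignments = assignments, pairs = pairs,
                        interactions = ints)))
}

#' Local signaling-tree analysis with file outputs
#'
#' Runs [detectTrees()] (optionally with spatial support restriction),
#' writes trees as nested JSON and Newick, the frequency ranking TSV, and a
#' manifest.
#'
#' @param em raw-count ExpressionMatrix.
#' @param db an LRDatabase.
#' @param outDir output directory (created).
#' @param config config list overrides (kind, tau, eps, minCells, minNodes,
#'   radius).
#' @param coords optional SpatialCoords; when given and kind is ligand or
#'   receptor, supports are restricted to spots with a cognate partner
#'   within the radius before tree detection.
#' @return (invisibly) the TreeSet.
#' @export
runTreePipeline <- function(em, db, outDir, config = list(), coords = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- validateRunConfig(config)
  if (!is.null(coords) && cfg$kind %in% c("ligand", "receptor")) {
    idx <- neighborhoodIndex(coords, r = cfg$radius)
    sm <- binarizeSupports(em, dbUnits(db, cfg$kind), tau = cfg$tau,
                           minCells = cfg$minCells)
    other <- if (cfg$kind == "ligand") "receptor" else "ligand"
    psm <- binarizeSupports(em, dbUnits(db, other), tau = cfg$tau,
                            minCells = cfg$minCells)
    sm <- suppressWarnings(restrictSupports(sm, psm, db, idx, side = cfg$kind,
                                            minCells = cfg$minCells))
    ts <- detectTreesFromSupports(sm, kind = cfg$kind, eps = cfg$eps,
                                  minNodes = cfg$minNodes)
  } else {
    ts <- detectTrees(em, db, kind = cfg$kind, tau = cfg$tau, eps = cfg$eps,
                      minCells = cfg$minCells, minNodes = cfg$minNodes)
  }
  treesToJSON(ts, file.path(outDir, "trees.json"))
  writeLines(vapply(trees(ts), treeToNewick, character(1)),
             file.path(outDir, "trees.nwk"))
  utils::write.table(frequencyRanking(ts),
                     file.path(outDir, "frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeManifest(file.path(outDir, "manifest.json"), cfg, stage = "trees",
                nCells = nrow(exprValues(em)), nGenes = ncol(exprValues(em)))
  invisible(ts)
}

writeManifest <- function(path, cfg, stage, ...) {
  cfg <- cfg[order(names(cfg))]
  payload <- list(stage = stage,
                  package = "hierCCC",
                  version = as.character(utils::packageVersion("hierCCC")),
                  config = cfg, inputs = list(...))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(NULL)
}
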