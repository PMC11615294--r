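#' Read an expression matrix from a dense CSV/TSV file
#'
#' Expected layout: cells as rows, a header row of gene ids, and the first
#' column holding cell ids. The separator is inferred from the file
#' extension (".tsv"/".txt" = tab, otherwise comma).
#'
#' @param path file path.
#' @param layerTag "raw_counts" or "lognorm".
#' @param sep field separator; inferred from the extension when NULL.
#' @return An [ExpressionMatrix-class].
#' @export
readExpression <- function(path, layerTag = c("raw_counts", "lognorm"),
                           sep = NULL) {
  layerTag <- match.arg(layerTag)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("format error in ", path, ": non-numeric entries")
  if (any(m < 0)) stop("validation error in ", path, ": negative entries")
  ExpressionMatrix(Matrix::Matrix(m, sparse = TRUE),
                   geneIds = colnames(df), cellIds = rownames(df),
                   layerTag = layerTag)
}

#' Read a 10x-style sparse triplet expression matrix
#'
#' The triplet consists of a MatrixMarket coordinate file, a one-column gene
#' list and a one-column barcode list. Both gene-major (genes x cells, the
#' 10x convention) and cell-major orientations are accepted; the orientation
#' is auto-detected by matching the id-list lengths against the matrix
#' dimensions. A square matrix with equally long id lists is ambiguous and
#' requires `orientation` to be given explicitly.
#'
#' @param matrixPath MatrixMarket (.mtx) file.
#' @param genesPath one-column gene id file.
#' @param barcodesPath one-column cell barcode file.
#' @param layerTag "raw_counts" or "lognorm".
#' @param orientation "auto", "gene_major" (rows = genes) or "cell_major".
#' @return An [ExpressionMatrix-class] with cells as rows (memory stays
#'   proportional to the number of nonzeros).
#' @export
readExpressionTriplet <- function(matrixPath, genesPath, barcodesPath,
                                  layerTag = c("raw_counts", "lognorm"),
                                  orientation = c("auto", "gene_major", "cell_major")) {
  layerTag <- match.arg(layerTag)
  orientation <- match.arg(orientation)
  for (p in c(matrixPath, genesPath, barcodesPath))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrixPath)
  genes <- utils::read.table(genesPath, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(barcodesPath, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (orientation == "auto") {
    geneMajor <- nrow(m) == length(genes) && ncol(m) == length(cells)
    cellMajor <- nrow(m) == length(cells) && ncol(m) == length(genes)
    if (geneMajor && cellMajor && length(genes) != length(cells))
      stop("internal orientation detection conflict")  # unreachable
    if (geneMajor && cellMajor)
      stop("format error: square matrix with equal id-list lengths; ",
           "pass orientation explicitly")
    if (!geneMajor && !cellMajor)
      stop("format error: dimensions of ", matrixPath, " (", nrow(m), " x ",
           ncol(m), ") match neither ", genesPath, " (", length(genes),
           ") nor ", barcodesPath, " (", length(cells), ")")
    orientation <- if (geneMajor) "gene_major" else "cell_major"
  } else {
    nr <- if (orientation == "gene_major") length(genes) else length(cells)
    nc <- if (orientation == "gene_major") length(cells) else length(genes)
    if (nrow(m) != nr || ncol(m) != nc)
      stop("format error: matrix dimensions do not match id lists (",
           matrixPath, ")")
  }
  if (orientation == "gene_major") m <- Matrix::t(m)
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  if (length(m@x) && min(m@x) < 0)
    stop("validation error: negative entries in ", matrixPath)
  ExpressionMatrix(m, geneIds = genes, cellIds = cells, layerTag = layerTag)
}

#' Write an ExpressionMatrix as a sparse triplet (MatrixMarket + id lists)
#'
#' Written gene-major (genes x cells), the 10x convention, so the files
#' round-trip through [readExpressionTriplet()].
#'
#' @param em an ExpressionMatrix.
#' @param matrixPath,genesPath,barcodesPath output paths.
#' @export
writeExpressionTriplet <- function(em, matrixPath, genesPath, barcodesPath) {
  m <- Matrix::t(Matrix::Matrix(exprValues(em), sparse = TRUE))
  Matrix::writeMM(as(m, "generalMatrix"), matrixPath)
  writeLines(geneIds(em), genesPath)
  writeLines(cellIds(em), barcodesPath)
  invisible(NULL)
}

#' Write an ExpressionMatrix as a dense CSV (cells as rows)
#' @param em an ExpressionMatrix.
#' @param path output path.
#' @export
writeExpression <- function(em, path) {
  m <- as.matrix(exprValues(em))
  utils::write.csv(data.frame(cell_id = cellIds(em), m, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a ligand-receptor interaction database from CSV
#'
#' Requires columns `ligand`, `receptor`, `pathway`. Multi-subunit units
#' join subunits with "_". Duplicated (ligand, receptor) rows are collapsed
#' with a warning.
#'
#' @param path CSV file.
#' @return An [LRDatabase-class].
#' @export
readLRDatabase <- function(path) {
  if (!file.exists(path)) stop("LR database file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "pathway")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (any(!nzchar(df$ligand)) || any(is.na(df$ligand)) ||
      any(!nzchar(df$receptor)) || any(is.na(df$receptor)))
    stop("validation error in ", path, ": empty ligand or receptor field")
  dup <- duplicated(df[, c("ligand", "receptor")])
  if (any(dup)) {
    warning(sum(dup), " duplicated interaction row(s) collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  LRDatabase(df$ligand, df$receptor, df$pathway)
}

#' Split a unit into its subunit gene symbols
#' @param unit character vector of units (subunits joined by "_").
#' @return list of character vectors.
#' @export
unitSubunits <- function(unit) strsplit(unit, "_", fixed = TRUE)

#' All ligand (or receptor) units of a database
#' @param db an LRDatabase.
#' @param side "ligand" or "receptor".
#' @return character vector of unique units.
#' @export
dbUnits <- function(db, side = c("ligand", "receptor")) {
  side <- match.arg(side)
  unique(interactions(db)[[side]])
}

#' Genes making up the ligand or receptor side of a database
#' @inheritParams dbUnits
#' @return character vector of unique gene symbols (subunits expanded).
#' @export
dbGenes <- function(db, side = c("ligand", "receptor")) {
  unique(unlist(unitSubunits(dbUnits(db, side))))
}

#' Read per-cell 2D coordinates from CSV (cell_id,x,y)
#' @param path CSV file.
#' @return A [SpatialCoords-class].
#' @export
readSpatialCoords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("format error in ", path, ": need columns cell_id,x,y")
  SpatialCoords(df$cell_id, cbind(df$x, df$y))
}

#' Read per-cell labels from CSV (cell_id,label)
#' @param path CSV file.
#' @return data.frame with columns cell_id and label.
#' @export
readCellLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "label") %in% names(df)))
    stop("format error in ", path, ": need columns cell_id,label")
  if (any(is.na(df$label)))
    stop("validation error in ", path, ": labels must cover all cells")
  df
}

#' Drop cells with zero total counts
#' @param em an ExpressionMatrix.
#' @return ExpressionMatrix without the empty cells (warning if any dropped).
#' @export
dropEmptyCells <- function(em) {
  tot <- Matrix::rowSums(exprValues(em))
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0), " cell(s) with zero total counts")
    keep <- tot > 0
    em <- ExpressionMatrix(exprValues(em)[keep, , drop = FALSE],
                           geneIds = geneIds(em),
                           cellIds = cellIds(em)[keep],
                           layerTag = layerTag(em))
  }
  em
}

#' Remove low-coverage spots/cells by total UMI count
#' @param em raw-count ExpressionMatrix.
#' @param minCounts keep cells with total counts >= minCounts.
#' @return filtered ExpressionMatrix.
#' @export
filterCellsByCounts <- function(em, minCounts = 200) {
  stopifnot(layerTag(em) == "raw_counts")
  keep <- Matrix::rowSums(exprValues(em)) >= minCounts
  ExpressionMatrix(exprValues(em)[keep, , drop = FALSE], geneIds = geneIds(em),
                   cellIds = cellIds(em)[keep], layerTag = "raw_counts")
}

#' Log-normalize a raw count matrix
#'
#' Scales every cell to the median total count across cells, then applies
#' log(1 + x). Cells with zero totals are an error; filter them first with
#' [dropEmptyCells()].
#'
#' @param em raw-count ExpressionMatrix.
#' @return lognorm ExpressionMatrix.
#' @export
logNormalize <- function(em) {
  if (layerTag(em) != "raw_counts")
    stop("logNormalize expects a raw_counts matrix")
  v <- exprValues(em)
  tot <- Matrix::rowSums(v)
  if (any(tot == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(cellIds(em)[tot == 0], 10), collapse = ", "),
         "; filter with dropEmptyCells() first")
  f <- stats::median(tot) / tot
  if (inherits(v, "sparseMatrix")) {
    out <- Matrix::Diagonal(x = f) %*% v
    out@x <- log1p(out@x)
  } else {
    out <- log1p(v * f)
  }
  ExpressionMatrix(out, geneIds = geneIds(em), cellIds = cellIds(em),
                   layerTag = "lognorm")
}
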