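#' Append scaled spatial coordinates to a PCA embedding
#'
#' Each coordinate axis is min-max scaled to [0, 1], multiplied by `weight`,
#' and concatenated to the embedding columns. Weight 0 leaves downstream
#' clustering identical to the nonspatial run; large weights drive the
#' clustering toward a pure spatial tessellation.
#'
#' @param emb an Embedding.
#' @param coords a SpatialCoords covering the embedding's cells.
#' @param weight multiplier for the two scaled coordinate columns.
#' @return An [Embedding-class] with provenance "pca_plus_spatial".
#' @export
augmentEmbedding <- function(emb, coords, weight = 1) {
  idx <- match(cellIds(emb), cellIds(coords))
  if (anyNA(idx))
    stop("missing coordinates for cell(s): ",
         paste(utils::head(cellIds(emb)[is.na(idx)], 10), collapse = ", "))
  xy <- coords@xy[idx, , drop = FALSE]
  rng <- apply(xy, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  scaled <- sweep(sweep(xy, 2, rng[1, ], "-"), 2, span, "/")
  new("Embedding", cellIds = cellIds(emb),
      vectors = cbind(embeddingVectors(emb), scaled * weight),
      provenance = "pca_plus_spatial")
}

#' Radius-neighborhood index over spatial coordinates
#'
#' Exact Euclidean neighbor lists within radius r (original coordinate
#' units), self excluded, found through a uniform grid of bucket size r.
#'
#' @param coords a SpatialCoords.
#' @param r neighborhood radius; when NULL, twice the 5th percentile of the
#'   nearest-neighbor distance distribution.
#' @return list with `neighbors` (list of integer vectors), `r`, `cellIds`.
#' @export
neighborhoodIndex <- function(coords, r = NULL) {
  xy <- coords@xy
  n <- nrow(xy)
  if (is.null(r)) r <- 2 * stats::quantile(nearestNeighborDistances(xy), 0.05)
  cellx <- floor((xy[, 1] - min(xy[, 1])) / r)
  celly <- floor((xy[, 2] - min(xy[, 2])) / r)
  key <- paste(cellx, celly)
  buckets <- split(seq_len(n), key)
  nbrs <- vector("list", n)
  r2 <- r^2
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cellx[i] + dx, celly[i] + dy)
      b <- buckets[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    nbrs[[i]] <- sort(cand[d2 <= r2 & cand != i])
  }
  list(neighbors = nbrs, r = as.numeric(r), cellIds = coords@cellIds)
}

nearestNeighborDistances <- function(xy) {
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Restrict supports to spots with a cognate partner nearby
#'
#' A ligand spot stays in a ligand unit's support only if some neighbor
#' (within the index radius) supports at least one cognate receptor unit of
#' that ligand in the database; symmetric for receptors via `side`. Units
#' with no cognate partner in the database get an emptied support with a
#' warning. The operation is contractive (filtered support is a subset of
#' the original) and monotone in the radius.
#'
#' @param sm SupportMatrix of the side being filtered.
#' @param partnerSm SupportMatrix of the cognate side, over the same spots.
#' @param db an LRDatabase.
#' @param idx a [neighborhoodIndex()] over the same spots.
#' @param side which side `sm` holds: "ligand" or "receptor".
#' @param minCells entities falling below this support size are dropped.
#' @return filtered [SupportMatrix-class].
#' @export
restrictSupports <- function(sm, partnerSm, db, idx,
                             side = c("ligand", "receptor"), minCells = 1) {
  side <- match.arg(side)
  if (sm@nCells != partnerSm@nCells)
    stop("support matrices must index the same spot set")
  ia <- interactions(db)
  partnerOf <- function(u) {
    labels <- strsplit(u, "=", fixed = TRUE)[[1]]
    if (side == "ligand") unique(ia$receptor[ia$ligand %in% labels])
    else unique(ia$ligand[ia$receptor %in% labels])
  }
  partnerLabels <- lapply(partnerSm@entities,
                          function(e) strsplit(e, "=", fixed = TRUE)[[1]])
  ents <- character()
  sups <- list()
  for (i in seq_along(sm@entities)) {
    partners <- partnerOf(sm@entities[i])
    hit <- which(vapply(partnerLabels, function(l) any(l %in% partners),
                        logical(1)))
    if (!length(partners) || !length(hit)) {
      warning("no cognate partner with support for ", sm@entities[i],
              "; support emptied")
      next
    }
    partnerSpots <- logical(sm@nCells)
    partnerSpots[unique(unlist(partnerSm@supports[hit]))] <- TRUE
    keep <- vapply(sm@supports[[i]], function(s) {
      nb <- idx$neighbors[[s]]
      length(nb) > 0 && any(partnerSpots[nb])
    }, logical(1))
    s2 <- sm@supports[[i]][keep]
    if (length(s2) < minCells) next
    ents <- c(ents, sm@entities[i])
    sups[[length(sups) + 1]] <- s2
  }
  new("SupportMatrix", entities = ents, supports = sups,
      nCells = sm@nCells, cellIds = sm@cellIds, tau = sm@tau)
}

#' Spatial neighborhood enrichment z-scores per label
#'
#' Observed count of same-label neighbor pairs per label, z-scored against
#' `nPerm` random label permutations (fixed seed). Labels with fewer than
#' two cells, or degenerate permutation variance, are reported NA.
#'
#' @param labels character/factor label per indexed cell.
#' @param idx a [neighborhoodIndex()].
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @return data.frame: label, observed, z.
#' @export
neighborhoodEnrichment <- function(labels, idx, nPerm = 200, seed = 0) {
  labels <- as.character(labels)
  n <- length(idx$neighbors)
  if (length(labels) != n) stop("labels must cover all indexed cells")
  ii <- rep(seq_len(n), lengths(idx$neighbors))
  jj <- unlist(idx$neighbors)
  up <- ii < jj                     # each undirected pair once
  ii <- ii[up]; jj <- jj[up]
  uniq <- sort(unique(labels))
  countSame <- function(lab) {
    same <- lab[ii] == lab[jj]
    tab <- table(factor(lab[ii][same], levels = uniq))
    as.numeric(tab)
  }
  obs <- countSame(labels)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- matrix(0, nPerm, length(uniq))
  for (p in seq_len(nPerm)) perm[p, ] <- countSame(sample(labels))
  mu <- colMeans(perm)
  sd_ <- apply(perm, 2, stats::sd)
  z <- ifelse(sd_ > 0, (obs - mu) / sd_, NA_real_)
  sizes <- as.numeric(table(factor(labels, levels = uniq)))
  z[sizes < 2] <- NA_real_
  data.frame(label = uniq, observed = obs, z = z)
}
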