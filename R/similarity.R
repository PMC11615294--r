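#' Multiscale mean-expression profile of a unit
#'
#' For every selected scale, the unit's mean expression over each cluster at
#' that scale, collected as a list of vectors.
#'
#' @param em an ExpressionMatrix aligned with `hier`.
#' @param hier a HierarchicalClustering.
#' @param unit unit name (or a precomputed per-cell numeric vector).
#' @return list with `vectors` (one numeric vector per scale) and `times`.
#' @export
multiscaleProfile <- function(em, hier, unit) {
  x <- if (is.numeric(unit)) unit else unitExpression(em, unit)
  if (is.null(x)) return(NULL)
  vecs <- lapply(seq_along(hier@times), function(s) {
    m <- hier@memberships[, s]
    as.numeric(tapply(x, m, mean)[as.character(sort(unique(m)))])
  })
  list(vectors = vecs, times = hier@times)
}

# weight of scale with Markov time T: 1 / (ln(max(T, 1)) + 1), so coarser
# (larger-time) scales contribute less; clamping at 1 keeps weights in (0, 1]
scaleWeight <- function(times) 1 / (log(pmax(times, 1)) + 1)

#' Markov-time-weighted cosine similarity between two multiscale profiles
#'
#' sum over scales of w_i * cosine(u_i, v_i) with w_i = 1/(ln(max(T_i,1))+1).
#' A zero vector contributes 0 at its scale.
#'
#' @param p1,p2 profiles from [multiscaleProfile()] over the same hierarchy.
#' @return scalar, bounded by sum(w) in absolute value.
#' @export
weightedSimilarity <- function(p1, p2) {
  if (length(p1$vectors) != length(p2$vectors) ||
      any(lengths(p1$vectors) != lengths(p2$vectors)) ||
      !isTRUE(all.equal(p1$times, p2$times)))
    stop("profiles have mismatched scale structure")
  w <- scaleWeight(p1$times)
  s <- 0
  for (i in seq_along(w)) {
    u <- p1$vectors[[i]]
    v <- p2$vectors[[i]]
    nu <- sqrt(sum(u^2))
    nv <- sqrt(sum(v^2))
    if (nu > 0 && nv > 0) s <- s + w[i] * sum(u * v) / (nu * nv)
  }
  s
}

#' Pairwise similarity matrix of ligand-receptor pairs
#'
#' The similarity of two LR pairs is the ligand-side weighted similarity
#' plus the receptor-side weighted similarity of their multiscale profiles.
#'
#' @param em ExpressionMatrix aligned with `hier`.
#' @param hier a HierarchicalClustering.
#' @param pairs data.frame with columns ligand and receptor (e.g. rows of
#'   [specificPairs()] output or of [interactions()]).
#' @return list: `sim` symmetric matrix, `ids` "ligand->receptor" labels.
#' @export
pairSimilarityMatrix <- function(em, hier, pairs) {
  ids <- paste0(pairs$ligand, "->", pairs$receptor)
  profL <- lapply(pairs$ligand, function(u) multiscaleProfile(em, hier, u))
  profR <- lapply(pairs$receptor, function(u) multiscaleProfile(em, hier, u))
  ok <- !vapply(profL, is.null, logical(1)) & !vapply(profR, is.null, logical(1))
  ids <- ids[ok]
  profL <- profL[ok]
  profR <- profR[ok]
  k <- length(ids)
  sim <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) for (j in i:k) {
    sim[i, j] <- sim[j, i] <- weightedSimilarity(profL[[i]], profL[[j]]) +
      weightedSimilarity(profR[[i]], profR[[j]])
  }
  list(sim = sim, ids = ids)
}

#' Pairwise similarity matrix of pathways
#'
#' A pathway's ligand (receptor) expression is the per-cell sum of its member
#' ligand (receptor) units' expression; similarity of two pathways is the
#' weighted similarity of the ligand-side profiles plus the receptor-side
#' profiles. Pathways with no detected member unit are excluded with a
#' warning.
#'
#' @param em ExpressionMatrix aligned with `hier`.
#' @param hier a HierarchicalClustering.
#' @param db an LRDatabase.
#' @param pathways pathways to include (default: all in db).
#' @return list: `sim` symmetric matrix, `ids` pathway names.
#' @export
pathwaySimilarityMatrix <- function(em, hier, db,
                                    pathways = unique(interactions(db)$pathway)) {
  ia <- interactions(db)
  sideSum <- function(units) {
    xs <- lapply(unique(units), function(u)
      suppressWarnings(unitExpression(em, u)))
    xs <- xs[!vapply(xs, is.null, logical(1))]
    if (!length(xs)) return(NULL)
    Reduce(`+`, xs)
  }
  profs <- lapply(pathways, function(pw) {
    rows <- ia$pathway == pw
    l <- sideSum(ia$ligand[rows])
    r <- sideSum(ia$receptor[rows])
    if (is.null(l) || is.null(r)) return(NULL)
    list(L = multiscaleProfile(em, hier, l), R = multiscaleProfile(em, hier, r))
  })
  ok <- !vapply(profs, is.null, logical(1))
  if (any(!ok))
    warning("pathway(s) with no detected members excluded: ",
            paste(pathways[!ok], collapse = ", "))
  pathways <- pathways[ok]
  profs <- profs[ok]
  k <- length(pathways)
  sim <- matrix(0, k, k, dimnames = list(pathways, pathways))
  for (i in seq_len(k)) for (j in i:k) {
    sim[i, j] <- sim[j, i] <-
      weightedSimilarity(profs[[i]]$L, profs[[j]]$L) +
      weightedSimilarity(profs[[i]]$R, profs[[j]]$R)
  }
  list(sim = sim, ids = pathways)
}

#' Embed a similarity matrix in 2D and group items
#'
#' Converts the similarity matrix to distances (max(sim) - sim), embeds with
#' seeded classical multidimensional scaling into 2D, and clusters with
#' K-means (fixed seed, multiple restarts). Deterministic given the seed.
#'
#' @param sim symmetric similarity matrix (rownames = item ids).
#' @param nGroups number of groups (<= number of items).
#' @param seed RNG seed for K-means.
#' @param nstart K-means restarts.
#' @return data.frame: item, group, x, y.
#' @export
embedAndGroup <- function(sim, nGroups, seed = 0, nstart = 25) {
  k <- nrow(sim)
  if (nGroups > k) stop("nGroups exceeds the number of items")
  d <- max(sim) - sim
  diag(d) <- 0
  xy <- stats::cmdscale(stats::as.dist(d), k = 2)
  if (ncol(xy) < 2) xy <- cbind(xy, 0)   # degenerate (collinear) case
  grp <- if (nGroups == 1L) rep(1L, k) else {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    as.integer(stats::kmeans(xy, centers = nGroups, nstart = nstart)$cluster)
  }
  data.frame(item = rownames(sim), group = grp, x = xy[, 1], y = xy[, 2],
             row.names = NULL)
}
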