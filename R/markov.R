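#' Build the random-walk operator of a connected cell graph
#'
#' The random-walk Laplacian is L = I - D^{-1}A with degree matrix D. Its
#' heat kernel P(t) = exp(-tL) is evaluated exactly through the
#' eigendecomposition of the symmetric conjugate D^{-1/2} A D^{-1/2}. For an
#' undirected graph the stationary distribution of D^{-1}A is available in
#' closed form, pi_u = d_u / sum(d).
#'
#' @param g a connected [CellGraph-class].
#' @return A [RandomWalkOperator-class].
#' @export
buildOperator <- function(g) {
  A <- adjacency(g)
  if (max(graphComponents(A)) > 1L)
    stop("graph is disconnected; repair connectivity before building the operator")
  d <- Matrix::rowSums(A)
  dm <- 1 / sqrt(d)
  M <- as.matrix(A) * outer(dm, dm)   # D^{-1/2} A D^{-1/2}, symmetric
  e <- eigen(M, symmetric = TRUE)
  new("RandomWalkOperator", evectors = e$vectors, evalues = e$values,
      degrees = as.numeric(d), pi = as.numeric(d / sum(d)),
      cellIds = cellIds(g))
}

#' Evaluate the continuous-time transition matrix P(t) = exp(-tL)
#' @param op a RandomWalkOperator.
#' @param t Markov time (t >= 0).
#' @param linearized use the first-order approximation I - tL instead of the
#'   exact spectral evaluation (intended for graphs too large to
#'   eigendecompose; row sums remain 1 but entries may go negative for
#'   large t).
#' @return dense n x n matrix with rows summing to 1 (exact mode).
#' @export
transitionMatrix <- function(op, t, linearized = FALSE) {
  stopifnot(t >= 0)
  V <- op@evectors
  lam <- op@evalues
  dsq <- sqrt(op@degrees)
  if (linearized) {
    M <- (V * rep(lam, each = nrow(V))) %*% t(V)   # D^{-1/2} A D^{-1/2}
    DinvA <- M * outer(1 / dsq, dsq)
    return(diag(nrow(V)) * (1 - t) + t * DinvA)
  }
  ew <- exp(-t * (1 - lam))
  # P(t) = D^{-1/2} V e^{-t(1-Lam)} V' D^{1/2}
  left <- V * (1 / dsq)
  right <- t(V * dsq)
  left %*% (ew * right)
}

#' Markov stability of a partition
#'
#' MS(partition, t) = sum over all same-community vertex pairs (u, v),
#' including u = v, of P(t)_{uv} - pi_v: the excess probability that a
#' stationary random walker remains in its community after time t. Zero for
#' the all-in-one-block partition at any t; n - 1 for singletons at t = 0;
#' non-increasing in t for a fixed partition.
#'
#' @param op a RandomWalkOperator.
#' @param membership integer community label per cell.
#' @param t Markov time.
#' @param P optional precomputed transition matrix for this t.
#' @return scalar stability value.
#' @export
markovStability <- function(op, membership, t, P = NULL) {
  n <- length(op@pi)
  if (length(membership) != n || anyNA(membership))
    stop("membership must cover all cells")
  if (is.null(P)) P <- transitionMatrix(op, t)
  ms <- 0
  for (cells in split(seq_len(n), membership)) {
    ms <- ms + sum(P[cells, cells, drop = FALSE]) -
      length(cells) * sum(op@pi[cells])
  }
  ms
}

# Symmetrized quality matrix whose within-community sums equal the Markov
# stability above: Q(t) = (P + P')/2 - (1 pi' + pi 1')/2.
stabilityQuality <- function(op, t, P = NULL) {
  if (is.null(P)) P <- transitionMatrix(op, t)
  n <- length(op@pi)
  (P + t(P)) / 2 - (matrix(op@pi, n, n, byrow = TRUE) +
                    matrix(op@pi, n, n)) / 2
}

#' Variation of information between two partitions
#'
#' VI(X, Y) = -sum_ij r_ij [log(r_ij / p_i) + log(r_ij / q_j)] with
#' p_i = |X_i|/n, q_j = |Y_j|/n, r_ij = |X_i intersect Y_j|/n, natural logs,
#' and 0 log 0 = 0. A metric on partitions.
#'
#' @param x,y label vectors over the same cells.
#' @return non-negative scalar.
#' @export
variationOfInformation <- function(x, y) {
  if (length(x) != length(y)) stop("partitions must cover the same cell set")
  n <- length(x)
  tab <- table(x, y) / n
  p <- rowSums(tab)
  q <- colSums(tab)
  r <- as.numeric(tab)
  pi_ <- rep(p, times = ncol(tab))
  qj <- rep(q, each = nrow(tab))
  keep <- r > 0
  max(-sum(r[keep] * (log(r[keep] / pi_[keep]) + log(r[keep] / qj[keep]))), 0)
}

#' Louvain ensemble maximizing Markov stability at one Markov time
#'
#' Runs a generalized Louvain algorithm `nRuns` times on the stability
#' quality matrix at time t (each run with a distinct deterministic
#' sub-seed), returns the representative partition (highest stability; ties
#' broken by lowest run index), the full ensemble, and the ensemble mean
#' pairwise variation of information VI_g.
#'
#' @param op a RandomWalkOperator.
#' @param t Markov time (> 0 for a meaningful scan point; t = 0 is allowed).
#' @param nRuns ensemble size.
#' @param seed master seed for the run sub-seeds.
#' @param P optional precomputed transition matrix.
#' @return list with `representative` (integer labels, 1-based, relabeled by
#'   decreasing community size), `ensemble` (cells x nRuns matrix), `ms`
#'   (stability of the representative), `viG`.
#' @export
louvainStability <- function(op, t, nRuns = 100, seed = 0, P = NULL) {
  Q <- stabilityQuality(op, t, P = P)
  n <- nrow(Q)
  # fully decayed kernel: every partition ties at MS = 0 and Q holds only
  # eigen-reconstruction noise; report the one-block limit rather than
  # noise-driven singletons
  if (max(abs(Q)) < 1e-9) {
    one <- rep(1L, n)
    return(list(representative = one,
                ensemble = matrix(one, n, nRuns), ms = 0, viG = 0))
  }
  res <- .louvainEnsembleCpp(Q, as.integer(nRuns), as.double(seed))
  best <- which.max(res$quality)   # first maximum: lowest run index
  rep_ <- res$memberships[, best] + 1L
  ms <- res$quality[best]
  # the representative must never score below the trivial partitions
  tol <- 1e-12 * max(abs(Q))
  qOne <- sum(Q)
  qSing <- sum(diag(Q))
  if (qOne > ms + tol) { rep_ <- rep(1L, n); ms <- qOne }
  if (qSing > ms + tol) { rep_ <- seq_len(n); ms <- qSing }
  list(representative = relabelBySize(rep_), ensemble = res$memberships + 1L,
       ms = ms, viG = .viEnsembleMeanCpp(res$memberships))
}

# relabel community ids 1..k by decreasing community size (ties: first
# occurrence order), for stable reporting
relabelBySize <- function(m) {
  tab <- sort(table(m), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(m)])
}

#' Scan Markov times and collect stability/VI diagnostics
#'
#' Evaluates `gridPoints` log-spaced Markov times 10^l for l in
#' [gridMin, gridMax]; at each time runs the Louvain ensemble, records the
#' representative partition, its stability, the ensemble VI_g, and finally
#' the cross-scale VI matrix between representative partitions.
#'
#' @param op a RandomWalkOperator.
#' @param gridMin,gridMax log10 Markov-time range.
#' @param gridPoints number of scales.
#' @param nRuns Louvain runs per scale.
#' @param seed master seed; scale i uses sub-seed seed*1000 + i.
#' @param verbose print progress.
#' @return A [ScaleScan-class].
#' @export
scanScales <- function(op, gridMin = -1, gridMax = 4, gridPoints = 100,
                       nRuns = 100, seed = 0, verbose = FALSE) {
  l <- seq(gridMin, gridMax, length.out = gridPoints)
  tt <- 10^l
  n <- length(op@pi)
  memb <- matrix(0L, n, gridPoints)
  ms <- viG <- numeric(gridPoints)
  for (i in seq_len(gridPoints)) {
    P <- transitionMatrix(op, tt[i])
    fit <- louvainStability(op, tt[i], nRuns = nRuns,
                            seed = seed * 1000 + i, P = P)
    memb[, i] <- fit$representative
    ms[i] <- fit$ms
    viG[i] <- fit$viG
    if (verbose && i %% 10 == 0)
      message(sprintf("scale %d/%d: t=%.3g, %d communities", i, gridPoints,
                      tt[i], length(unique(fit$representative))))
  }
  viP <- matrix(0, gridPoints, gridPoints)
  for (i in seq_len(gridPoints - 1)) for (j in seq((i + 1), gridPoints)) {
    viP[i, j] <- viP[j, i] <- .viCpp(memb[, i], memb[, j])
  }
  new("ScaleScan", logGrid = l, times = tt, memberships = memb,
      msValues = ms, viG = viG, viP = viP,
      nCommunities = apply(memb, 2, function(m) length(unique(m))),
      cellIds = op@cellIds)
}

#' Select robust scales from a scan by VI basins
#'
#' A basin is a maximal contiguous run of scales whose representative
#' partitions are all pairwise within `basinTheta` VI of each other. Runs of
#' width >= `basinMinWidth` are kept; within each kept basin the scale with
#' minimal ensemble VI_g is selected (ties: earliest). Selected scales are
#' ordered coarse to fine (decreasing Markov time) and adjacent duplicates
#' (identical partitions) are removed. If no basin qualifies, the single
#' global VI_g minimum is returned with a warning. A warning (not an error)
#' is raised when the selected hierarchy is not strictly nested in community
#' count.
#'
#' @param scan a ScaleScan.
#' @param basinTheta VI depth threshold (natural-log units).
#' @param basinMinWidth minimum basin width in grid points.
#' @return A [HierarchicalClustering-class].
#' @export
selectScales <- function(scan, basinTheta = 0.1, basinMinWidth = 5) {
  viP <- scan@viP
  ng <- length(scan@times)
  # furthest right end of a valid window starting at i (validity monotone)
  runEnd <- integer(ng)
  for (i in seq_len(ng)) {
    j <- i
    while (j < ng && max(viP[i:(j + 1), i:(j + 1)]) <= basinTheta) j <- j + 1
    runEnd[i] <- j
  }
  starts <- which(runEnd - seq_len(ng) + 1 >= basinMinWidth)
  # keep only maximal runs (not contained in an earlier one)
  if (length(starts)) {
    keep <- logical(length(starts))
    lastEnd <- -1L
    for (k in seq_along(starts)) {
      if (runEnd[starts[k]] > lastEnd) {
        keep[k] <- TRUE
        lastEnd <- runEnd[starts[k]]
      }
    }
    starts <- starts[keep]
  }
  if (!length(starts)) {
    warning("no VI basin of width >= ", basinMinWidth,
            " found; falling back to the global VI_g minimum")
    sel <- which.min(scan@viG)
  } else {
    sel <- vapply(starts, function(s) {
      win <- s:runEnd[s]
      win[which.min(scan@viG[win])]
    }, 1L)
  }
  sel <- sel[order(scan@times[sel], decreasing = TRUE)]  # coarse -> fine
  # deduplicate identical partitions across basins
  if (length(sel) > 1) {
    dup <- logical(length(sel))
    for (k in 2:length(sel))
      dup[k] <- any(vapply(sel[seq_len(k - 1)], function(s)
        .viCpp(scan@memberships[, s], scan@memberships[, sel[k]]) < 1e-12,
        logical(1)))
    sel <- sel[!dup]
  }
  memb <- scan@memberships[, sel, drop = FALSE]
  k <- apply(memb, 2, function(m) length(unique(m)))
  if (any(diff(k) < 0))
    warning("community count is not non-decreasing from coarse to fine; ",
            "hierarchy reported as-is")
  new("HierarchicalClustering",
      scaleIndex = as.integer(sel), times = scan@times[sel],
      memberships = memb, cellIds = scan@cellIds,
      diagnostics = data.frame(scaleIndex = sel, time = scan@times[sel],
                               nCommunities = k, ms = scan@msValues[sel],
                               viG = scan@viG[sel]))
}

#' Write per-scale cluster assignments as TSV
#' @param hier a HierarchicalClustering.
#' @param path output TSV (cell_id, scale_index, markov_time, cluster_id).
#' @export
writeClusterAssignments <- function(hier, path) {
  S <- length(hier@times)
  n <- length(hier@cellIds)
  df <- data.frame(
    cell_id = rep(hier@cellIds, S),
    scale_index = rep(seq_len(S), each = n),
    markov_time = rep(hier@times, each = n),
    cluster_id = as.integer(hier@memberships))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
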