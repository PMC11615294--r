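#' Mass-action interaction strength between two cell groups
#'
#' A simplified saturating mass-action score: with x = mean ligand-unit
#' expression over sender cells and y = mean receptor-unit expression over
#' receiver cells, strength = x*y / (Kh + x*y). Bounded in [0, 1), zero iff
#' either side's mean expression is zero, monotone in both means. Any
#' alternative scoring function with the same signature can be plugged into
#' [hierarchyInteractions()].
#'
#' @param em an ExpressionMatrix.
#' @param senders,receivers integer cell indices (nonempty).
#' @param ligand,receptor unit names.
#' @param Kh half-saturation constant.
#' @return scalar strength.
#' @export
interactionStrength <- function(em, senders, receivers, ligand, receptor,
                                Kh = 0.5) {
  stopifnot(length(senders) > 0, length(receivers) > 0)
  xl <- unitExpression(em, ligand)
  xr <- unitExpression(em, receptor)
  if (is.null(xl) || is.null(xr))
    stop("unknown ligand or receptor unit: ", ligand, " / ", receptor)
  x <- mean(xl[senders])
  y <- mean(xr[receivers])
  (x * y) / (Kh + x * y)
}

#' Score all group pairs for a set of LR pairs
#'
#' Evaluates the interaction strength for every (sender group, receiver
#' group) combination and every requested LR pair, and the per-pair
#' interaction proportion (share of the pair's total strength over all group
#' pairs; proportions sum to 1 when the total is positive).
#'
#' @param em an ExpressionMatrix.
#' @param groups named list of integer cell-index vectors (e.g. clusters of
#'   one hierarchy scale via [hierarchyGroups()], or tree-node supports).
#' @param pairs data.frame with columns ligand, receptor (and optionally
#'   pathway).
#' @param scoreFun scoring backend; defaults to [interactionStrength()].
#' @param ... passed to `scoreFun`.
#' @return data.frame: sender, receiver, ligand, receptor, pathway,
#'   strength, proportion.
#' @export
hierarchyInteractions <- function(em, groups, pairs,
                                  scoreFun = interactionStrength, ...) {
  gn <- names(groups)
  if (is.null(gn)) gn <- as.character(seq_along(groups))
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    lig <- pairs$ligand[r]
    rec <- pairs$receptor[r]
    pw <- if ("pathway" %in% names(pairs)) pairs$pathway[r] else NA_character_
    grid <- expand.grid(sender = seq_along(groups),
                        receiver = seq_along(groups))
    st <- vapply(seq_len(nrow(grid)), function(k)
      scoreFun(em, groups[[grid$sender[k]]], groups[[grid$receiver[k]]],
               lig, rec, ...), numeric(1))
    tot <- sum(st)
    out[[r]] <- data.frame(
      sender = gn[grid$sender], receiver = gn[grid$receiver],
      ligand = lig, receptor = rec, pathway = pw, strength = st,
      proportion = if (tot > 0) st / tot else 0)
  }
  do.call(rbind, out)
}

#' Cluster cell-index groups of one hierarchy scale
#' @param hier a HierarchicalClustering.
#' @param scale scale index (1 = coarsest selected scale).
#' @return named list of integer cell-index vectors ("s<scale>.c<id>").
#' @export
hierarchyGroups <- function(hier, scale = ncol(hier@memberships)) {
  m <- hier@memberships[, scale]
  g <- split(seq_along(m), m)
  names(g) <- paste0("s", scale, ".c", names(g))
  g
}

#' Split hierarchical clusters by an expression support
#'
#' Each cluster is split into (cluster intersect support) and (cluster minus
#' support); empty halves are dropped. Used for the "intersected" cluster
#' view where one half of every cluster expresses the unit and the other
#' does not.
#'
#' @param groups named list of integer cell-index vectors.
#' @param support integer vector of supporting cell indices.
#' @return named list of refined groups ("<name>.in" / "<name>.out").
#' @export
splitClustersBySupport <- function(groups, support) {
  out <- list()
  for (nm in names(groups)) {
    g <- groups[[nm]]
    a <- intersect(g, support)
    b <- setdiff(g, support)
    if (length(a)) out[[paste0(nm, ".in")]] <- a
    if (length(b)) out[[paste0(nm, ".out")]] <- b
  }
  out
}

#' Robustness of per-cluster CCC patterns under subsampling
#'
#' For each replicate, cells are subsampled within every cluster, each
#' cluster's outgoing-strength vector over the LR pairs (summed over
#' receiver clusters) is recomputed, and the cosine distance to the
#' full-data vector is reported. Small distances indicate subsampling-robust
#' communication patterns.
#'
#' @param em an ExpressionMatrix.
#' @param groups named list of cell-index vectors.
#' @param pairs data.frame with ligand, receptor columns.
#' @param frac subsampling fraction in (0, 1].
#' @param nReps replicates.
#' @param seed RNG seed.
#' @param ... passed to [hierarchyInteractions()].
#' @return data.frame: cluster, rep, distance.
#' @export
patternDistanceUnderSubsampling <- function(em, groups, pairs, frac = 0.8,
                                            nReps = 20, seed = 0, ...) {
  stopifnot(frac > 0, frac <= 1)
  outgoing <- function(gr) {
    ints <- hierarchyInteractions(em, gr, pairs, ...)
    agg <- stats::aggregate(strength ~ sender + ligand + receptor, ints, sum)
    # cluster x pair matrix
    key <- paste(agg$ligand, agg$receptor)
    tapply(agg$strength, list(agg$sender, key), sum)
  }
  full <- outgoing(groups)
  cosDist <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(NA_real_)
    1 - sum(u * v) / (nu * nv)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- list()
  for (rep_ in seq_len(nReps)) {
    sub <- lapply(groups, function(g) {
      k <- max(1L, floor(frac * length(g)))
      if (frac == 1) g else sort(sample(g, k))
    })
    empty <- lengths(sub) == 0
    if (any(empty)) {
      warning("replicate ", rep_, ": cluster(s) emptied by subsampling; skipped")
      next
    }
    subM <- outgoing(sub)
    for (cl in rownames(full)) {
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, rep = rep_,
        distance = cosDist(full[cl, ], subM[cl, ]))
    }
  }
  do.call(rbind, rows)
}
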