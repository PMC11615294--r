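#' Plot a cluster hierarchy with optional interaction edges
#'
#' Scales are drawn as rows (coarse on top); node sizes are proportional to
#' cluster cell counts, vertical edges link nested clusters (majority
#' overlap), and, when an interaction table is given, arrows between the
#' finest-scale clusters are drawn with width proportional to strength.
#' Base graphics; intended as a quick structural view.
#'
#' @param hier a HierarchicalClustering.
#' @param interactions optional data.frame from [hierarchyInteractions()]
#'   with sender/receiver names matching [hierarchyGroups()] of the finest
#'   scale.
#' @param main plot title.
#' @export
plotHierarchy <- function(hier, interactions = NULL, main = "cluster hierarchy") {
  S <- ncol(hier@memberships)
  n <- nrow(hier@memberships)
  pos <- list()
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0.5, S + 0.5))
  graphics::title(main = main)
  for (s in seq_len(S)) {
    tab <- table(hier@memberships[, s])
    ids <- as.integer(names(tab))
    x <- (cumsum(as.numeric(tab)) - as.numeric(tab) / 2) / n
    y <- S - s + 1
    pos[[s]] <- data.frame(cluster = ids, x = x, y = y, size = as.numeric(tab))
    if (s > 1) {
      for (i in seq_along(ids)) {
        sub <- hier@memberships[, s] == ids[i]
        par <- as.integer(names(which.max(table(hier@memberships[sub, s - 1]))))
        pi_ <- pos[[s - 1]]
        graphics::segments(pi_$x[pi_$cluster == par], pi_$y[1],
                           x[i], y, col = "grey60")
      }
    }
  }
  if (!is.null(interactions) && nrow(interactions)) {
    pf <- pos[[S]]
    nm <- paste0("s", S, ".c", pf$cluster)
    agg <- stats::aggregate(strength ~ sender + receiver, interactions, sum)
    for (r in seq_len(nrow(agg))) {
      i <- match(agg$sender[r], nm)
      j <- match(agg$receiver[r], nm)
      if (is.na(i) || is.na(j) || agg$strength[r] <= 0) next
      graphics::arrows(pf$x[i], pf$y[i] - 0.08, pf$x[j], pf$y[j] - 0.12,
                       lwd = 0.5 + 4 * agg$strength[r] / max(agg$strength),
                       length = 0.06, col = "tomato")
    }
  }
  for (s in seq_len(S)) {
    p <- pos[[s]]
    graphics::points(p$x, p$y, cex = 0.8 + 3 * sqrt(p$size / n), pch = 21,
                     bg = "steelblue")
    graphics::text(p$x, p$y, labels = p$cluster, cex = 0.7, pos = 3)
  }
  graphics::axis(2, at = S:1, labels = paste("scale", seq_len(S)), las = 1,
                 tick = FALSE)
  invisible(pos)
}

#' Plot one signaling tree
#'
#' Simple layered tree diagram: nodes labeled by entity, sized by support.
#'
#' @param tree a tree from a [TreeSet-class].
#' @param main title.
#' @export
plotTreeDiagram <- function(tree, main = NULL) {
  k <- length(tree$entities)
  depth <- integer(k)
  for (i in seq_len(k)) {
    d <- 0L
    j <- i
    while (!is.na(tree$parent[j])) { j <- tree$parent[j]; d <- d + 1L }
    depth[i] <- d
  }
  maxd <- max(depth)
  x <- numeric(k)
  for (d in 0:maxd) {
    idx <- which(depth == d)
    x[idx] <- seq_along(idx) / (length(idx) + 1)
  }
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(-maxd - 0.5, 0.5))
  graphics::title(main = main %||% "signaling tree")
  for (i in seq_len(k)) if (!is.na(tree$parent[i]))
    graphics::segments(x[tree$parent[i]], -depth[tree$parent[i]],
                       x[i], -depth[i], col = "grey50")
  sz <- lengths(tree$supports)
  graphics::points(x, -depth, cex = 0.8 + 2.5 * sqrt(sz / max(sz)),
                   pch = 21, bg = "darkseagreen")
  graphics::text(x, -depth, labels = tree$entities, pos = 3, cex = 0.75)
  invisible(NULL)
}

#' Bar chart of entity frequencies across trees
#' @param freq output of [frequencyRanking()].
#' @param topN show the most frequent entities only.
#' @export
plotFrequency <- function(freq, topN = 20) {
  f <- utils::head(freq, topN)
  graphics::barplot(rev(f$count), names.arg = rev(f$entity), horiz = TRUE,
                    las = 1, col = "steelblue", cex.names = 0.7,
                    xlab = "trees containing entity")
  invisible(NULL)
}

#' Scatter of grouped items in the 2D similarity embedding
#' @param groups output of [embedAndGroup()].
#' @export
plotSimilarityGroups <- function(groups) {
  graphics::plot(groups$x, groups$y, col = groups$group, pch = 19,
                 xlab = "dim 1", ylab = "dim 2")
  graphics::text(groups$x, groups$y, labels = groups$item, pos = 3, cex = 0.6)
  invisible(NULL)
}
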