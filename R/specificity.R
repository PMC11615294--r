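#' Per-cell expression of a ligand/receptor unit
#'
#' Single-subunit units return the gene's column; multi-subunit complexes
#' return the elementwise geometric mean of the subunit columns (zero in any
#' subunit annihilates the complex).
#'
#' @param em an ExpressionMatrix.
#' @param unit unit name, subunits joined by "_".
#' @return numeric vector over cells, or NULL (with a warning) when a
#'   subunit gene is absent.
#' @export
unitExpression <- function(em, unit) {
  sub <- unitSubunits(unit)[[1]]
  miss <- setdiff(sub, geneIds(em))
  if (length(miss)) {
    warning("unit ", unit, " skipped: missing gene(s) ",
            paste(miss, collapse = ", "))
    return(NULL)
  }
  x <- as.matrix(exprValues(em)[, sub, drop = FALSE])
  if (length(sub) == 1L) return(as.numeric(x))
  unname(exp(rowMeans(log(x))))   # 0 in any subunit -> -Inf -> 0
}

# One-sided ("greater") Wilcoxon rank-sum p-value of group-1 cells versus
# the rest. Normal approximation with continuity and tie corrections;
# exact distribution (DP over the tied-rank multiset) when both groups have
# <= `exactMax` observations.
rankSumP <- function(x, inGroup, exactMax = 12L) {
  n <- length(x)
  n1 <- sum(inGroup)
  n2 <- n - n1
  if (n1 < 1 || n2 < 1) return(NA_real_)
  r <- rank(x)
  W <- sum(r[inGroup])
  if (n1 <= exactMax && n2 <= exactMax)
    return(exactRankSumTail(r, n1, W))
  mu <- n1 * (n + 1) / 2
  tie <- tabulate(match(x, unique(x)))
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  z <- (W - mu - 0.5) / sqrt(sig2)
  stats::pnorm(z, lower.tail = FALSE)
}

# Exact P(rank-sum of a random size-n1 subset >= W) for the given tied-rank
# vector, by dynamic programming over subset-size x sum counts. Ranks are
# doubled so midranks become integers.
exactRankSumTail <- function(r, n1, W) {
  r2 <- as.integer(round(2 * r))
  W2 <- as.integer(round(2 * W))
  total <- sum(r2)
  # dp[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  dp <- matrix(0, n1 + 1, total + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    for (k in n1:1) {  # descending k so each rank is used at most once
      shifted <- c(rep(0, v), dp[k, seq_len(total + 1 - v)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  counts <- dp[n1 + 1, ]
  tail <- sum(counts[seq(W2 + 1, total + 1)])
  tail / choose(length(r), n1)
}

#' Assign ligand/receptor units to hierarchical clusters by rank-sum markers
#'
#' For every unit and every cluster at every selected scale, tests whether
#' the unit's expression is higher inside the cluster than outside
#' (one-sided Wilcoxon rank-sum). Each unit is assigned globally to the
#' (scale, cluster) with the minimum p-value; ties go to the coarser scale,
#' then the lower cluster id. Clusters of size < 2 are skipped with a
#' warning; units with identically zero expression are excluded.
#'
#' @param em lognorm (or raw) ExpressionMatrix; cells must match `hier`.
#' @param hier a HierarchicalClustering.
#' @param units character vector of unit names (genes or "_"-joined
#'   complexes).
#' @param bhCorrect apply Benjamini-Hochberg correction across clusters per
#'   unit before assignment/thresholding (off by default; the method filters
#'   raw p-values).
#' @return data.frame: unit, scale, cluster, p_value (one row per unit),
#'   plus attribute "all" with the full unit x (scale, cluster) p-value
#'   table.
#' @export
assignMarkers <- function(em, hier, units, bhCorrect = FALSE) {
  if (!identical(cellIds(em), cellIds(hier)))
    stop("hierarchy does not cover the expression matrix's cells")
  n <- nrow(exprValues(em))
  # unit expression matrix (cells x units), skipping unavailable units
  cols <- lapply(units, function(u) unitExpression(em, u))
  ok <- !vapply(cols, is.null, logical(1))
  units <- units[ok]
  X <- do.call(cbind, cols[ok])
  nz <- colSums(X > 0) > 0
  units <- units[nz]
  X <- X[, nz, drop = FALSE]
  if (!length(units)) return(data.frame(unit = character(), scale = integer(),
                                        cluster = integer(), p_value = numeric()))
  R <- apply(X, 2, rank)                       # cells x units midranks
  tieTerm <- apply(X, 2, function(x) {
    t_ <- tabulate(match(x, unique(x)))
    sum(t_^3 - t_)
  })
  S <- length(hier@times)
  rows <- list()
  for (s in seq_len(S)) {
    m <- hier@memberships[, s]
    for (cl in sort(unique(m))) {
      inG <- m == cl
      n1 <- sum(inG)
      if (n1 < 2) {
        warning("scale ", s, " cluster ", cl, " has < 2 cells; skipped")
        next
      }
      n2 <- n - n1
      if (n2 < 1) next
      if (n1 <= 12 && n2 <= 12) {
        p <- vapply(seq_along(units), function(j)
          rankSumP(X[, j], inG), numeric(1))
      } else {
        W <- colSums(R[inG, , drop = FALSE])
        mu <- n1 * (n + 1) / 2
        sig2 <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
        p <- ifelse(sig2 <= 0, 1,
                    stats::pnorm((W - mu - 0.5) / sqrt(pmax(sig2, 1e-300)),
                                 lower.tail = FALSE))
      }
      rows[[length(rows) + 1]] <-
        data.frame(unit = units, scale = s, cluster = cl, p_value = p)
    }
  }
  all <- do.call(rbind, rows)
  if (bhCorrect)
    all$p_value <- stats::ave(all$p_value, all$unit,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  # global assignment: min p, ties -> coarser scale then lower cluster id
  o <- order(all$unit, all$p_value, all$scale, all$cluster)
  all_o <- all[o, ]
  assigned <- all_o[!duplicated(all_o$unit), ]
  assigned <- assigned[match(units, assigned$unit), ]
  rownames(assigned) <- NULL
  attr(assigned, "all") <- all
  assigned
}

#' Ordered list of specific ligand-receptor pairs
#'
#' Keeps database pairs whose ligand and receptor marker p-values both pass
#' the threshold; the specificity score is the product of the two p-values
#' and pairs are returned ascending by score (most specific first), ties
#' broken by interaction name.
#'
#' @param assignments output of [assignMarkers()] covering both ligand and
#'   receptor units.
#' @param db an LRDatabase.
#' @param pThreshold raw p-value cutoff (both sides must pass).
#' @return data.frame: ligand, receptor, pathway, ligand_scale,
#'   ligand_cluster, p_L, receptor_scale, receptor_cluster, p_R, score.
#' @export
specificPairs <- function(assignments, db, pThreshold = 1e-3) {
  ia <- interactions(db)
  idxL <- match(ia$ligand, assignments$unit)
  idxR <- match(ia$receptor, assignments$unit)
  keep <- !is.na(idxL) & !is.na(idxR) &
    assignments$p_value[idxL] < pThreshold &
    assignments$p_value[idxR] < pThreshold
  out <- data.frame(
    ligand = ia$ligand[keep], receptor = ia$receptor[keep],
    pathway = ia$pathway[keep],
    ligand_scale = assignments$scale[idxL[keep]],
    ligand_cluster = assignments$cluster[idxL[keep]],
    p_L = assignments$p_value[idxL[keep]],
    receptor_scale = assignments$scale[idxR[keep]],
    receptor_cluster = assignments$cluster[idxR[keep]],
    p_R = assignments$p_value[idxR[keep]])
  out$score <- out$p_L * out$p_R
  out <- out[order(out$score, paste(out$ligand, out$receptor)), ]
  rownames(out) <- NULL
  out
}
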