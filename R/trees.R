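#' Binarize unit expression into supports
#'
#' The support of a unit is the set of cells in which its expression (gene
#' value, or geometric mean for complexes) exceeds `tau`; by convention this
#' is evaluated on the raw-count scale. Entities supported by fewer than
#' `minCells` cells are dropped, as are units with missing subunit genes.
#' Distinct entities with identical supports are merged into one node whose
#' label joins theirs with "=" (inclusion is ambiguous for equal sets).
#'
#' @param em an ExpressionMatrix (raw counts by default).
#' @param units character vector of unit names.
#' @param tau binarization threshold (support = expression > tau).
#' @param minCells minimum support size.
#' @param mergeEqual merge entities with identical supports (default TRUE).
#' @return A [SupportMatrix-class].
#' @export
binarizeSupports <- function(em, units, tau = 0, minCells = 10,
                             mergeEqual = TRUE) {
  stopifnot(tau >= 0)
  units <- unique(units)
  sup <- list()
  keep <- character()
  for (u in units) {
    x <- suppressWarnings(unitExpression(em, u))
    if (is.null(x)) next
    s <- which(x > tau)
    if (length(s) < minCells) next
    keep <- c(keep, u)
    sup[[length(sup) + 1]] <- s
  }
  if (mergeEqual && length(sup) > 1) {
    key <- vapply(sup, function(s) paste(s, collapse = ","), character(1))
    grp <- split(seq_along(sup), key)
    ord <- vapply(grp, min, 1L)
    grp <- grp[order(ord)]
    keep2 <- vapply(grp, function(g) paste(keep[g], collapse = "="), character(1))
    sup <- lapply(grp, function(g) sup[[g[1]]])
    keep <- unname(keep2)
    sup <- unname(sup)
  }
  new("SupportMatrix", entities = keep, supports = sup,
      nCells = nrow(exprValues(em)), cellIds = cellIds(em), tau = tau)
}

#' Relation between two supports
#'
#' With m = min(|s1|, |s2|) and tolerance eps: "equal" iff the supports are
#' identical; "disjoint" iff |s1 & s2| <= eps*m; "inclusive" iff
#' |s1 & s2| >= (1-eps)*m and |s1| != |s2|; otherwise "overlap". At eps = 0
#' these reduce to exact set disjointness/containment.
#'
#' @param s1,s2 integer vectors of cell indices (nonempty).
#' @param eps relation tolerance in [0, 0.5).
#' @return one of "equal", "disjoint", "inclusive", "overlap".
#' @export
supportRelation <- function(s1, s2, eps = 0) {
  stopifnot(length(s1) > 0, length(s2) > 0)
  m <- min(length(s1), length(s2))
  i <- length(intersect(s1, s2))
  if (length(s1) == length(s2) && i == length(s1)) return("equal")
  if (i <= eps * m) return("disjoint")
  if (i >= (1 - eps) * m && length(s1) != length(s2)) return("inclusive")
  "overlap"
}

# Pairwise relation codes for a support matrix: 0 none/overlap, 1 disjoint,
# 2 inclusive (smaller inside larger), 3 equal. Vectorized via sparse
# cross-products on the binary cells x entities indicator.
relationMatrix <- function(sm, eps = 0) {
  k <- length(sm@entities)
  sizes <- lengths(sm@supports)
  B <- Matrix::sparseMatrix(
    i = unlist(sm@supports),
    j = rep(seq_len(k), sizes),
    x = 1, dims = c(sm@nCells, k))
  I <- as.matrix(Matrix::crossprod(B))           # intersection sizes
  M <- outer(sizes, sizes, pmin)
  R <- matrix(0L, k, k)
  R[I <= eps * M] <- 1L
  incl <- I >= (1 - eps) * M & outer(sizes, sizes, "!=")
  R[incl] <- 2L
  eq <- I == M & outer(sizes, sizes, "==")
  R[eq] <- 3L
  diag(R) <- 3L
  R
}

#' Build the disjoint-or-inclusive relation graph over supports
#'
#' Nodes are entities; an edge joins two entities iff their supports are
#' disjoint or inclusive under tolerance eps (equal supports should have
#' been merged by [binarizeSupports()]; if still present they are connected).
#'
#' @param sm a SupportMatrix.
#' @param eps relation tolerance.
#' @return logical adjacency matrix with entity dimnames.
#' @export
relationGraph <- function(sm, eps = 0) {
  R <- relationMatrix(sm, eps)
  adj <- R >= 1L
  diag(adj) <- FALSE
  dimnames(adj) <- list(sm@entities, sm@entities)
  adj
}

#' Enumerate all maximal cliques (Bron-Kerbosch with pivoting)
#'
#' Exact enumeration on a logical adjacency matrix. Output is canonically
#' sorted (members ascending within a clique; cliques in lexicographic
#' order). Isolated vertices are returned as singleton cliques.
#'
#' @param adj symmetric logical adjacency matrix, FALSE diagonal.
#' @return list of integer vectors (vertex indices).
#' @export
maximalCliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  nb <- lapply(seq_len(n), function(i) which(adj[i, ]))
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1]] <<- sort(R)
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbors in P
    PX <- c(P, X)
    deg <- vapply(PX, function(u) length(intersect(nb[[u]], P)), 1L)
    pivot <- PX[which.max(deg)]
    for (v in setdiff(P, nb[[pivot]])) {
      bk(c(R, v), intersect(P, nb[[v]]), intersect(X, nb[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  out[order(vapply(out, function(cl) paste(sprintf("%06d", cl), collapse = ","),
                   character(1)))]
}

#' Decompose a laminar clique into rooted trees
#'
#' Within a clique of the relation graph all supports are pairwise disjoint
#' or nested (a laminar family, up to eps), so strict inclusion induces a
#' forest: each entity's parent is its smallest strict superset. Connected
#' components are emitted as separate trees; components with fewer than
#' `minNodes` nodes are filtered. With eps > 0 inclusion can be intransitive;
#' a child whose nominal parent does not contain it (beyond tolerance) is
#' detached to a new root with a warning.
#'
#' @param entities character vector of entity names in the clique.
#' @param sup list of support index vectors, parallel to `entities`.
#' @param eps relation tolerance used to build the clique.
#' @param minNodes minimum tree size retained.
#' @return list of trees, each a list(entities, parent, supports).
#' @export
forestFromClique <- function(entities, sup, eps = 0, minNodes = 2) {
  k <- length(entities)
  sizes <- lengths(sup)
  parent <- rep(NA_integer_, k)
  for (i in seq_len(k)) {
    # candidate parents: strict supersets under the relation tolerance
    cand <- integer(0)
    for (j in seq_len(k)) {
      if (i == j || sizes[j] <= sizes[i]) next
      inter <- length(intersect(sup[[i]], sup[[j]]))
      if (inter >= (1 - eps) * sizes[i]) cand <- c(cand, j)
    }
    if (length(cand))
      parent[i] <- cand[order(sizes[cand], cand)][1]   # smallest superset
  }
  # sanity under eps > 0: verify parent really contains the child
  if (eps > 0) {
    for (i in which(!is.na(parent))) {
      j <- parent[i]
      if (length(intersect(sup[[i]], sup[[j]])) < (1 - eps) * sizes[i]) {
        warning("relation violation inside clique; detaching ", entities[i])
        parent[i] <- NA_integer_
      }
    }
  }
  # connected components of the parent forest
  root <- seq_len(k)
  for (i in seq_len(k)) {
    r <- i
    while (!is.na(parent[r])) r <- parent[r]
    root[i] <- r
  }
  comps <- split(seq_len(k), root)
  keep <- comps[vapply(comps, length, 1L) >= minNodes]
  lapply(unname(keep), function(id) {
    remap <- match(seq_along(entities), id)
    list(entities = entities[id],
         parent = remap[parent[id]],
         supports = sup[id])
  })
}

treeKey <- function(tree) {
  o <- order(tree$entities)
  pe <- ifelse(is.na(tree$parent[o]), "", tree$entities[tree$parent[o]])
  paste(tree$entities[o], pe, sep = "<", collapse = "|")
}

#' Detect signaling trees of ligands, receptors, or LR-unions
#'
#' Pipeline: binarize unit expression into supports, connect entities whose
#' supports are disjoint or inclusive, enumerate maximal cliques
#' (Bron-Kerbosch), and decompose every clique into rooted trees. For
#' `kind = "lr_union"` the entities are per-database-pair support unions
#' ("ligand->receptor" labels). Duplicate trees arising from different
#' cliques are reported once.
#'
#' @param em an ExpressionMatrix (raw counts by default).
#' @param db an LRDatabase.
#' @param kind "ligand", "receptor" or "lr_union".
#' @param tau binarization threshold.
#' @param eps relation tolerance.
#' @param minCells minimum support size per entity.
#' @param minNodes minimum tree size.
#' @return A [TreeSet-class].
#' @export
detectTrees <- function(em, db, kind = c("ligand", "receptor", "lr_union"),
                        tau = 0, eps = 0, minCells = 10, minNodes = 2) {
  kind <- match.arg(kind)
  if (kind %in% c("ligand", "receptor")) {
    sm <- binarizeSupports(em, dbUnits(db, kind), tau = tau, minCells = minCells)
  } else {
    ia <- interactions(db)
    sup <- list()
    keep <- character()
    for (r in seq_len(nrow(ia))) {
      xl <- suppressWarnings(unitExpression(em, ia$ligand[r]))
      xr <- suppressWarnings(unitExpression(em, ia$receptor[r]))
      if (is.null(xl) || is.null(xr)) next
      s <- which(xl > tau | xr > tau)
      if (length(s) < minCells) next
      keep <- c(keep, paste0(ia$ligand[r], "->", ia$receptor[r]))
      sup[[length(sup) + 1]] <- s
    }
    sm <- new("SupportMatrix", entities = keep, supports = sup,
              nCells = nrow(exprValues(em)), cellIds = cellIds(em), tau = tau)
    sm <- mergeEqualSupports(sm)
  }
  detectTreesFromSupports(sm, kind = kind, eps = eps, minNodes = minNodes)
}

mergeEqualSupports <- function(sm) {
  if (length(sm@supports) < 2) return(sm)
  key <- vapply(sm@supports, function(s) paste(s, collapse = ","), character(1))
  grp <- split(seq_along(sm@supports), key)
  grp <- grp[order(vapply(grp, min, 1L))]
  new("SupportMatrix",
      entities = unname(vapply(grp, function(g)
        paste(sm@entities[g], collapse = "="), character(1))),
      supports = unname(lapply(grp, function(g) sm@supports[[g[1]]])),
      nCells = sm@nCells, cellIds = sm@cellIds, tau = sm@tau)
}

#' Tree detection from a precomputed support matrix
#' @param sm a SupportMatrix (equal supports merged).
#' @param kind provenance tag for the resulting TreeSet.
#' @param eps relation tolerance.
#' @param minNodes minimum tree size.
#' @return A [TreeSet-class].
#' @export
detectTreesFromSupports <- function(sm, kind = "ligand", eps = 0, minNodes = 2) {
  if (!length(sm@entities))
    return(new("TreeSet", trees = list(), kind = kind, tau = sm@tau,
               eps = eps, nCells = sm@nCells))
  adj <- relationGraph(sm, eps)
  cliques <- maximalCliques(adj)
  all <- list()
  for (cl in cliques) {
    ts <- forestFromClique(sm@entities[cl], sm@supports[cl],
                           eps = eps, minNodes = minNodes)
    all <- c(all, ts)
  }
  if (length(all)) {
    keys <- vapply(all, treeKey, character(1))
    all <- all[!duplicated(keys)]
  }
  new("TreeSet", trees = all, kind = kind, tau = sm@tau, eps = eps,
      nCells = sm@nCells)
}

#' Frequency ranking of entities across trees
#'
#' Counts, for every entity, the number of trees containing it; descending
#' by count, ties alphabetical. Merged equal-support nodes ("a=b") count for
#' each member label.
#'
#' @param ts a TreeSet.
#' @return data.frame: entity, count.
#' @export
frequencyRanking <- function(ts) {
  if (!length(ts@trees))
    return(data.frame(entity = character(), count = integer()))
  occ <- lapply(ts@trees, function(tr)
    unique(unlist(strsplit(tr$entities, "=", fixed = TRUE))))
  tab <- table(unlist(occ))
  df <- data.frame(entity = names(tab), count = as.integer(tab))
  df <- df[order(-df$count, df$entity), ]
  rownames(df) <- NULL
  df
}

#' Pair ligand trees with receptor trees through database interactions
#'
#' Returns every (ligand tree, receptor tree) combination sharing at least
#' one database interaction, with the matched interactions listed.
#'
#' @param ligandTs,receptorTs TreeSets of kind ligand / receptor.
#' @param db an LRDatabase.
#' @return data.frame: ligand_tree, receptor_tree, interactions
#'   (";"-separated "L->R" strings).
#' @export
pairTrees <- function(ligandTs, receptorTs, db) {
  ia <- interactions(db)
  treeLabels <- function(tr) unique(unlist(strsplit(tr$entities, "=", fixed = TRUE)))
  out <- list()
  for (i in seq_along(ligandTs@trees)) {
    lset <- treeLabels(ligandTs@trees[[i]])
    for (j in seq_along(receptorTs@trees)) {
      rset <- treeLabels(receptorTs@trees[[j]])
      hit <- ia$ligand %in% lset & ia$receptor %in% rset
      if (any(hit))
        out[[length(out) + 1]] <- data.frame(
          ligand_tree = i, receptor_tree = j,
          interactions = paste(paste0(ia$ligand[hit], "->", ia$receptor[hit]),
                               collapse = ";"))
    }
  }
  if (!length(out))
    return(data.frame(ligand_tree = integer(), receptor_tree = integer(),
                      interactions = character()))
  do.call(rbind, out)
}

#' Serialize a tree as a Newick string
#' @param tree a tree from a TreeSet (list with entities, parent, supports).
#' @return single Newick string, node labels = entity names.
#' @export
treeToNewick <- function(tree) {
  children <- lapply(seq_along(tree$entities),
                     function(i) which(tree$parent == i))
  rec <- function(i) {
    lab <- gsub("[(),;: ]", "_", tree$entities[i])
    kids <- children[[i]]
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
           ")", lab)
  }
  roots <- which(is.na(tree$parent))
  if (length(roots) == 1L) return(paste0(rec(roots), ";"))
  paste0("(", paste(vapply(roots, rec, character(1)), collapse = ","), ");")
}

#' Serialize a TreeSet as nested JSON
#' @param ts a TreeSet.
#' @param path output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
treesToJSON <- function(ts, path = NULL) {
  asNested <- function(tree, i) {
    kids <- which(tree$parent == i)
    node <- list(entity = tree$entities[i],
                 support_size = length(tree$supports[[i]]))
    if (length(kids))
      node$children <- lapply(kids, function(j) asNested(tree, j))
    node
  }
  payload <- lapply(ts@trees, function(tr) {
    roots <- which(is.na(tr$parent))
    if (length(roots) == 1L) asNested(tr, roots)
    else list(entity = ".forest.",
              children = lapply(roots, function(r) asNested(tr, r)))
  })
  js <- jsonlite::toJSON(list(kind = ts@kind, tau = ts@tau, eps = ts@eps,
                              n_trees = length(ts@trees), trees = payload),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
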