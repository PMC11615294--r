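test_that("unit expression is the column for single units, geometric mean for complexes", {
  em <- toyExpression()
  expect_equal(unitExpression(em, "Igf2"), as.numeric(exprValues(em)[, "Igf2"]))
  gm <- unitExpression(em, "Itga6_Itgb4")
  v <- as.matrix(exprValues(em)[, c("Itga6", "Itgb4")])
  expect_equal(gm, unname(sqrt(v[, 1] * v[, 2])), tolerance = 1e-12)
  expect_equal(gm[4], 0)  # any zero subunit annihilates
  # (4, 9) -> 6
  em49 <- ExpressionMatrix(matrix(c(4, 9), 1), geneIds = c("a", "b"),
                           cellIds = "c1", layerTag = "raw_counts")
  expect_equal(unitExpression(em49, "a_b"), 6)
  expect_warning(expect_null(unitExpression(em, "Igf2_Missing")), "missing")
})

test_that("exact rank-sum tail matches wilcox.test and handles complete separation", {
  # tie-free case: compare against the exact distribution in wilcox.test
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample(seq_len(50), n1 + n2)   # distinct values, no ties
    inG <- c(rep(TRUE, n1), rep(FALSE, n2))
    p_pkg <- hierCCC:::rankSumP(x, inG)
    p_ref <- wilcox.test(x[inG], x[!inG], alternative = "greater",
                         exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
  # complete separation with both groups <= 12: exact tail = 1/C(n, n1)
  x <- c(rep(10, 5), rep(0, 12))
  p <- hierCCC:::rankSumP(x, c(rep(TRUE, 5), rep(FALSE, 12)))
  expect_equal(p, 1 / choose(17, 5), tolerance = 1e-12)
  # larger groups switch to the normal approximation, still tiny p
  x2 <- c(rep(10, 5), rep(0, 20))
  p2 <- hierCCC:::rankSumP(x2, c(rep(TRUE, 5), rep(FALSE, 20)))
  expect_lt(p2, 1e-4)
})

test_that("normal approximation agrees with wilcox.test at larger n", {
  set.seed(32)
  x <- c(rnorm(40, 1), rnorm(60))
  inG <- c(rep(TRUE, 40), rep(FALSE, 60))
  p_pkg <- hierCCC:::rankSumP(x, inG)
  p_ref <- wilcox.test(x[inG], x[!inG], alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  # with ties
  xt <- round(x)
  expect_equal(hierCCC:::rankSumP(xt, inG),
               wilcox.test(xt[inG], xt[!inG], alternative = "greater",
                           exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

mkHier <- function(n, memberships) {
  new("HierarchicalClustering",
      scaleIndex = seq_len(ncol(memberships)),
      times = rev(10^seq_len(ncol(memberships))),
      memberships = memberships, cellIds = paste0("c", seq_len(n)),
      diagnostics = data.frame())
}

test_that("markers are assigned to the scale and cluster of true over-expression", {
  set.seed(33)
  n <- 40
  m2 <- cbind(rep(1:2, each = 20), rep(1:4, each = 10))
  hier <- mkHier(n, m2)
  # geneA: elevated exactly in scale-2 cluster 3 (a sub-cluster)
  gA <- rnorm(n, 1, 0.1)
  gA[21:30] <- gA[21:30] + 5
  # geneB: elevated in the whole scale-1 cluster 2
  gB <- rnorm(n, 1, 0.1)
  gB[21:40] <- gB[21:40] + 5
  # geneC: uniform
  gC <- rnorm(n, 1, 0.1)
  em <- ExpressionMatrix(cbind(gA, gB, gC) + 10,
                         geneIds = c("gA", "gB", "gC"),
                         cellIds = paste0("c", 1:n), layerTag = "lognorm")
  asn <- assignMarkers(em, hier, c("gA", "gB", "gC"))
  expect_equal(asn$scale[asn$unit == "gA"], 2)
  expect_equal(asn$cluster[asn$unit == "gA"], 3)
  expect_equal(asn$scale[asn$unit == "gB"], 1)
  expect_equal(asn$cluster[asn$unit == "gB"], 2)
  expect_gt(asn$p_value[asn$unit == "gC"], 1e-3)
  # permutation of cell order never changes assignments
  perm <- sample(n)
  emP <- ExpressionMatrix(as.matrix(exprValues(em))[perm, ],
                          geneIds = geneIds(em),
                          cellIds = cellIds(em)[perm], layerTag = "lognorm")
  hierP <- mkHier(n, m2[perm, , drop = FALSE])
  hierP@cellIds <- cellIds(em)[perm]
  asnP <- assignMarkers(emP, hierP, c("gA", "gB", "gC"))
  expect_equal(asnP[order(asnP$unit), c("scale", "cluster", "p_value")],
               asn[order(asn$unit), c("scale", "cluster", "p_value")],
               ignore_attr = TRUE)
})

test_that("specific pairs require both sides under threshold and order by score", {
  asn <- data.frame(unit = c("L1", "L2", "R1", "R2"),
                    scale = c(2, 1, 1, 2), cluster = c(3, 1, 1, 2),
                    p_value = c(1e-4, 1e-5, 1e-5, 1e-2))
  db <- LRDatabase(ligand = c("L1", "L2", "L1"),
                   receptor = c("R1", "R1", "R2"),
                   pathway = c("P1", "P1", "P2"))
  sp <- specificPairs(asn, db, pThreshold = 1e-3)
  expect_equal(nrow(sp), 2)                    # L1-R2 excluded (p_R = 0.01)
  expect_equal(sp$score, sp$p_L * sp$p_R)
  expect_equal(sp$ligand[1], "L2")             # 1e-10 < 1e-9
  expect_true(all(diff(sp$score) >= 0))
  # monotone transform of both p-values leaves the order unchanged
  o1 <- order(sp$score)
  o2 <- order(log(sp$p_L) + log(sp$p_R))
  expect_equal(o1, o2)
})

test_that("child-specific ligand pairs with parent-specific receptor keep both scales", {
  set.seed(34)
  n <- 60
  memb <- cbind(rep(1:2, each = 30), rep(1:4, each = 15))
  hier <- mkHier(n, memb)
  lig <- rnorm(n, 0.5, 0.05)
  lig[31:45] <- lig[31:45] + 4      # scale-2 cluster 3 (child of scale-1 c2)
  rec <- rnorm(n, 0.5, 0.05)
  rec[31:60] <- rec[31:60] + 4      # whole scale-1 cluster 2 (the parent)
  em <- ExpressionMatrix(cbind(CCL3 = lig, CCR1 = rec) + 5,
                         geneIds = c("CCL3", "CCR1"),
                         cellIds = paste0("c", 1:n), layerTag = "lognorm")
  db <- LRDatabase("CCL3", "CCR1", "CCL")
  asn <- assignMarkers(em, hier, c("CCL3", "CCR1"))
  sp <- specificPairs(asn, db)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$ligand_scale, 2)   # sender: the child cluster
  expect_equal(sp$ligand_cluster, 3)
  expect_equal(sp$receptor_scale, 1) # receiver: the parent cluster
  expect_equal(sp$receptor_cluster, 2)
})
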