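test_that("linker p-values are exact hypergeometric upper tails", {
  expect_equal(linkerPvalue(3, 3, 10, 4), 4 / 84)
  expect_equal(linkerPvalue(2, 2, 6, 5), 1)       # every draw is altered
  for (n in c(1, 3, 5)) expect_equal(linkerPvalue(n, 0, 12, 4), 1)
  expect_error(linkerPvalue(3, 4, 10, 4), "alteredNeighbors")
  expect_error(linkerPvalue(10, 2, 10, 4), "hinSize")
  # vectorized and order-preserving
  expect_equal(linkerPvalue(c(3, 2), c(3, 2), c(10, 6), c(4, 5)),
               c(4 / 84, 1))
})

test_that("BH adjustment matches the hand-applied step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_equal(bhAdjust(c(1, 1)), c(1, 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (r in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), bhStepUp(p), tolerance = 1e-12)
  }
})

# a small global network where X links two altered genes: A - X - B, with
# isolated bystander genes enlarging the hypergeometric population
linkerHin <- function(nIsolated = 17) {
  interactionNetwork(
    data.frame(a = c("A", "X"), b = c("X", "B"), type = "pp"),
    nodes = paste0("iso", seq_len(nIsolated)))
}

test_that("direct connections need no linkers; enriched linkers are retained", {
  hinAB <- mkNet("A", "B")
  ex <- extractNetwork(hinAB, c("A", "B"), spThreshold = 1)
  expect_equal(genes(ex), c("A", "B"))
  expect_equal(numEdges(ex), 1L)
  expect_equal(unname(roles(ex)), c("ALTERED", "ALTERED"))
  expect_equal(nrow(linkerStats(ex)), 0L)

  hin <- linkerHin()   # 20 genes total; X: degree 2, both neighbors altered
  ex <- extractNetwork(hin, c("A", "B"), spThreshold = 2, fdrCutoff = 0.05)
  expect_equal(unname(roles(ex)["X"]), "LINKER")
  expect_equal(numEdges(ex), 2L)
  st <- linkerStats(ex)
  expect_equal(st$pValue, choose(2, 2) / choose(19, 2))
  expect_equal(st$alteredNeighbors, 2L)
})

test_that("degree-1 neighbors are pruned before testing", {
  # Y touches exactly one altered gene: never a candidate
  hin <- mkNet(c("A", "X", "A"), c("X", "B", "Y"),
               nodes = paste0("iso", 1:16))
  ex <- extractNetwork(hin, c("A", "B"))
  expect_false("Y" %in% genes(ex))
  expect_false("Y" %in% linkerStats(ex, all = TRUE)$gene)
  expect_true("X" %in% linkerStats(ex, all = TRUE)$gene)
})

test_that("linker retention is strict at the cutoff and monotone in it", {
  hin <- linkerHin()
  q <- linkerStats(extractNetwork(hin, c("A", "B")), all = FALSE)$qValue
  atCut <- extractNetwork(hin, c("A", "B"), fdrCutoff = q)
  expect_equal(sum(roles(atCut) == "LINKER"), 0L)   # q < cutoff is strict
  above <- extractNetwork(hin, c("A", "B"), fdrCutoff = min(1, q + 1e-9))
  expect_equal(sum(roles(above) == "LINKER"), 1L)

  set.seed(19)
  hinR <- randomNet(40, 0.12, seed = 19)
  altered <- sample(genes(hinR), 12)
  prev <- Inf
  for (fdr in c(0.5, 0.2, 0.05, 0.01)) {
    nl <- sum(roles(extractNetwork(hinR, altered, fdrCutoff = fdr)) == "LINKER")
    expect_lte(nl, prev)
    prev <- nl
  }
})

test_that("sp-threshold 1 equals the induced subgraph on altered genes", {
  for (s in 1:5) {
    hin <- randomNet(25, 0.15, seed = 100 + s)
    set.seed(s)
    altered <- sample(genes(hin), 8)
    ex <- extractNetwork(hin, altered, spThreshold = 1)
    sub <- igraph::induced_subgraph(asIgraph(hin), sort(altered))
    sub <- igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
    expect_setequal(genes(ex), igraph::V(sub)$name)
    expect_equal(numEdges(ex), igraph::gsize(sub))
  }
})

test_that("extraction is deterministic and invariant to input gene order", {
  hin <- randomNet(30, 0.15, seed = 4)
  set.seed(4)
  altered <- sample(genes(hin), 10)
  a <- extractNetwork(hin, altered)
  b <- extractNetwork(hin, rev(altered))
  expect_identical(genes(a), genes(b))
  expect_identical(roles(a), roles(b))
  expect_identical(linkerStats(a), linkerStats(b))
})

test_that("every retained linker keeps >= 2 altered neighbors in the graph", {
  for (s in 1:4) {
    hin <- randomNet(35, 0.12, seed = 200 + s)
    set.seed(s)
    altered <- sample(genes(hin), 12)
    ex <- extractNetwork(hin, altered, fdrCutoff = 0.3)
    g <- asIgraph(ex)
    for (lk in names(roles(ex))[roles(ex) == "LINKER"]) {
      nb <- igraph::neighbors(g, lk)$name
      expect_gte(sum(roles(ex)[nb] == "ALTERED"), 2L)
    }
    # linker-linker edges come from the global network
    et <- AlteredNet:::.edgeTable(ex@graph)
    for (i in seq_len(nrow(et)))
      expect_true(igraph::are_adjacent(asIgraph(hin), et$a[i], et$b[i]))
  }
})

test_that("altered genes absent from the network yield an empty result with warning", {
  hin <- mkNet("A", "B")
  expect_warning(ex <- extractNetwork(hin, c("ZZ", "YY")), "no altered gene")
  expect_equal(numNodes(ex), 0L)
  # altered genes with no retained edge are reported unplaced, not placed
  hin2 <- mkNet(c("A", "C"), c("B", "D"), nodes = "E")
  ex2 <- extractNetwork(hin2, c("A", "B", "E"))
  expect_setequal(genes(ex2), c("A", "B"))
  expect_equal(ex2@unplaced, "E")
  expect_setequal(ex2@alteredGenes, c("A", "B", "E"))
})
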