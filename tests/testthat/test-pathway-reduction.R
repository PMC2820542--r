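# a kinase K phosphorylating substrate S (two states of the same gene)
kinaseModel <- function() {
  pathwayModel(
    molecules = data.frame(id = c("K1", "S1", "S1p", "atp"),
                           gene = c("K", "S", "S", NA),
                           state = c("", "unphos", "phos", "")),
    reactions = list(r1 = list(inputs = c("S1", "atp"), outputs = "S1p")),
    controls = data.frame(controller = "K1", reaction = "r1",
                          type = "CATALYSIS"))
}

test_that("a controlled state change maps to a STATE_CHANGE interaction", {
  out <- reducePathway(kinaseModel(), rules = "STATE_CHANGE")
  expect_equal(nrow(out), 1L)
  expect_equal(sort(c(out$a, out$b)), c("K", "S"))
  expect_equal(out$rule, "STATE_CHANGE")
  # small molecules (no gene ref) never generate edges
  expect_false(any(c(out$a, out$b) %in% "atp"))
})

test_that("complex members pair up, recursively flattened, homodimers suppressed", {
  m <- pathwayModel(
    molecules = data.frame(id = c("p", "q", "r"), gene = c("P", "Q", "R")),
    complexes = list(cx = c("p", "q", "r")))
  out <- reducePathway(m, rules = "IN_SAME_COMPLEX")
  expect_equal(nrow(out), choose(3, 2))

  nested <- pathwayModel(
    molecules = data.frame(id = c("p", "q", "r"), gene = c("P", "Q", "R")),
    complexes = list(outer = c("p", "inner"), inner = c("q", "r")))
  out <- reducePathway(nested, rules = "IN_SAME_COMPLEX")
  # outer (flattened) pairs P,Q,R; the inner complex re-emits (Q,R);
  # gene-level collapse reduces this to the 3 unique pairs
  expect_equal(nrow(out), 4L)
  expect_equal(numEdges(interactionsToNetwork(out)), 3L)

  homodimer <- pathwayModel(
    molecules = data.frame(id = c("p1", "p2"), gene = c("P", "P")),
    complexes = list(cx = c("p1", "p2")))
  out <- reducePathway(homodimer, rules = "IN_SAME_COMPLEX")
  expect_equal(nrow(out), 0L)
  expect_equal(numEdges(interactionsToNetwork(out)), 0L)
})

test_that("REACTS_WITH pairs reaction inputs; a bare conversion fires no rule", {
  m <- pathwayModel(
    molecules = data.frame(id = c("x", "y", "z"), gene = c("X", "Y", "Z")),
    reactions = list(r = list(inputs = c("x", "y"), outputs = "z")))
  out <- reducePathway(m, rules = "REACTS_WITH")
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$a, out$b), c("X", "Y"))   # inputs only, not outputs

  bare <- pathwayModel(
    molecules = data.frame(id = c("x", "z"), gene = c("X", "Z")),
    reactions = list(r = list(inputs = "x", outputs = "z")))
  expect_equal(nrow(reducePathway(bare)), 0L)
})

test_that("sequential catalysis requires molecule-level identity between reactions", {
  mols <- data.frame(id = c("e1", "e2", "a", "b", "b2", "c"),
                     gene = c("E1", "E2", "A", "B", "B", "C"))
  chained <- pathwayModel(
    molecules = mols,
    reactions = list(r1 = list(inputs = "a", outputs = "b"),
                     r2 = list(inputs = "b", outputs = "c")),
    controls = data.frame(controller = c("e1", "e2"),
                          reaction = c("r1", "r2"),
                          type = "CATALYSIS"))
  out <- reducePathway(chained, rules = "SEQUENTIAL_CATALYSIS")
  expect_equal(nrow(out), 1L)
  expect_setequal(c(out$a, out$b), c("E1", "E2"))

  # same gene product but a different molecule id does not chain
  unchained <- pathwayModel(
    molecules = mols,
    reactions = list(r1 = list(inputs = "a", outputs = "b"),
                     r2 = list(inputs = "b2", outputs = "c")),
    controls = data.frame(controller = c("e1", "e2"),
                          reaction = c("r1", "r2"),
                          type = "CATALYSIS"))
  expect_equal(nrow(reducePathway(unchained, rules = "SEQUENTIAL_CATALYSIS")),
               0L)
})

test_that("co-control pairs distinct controllers of one reaction", {
  m <- pathwayModel(
    molecules = data.frame(id = c("e1", "e2", "e3", "x", "y"),
                           gene = c("E1", "E2", "E3", "X", "Y")),
    reactions = list(r = list(inputs = "x", outputs = "y")),
    controls = data.frame(controller = c("e1", "e2", "e3"),
                          reaction = "r", type = "CATALYSIS"))
  out <- reducePathway(m, rules = "CO_CONTROL")
  expect_equal(nrow(out), choose(3, 2))
})

test_that("rule counts match a brute-force pattern enumeration on a random model", {
  set.seed(7)
  nMol <- 14
  genesOf <- sample(c(paste0("G", 1:7), NA), nMol, replace = TRUE)
  mols <- data.frame(id = paste0("m", 1:nMol), gene = genesOf)
  cxs <- list(c1 = sample(mols$id, 4), c2 = sample(mols$id, 3))
  rxs <- lapply(1:4, function(i)
    list(inputs = sample(mols$id, sample(1:3, 1)),
         outputs = sample(mols$id, sample(1:2, 1))))
  names(rxs) <- paste0("r", 1:4)
  ctl <- data.frame(controller = sample(mols$id, 5, replace = TRUE),
                    reaction = sample(names(rxs), 5, replace = TRUE),
                    type = "CATALYSIS")
  model <- pathwayModel(mols, cxs, rxs, ctl)
  out <- reducePathway(model)

  gene <- function(ids) sort(unique(na.omit(mols$gene[match(ids, mols$id)])))
  pairCount <- function(gg) if (length(gg) >= 2) choose(length(gg), 2) else 0
  # brute force each rule with direct nested loops over the record lists
  nComplex <- sum(vapply(cxs, function(mem) pairCount(gene(mem)), numeric(1)))
  nReacts <- sum(vapply(rxs, function(r) pairCount(gene(r$inputs)), numeric(1)))
  nState <- 0; nCo <- 0; nSeq <- 0
  for (rid in names(rxs)) {
    ctrl <- gene(ctl$controller[ctl$reaction == rid])
    changed <- intersect(gene(rxs[[rid]]$inputs), gene(rxs[[rid]]$outputs))
    for (cg in ctrl) nState <- nState + sum(changed != cg)
    nCo <- nCo + pairCount(ctrl)
  }
  for (ri in names(rxs)) for (rj in names(rxs)) {
    if (ri == rj) next
    if (length(intersect(rxs[[ri]]$outputs, rxs[[rj]]$inputs)) == 0) next
    gi <- gene(ctl$controller[ctl$reaction == ri])
    gj <- gene(ctl$controller[ctl$reaction == rj])
    for (a in gi) nSeq <- nSeq + sum(gj != a)
  }
  counts <- table(factor(out$rule, levels = c("IN_SAME_COMPLEX", "REACTS_WITH",
                                              "STATE_CHANGE",
                                              "SEQUENTIAL_CATALYSIS",
                                              "CO_CONTROL")))
  expect_equal(unname(counts[["IN_SAME_COMPLEX"]]), nComplex)
  expect_equal(unname(counts[["REACTS_WITH"]]), nReacts)
  expect_equal(unname(counts[["STATE_CHANGE"]]), nState)
  expect_equal(unname(counts[["SEQUENTIAL_CATALYSIS"]]), nSeq)
  expect_equal(unname(counts[["CO_CONTROL"]]), nCo)

  # enabling rules is monotone in the emitted multiset
  for (rule in unique(out$rule)) {
    sub <- reducePathway(model, rules = rule)
    expect_equal(nrow(sub), sum(out$rule == rule))
  }
})

test_that("gene-level collapse accumulates tags, drops self-pairs, is idempotent", {
  ints <- data.frame(a = c("K", "S"), b = c("S", "K"),
                     rule = c("STATE_CHANGE", "REACTS_WITH"))
  net <- interactionsToNetwork(ints)
  expect_equal(numEdges(net), 1L)
  expect_equal(AlteredNet:::.edgeTable(net)$types[[1]],
               c("REACTS_WITH", "STATE_CHANGE"))
  expect_equal(numEdges(interactionsToNetwork(data.frame(
    a = character(), b = character(), rule = character()))), 0L)
  # idempotence: re-collapsing the collapsed edge table changes nothing
  et <- AlteredNet:::.edgeTable(net)
  again <- interactionsToNetwork(data.frame(a = et$a, b = et$b,
                                            rule = "STATE_CHANGE"))
  expect_equal(numEdges(again), numEdges(net))
})

test_that("dangling references and cyclic complexes fail validation", {
  expect_error(pathwayModel(
    molecules = data.frame(id = "x", gene = "X"),
    reactions = list(r = list(inputs = "nope", outputs = "x"))),
    "dangling")
  expect_error(pathwayModel(
    molecules = data.frame(id = "x", gene = "X"),
    complexes = list(c1 = c("x", "c2"), c2 = "c1")),
    "cycle")
})

test_that("reaction tables round-trip through the reader", {
  f <- tempfile()
  writeLines(c("# toy kinase cascade",
               "MOLECULE\tK1\tK",
               "MOLECULE\tS1\tS\tunphos",
               "MOLECULE\tS1p\tS\tphos",
               "MOLECULE\tatp\t-",
               "REACTION\tr1\tS1,atp\tS1p",
               "CONTROL\tK1\tr1\tCATALYSIS"), f)
  model <- readPathwayModel(f)
  out <- reducePathway(model, rules = "STATE_CHANGE")
  expect_equal(sort(c(out$a, out$b)), c("K", "S"))
  expect_error(readPathwayModel(tempfile()), "not found")
  bad <- tempfile(); writeLines("WHAT\tx", bad)
  expect_error(readPathwayModel(bad), "malformed")
})
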