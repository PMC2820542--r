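test_that("the altered-gene definition counts mutations, deletions, amplifications only", {
  m <- alterationMatrix(data.frame(
    case = c("c1", "c2", "c1"),
    gene = c("TP53", "TP53", "PTEN"),
    state = c("MUTATION", "HOMOZYGOUS_DELETION", "HETEROZYGOUS_LOSS")))
  gs <- alteredGeneSet(m, minCases = 2)
  expect_equal(genes(gs), "TP53")
  expect_equal(gs@frequency$count, 2L)
  # PTEN carries only an ignored copy-number event: altered in 0 cases
  gs1 <- alteredGeneSet(m, minCases = 1)
  expect_false("PTEN" %in% genes(gs1))
})

test_that("ingestion is idempotent; contradictions error naming the pair", {
  m <- alterationMatrix(data.frame(
    case = c("c1", "c1"), gene = c("TP53", "TP53"),
    state = c("MUTATION", "MUTATION")))
  expect_equal(nrow(m@calls), 1L)
  # a mutated and amplified gene in one case counts once toward recurrence
  both <- alterationMatrix(data.frame(
    case = c("c1", "c1", "c2"), gene = c("EGFR", "EGFR", "EGFR"),
    state = c("MUTATION", "AMPLIFICATION", "MUTATION")))
  expect_equal(alteredGeneSet(both, minCases = 1)@frequency$count, 2L)
  # contradictions: NONE vs altered, or two different copy-number states
  expect_error(alterationMatrix(data.frame(
    case = "c1", gene = c("TP53", "TP53"),
    state = c("NONE", "MUTATION"))), "conflicting states.*c1.*TP53")
  expect_error(alterationMatrix(data.frame(
    case = "c1", gene = c("EGFR", "EGFR"),
    state = c("AMPLIFICATION", "HOMOZYGOUS_DELETION"))), "conflicting")
  expect_error(alterationMatrix(data.frame(
    case = "c1", gene = "TP53", state = "SOMETHING")), "unknown")
})

test_that("hypermutator exclusion retains the remaining cohort", {
  cases <- sprintf("c%02d", 1:91)
  hyper <- cases[1:7]
  m <- alterationMatrix(data.frame(case = c("c10", "c11"), gene = "TP53",
                                   state = "MUTATION"),
                        cases = cases, hypermutators = hyper)
  gs <- alteredGeneSet(m, minCases = 2, excludeHypermutators = TRUE)
  expect_equal(nCases(gs), 84L)
  expect_equal(nCases(alteredGeneSet(m, excludeHypermutators = FALSE)), 91L)
})

test_that("recurrence thresholding is monotone and order-invariant", {
  set.seed(11)
  calls <- data.frame(
    case = sample(sprintf("c%02d", 1:20), 60, replace = TRUE),
    gene = sample(paste0("G", 1:8), 60, replace = TRUE),
    state = "MUTATION")
  m <- alterationMatrix(calls, cases = sprintf("c%02d", 1:20))
  prev <- genes(alteredGeneSet(m, minCases = 1))
  for (k in 2:5) {
    cur <- genes(alteredGeneSet(m, minCases = k))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  shuffled <- alterationMatrix(calls[sample(nrow(calls)), ],
                               cases = rev(sprintf("c%02d", 1:20)))
  expect_equal(alteredGeneSet(m, minCases = 2)@frequency,
               alteredGeneSet(shuffled, minCases = 2)@frequency)
})

test_that("with hypermutators kept, counts equal retained plus flagged contributions", {
  m <- alterationMatrix(data.frame(case = c("h1", "c1", "c2"), gene = "G1",
                                   state = "MUTATION"),
                        cases = c("h1", "c1", "c2"), hypermutators = "h1")
  withH <- alteredGeneSet(m, minCases = 1, excludeHypermutators = FALSE)
  noH <- alteredGeneSet(m, minCases = 1, excludeHypermutators = TRUE)
  expect_equal(withH@frequency$count, 3L)
  expect_equal(noH@frequency$count, 2L)
})

test_that("threshold and case-count edge cases error or return empty cleanly", {
  m <- alterationMatrix(data.frame(case = character(), gene = character(),
                                   state = character()),
                        cases = c("c1", "c2", "c3"))
  gs <- alteredGeneSet(m, minCases = 1)
  expect_length(genes(gs), 0L)
  expect_equal(nCases(gs), 3L)
  expect_error(alteredGeneSet(m, minCases = 4), "retained cases")
  expect_error(alteredGeneSet(m, minCases = 0), ">= 1")
})

test_that("alteration tables load with optional header and hypermutator list", {
  f <- tempfile()
  writeLines(c("case\tgene\tstate",
               "c1\tTP53\tMUTATION",
               "c2\tTP53\tHOMOZYGOUS_DELETION",
               "c1\tPTEN\tHETEROZYGOUS_LOSS"), f)
  hf <- tempfile()
  writeLines(c("c3", "# comment"), hf)
  m <- loadAlterations(f, hypermutatorFile = hf)
  expect_setequal(m@cases, c("c1", "c2", "c3"))   # flagged case joins cohort
  expect_equal(m@hypermutators, "c3")
  expect_equal(nrow(m@calls), 3L)

  bad <- tempfile(); writeLines("c1\tTP53\tBOGUS", bad)
  expect_error(loadAlterations(bad), "unknown")
  short <- tempfile(); writeLines("c1\tTP53", short)
  expect_error(loadAlterations(short), "line 1")
})

test_that("frequency tables serialize as gene/count/fraction", {
  m <- alterationMatrix(data.frame(case = c("c1", "c2"), gene = "TP53",
                                   state = "MUTATION"),
                        cases = c("c1", "c2", "c3", "c4"))
  gs <- alteredGeneSet(m, minCases = 2)
  f <- tempfile()
  writeFrequencies(gs, f)
  tab <- read.delim(f)
  expect_equal(tab$gene, "TP53")
  expect_equal(tab$count, 2L)
  expect_equal(tab$fraction, 0.5)
})
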