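# Synthetic-data generation: random interaction networks, planted dense
# altered-gene modules, and case x gene alteration matrices, so the whole
# pipeline is exercisable and benchmarkable without any download.

#' Synthetic global interaction network
#'
#' Random simple undirected graph standing in for a literature-curated
#' interaction network: Erdos-Renyi (\code{"ER"}, fixed edge count
#' \code{round(meanDegree * n / 2)}) or preferential attachment
#' (\code{"BA"}, \code{round(meanDegree / 2)} edges per new node).
#'
#' @param nGenes number of genes (>= 3).
#' @param meanDegree target mean degree (< nGenes - 1).
#' @param model \code{"ER"} or \code{"BA"}.
#' @param seed integer seed; identical seeds give identical networks.
#' @return an [InteractionNetwork-class] with genes \code{g0001, ...}.
#' @export
synthHIN <- function(nGenes, meanDegree, model = c("ER", "BA"), seed = 1L) {
  model <- match.arg(model)
  nGenes <- as.integer(nGenes)
  if (nGenes < 3L) stop("nGenes must be >= 3")
  if (meanDegree > nGenes - 1) stop("meanDegree must be <= nGenes - 1")
  if (meanDegree <= 0) stop("meanDegree must be positive")
  set.seed(as.integer(seed))
  g <- if (model == "ER") {
    m <- max(1L, round(meanDegree * nGenes / 2))
    igraph::sample_gnm(nGenes, m)
  } else {
    igraph::sample_pa(nGenes, m = max(1L, round(meanDegree / 2)),
                      directed = FALSE)
  }
  g <- igraph::simplify(g)
  nm <- sprintf("g%04d", seq_len(nGenes))
  el <- if (igraph::gsize(g)) igraph::as_edgelist(g, names = FALSE) else
    matrix(integer(), ncol = 2L)
  .buildGraph(data.frame(a = nm[el[, 1]], b = nm[el[, 2]], type = "pp"),
              nodes = nm)
}

#' Plant dense modules of altered genes into a network
#'
#' Selects \code{nModules} disjoint sets of \code{moduleSize} genes,
#' removes all pre-existing edges among the selected genes, then connects
#' within-module pairs with probability \code{pWithin} and cross-module
#' pairs with probability \code{pBetween} (requires
#' \code{pWithin > pBetween}).  Edges between planted and background genes
#' are left untouched.  All planted genes are marked altered in the
#' returned truth.
#'
#' @param hin an [InteractionNetwork-class] to plant into.
#' @param nModules number of planted modules.
#' @param moduleSize genes per module.
#' @param pWithin,pBetween within- and between-module edge probabilities.
#' @param seed integer seed.
#' @return list with the modified network (\code{network}) and a
#'   [PlantedTruth-class] (\code{truth}).
#' @export
plantModules <- function(hin, nModules, moduleSize, pWithin = 0.9,
                         pBetween = 0.05, seed = 1L) {
  stopifnot(is(hin, "InteractionNetwork"))
  nModules <- as.integer(nModules); moduleSize <- as.integer(moduleSize)
  if (!(pWithin > pBetween)) stop("pWithin must exceed pBetween")
  if (any(c(pWithin, pBetween) < 0) || any(c(pWithin, pBetween) > 1))
    stop("densities must be probabilities")
  pool <- genes(hin)
  if (nModules * moduleSize > length(pool))
    stop("planted genes exceed the network size")
  set.seed(as.integer(seed))
  planted <- sample(pool, nModules * moduleSize)
  assign <- setNames(rep(seq_len(nModules) - 1L, each = moduleSize), planted)
  plantedSet <- sort(planted)

  et <- .edgeTable(hin)
  keep <- !(et$a %in% plantedSet & et$b %in% plantedSet)
  edges <- data.frame(a = et$a[keep], b = et$b[keep], type = "pp")
  pairs <- combn(plantedSet, 2L)
  sameMod <- assign[pairs[1L, ]] == assign[pairs[2L, ]]
  p <- ifelse(sameMod, pWithin, pBetween)
  hit <- runif(ncol(pairs)) < p
  if (any(hit))
    edges <- rbind(edges, data.frame(a = pairs[1L, hit], b = pairs[2L, hit],
                                     type = ifelse(sameMod[hit],
                                                   "planted_within",
                                                   "planted_between")))
  net <- .buildGraph(edges, nodes = pool)
  truth <- new("PlantedTruth",
               moduleAssignments = assign[order(names(assign))],
               alteredGenes = plantedSet,
               parameters = list(nGenes = length(pool), nModules = nModules,
                                 moduleSize = moduleSize, pWithin = pWithin,
                                 pBetween = pBetween, seed = as.integer(seed)))
  list(network = net, truth = truth)
}

#' Synthetic alteration matrix over a planted truth
#'
#' Emulates the study design the pipeline expects: a cohort of cases with
#' discrete per-gene alteration calls, recurrent alteration of the planted
#' (driver) genes, sparse background (passenger) alterations, and a small
#' fraction of hypermutator cases whose rates are inflated tenfold.
#' States are drawn uniformly from MUTATION / HOMOZYGOUS_DELETION /
#' AMPLIFICATION.  Defaults mirror a cohort of 91 cases of which about 7
#' are hypermutators.
#'
#' @param truth a [PlantedTruth-class] (planted genes are altered
#'   recurrently).
#' @param backgroundGenes genes alterable at the background rate
#'   (typically the non-planted network genes).
#' @param nCases cohort size (default 91).
#' @param perGeneRate per-case alteration probability of a planted gene
#'   (default 0.25).
#' @param backgroundRate per-case alteration probability of a background
#'   gene (default 0.01).
#' @param hypermutatorFraction fraction of cases flagged hypermutator,
#'   with 10x rates capped at 1 (default 7/91).
#' @param seed integer seed.
#' @return an [AlterationMatrix-class] with cases \code{case001, ...} and
#'   hypermutators flagged.
#' @export
synthAlterations <- function(truth, backgroundGenes = character(),
                             nCases = 91L, perGeneRate = 0.25,
                             backgroundRate = 0.01,
                             hypermutatorFraction = 7 / 91, seed = 1L) {
  stopifnot(is(truth, "PlantedTruth"))
  rates <- c(perGeneRate, backgroundRate, hypermutatorFraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  nCases <- as.integer(nCases)
  set.seed(as.integer(seed))
  cases <- sprintf("case%03d", seq_len(nCases))
  hyper <- cases[runif(nCases) < hypermutatorFraction]
  geneRate <- c(setNames(rep(perGeneRate, length(truth@alteredGenes)),
                         truth@alteredGenes),
                setNames(rep(backgroundRate, length(backgroundGenes)),
                         setdiff(backgroundGenes, truth@alteredGenes)))
  rows <- list()
  for (cs in cases) {
    r <- if (cs %in% hyper) pmin(1, geneRate * 10) else geneRate
    hitGenes <- names(r)[runif(length(r)) < r]
    if (length(hitGenes))
      rows[[cs]] <- data.frame(
        case = cs, gene = hitGenes,
        state = sample(.ALTERED_STATES, length(hitGenes), replace = TRUE))
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case = character(), gene = character(), state = character())
  alterationMatrix(calls, cases = cases, hypermutators = hyper)
}

#' Write a ready-to-run fixture directory
#'
#' Generates a synthetic global network with planted modules and a
#' matching alteration matrix, and writes \code{network.sif},
#' \code{alterations.tsv}, \code{hypermutators.txt} and
#' \code{truth.json} into \code{dir}.
#'
#' @param dir output directory (created if missing).
#' @param nGenes,meanDegree,model passed to [synthHIN()].
#' @param nModules,moduleSize,pWithin,pBetween passed to [plantModules()].
#' @param nCases,perGeneRate,backgroundRate,hypermutatorFraction passed to
#'   [synthAlterations()].
#' @param seed master seed (sub-seeds derived per stage).
#' @return invisibly, a list with the network, truth, matrix and file
#'   paths.
#' @export
writeFixtures <- function(dir, nGenes = 100L, meanDegree = 3,
                          model = "ER", nModules = 3L, moduleSize = 6L,
                          pWithin = 0.9, pBetween = 0.05, nCases = 91L,
                          perGeneRate = 0.25, backgroundRate = 0.01,
                          hypermutatorFraction = 7 / 91, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hin <- synthHIN(nGenes, meanDegree, model, seed = .deriveSeed(seed, 1L))
  pl <- plantModules(hin, nModules, moduleSize, pWithin, pBetween,
                     seed = .deriveSeed(seed, 2L))
  am <- synthAlterations(pl$truth,
                         backgroundGenes = setdiff(genes(pl$network),
                                                   pl$truth@alteredGenes),
                         nCases = nCases, perGeneRate = perGeneRate,
                         backgroundRate = backgroundRate,
                         hypermutatorFraction = hypermutatorFraction,
                         seed = .deriveSeed(seed, 3L))
  paths <- list(network = file.path(dir, "network.sif"),
                alterations = file.path(dir, "alterations.tsv"),
                hypermutators = file.path(dir, "hypermutators.txt"),
                truth = file.path(dir, "truth.json"))
  writeSIF(pl$network, paths$network)
  write.table(am@calls, paths$alterations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(am@hypermutators, paths$hypermutators)
  jsonlite::write_json(
    list(moduleAssignments = as.list(pl$truth@moduleAssignments),
         alteredGenes = pl$truth@alteredGenes,
         parameters = pl$truth@parameters),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(network = pl$network, truth = pl$truth, alterations = am,
                 paths = paths))
}

setMethod("show", "PlantedTruth", function(object) {
  p <- object@parameters
  cat("PlantedTruth:", length(object@alteredGenes), "planted genes in",
      length(unique(object@moduleAssignments)), "modules\n")
  cat("  pWithin =", p$pWithin, ", pBetween =", p$pBetween, "\n")
})
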