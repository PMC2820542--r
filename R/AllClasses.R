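#' @import methods
#' @importFrom stats phyper p.adjust sd setNames runif
#' @importFrom utils read.delim write.table packageVersion combn head
NULL

setOldClass("igraph")

#' InteractionNetwork: an undirected simple gene graph
#'
#' Container for a literature-curated interaction network (and every
#' subnetwork derived from it).  Nodes are gene symbols used verbatim as
#' keys; edges are unordered gene pairs carrying a set of interaction-type
#' annotations (e.g. \code{pp}, \code{STATE_CHANGE}).  The class enforces
#' the simple-graph contract: no self-edges, no parallel edges.
#'
#' @slot graph an undirected simple \code{igraph} object whose vertices are
#'   named by gene symbol; edges carry a list attribute \code{types} with
#'   the sorted annotation tags accumulated during collapsing.
#' @slot stats list with counts recorded while building the network:
#'   \code{duplicatesCollapsed} (redundant edge records merged into an
#'   existing edge) and \code{selfEdgesDropped}.
#'
#' @seealso [interactionNetwork()], [loadNetwork()], [largestComponent()]
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  representation(graph = "igraph", stats = "list"),
  prototype(stats = list(duplicatesCollapsed = 0L, selfEdgesDropped = 0L))
)

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::gsize(g) > 0L && igraph::any_loop(g))
    msg <- c(msg, "self-edges are forbidden")
  if (igraph::gsize(g) > 0L && igraph::any_multiple(g))
    msg <- c(msg, "parallel edges are forbidden")
  nm <- igraph::V(g)$name
  if (igraph::gorder(g) > 0L &&
      (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm) ||
       any(grepl("[ \t]", nm))))
    msg <- c(msg, "vertex names must be unique non-empty tokens without whitespace")
  if (length(msg)) msg else TRUE
})

#' PathwayModel: a simplified biochemical pathway description
#'
#' Minimal reaction-level pathway model (molecules in states, complexes,
#' reactions with inputs/outputs, and controls) intended to be reduced to
#' binary gene-gene interactions by [reducePathway()].
#'
#' @slot molecules data.frame with columns \code{id}, \code{gene}
#'   (gene symbol or \code{NA} for small molecules), \code{state}.
#' @slot complexes named list: complex id -> character vector of member
#'   molecule/complex ids (nesting allowed, cycles are not).
#' @slot reactions named list: reaction id -> list with character vectors
#'   \code{inputs} and \code{outputs} of molecule ids.
#' @slot controls data.frame with columns \code{controller} (molecule id),
#'   \code{reaction} (reaction id), \code{type} (free-text control tag).
#'
#' @exportClass PathwayModel
setClass("PathwayModel",
  representation(molecules = "data.frame", complexes = "list",
                 reactions = "list", controls = "data.frame")
)

setValidity("PathwayModel", function(object) {
  mol <- object@molecules
  msg <- character()
  known <- c(mol$id, names(object@complexes))
  dangling <- character()
  for (cx in names(object@complexes)) {
    miss <- setdiff(object@complexes[[cx]], known)
    if (length(miss)) dangling <- c(dangling, miss)
  }
  for (rx in names(object@reactions)) {
    r <- object@reactions[[rx]]
    miss <- setdiff(c(r$inputs, r$outputs), mol$id)
    if (length(miss)) dangling <- c(dangling, miss)
  }
  if (nrow(object@controls)) {
    miss <- setdiff(object@controls$controller, mol$id)
    missR <- setdiff(object@controls$reaction, names(object@reactions))
    dangling <- c(dangling, miss, missR)
  }
  if (length(dangling))
    msg <- c(msg, paste0("dangling references: ",
                         paste(sort(unique(dangling)), collapse = ", ")))
  # complex membership must be acyclic
  if (length(object@complexes)) {
    colour <- new.env(parent = emptyenv())
    cyc <- FALSE
    visit <- function(id) {
      st <- get0(id, envir = colour, ifnotfound = 0L)
      if (st == 1L) { cyc <<- TRUE; return(invisible()) }
      if (st == 2L) return(invisible())
      assign(id, 1L, envir = colour)
      for (m in object@complexes[[id]])
        if (m %in% names(object@complexes)) visit(m)
      assign(id, 2L, envir = colour)
    }
    for (cx in names(object@complexes)) visit(cx)
    if (cyc) msg <- c(msg, "complex membership graph contains a cycle")
  }
  if (length(msg)) msg else TRUE
})

.ALTERATION_STATES <- c("NONE", "MUTATION", "HOMOZYGOUS_DELETION",
                        "AMPLIFICATION", "HETEROZYGOUS_LOSS",
                        "SINGLE_COPY_GAIN")
.ALTERED_STATES <- c("MUTATION", "HOMOZYGOUS_DELETION", "AMPLIFICATION")

#' AlterationMatrix: per-case discrete alteration states
#'
#' Sparse case x gene store of discrete alteration calls.  Pairs absent
#' from \code{calls} are implicitly \code{NONE}.  The state vocabulary is
#' closed: \code{NONE}, \code{MUTATION}, \code{HOMOZYGOUS_DELETION},
#' \code{AMPLIFICATION}, \code{HETEROZYGOUS_LOSS}, \code{SINGLE_COPY_GAIN}.
#' Only mutations, homozygous deletions and multi-copy amplifications count
#' as "altered"; other copy-number events are carried but ignored by
#' [alteredGeneSet()].
#'
#' @slot cases ordered character vector of case ids (includes cases with
#'   no calls).
#' @slot calls data.frame with columns \code{case}, \code{gene},
#'   \code{state}; one row per recorded (case, gene, state).
#' @slot hypermutators character vector of case ids flagged as
#'   hypermutators (subset of \code{cases}).
#'
#' @exportClass AlterationMatrix
setClass("AlterationMatrix",
  representation(cases = "character", calls = "data.frame",
                 hypermutators = "character")
)

setValidity("AlterationMatrix", function(object) {
  msg <- character()
  if (anyDuplicated(object@cases)) msg <- c(msg, "duplicate case ids")
  if (nrow(object@calls)) {
    bad <- setdiff(object@calls$state, .ALTERATION_STATES)
    if (length(bad))
      msg <- c(msg, paste0("unknown state tag(s): ", paste(bad, collapse = ", ")))
    if (!all(object@calls$case %in% object@cases))
      msg <- c(msg, "calls reference unlisted cases")
  }
  if (!all(object@hypermutators %in% object@cases))
    msg <- c(msg, "hypermutator flags reference unlisted cases")
  if (length(msg)) msg else TRUE
})

#' AlteredGeneSet: recurrently altered genes and their frequencies
#'
#' Genes altered in at least \code{minCases} of the retained cases,
#' together with per-gene altered-case counts and fractions.
#'
#' @slot genes sorted character vector of gene symbols.
#' @slot frequency data.frame with columns \code{gene}, \code{count},
#'   \code{fraction} (count / nCases).
#' @slot nCases number of retained cases the fractions are computed over.
#' @slot minCases the recurrence threshold applied.
#'
#' @exportClass AlteredGeneSet
setClass("AlteredGeneSet",
  representation(genes = "character", frequency = "data.frame",
                 nCases = "integer", minCases = "integer")
)

setValidity("AlteredGeneSet", function(object) {
  msg <- character()
  f <- object@frequency
  if (!setequal(object@genes, f$gene)) msg <- c(msg, "genes and frequency table disagree")
  if (nrow(f)) {
    if (any(f$count < object@minCases))
      msg <- c(msg, "gene below the minCases threshold present")
    if (any(abs(f$fraction - f$count / object@nCases) > 1e-12))
      msg <- c(msg, "fraction != count / nCases")
  }
  if (length(msg)) msg else TRUE
})

#' ExtractedNetwork: altered-gene subnetwork with enriched linkers
#'
#' Result of [extractNetwork()]: the subgraph over ALTERED and retained
#' LINKER genes, the hypergeometric statistics of every tested linker
#' candidate, and the altered genes that could not be placed.
#'
#' @slot graph the extracted [InteractionNetwork-class].
#' @slot roles named character vector (gene -> \code{"ALTERED"} or
#'   \code{"LINKER"}) covering every node of \code{graph}.
#' @slot linkerStats data.frame over retained linkers: \code{gene},
#'   \code{globalDegree}, \code{alteredNeighbors}, \code{pValue},
#'   \code{qValue}.
#' @slot candidateStats same columns over all tested candidates (degree >=
#'   2 neighbors of altered genes), retained or not.
#' @slot alteredGenes character vector: the altered genes present in the
#'   global network (the universe the nulls resample from).
#' @slot unplaced altered genes in the global network left with no retained
#'   edge; reported separately rather than as isolated nodes.
#' @slot parameters list with \code{spThreshold} and \code{fdrCutoff}.
#'
#' @exportClass ExtractedNetwork
setClass("ExtractedNetwork",
  representation(graph = "InteractionNetwork", roles = "character",
                 linkerStats = "data.frame", candidateStats = "data.frame",
                 alteredGenes = "character", unplaced = "character",
                 parameters = "list")
)

setValidity("ExtractedNetwork", function(object) {
  msg <- character()
  nodes <- genes(object@graph)
  if (!setequal(names(object@roles), nodes))
    msg <- c(msg, "roles must cover exactly the graph nodes")
  if (length(object@roles) && !all(object@roles %in% c("ALTERED", "LINKER")))
    msg <- c(msg, "roles outside {ALTERED, LINKER}")
  ls <- object@linkerStats
  if (nrow(ls)) {
    if (any(ls$alteredNeighbors < 2L))
      msg <- c(msg, "retained linker with < 2 altered neighbors")
    if (any(ls$qValue < 0 | ls$qValue > 1)) msg <- c(msg, "q-value outside [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' ModulePartition: a module assignment and its modularity
#'
#' Node -> module assignment produced by [detectModules()] (or scored by
#' [networkModularity()]), together with the modularity Q over the
#' reference network and per-module bookkeeping: l_s (within-module edge
#' count), d_s (degree sum), against L total edges.
#'
#' @slot assignment named integer vector: gene -> module index in
#'   0..(Nm - 1); indices ordered by decreasing module size, ties by
#'   lexicographically smallest member.
#' @slot Q modularity of the assignment over the reference network.
#' @slot Nm number of modules.
#' @slot moduleStats data.frame: \code{module}, \code{size},
#'   \code{withinEdges} (l_s), \code{degreeSum} (d_s), \code{density}.
#' @slot L total edge count of the reference network.
#'
#' @exportClass ModulePartition
setClass("ModulePartition",
  representation(assignment = "integer", Q = "numeric", Nm = "integer",
                 moduleStats = "data.frame", L = "integer")
)

setValidity("ModulePartition", function(object) {
  msg <- character()
  if (anyNA(object@assignment)) msg <- c(msg, "NA module index")
  if (length(object@assignment) &&
      !setequal(unique(object@assignment), seq_len(object@Nm) - 1L))
    msg <- c(msg, "module indices must be 0..(Nm-1), all used")
  if (sum(object@moduleStats$withinEdges) > object@L)
    msg <- c(msg, "sum of within-module edges exceeds L")
  if (object@Q < -1 - 1e-9 || object@Q > 1 + 1e-9)
    msg <- c(msg, "Q outside [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' NullSummary: null-model distribution and significance
#'
#' Summary of one null-model run: the per-iteration null statistics, the
#' observed statistic(s), and either empirical p-values (global
#' random-gene-set null) or a scaled-modularity z-score (local rewiring
#' null).
#'
#' @slot kind \code{"GLOBAL_GENE_SET"} or \code{"LOCAL_REWIRE"}.
#' @slot iterations number of null draws.
#' @slot observed named numeric: \code{nodes}/\code{edges} (global) or
#'   \code{Q} (local).
#' @slot nullValues data.frame of per-iteration statistics, first column
#'   \code{iteration}.
#' @slot summaryStats data.frame: \code{statistic}, \code{mean}, \code{sd}
#'   (sample sd, n - 1 denominator).
#' @slot pValues named numeric empirical p-values (global only; a zero
#'   count is shown as "< 1/iterations" but stored as 0).
#' @slot z scaled modularity z-score (local only; \code{NA} when the null
#'   sd is 0).
#' @slot seed master seed of the run.
#'
#' @exportClass NullSummary
setClass("NullSummary",
  representation(kind = "character", iterations = "integer",
                 observed = "numeric", nullValues = "data.frame",
                 summaryStats = "data.frame", pValues = "numeric",
                 z = "numeric", seed = "integer")
)

setValidity("NullSummary", function(object) {
  msg <- character()
  if (!object@kind %in% c("GLOBAL_GENE_SET", "LOCAL_REWIRE"))
    msg <- c(msg, "unknown null-model kind")
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (length(object@pValues) &&
      any(object@pValues < 0 | object@pValues > 1))
    msg <- c(msg, "empirical p outside [0,1]")
  if (any(object@summaryStats$sd < 0, na.rm = TRUE)) msg <- c(msg, "negative sd")
  if (length(msg)) msg else TRUE
})

#' PlantedTruth: ground truth of a synthetic benchmark
#'
#' Records which genes were planted into which module and with what
#' generator parameters, so recovery can be scored against truth.
#'
#' @slot moduleAssignments named integer vector: planted gene -> module.
#' @slot alteredGenes character vector of planted (ground-truth altered)
#'   genes.
#' @slot parameters generator parameter echo.
#'
#' @exportClass PlantedTruth
setClass("PlantedTruth",
  representation(moduleAssignments = "integer", alteredGenes = "character",
                 parameters = "list")
)

setValidity("PlantedTruth", function(object) {
  if (!setequal(names(object@moduleAssignments), object@alteredGenes))
    return("planted module assignments must cover exactly the altered genes")
  TRUE
})

setClassUnion("ModulePartitionOrNULL", c("ModulePartition", "NULL"))
setClassUnion("NullSummaryOrNULL", c("NullSummary", "NULL"))

#' RunResult: everything one pipeline run produced
#'
#' @slot alteredSet the [AlteredGeneSet-class] that passed the recurrence
#'   threshold.
#' @slot extracted the [ExtractedNetwork-class].
#' @slot partition the [ModulePartition-class], or NULL when the extracted
#'   graph was edgeless.
#' @slot globalNull,localNull [NullSummary-class] objects or NULL when the
#'   corresponding null was disabled or skipped.
#' @slot provenance parameter echo, package/R versions and seed; enough to
#'   reproduce the run bit-for-bit.
#'
#' @exportClass RunResult
setClass("RunResult",
  representation(alteredSet = "AlteredGeneSet", extracted = "ExtractedNetwork",
                 partition = "ModulePartitionOrNULL",
                 globalNull = "NullSummaryOrNULL",
                 localNull = "NullSummaryOrNULL",
                 provenance = "list")
)
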