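# Altered-gene subnetwork extraction: connect recurrently altered genes
# through the global network, test candidate linker genes for enrichment
# of altered neighbors with the hypergeometric distribution, BH-correct,
# and keep significant linkers plus their interconnections.

#' Hypergeometric linker p-value
#'
#' Upper-tail probability that a gene of the given global degree connects
#' to at least the observed number of altered genes by chance: draws are
#' the gene's \code{globalDegree} neighbors, taken without replacement
#' from the other \code{hinSize - 1} genes of the global network, of which
#' \code{alteredInHin} are altered (the candidate is excluded from its own
#' population).
#'
#' @param globalDegree degree of the candidate in the global network.
#' @param alteredNeighbors observed number of altered neighbors.
#' @param hinSize number of genes in the global network (isolated nodes
#'   included).
#' @param alteredInHin number of altered genes present in the global
#'   network.
#' @return P(X >= alteredNeighbors); vectorized over its arguments.
#' @examples
#' linkerPvalue(3, 3, 10, 4)  # choose(4,3)/choose(9,3) = 4/84
#' @export
linkerPvalue <- function(globalDegree, alteredNeighbors, hinSize,
                         alteredInHin) {
  n <- length(globalDegree)
  args <- cbind(globalDegree, alteredNeighbors, hinSize, alteredInHin)
  gd <- args[, 1]; k <- args[, 2]; N <- args[, 3]; K <- args[, 4]
  if (any(k < 0 | gd < k | gd > N - 1 | K > N - 1 | K < 0))
    stop("require 0 <= alteredNeighbors <= globalDegree <= hinSize - 1 ",
         "and 0 <= alteredInHin <= hinSize - 1")
  unname(phyper(k - 1, K, (N - 1) - K, gd, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, q_(i) = min over j >= i of p_(j) * m / j
#' clipped to 1, returned in input order.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return adjusted q-values in input order.
#' @export
bhAdjust <- function(pValues) {
  if (length(pValues) == 0L) return(numeric())
  if (anyNA(pValues) || any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pValues, method = "BH")
}

#' Extract the altered-gene subnetwork with enriched linkers
#'
#' Starting from an empty graph, adds every interaction of the global
#' network between altered genes.  With \code{spThreshold = 2}, non-altered
#' neighbors of altered genes become linker candidates; candidates adjacent
#' to exactly one altered gene inter-connect nothing and are immediately
#' pruned.  Each remaining candidate is scored with [linkerPvalue()] (its
#' global degree against its count of distinct altered neighbors), the
#' candidate family is BH-adjusted, and candidates with q-value strictly
#' below \code{fdrCutoff} are retained as LINKER nodes together with their
#' edges to altered genes.  Finally, global-network interactions between
#' retained linkers are added.  Altered genes left without any retained
#' edge are not placed in the graph; they are reported in the
#' \code{unplaced} slot.
#'
#' @param hin the global [InteractionNetwork-class].
#' @param altered an [AlteredGeneSet-class] (or character vector of gene
#'   symbols).
#' @param spThreshold 1 (direct interactions only) or 2 (also length-2
#'   paths through linker genes).
#' @param fdrCutoff BH-adjusted significance cutoff in (0, 1]; default
#'   0.05 (0.001 reproduces the stricter configuration used for smaller
#'   curated gene lists).
#' @return an [ExtractedNetwork-class].
#' @export
extractNetwork <- function(hin, altered, spThreshold = 2L, fdrCutoff = 0.05) {
  stopifnot(is(hin, "InteractionNetwork"))
  if (is(altered, "AlteredGeneSet")) altered <- genes(altered)
  altered <- sort(unique(as.character(altered)))
  spThreshold <- as.integer(spThreshold)
  if (!spThreshold %in% c(1L, 2L)) stop("spThreshold must be 1 or 2")
  if (!(fdrCutoff > 0 && fdrCutoff <= 1)) stop("fdrCutoff must be in (0, 1]")

  g <- hin@graph
  hinGenes <- igraph::V(g)$name
  alteredInHin <- sort(intersect(altered, hinGenes))
  emptyStats <- data.frame(gene = character(), globalDegree = integer(),
                           alteredNeighbors = integer(), pValue = numeric(),
                           qValue = numeric())
  params <- list(spThreshold = spThreshold, fdrCutoff = fdrCutoff)
  if (!length(alteredInHin)) {
    warning("no altered gene is present in the global network")
    return(new("ExtractedNetwork", graph = interactionNetwork(),
               roles = setNames(character(), character()),
               linkerStats = emptyStats, candidateStats = emptyStats,
               alteredGenes = character(), unplaced = character(),
               parameters = params))
  }

  # altered-altered edges
  sub <- igraph::induced_subgraph(g, alteredInHin)
  ee <- if (igraph::gsize(sub)) igraph::as_edgelist(sub, names = TRUE) else
    matrix(character(), ncol = 2L)
  edges <- data.frame(a = ee[, 1], b = ee[, 2],
                      type = rep("ALTERED_ALTERED", nrow(ee)))

  candStats <- emptyStats
  keepStats <- emptyStats
  linkers <- character()
  if (spThreshold == 2L) {
    nbrs <- igraph::adjacent_vertices(g, alteredInHin)
    cand <- sort(setdiff(unique(unlist(lapply(nbrs, function(v) v$name))),
                         altered))
    if (length(cand)) {
      altSet <- alteredInHin
      altCount <- vapply(cand, function(x) {
        sum(igraph::neighbors(g, x)$name %in% altSet)
      }, integer(1))
      cand <- cand[altCount >= 2L]        # degree-1 neighbors pruned outright
      altCount <- altCount[altCount >= 2L]
      if (length(cand)) {
        gd <- as.integer(igraph::degree(g, cand))
        p <- linkerPvalue(gd, as.integer(altCount), length(hinGenes),
                          length(alteredInHin))
        q <- bhAdjust(p)
        candStats <- data.frame(gene = cand, globalDegree = gd,
                                alteredNeighbors = as.integer(altCount),
                                pValue = p, qValue = q)
        candStats <- candStats[order(candStats$qValue, candStats$pValue,
                                     candStats$gene), , drop = FALSE]
        rownames(candStats) <- NULL
        keepStats <- candStats[candStats$qValue < fdrCutoff, , drop = FALSE]
        rownames(keepStats) <- NULL
        linkers <- keepStats$gene
      }
    }
    if (length(linkers)) {
      # linker-altered edges
      for (lk in linkers) {
        nb <- intersect(igraph::neighbors(g, lk)$name, alteredInHin)
        if (length(nb))
          edges <- rbind(edges, data.frame(a = lk, b = nb,
                                           type = "LINKER_ALTERED"))
      }
      # linker-linker edges from the global network
      lsub <- igraph::induced_subgraph(g, linkers)
      if (igraph::gsize(lsub)) {
        le <- igraph::as_edgelist(lsub, names = TRUE)
        edges <- rbind(edges, data.frame(a = le[, 1], b = le[, 2],
                                         type = "LINKER_LINKER"))
      }
    }
  }

  net <- .buildGraph(edges)
  placed <- genes(net)
  unplaced <- setdiff(alteredInHin, placed)
  role <- rep("ALTERED", length(placed))
  role[placed %in% linkers] <- "LINKER"
  roles <- setNames(role, placed)
  new("ExtractedNetwork", graph = net, roles = roles,
      linkerStats = keepStats, candidateStats = candStats,
      alteredGenes = alteredInHin, unplaced = unplaced, parameters = params)
}

#' @describeIn genes Sorted node symbols of an extracted network.
#' @export
setMethod("genes", "ExtractedNetwork", function(x) genes(x@graph))

#' @describeIn numNodes Node count of an extracted network.
#' @export
setMethod("numNodes", "ExtractedNetwork", function(x) numNodes(x@graph))

#' @describeIn numNodes Edge count of an extracted network.
#' @export
setMethod("numEdges", "ExtractedNetwork", function(x) numEdges(x@graph))

#' @describeIn asIgraph The igraph object backing an extracted network.
#' @export
setMethod("asIgraph", "ExtractedNetwork", function(x) x@graph@graph)

#' @describeIn roles Node roles of an extracted network.
#' @export
setMethod("roles", "ExtractedNetwork", function(x) x@roles)

#' @describeIn linkerStats Retained (or, with \code{all = TRUE}, every
#'   tested) linker candidate of an extracted network.
#' @export
setMethod("linkerStats", "ExtractedNetwork", function(x, all = FALSE) {
  if (all) x@candidateStats else x@linkerStats
})

setMethod("show", "ExtractedNetwork", function(object) {
  nAlt <- sum(object@roles == "ALTERED")
  nLin <- sum(object@roles == "LINKER")
  cat("ExtractedNetwork:", nAlt, "altered genes and", nLin,
      "linker genes connected by", numEdges(object), "interactions\n")
  cat("  (", length(object@alteredGenes), "altered genes in the global",
      "network;", length(object@unplaced), "unplaced )\n")
  cat("  spThreshold =", object@parameters$spThreshold,
      ", fdrCutoff =", object@parameters$fdrCutoff, "\n")
})
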