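#' Gene symbols of an object
#'
#' @param x an object holding genes (a network, an altered gene set, ...).
#' @return character vector of gene symbols, sorted for networks and gene
#'   sets.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Number of nodes / edges
#'
#' @param x a network-bearing object.
#' @return a single integer.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname numNodes
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Underlying igraph object
#'
#' @param x a network-bearing object.
#' @return the \code{igraph} graph backing \code{x}.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Node roles of an extracted network
#'
#' @param x an [ExtractedNetwork-class].
#' @return named character vector, gene -> \code{ALTERED} / \code{LINKER}.
#' @export
setGeneric("roles", function(x) standardGeneric("roles"))

#' Linker statistics of an extracted network
#'
#' @param x an [ExtractedNetwork-class].
#' @param all logical; return all tested candidates instead of the
#'   retained linkers only.
#' @return data.frame of per-linker hypergeometric statistics.
#' @export
setGeneric("linkerStats", function(x, all = FALSE) standardGeneric("linkerStats"))

#' Module assignment of a partition
#'
#' @param x a [ModulePartition-class] (or an object carrying one).
#' @return named integer vector gene -> module index (0-based).
#' @export
setGeneric("moduleAssignments", function(x) standardGeneric("moduleAssignments"))

#' Modularity score Q
#'
#' @param x a [ModulePartition-class] (or an object carrying one).
#' @return numeric Q.
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))

#' Number of retained cases
#'
#' @param x an [AlteredGeneSet-class] or [AlterationMatrix-class].
#' @return integer case count.
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))
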