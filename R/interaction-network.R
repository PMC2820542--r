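# Data model and I/O for the global interaction network and all derived
# graphs. The simple-graph contract (no self or parallel edges) is enforced
# at construction: redundant edge records are collapsed into single edges
# with accumulated annotations, self-directed records are dropped.

# Build the canonical igraph from an edge table. edges: data.frame with
# columns a, b, type (type may be NA); nodes: extra isolated nodes.
.buildGraph <- function(edges, nodes = character()) {
  stopifnot(is.data.frame(edges))
  dup <- 0L; selfd <- 0L
  if (nrow(edges)) {
    a <- as.character(edges$a); b <- as.character(edges$b)
    type <- if ("type" %in% names(edges)) as.character(edges$type)
            else rep(NA_character_, nrow(edges))
    self <- a == b
    selfd <- sum(self)
    a <- a[!self]; b <- b[!self]; type <- type[!self]
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\t")
    dup <- length(key) - length(unique(key))
    ord <- order(lo, hi)
    keyu <- unique(key[ord])
    ann <- lapply(split(type, factor(key, levels = keyu)), function(tt) {
      tt <- sort(unique(tt[!is.na(tt)]))
      if (length(tt)) tt else character()
    })
    pairs <- do.call(rbind, strsplit(keyu, "\t", fixed = TRUE))
    allNodes <- sort(unique(c(pairs[, 1], pairs[, 2], nodes,
                              as.character(edges$a[self]))))
    g <- igraph::make_empty_graph(n = length(allNodes), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = allNodes)
    g <- igraph::add_edges(g, rbind(pairs[, 1], pairs[, 2]))
    g <- igraph::set_edge_attr(g, "types", value = unname(ann))
  } else {
    allNodes <- sort(unique(as.character(nodes)))
    g <- igraph::make_empty_graph(n = length(allNodes), directed = FALSE)
    if (length(allNodes)) g <- igraph::set_vertex_attr(g, "name", value = allNodes)
  }
  new("InteractionNetwork", graph = g,
      stats = list(duplicatesCollapsed = as.integer(dup),
                   selfEdgesDropped = as.integer(selfd)))
}

#' Construct an interaction network from an edge table
#'
#' Collapses redundant edge records into single annotated edges and drops
#' self-edges, enforcing the simple-graph contract.
#'
#' @param edges data.frame with columns \code{a}, \code{b} and optionally
#'   \code{type} (interaction-type annotation); one row per edge record.
#' @param nodes additional isolated gene symbols to include.
#' @return an [InteractionNetwork-class].
#' @examples
#' net <- interactionNetwork(data.frame(a = c("A", "B"), b = c("B", "A"),
#'                                      type = c("pp", "state_change")))
#' numEdges(net)  # 1: the two records collapse to one annotated edge
#' @export
interactionNetwork <- function(edges = data.frame(a = character(),
                                                  b = character(),
                                                  type = character()),
                               nodes = character()) {
  .buildGraph(edges, nodes)
}

#' Load an interaction network from a SIF-style edge list
#'
#' Reads a tab-delimited edge list: 3-column SIF
#' (\code{geneA<TAB>type<TAB>geneB}) or a plain 2-column pair list.  Lines
#' starting with \code{#} and blank lines are skipped.  Duplicate records
#' for the same unordered pair are collapsed into one edge whose
#' annotations accumulate; self-directed records are pruned.  The counts of
#' collapsed duplicates and dropped self-edges are kept in the object's
#' \code{stats} and reported by \code{show()}.
#'
#' @param path path to the edge-list file.
#' @param dialect \code{"sif3"} (gene, type, gene) or \code{"edge2"}
#'   (gene, gene).
#' @return an [InteractionNetwork-class].  An empty file yields an empty
#'   network.
#' @export
loadNetwork <- function(path, dialect = c("sif3", "edge2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  want <- if (dialect == "sif3") 3L else 2L
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != want))
    stop("malformed line ", idx[which(nf != want)[1L]], ": expected ", want,
         " tab-delimited columns, found ", nf[which(nf != want)[1L]])
  if (!length(fields)) return(interactionNetwork())
  m <- do.call(rbind, fields)
  edges <- if (dialect == "sif3")
    data.frame(a = m[, 1], b = m[, 3], type = m[, 2]) else
    data.frame(a = m[, 1], b = m[, 2], type = NA_character_)
  .buildGraph(edges)
}

#' Degree of a gene in a network
#'
#' Number of distinct neighbors after edge collapsing.
#'
#' @param net an [InteractionNetwork-class].
#' @param gene gene symbol(s); must be nodes of \code{net}.
#' @return integer vector of degrees, named by gene.
#' @export
geneDegree <- function(net, gene) {
  stopifnot(is(net, "InteractionNetwork"))
  miss <- setdiff(gene, genes(net))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  d <- igraph::degree(net@graph, v = gene)
  setNames(as.integer(d), gene)
}

#' Largest connected component
#'
#' Connected component maximizing node count; ties broken by larger edge
#' count, then by lexicographically smallest member set.
#'
#' @param net an [InteractionNetwork-class].
#' @return list with \code{nodeCount}, \code{edgeCount} and sorted
#'   \code{members}; \code{(0, 0, character(0))} for an empty network.
#' @export
largestComponent <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  g <- net@graph
  if (igraph::gorder(g) == 0L)
    return(list(nodeCount = 0L, edgeCount = 0L, members = character()))
  comp <- igraph::components(g)
  memb <- comp$membership
  stats <- lapply(seq_len(comp$no), function(i) {
    mem <- sort(names(memb)[memb == i])
    sub <- igraph::induced_subgraph(g, mem)
    list(n = length(mem), e = igraph::gsize(sub), members = mem)
  })
  best <- stats[[1L]]
  for (s in stats[-1L]) {
    if (s$n > best$n || (s$n == best$n && s$e > best$e) ||
        (s$n == best$n && s$e == best$e &&
         paste(s$members, collapse = "\r") < paste(best$members, collapse = "\r")))
      best <- s
  }
  list(nodeCount = as.integer(best$n), edgeCount = as.integer(best$e),
       members = best$members)
}

# Sorted edge table of a network: data.frame(a, b, types-list), a < b.
.edgeTable <- function(net) {
  g <- net@graph
  if (igraph::gsize(g) == 0L)
    return(data.frame(a = character(), b = character()))
  e <- igraph::as_edgelist(g, names = TRUE)
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  types <- igraph::edge_attr(g, "types")
  if (is.null(types)) types <- rep(list(character()), length(a))
  ord <- order(a, b)
  out <- data.frame(a = a[ord], b = b[ord])
  out$types <- types[ord]
  out
}

#' Write a network as SIF
#'
#' One line per edge, \code{geneA<TAB>type<TAB>geneB}; edges with several
#' annotations emit one line per annotation, edges with none use
#' \code{fallbackType}.  Output is sorted so identical networks serialize
#' identically.
#'
#' @param net an [InteractionNetwork-class].
#' @param path output file path.
#' @param fallbackType interaction type written for unannotated edges.
#' @return \code{path}, invisibly.
#' @export
writeSIF <- function(net, path, fallbackType = "pp") {
  et <- .edgeTable(net)
  lines <- character()
  if (nrow(et)) {
    lines <- unlist(lapply(seq_len(nrow(et)), function(i) {
      tt <- et$types[[i]]
      if (!length(tt)) tt <- fallbackType
      paste(et$a[i], tt, et$b[i], sep = "\t")
    }))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a Cytoscape edge-attribute file
#'
#' Classic Cytoscape \code{.eda} format: a header naming the attribute,
#' then one \code{"A (type) B = value"} line per edge, listing the
#' accumulated interaction-type annotations.
#'
#' @param net an [InteractionNetwork-class].
#' @param path output file path.
#' @param name attribute name written on the first line.
#' @return \code{path}, invisibly.
#' @export
writeEdgeAttributes <- function(net, path, name = "annotations") {
  et <- .edgeTable(net)
  lines <- name
  if (nrow(et)) {
    lines <- c(lines, vapply(seq_len(nrow(et)), function(i) {
      tt <- et$types[[i]]
      tag <- if (length(tt)) tt[1L] else "pp"
      val <- if (length(tt)) paste(tt, collapse = ";") else "pp"
      paste0(et$a[i], " (", tag, ") ", et$b[i], " = ", val)
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a Cytoscape node-attribute file
#'
#' Classic \code{.noa} format: the attribute name, then one
#' \code{"GENE = value"} line per node, sorted by gene.
#'
#' @param values named vector (gene -> value).
#' @param path output file path.
#' @param name attribute name.
#' @return \code{path}, invisibly.
#' @export
writeNodeAttributes <- function(values, path, name) {
  nm <- sort(names(values))
  writeLines(c(name, paste(nm, "=", unname(values[nm]))), path)
  invisible(path)
}

#' @describeIn genes Sorted node symbols of an interaction network.
#' @export
setMethod("genes", "InteractionNetwork",
          function(x) sort(igraph::V(x@graph)$name))

#' @describeIn numNodes Node count of an interaction network.
#' @export
setMethod("numNodes", "InteractionNetwork",
          function(x) igraph::gorder(x@graph))

#' @describeIn numNodes Edge count of an interaction network.
#' @export
setMethod("numEdges", "InteractionNetwork",
          function(x) igraph::gsize(x@graph))

#' @describeIn asIgraph The igraph object backing an interaction network.
#' @export
setMethod("asIgraph", "InteractionNetwork", function(x) x@graph)

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork with", numNodes(object), "genes and",
      numEdges(object), "interactions\n")
  st <- object@stats
  if (isTRUE(st$duplicatesCollapsed > 0) || isTRUE(st$selfEdgesDropped > 0))
    cat("  collapsed", st$duplicatesCollapsed, "redundant record(s), dropped",
        st$selfEdgesDropped, "self-edge(s)\n")
})
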