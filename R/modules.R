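# Module detection by iterative removal of the highest-betweenness edge
# (Girvan-Newman), scoring the component partition after every removal
# with Newman modularity against the original network and keeping the
# partition with maximal Q.

# Q and per-module l_s / d_s for a membership vector over a fixed
# reference: ei/ej are integer endpoint indices of the reference edges,
# deg the reference degree vector, L the reference edge count.
.modularityParts <- function(membership, ei, ej, deg, L) {
  mods <- sort(unique(membership))
  midx <- match(membership, mods)
  nb <- length(mods)
  same <- midx[ei] == midx[ej]
  ls <- tabulate(midx[ei][same], nbins = nb)
  ds <- as.vector(rowsum(deg, midx, reorder = TRUE))
  list(Q = sum(ls / L - (ds / (2 * L))^2), ls = ls, ds = ds, modules = mods)
}

#' Newman modularity of a partition
#'
#' Q = sum over modules s of [ l_s / L - (d_s / 2L)^2 ], where l_s is the
#' number of edges within module s, d_s the sum of degrees of its nodes,
#' and L the total number of edges -- all measured on the reference
#' network.  Near 0 when within-module edges are no better than random;
#' toward 1 for strong modular structure.
#'
#' @param reference the [InteractionNetwork-class] whose edges and degrees
#'   define L, l_s and d_s.
#' @param assignment named vector (gene -> module label) covering every
#'   node of \code{reference}; labels may be arbitrary.
#' @return numeric Q.
#' @export
networkModularity <- function(reference, assignment) {
  stopifnot(is(reference, "InteractionNetwork"))
  g <- reference@graph
  L <- igraph::gsize(g)
  if (L == 0L) stop("modularity is undefined on an edgeless network")
  nodes <- igraph::V(g)$name
  miss <- setdiff(nodes, names(assignment))
  if (length(miss))
    stop("assignment must cover all nodes; missing: ",
         paste(head(miss, 5L), collapse = ", "))
  memb <- as.character(assignment[nodes])
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- as.numeric(igraph::degree(g))
  .modularityParts(memb, el[, 1], el[, 2], deg, L)$Q
}

# lexicographic key of an edge endpoint pair
.edgeKeys <- function(g, eids = igraph::E(g)) {
  e <- igraph::ends(g, eids, names = TRUE)
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "\t")
}

#' Girvan-Newman module detection with modularity-optimal stopping
#'
#' Sequentially removes the edge of maximal shortest-path betweenness
#' (recomputed after every removal; ties broken by the lexicographically
#' smallest endpoint pair), scores the connected components of the pruned
#' graph against the ORIGINAL network with [networkModularity()] after
#' each removal, and returns the partition of maximal Q over the whole
#' removal sequence (the unpruned component partition included).  Equal
#' maxima resolve to the fewest removals, preferring coarser partitions.
#' Module indices are assigned by decreasing module size, ties by
#' lexicographically smallest member.
#'
#' @param net an [InteractionNetwork-class] with at least one edge.
#' @return a [ModulePartition-class].
#' @export
detectModules <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  g0 <- net@graph
  L <- igraph::gsize(g0)
  if (L == 0L) stop("module detection requires at least one edge")
  nodes <- igraph::V(g0)$name
  el <- igraph::as_edgelist(g0, names = FALSE)
  ei <- el[, 1]; ej <- el[, 2]
  deg <- as.numeric(igraph::degree(g0))

  g <- g0
  best <- NULL
  score <- function(gCur) {
    memb <- igraph::components(gCur)$membership[nodes]
    list(memb = memb,
         Q = .modularityParts(as.character(memb), ei, ej, deg, L)$Q)
  }
  cur <- score(g)
  best <- cur
  for (step in seq_len(L)) {
    eb <- igraph::edge_betweenness(g, directed = FALSE)
    mx <- max(eb)
    tied <- which(eb >= mx - 1e-9 * max(1, mx))
    keys <- .edgeKeys(g, igraph::E(g)[tied])
    drop <- tied[order(keys)[1L]]
    g <- igraph::delete_edges(g, drop)
    cur <- score(g)
    if (cur$Q > best$Q + 1e-12) best <- cur   # strict: earliest max wins
  }

  memb <- as.character(best$memb)
  # renumber: decreasing size, ties by lexicographically smallest member
  sizes <- table(memb)
  firstMember <- vapply(names(sizes),
                        function(m) min(nodes[memb == m]), character(1))
  ord <- names(sizes)[order(-as.integer(sizes), firstMember)]
  newIdx <- setNames(seq_along(ord) - 1L, ord)
  assignment <- setNames(as.integer(newIdx[memb]), nodes)
  assignment <- assignment[order(names(assignment))]

  parts <- .modularityParts(as.character(assignment[nodes]), ei, ej, deg, L)
  modOrd <- order(as.integer(parts$modules))
  sizeByMod <- as.integer(table(factor(assignment,
                                       levels = sort(unique(assignment)))))
  stats <- data.frame(
    module = as.integer(parts$modules[modOrd]),
    size = sizeByMod,
    withinEdges = as.integer(parts$ls[modOrd]),
    degreeSum = as.integer(parts$ds[modOrd]))
  stats$density <- ifelse(stats$size > 1,
                          stats$withinEdges / choose(stats$size, 2), NA_real_)
  new("ModulePartition", assignment = assignment, Q = parts$Q,
      Nm = as.integer(nrow(stats)), moduleStats = stats, L = as.integer(L))
}

#' Write module assignments and a per-module summary
#'
#' Emits a Cytoscape node-attribute file (gene -> module index) and a
#' tab-delimited per-module summary (size, within-module edges l_s, degree
#' sum d_s, within-module density).
#'
#' @param partition a [ModulePartition-class].
#' @param attrPath node-attribute output path.
#' @param summaryPath module-summary output path.
#' @return invisibly, the two paths.
#' @export
writeModules <- function(partition, attrPath, summaryPath) {
  stopifnot(is(partition, "ModulePartition"))
  writeNodeAttributes(partition@assignment, attrPath, "Module")
  write.table(partition@moduleStats, summaryPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(attrPath, summaryPath))
}

#' @describeIn moduleAssignments Assignment of a module partition.
#' @export
setMethod("moduleAssignments", "ModulePartition", function(x) x@assignment)

#' @describeIn modularityQ Modularity of a module partition.
#' @export
setMethod("modularityQ", "ModulePartition", function(x) x@Q)

setMethod("show", "ModulePartition", function(object) {
  cat("ModulePartition:", object@Nm, "modules over",
      length(object@assignment), "genes; Q =",
      format(object@Q, digits = 4), "\n")
  cat("  module sizes:",
      paste(object@moduleStats$size, collapse = ", "), "\n")
})
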