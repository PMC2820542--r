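# Statistical assessment of the extracted network: a global null that
# resamples random gene sets of the same size and re-runs extraction, and
# a local null that rewires the network degree-preservingly and re-runs
# module detection. Per-iteration seeds are derived from the master seed
# by a counter scheme, so results do not depend on execution order.

# counter-based sub-seed: a fixed LCG mix of (master, counter), < 2^31
.deriveSeed <- function(master, counter) {
  m <- 2147483647
  x <- (as.double(master) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + as.double(counter) * 69621 + 12345) %% m
  x <- (x * 16807) %% m
  as.integer(x)
}

#' Degree-preserving random rewiring
#'
#' Randomizes interaction partners while every gene keeps its exact
#' degree, by repeated double-edge swaps: two distinct edges (a,b), (c,d)
#' are replaced by (a,d), (c,b); swaps that would create a self-edge or a
#' parallel edge are rejected and retried.  Runs until
#' \code{swapMultiplier * numEdges(net)} successful swaps (the usual
#' mixing heuristic), or a bounded number of rejected attempts on graphs
#' where no valid swap exists (e.g. a star), in which case an identical
#' copy is returned with a warning.
#'
#' @param net an [InteractionNetwork-class] with at least 2 edges.
#' @param swapMultiplier successful swaps per edge (default 10).
#' @param seed optional integer seed for reproducibility.
#' @return a rewired [InteractionNetwork-class] with identical node set,
#'   edge count and degree sequence.
#' @export
rewireNetwork <- function(net, swapMultiplier = 10L, seed = NULL) {
  stopifnot(is(net, "InteractionNetwork"))
  nE <- numEdges(net)
  if (nE < 2L) stop("rewiring requires at least 2 edges")
  if (!is.null(seed)) set.seed(seed)
  el <- igraph::as_edgelist(net@graph, names = TRUE)
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  keys <- new.env(parent = emptyenv(), size = 2L * nE)
  kfun <- function(x, y) paste(min(x, y), max(x, y), sep = "\t")
  for (i in seq_len(nE)) assign(kfun(a[i], b[i]), TRUE, envir = keys)
  target <- as.integer(swapMultiplier) * nE
  maxAttempts <- 200L * target + 1000L
  done <- 0L; attempts <- 0L
  while (done < target && attempts < maxAttempts) {
    attempts <- attempts + 1L
    ij <- sample.int(nE, 2L)
    i <- ij[1L]; j <- ij[2L]
    x1 <- a[i]; y1 <- b[i]; x2 <- a[j]; y2 <- b[j]
    if (runif(1L) < 0.5) { tmp <- x2; x2 <- y2; y2 <- tmp }
    # proposed: (x1, y2) and (x2, y1)
    if (x1 == y2 || x2 == y1) next
    k1 <- kfun(x1, y2); k2 <- kfun(x2, y1)
    if (k1 == k2) next
    if (exists(k1, envir = keys, inherits = FALSE) ||
        exists(k2, envir = keys, inherits = FALSE)) next
    rm(list = c(kfun(x1, y1), kfun(x2, y2)), envir = keys)
    assign(k1, TRUE, envir = keys); assign(k2, TRUE, envir = keys)
    a[i] <- min(x1, y2); b[i] <- max(x1, y2)
    a[j] <- min(x2, y1); b[j] <- max(x2, y1)
    done <- done + 1L
  }
  if (done < target)
    warning("rewiring stopped after ", done, " of ", target,
            " successful swaps (no further valid swap found)")
  .buildGraph(data.frame(a = a, b = b, type = "rewired"),
              nodes = genes(net))
}

.sampleSd <- function(x) if (length(x) > 1L) sd(x) else NA_real_

#' Global random-gene-set null model
#'
#' At each iteration, samples as many genes from the global network as
#' there are altered genes, connects them with the same shortest-path
#' threshold and FDR cutoff via [extractNetwork()], and records the size
#' (nodes and edges) of the largest component.  Empirical p-values count
#' the iterations whose largest component equaled or exceeded the
#' observed one.
#'
#' @param hin the global [InteractionNetwork-class].
#' @param observed the observed [ExtractedNetwork-class]; supplies the
#'   number of genes to resample, the extraction parameters and the
#'   observed largest component.
#' @param iterations number of random draws (default 1000).
#' @param seed master seed.
#' @return a [NullSummary-class] of kind \code{GLOBAL_GENE_SET} with
#'   \code{pValues["nodes"]} and \code{pValues["edges"]}.
#' @export
globalNull <- function(hin, observed, iterations = 1000L, seed = 1L) {
  stopifnot(is(hin, "InteractionNetwork"), is(observed, "ExtractedNetwork"))
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  nGenes <- length(observed@alteredGenes)
  pool <- genes(hin)
  if (nGenes > length(pool))
    stop("cannot sample ", nGenes, " genes from a network of ", length(pool))
  sp <- observed@parameters$spThreshold
  fdr <- observed@parameters$fdrCutoff
  obs <- largestComponent(observed@graph)
  nodes <- integer(iterations); edges <- integer(iterations)
  for (it in seq_len(iterations)) {
    set.seed(.deriveSeed(seed, it))
    draw <- sample(pool, nGenes)
    ex <- suppressWarnings(
      extractNetwork(hin, draw, spThreshold = sp, fdrCutoff = fdr))
    lc <- largestComponent(ex@graph)
    nodes[it] <- lc$nodeCount; edges[it] <- lc$edgeCount
  }
  nullValues <- data.frame(iteration = seq_len(iterations),
                           nodes = nodes, edges = edges)
  new("NullSummary", kind = "GLOBAL_GENE_SET", iterations = iterations,
      observed = c(nodes = obs$nodeCount, edges = obs$edgeCount),
      nullValues = nullValues,
      summaryStats = data.frame(
        statistic = c("nodes", "edges"),
        mean = c(mean(nodes), mean(edges)),
        sd = c(.sampleSd(nodes), .sampleSd(edges))),
      pValues = c(nodes = sum(nodes >= obs$nodeCount) / iterations,
                  edges = sum(edges >= obs$edgeCount) / iterations),
      z = NA_real_, seed = as.integer(seed))
}

#' Scaled modularity score
#'
#' z-score of an observed modularity against a null mean and standard
#' deviation: (Q_obs - mean) / sd.
#'
#' @param observedQ observed modularity.
#' @param nullMean,nullSd mean and (sample) standard deviation of the null
#'   modularity distribution.
#' @return numeric z; \code{NA} with a warning when \code{nullSd} is 0.
#' @examples
#' scaledModularity(0.519, 0.296, 0.058)  # ~3.84
#' @export
scaledModularity <- function(observedQ, nullMean, nullSd) {
  if (is.na(nullSd) || nullSd <= 0) {
    warning("null standard deviation is 0; scaled modularity undefined")
    return(NA_real_)
  }
  (observedQ - nullMean) / nullSd
}

#' Local degree-preserving rewiring null model
#'
#' At each iteration, rewires the network with [rewireNetwork()] (same
#' node set, same per-gene degree, random partners) and re-runs full
#' module detection to obtain that iteration's maximal modularity.  The
#' observed Q is converted to a scaled modularity score
#' z = (Q_obs - mean) / sd over the null draws.
#'
#' @param net the observed [InteractionNetwork-class] (e.g. the extracted
#'   subnetwork graph).
#' @param iterations number of rewired replicates (default 1000, >= 2).
#' @param swapMultiplier successful swaps per edge per replicate.
#' @param seed master seed.
#' @param observedQ optional pre-computed observed modularity; computed
#'   with [detectModules()] when missing.
#' @return a [NullSummary-class] of kind \code{LOCAL_REWIRE}.
#' @export
localNull <- function(net, iterations = 1000L, swapMultiplier = 10L,
                      seed = 1L, observedQ = NULL) {
  stopifnot(is(net, "InteractionNetwork"))
  iterations <- as.integer(iterations)
  if (iterations < 2L) stop("local null requires >= 2 iterations")
  if (is.null(observedQ)) observedQ <- detectModules(net)@Q
  qs <- numeric(iterations)
  for (it in seq_len(iterations)) {
    rg <- suppressWarnings(
      rewireNetwork(net, swapMultiplier, seed = .deriveSeed(seed, it)))
    qs[it] <- detectModules(rg)@Q
  }
  mu <- mean(qs); sdev <- .sampleSd(qs)
  z <- if (!is.na(sdev) && sdev > 0) (observedQ - mu) / sdev else NA_real_
  if (is.na(z))
    warning("degenerate null (sd = 0): scaled modularity undefined")
  new("NullSummary", kind = "LOCAL_REWIRE", iterations = iterations,
      observed = c(Q = observedQ),
      nullValues = data.frame(iteration = seq_len(iterations), Q = qs),
      summaryStats = data.frame(statistic = "Q", mean = mu, sd = sdev),
      pValues = setNames(numeric(), character()),
      z = z, seed = as.integer(seed))
}

#' Write the per-iteration null distribution
#'
#' Tab-delimited (iteration, statistic ...) table.
#'
#' @param x a [NullSummary-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeNullDistribution <- function(x, path) {
  stopifnot(is(x, "NullSummary"))
  write.table(x@nullValues, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

.formatP <- function(p, iterations) {
  if (p == 0) paste0("< ", format(1 / iterations)) else format(p)
}

setMethod("show", "NullSummary", function(object) {
  cat("NullSummary (", object@kind, "), ", object@iterations,
      " iterations, seed ", object@seed, "\n", sep = "")
  if (object@kind == "GLOBAL_GENE_SET") {
    cat("  observed largest component:", object@observed[["nodes"]],
        "nodes /", object@observed[["edges"]], "edges\n")
    cat("  p(nodes) =", .formatP(object@pValues[["nodes"]], object@iterations),
        "; p(edges) =", .formatP(object@pValues[["edges"]], object@iterations),
        "\n")
  } else {
    s <- object@summaryStats
    cat("  observed Q =", format(object@observed[["Q"]], digits = 4),
        "; null mean =", format(s$mean, digits = 4),
        ", sd =", format(s$sd, digits = 4), "\n")
    cat("  scaled modularity z =",
        if (is.na(object@z)) "undefined (sd = 0)"
        else format(object@z, digits = 4), "\n")
  }
})
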