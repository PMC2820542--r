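# End-to-end orchestration: alteration calls -> network extraction ->
# module detection -> null models, plus Cytoscape-compatible output
# writers. All serialized collections are explicitly sorted so a fixed
# seed reproduces outputs byte-for-byte.

#' Read a pipeline configuration file
#'
#' YAML file whose keys mirror the arguments of [runPipeline()]
#' (\code{networkFile}, \code{alterationFile}, \code{hypermutatorFile},
#' \code{minCases}, \code{spThreshold}, \code{linkerFdr},
#' \code{globalIterations}, \code{localIterations}, \code{swapMultiplier},
#' \code{seed}, \code{runGlobalNull}, \code{runLocalNull},
#' \code{outputDir}).
#'
#' @param path path to the YAML configuration.
#' @return named list of arguments for [runPipeline()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(runPipeline))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg
}

#' Run the full network-analysis pipeline
#'
#' Loads (or accepts) a global interaction network and per-case alteration
#' calls, applies the recurrence threshold, extracts the altered-gene
#' subnetwork with enriched linkers, partitions it into modules, and
#' assesses significance with the global random-gene-set and local
#' rewiring nulls.  Stages after extraction are skipped with a warning
#' when the extracted graph is edgeless.
#'
#' @param networkFile SIF file for the global network, or an
#'   [InteractionNetwork-class] via \code{network}.
#' @param alterationFile alteration-call TSV, or an
#'   [AlterationMatrix-class] via \code{alterations}.
#' @param hypermutatorFile optional flagged-case list file.
#' @param network,alterations pre-built objects overriding the file
#'   arguments.
#' @param minCases recurrence threshold (default 2).
#' @param excludeHypermutators drop flagged cases (default TRUE).
#' @param spThreshold shortest-path threshold, 1 or 2 (default 2).
#' @param linkerFdr BH cutoff for linker retention (default 0.05).
#' @param globalIterations,localIterations null-model iteration counts
#'   (default 1000 each).
#' @param swapMultiplier successful swaps per edge in the local null.
#' @param seed master seed for both nulls.
#' @param runGlobalNull,runLocalNull toggles for the two null models.
#' @param outputDir when non-NULL, outputs are written there via
#'   [writeOutputs()].
#' @return a [RunResult-class].
#' @export
runPipeline <- function(networkFile = NULL, alterationFile = NULL,
                        hypermutatorFile = NULL, network = NULL,
                        alterations = NULL, minCases = 2L,
                        excludeHypermutators = TRUE, spThreshold = 2L,
                        linkerFdr = 0.05, globalIterations = 1000L,
                        localIterations = 1000L, swapMultiplier = 10L,
                        seed = 1L, runGlobalNull = TRUE,
                        runLocalNull = TRUE, outputDir = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("[", what, "] ", conditionMessage(e), call. = FALSE))
  }
  hin <- stage("network", {
    if (!is.null(network)) network else loadNetwork(networkFile)
  })
  am <- stage("alterations", {
    if (!is.null(alterations)) alterations
    else loadAlterations(alterationFile, hypermutatorFile)
  })
  message("== alteration calls: ", length(am@cases), " cases, ",
          length(am@hypermutators), " hypermutator-flagged")
  altered <- stage("altered-gene-set",
                   alteredGeneSet(am, minCases = minCases,
                                  excludeHypermutators = excludeHypermutators))
  message("== recurrence threshold: ", length(genes(altered)),
          " genes altered in >= ", altered@minCases, " of ",
          nCases(altered), " cases")
  extracted <- stage("extraction",
                     extractNetwork(hin, altered, spThreshold = spThreshold,
                                    fdrCutoff = linkerFdr))
  message("== extracted network: ", sum(extracted@roles == "ALTERED"),
          " altered + ", sum(extracted@roles == "LINKER"),
          " linker genes, ", numEdges(extracted), " interactions")

  partition <- NULL; gnull <- NULL; lnull <- NULL
  if (numEdges(extracted) == 0L) {
    warning("extracted network has no edges; ",
            "module detection and null models skipped")
  } else {
    partition <- stage("module-detection", detectModules(extracted@graph))
    message("== modules: ", partition@Nm, ", Q = ",
            format(partition@Q, digits = 4))
    if (runGlobalNull) {
      gnull <- stage("global-null",
                     globalNull(hin, extracted, iterations = globalIterations,
                                seed = seed))
      message("== global null: p(nodes) = ",
              .formatP(gnull@pValues[["nodes"]], gnull@iterations),
              ", p(edges) = ",
              .formatP(gnull@pValues[["edges"]], gnull@iterations))
    }
    if (runLocalNull) {
      lnull <- stage("local-null",
                     localNull(extracted@graph, iterations = localIterations,
                               swapMultiplier = swapMultiplier, seed = seed,
                               observedQ = partition@Q))
      message("== local null: scaled modularity z = ",
              format(lnull@z, digits = 4))
    }
  }
  provenance <- list(
    package = "AlteredNet",
    version = as.character(packageVersion("AlteredNet")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    parameters = list(minCases = as.integer(minCases),
                      excludeHypermutators = excludeHypermutators,
                      spThreshold = as.integer(spThreshold),
                      linkerFdr = linkerFdr,
                      globalIterations = as.integer(globalIterations),
                      localIterations = as.integer(localIterations),
                      swapMultiplier = as.integer(swapMultiplier),
                      seed = as.integer(seed),
                      runGlobalNull = runGlobalNull,
                      runLocalNull = runLocalNull))
  res <- new("RunResult", alteredSet = altered, extracted = extracted,
             partition = partition, globalNull = gnull, localNull = lnull,
             provenance = provenance)
  if (!is.null(outputDir)) writeOutputs(res, outputDir)
  res
}

.reportLines <- function(result) {
  p <- result@provenance
  alt <- result@alteredSet
  ex <- result@extracted
  lines <- c(
    "Altered-gene subnetwork analysis report",
    "=======================================",
    "",
    paste0("package: ", p$package, " ", p$version, " (R ", p$rVersion, ")"),
    paste0("parameters: ",
           paste(names(p$parameters), unlist(lapply(p$parameters, format)),
                 sep = "=", collapse = ", ")),
    "",
    paste0("cases retained: ", alt@nCases),
    paste0("genes passing recurrence threshold (>=", alt@minCases,
           " cases): ", length(genes(alt))),
    paste0("altered genes present in the global network: ",
           length(ex@alteredGenes)),
    paste0("network: ", sum(ex@roles == "ALTERED"), " altered + ",
           sum(ex@roles == "LINKER"), " linker genes, ",
           numEdges(ex), " interactions"),
    paste0("unplaced altered genes: ", length(ex@unplaced)))
  lc <- largestComponent(ex@graph)
  lines <- c(lines, paste0("largest component: ", lc$nodeCount, " nodes / ",
                           lc$edgeCount, " edges"))
  if (!is.null(result@partition)) {
    pa <- result@partition
    lines <- c(lines, paste0("modules: ", pa@Nm, "; modularity Q = ",
                             format(pa@Q, digits = 6)))
  }
  if (!is.null(result@globalNull)) {
    gn <- result@globalNull
    lines <- c(lines,
      paste0("global null (", gn@iterations, " iterations): p(nodes) = ",
             .formatP(gn@pValues[["nodes"]], gn@iterations), ", p(edges) = ",
             .formatP(gn@pValues[["edges"]], gn@iterations)))
  }
  if (!is.null(result@localNull)) {
    ln <- result@localNull
    s <- ln@summaryStats
    lines <- c(lines,
      paste0("local null (", ln@iterations, " iterations): mean Q = ",
             format(s$mean, digits = 6), ", sd = ", format(s$sd, digits = 6),
             ", scaled modularity z = ",
             if (is.na(ln@z)) "undefined (sd = 0)" else format(ln@z, digits = 6)))
  }
  lines
}

#' Write all pipeline outputs
#'
#' Writes, into \code{dir}: the extracted network as SIF
#' (\code{network.sif}); Cytoscape node-attribute files for role, module
#' index, alteration frequency and linker q-value; an edge-attribute file
#' with the accumulated annotations; per-gene frequency, linker-statistics
#' and module-summary TSVs; per-iteration null distributions; a plain-text
#' and a minimal HTML report; and \code{MANIFEST.txt} listing every
#' written file.  All collections are sorted, so identical results
#' serialize identically.
#'
#' @param result a [RunResult-class].
#' @param dir output directory (created if missing).
#' @return character vector of written file paths, invisibly.
#' @export
writeOutputs <- function(result, dir) {
  stopifnot(is(result, "RunResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  add <- function(path) written <<- c(written, basename(path))
  ex <- result@extracted

  add(writeSIF(ex@graph, file.path(dir, "network.sif")))
  add(writeNodeAttributes(roles(ex), file.path(dir, "role.noa"), "Role"))
  freq <- result@alteredSet@frequency
  fr <- setNames(freq$fraction, freq$gene)
  fr <- fr[names(fr) %in% genes(ex)]
  add(writeNodeAttributes(format(fr, trim = TRUE),
                          file.path(dir, "alteration_frequency.noa"),
                          "AlterationFrequency"))
  if (nrow(ex@linkerStats))
    add(writeNodeAttributes(
      format(setNames(ex@linkerStats$qValue, ex@linkerStats$gene),
             trim = TRUE),
      file.path(dir, "linker_q.noa"), "LinkerQValue"))
  add(writeEdgeAttributes(ex@graph, file.path(dir, "annotations.eda"),
                          "Annotations"))
  add(writeFrequencies(result@alteredSet,
                       file.path(dir, "gene_frequencies.tsv")))
  cs <- ex@candidateStats
  write.table(cs, file.path(dir, "linker_statistics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  add(file.path(dir, "linker_statistics.tsv"))
  if (length(ex@unplaced)) {
    writeLines(ex@unplaced, file.path(dir, "unplaced_altered_genes.txt"))
    add(file.path(dir, "unplaced_altered_genes.txt"))
  }
  if (!is.null(result@partition)) {
    writeModules(result@partition, file.path(dir, "module.noa"),
                 file.path(dir, "module_summary.tsv"))
    add(file.path(dir, "module.noa")); add(file.path(dir, "module_summary.tsv"))
  }
  if (!is.null(result@globalNull))
    add(writeNullDistribution(result@globalNull,
                              file.path(dir, "global_null.tsv")))
  if (!is.null(result@localNull))
    add(writeNullDistribution(result@localNull,
                              file.path(dir, "local_null.tsv")))
  report <- .reportLines(result)
  writeLines(report, file.path(dir, "report.txt"))
  add(file.path(dir, "report.txt"))
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
            "<title>Altered-gene subnetwork analysis</title></head><body>",
            "<pre>", report, "</pre>", "</body></html>")
  writeLines(html, file.path(dir, "report.html"))
  add(file.path(dir, "report.html"))
  add(file.path(dir, "MANIFEST.txt"))
  writeLines(sort(unique(written)), file.path(dir, "MANIFEST.txt"))
  invisible(file.path(dir, sort(unique(written))))
}

setMethod("show", "RunResult", function(object) {
  cat(.reportLines(object), sep = "\n")
})
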