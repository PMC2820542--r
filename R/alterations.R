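# Per-case alteration calls: ingestion, the altered-gene definition
# (mutation, homozygous deletion or multi-copy amplification; other
# copy-number events ignored), hypermutator exclusion and the recurrence
# threshold.

# Copy-number states are mutually exclusive for one (case, gene); NONE
# conflicts with everything; MUTATION coexists with any copy-number state.
.CN_STATES <- c("HOMOZYGOUS_DELETION", "AMPLIFICATION",
                "HETEROZYGOUS_LOSS", "SINGLE_COPY_GAIN")

.checkCallConflicts <- function(calls) {
  if (!nrow(calls)) return(invisible())
  key <- paste(calls$case, calls$gene, sep = "\t")
  for (k in unique(key[duplicated(key)])) {
    st <- unique(calls$state[key == k])
    if (length(st) == 1L) next
    bad <- ("NONE" %in% st) || sum(st %in% .CN_STATES) > 1L
    if (bad) {
      cg <- strsplit(k, "\t", fixed = TRUE)[[1L]]
      stop("conflicting states for case ", cg[1L], ", gene ", cg[2L], ": ",
           paste(sort(st), collapse = " vs "))
    }
  }
  invisible()
}

#' Construct an alteration matrix
#'
#' @param calls data.frame with columns \code{case}, \code{gene},
#'   \code{state} (closed vocabulary, see
#'   [AlterationMatrix-class]).  Exact duplicate rows are dropped;
#'   contradictory states for one (case, gene) raise an error.
#' @param cases case universe; defaults to the cases seen in \code{calls}.
#' @param hypermutators case ids flagged as hypermutators.
#' @return an [AlterationMatrix-class].
#' @export
alterationMatrix <- function(calls, cases = NULL, hypermutators = character()) {
  calls <- as.data.frame(calls)[, c("case", "gene", "state")]
  calls[] <- lapply(calls, as.character)
  bad <- setdiff(calls$state, .ALTERATION_STATES)
  if (length(bad))
    stop("unknown alteration state tag(s): ", paste(sort(bad), collapse = ", "))
  calls <- unique(calls)
  calls <- calls[order(calls$case, calls$gene, calls$state), , drop = FALSE]
  rownames(calls) <- NULL
  .checkCallConflicts(calls)
  if (is.null(cases)) cases <- unique(calls$case)
  cases <- sort(unique(as.character(cases)))
  hypermutators <- sort(unique(as.character(hypermutators)))
  new("AlterationMatrix", cases = cases, calls = calls,
      hypermutators = hypermutators)
}

#' Load alteration calls from a tab-delimited table
#'
#' Rows are \code{case<TAB>gene<TAB>state}; an optional header row (tokens
#' such as \code{case}, \code{gene}, \code{state}) is skipped.  Unknown
#' state tokens are an error; exact duplicate rows are idempotent;
#' contradictory states for the same (case, gene) -- \code{NONE} against an
#' alteration, or two different copy-number states -- raise an error naming
#' the pair.
#'
#' @param path path to the alteration table.
#' @param hypermutatorFile optional plain-text file with one flagged case
#'   id per line.
#' @return an [AlterationMatrix-class].
#' @export
loadAlterations <- function(path, hypermutatorFile = NULL) {
  if (!file.exists(path)) stop("alteration file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop("malformed line ", idx[which(nf != 3L)[1L]],
         ": expected 3 tab-delimited columns")
  if (length(fields) &&
      all(tolower(fields[[1L]]) %in% c("case", "sample", "gene", "state",
                                       "status", "alteration")))
    fields <- fields[-1L]
  m <- if (length(fields)) do.call(rbind, fields) else
    matrix(character(), ncol = 3L)
  hyp <- character()
  if (!is.null(hypermutatorFile)) {
    if (!file.exists(hypermutatorFile))
      stop("hypermutator list not found: ", hypermutatorFile)
    hyp <- readLines(hypermutatorFile)
    hyp <- trimws(hyp[!grepl("^\\s*$", hyp) & !startsWith(trimws(hyp), "#")])
  }
  # flagged cases with no recorded call still belong to the cohort
  alterationMatrix(
    data.frame(case = m[, 1], gene = m[, 2], state = m[, 3]),
    cases = union(m[, 1], hyp), hypermutators = hyp)
}

#' Recurrently altered gene set
#'
#' Applies the altered-gene definition (a case counts as altered for a gene
#' if it carries a \code{MUTATION}, \code{HOMOZYGOUS_DELETION} or
#' \code{AMPLIFICATION}; heterozygous losses and single-copy gains are
#' ignored), optionally drops hypermutator cases, and keeps genes altered
#' in at least \code{minCases} of the retained cases.  A (case, gene) pair
#' with several alteration records counts once.
#'
#' @param m an [AlterationMatrix-class].
#' @param minCases recurrence threshold (default 2).
#' @param excludeHypermutators drop flagged cases before counting.
#' @return an [AlteredGeneSet-class] with per-gene counts and fractions
#'   over the retained cases.
#' @export
alteredGeneSet <- function(m, minCases = 2L, excludeHypermutators = TRUE) {
  stopifnot(is(m, "AlterationMatrix"))
  minCases <- as.integer(minCases)
  if (minCases < 1L) stop("minCases must be >= 1")
  retained <- m@cases
  if (excludeHypermutators) retained <- setdiff(retained, m@hypermutators)
  if (minCases > length(retained))
    stop("minCases (", minCases, ") exceeds the number of retained cases (",
         length(retained), ")")
  calls <- m@calls
  calls <- calls[calls$case %in% retained &
                 calls$state %in% .ALTERED_STATES, , drop = FALSE]
  counts <- integer()
  if (nrow(calls)) {
    pair <- unique(calls[, c("case", "gene")])
    tab <- table(pair$gene)
    counts <- setNames(as.integer(tab), names(tab))
  }
  counts <- counts[counts >= minCases]
  genes <- if (length(counts)) sort(names(counts)) else character()
  nC <- length(retained)
  freq <- data.frame(gene = genes,
                     count = as.integer(counts[genes]),
                     fraction = as.integer(counts[genes]) / nC)
  rownames(freq) <- NULL
  new("AlteredGeneSet", genes = genes, frequency = freq,
      nCases = as.integer(nC), minCases = minCases)
}

# internal: a gene set over an arbitrary gene vector (used by the global
# null, where sampled genes play the role of the altered set)
.geneSetFromGenes <- function(genes, nCases = 1L) {
  genes <- sort(unique(as.character(genes)))
  freq <- data.frame(gene = genes, count = rep(1L, length(genes)),
                     fraction = rep(1 / nCases, length(genes)))
  new("AlteredGeneSet", genes = genes, frequency = freq,
      nCases = as.integer(nCases), minCases = 1L)
}

#' Write per-gene alteration frequencies
#'
#' Tab-delimited table (gene, count, fraction), sorted by gene.
#'
#' @param x an [AlteredGeneSet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFrequencies <- function(x, path) {
  stopifnot(is(x, "AlteredGeneSet"))
  write.table(x@frequency, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @describeIn genes Genes passing the recurrence threshold.
#' @export
setMethod("genes", "AlteredGeneSet", function(x) x@genes)

#' @describeIn nCases Retained case count of an altered gene set.
#' @export
setMethod("nCases", "AlteredGeneSet", function(x) x@nCases)

#' @describeIn nCases Total case count of an alteration matrix.
#' @export
setMethod("nCases", "AlterationMatrix", function(x) length(x@cases))

setMethod("show", "AlterationMatrix", function(object) {
  cat("AlterationMatrix:", length(object@cases), "cases,",
      length(unique(object@calls$gene)), "genes with calls,",
      nrow(object@calls), "call records\n")
  if (length(object@hypermutators))
    cat("  hypermutator-flagged cases:", length(object@hypermutators), "\n")
})

setMethod("show", "AlteredGeneSet", function(object) {
  cat("AlteredGeneSet:", length(object@genes), "genes altered in >=",
      object@minCases, "of", object@nCases, "cases\n")
})
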