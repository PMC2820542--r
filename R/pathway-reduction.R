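# Reduction of a simplified biochemical pathway description (molecules in
# states, complexes, reactions, controls) to tagged binary gene-gene
# interactions: complex co-membership, co-substrates, controller-driven
# state changes, sequential catalysis and co-control.

.RULE_TAGS <- c("IN_SAME_COMPLEX", "REACTS_WITH", "STATE_CHANGE",
                "SEQUENTIAL_CATALYSIS", "CO_CONTROL")

#' Construct a pathway model
#'
#' @param molecules data.frame with columns \code{id}, \code{gene}
#'   (\code{NA} for small molecules) and optionally \code{state}.
#' @param complexes named list: complex id -> member molecule/complex ids.
#' @param reactions named list: reaction id -> list(inputs=, outputs=).
#' @param controls data.frame with columns \code{controller},
#'   \code{reaction}, \code{type}.
#' @return a validated [PathwayModel-class].
#' @export
pathwayModel <- function(molecules,
                         complexes = list(),
                         reactions = list(),
                         controls = data.frame(controller = character(),
                                               reaction = character(),
                                               type = character())) {
  molecules <- as.data.frame(molecules)
  if (!"state" %in% names(molecules)) molecules$state <- ""
  molecules$gene <- as.character(molecules$gene)
  molecules$gene[!is.na(molecules$gene) & molecules$gene %in% c("", "-")] <-
    NA_character_
  new("PathwayModel", molecules = molecules, complexes = complexes,
      reactions = reactions, controls = as.data.frame(controls))
}

#' Read a pathway model from a reaction table
#'
#' Line-oriented tab-delimited format with one record per line:
#' \preformatted{
#' MOLECULE <id> <gene or -> [state]
#' COMPLEX  <id> <member,member,...>
#' REACTION <id> <input,input,...> <output,output,...>
#' CONTROL  <controller molecule id> <reaction id> [control type]
#' }
#' Empty member lists are written as \code{-}.  \code{#} comments and blank
#' lines are skipped.
#'
#' @param path path to the reaction-table file.
#' @return a [PathwayModel-class].
#' @export
readPathwayModel <- function(path) {
  if (!file.exists(path)) stop("reaction table not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  mol <- list(); cx <- list(); rx <- list(); ctl <- list()
  splitIds <- function(x) if (x %in% c("", "-")) character()
                          else strsplit(x, ",", fixed = TRUE)[[1L]]
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    rec <- f[1L]
    if (rec == "MOLECULE" && length(f) >= 3L) {
      mol[[length(mol) + 1L]] <- data.frame(
        id = f[2L], gene = f[3L],
        state = if (length(f) >= 4L) f[4L] else "")
    } else if (rec == "COMPLEX" && length(f) == 3L) {
      cx[[f[2L]]] <- splitIds(f[3L])
    } else if (rec == "REACTION" && length(f) == 4L) {
      rx[[f[2L]]] <- list(inputs = splitIds(f[3L]), outputs = splitIds(f[4L]))
    } else if (rec == "CONTROL" && length(f) >= 3L) {
      ctl[[length(ctl) + 1L]] <- data.frame(
        controller = f[2L], reaction = f[3L],
        type = if (length(f) >= 4L) f[4L] else "CATALYSIS")
    } else {
      stop("malformed reaction-table line ", idx[k], ": ", lines[idx[k]])
    }
  }
  pathwayModel(
    molecules = if (length(mol)) do.call(rbind, mol) else
      data.frame(id = character(), gene = character(), state = character()),
    complexes = cx, reactions = rx,
    controls = if (length(ctl)) do.call(rbind, ctl) else
      data.frame(controller = character(), reaction = character(),
                 type = character()))
}

# gene refs (non-NA, unique, sorted) of a set of molecule ids
.genesOf <- function(model, molIds) {
  g <- model@molecules$gene[match(molIds, model@molecules$id)]
  sort(unique(g[!is.na(g)]))
}

# recursively flatten a complex to molecule ids
.flattenComplex <- function(model, id) {
  members <- model@complexes[[id]]
  out <- character()
  for (m in members) {
    if (m %in% names(model@complexes)) out <- c(out, .flattenComplex(model, m))
    else out <- c(out, m)
  }
  unique(out)
}

# controller genes of a reaction id
.controllerGenes <- function(model, rid) {
  ctl <- model@controls
  if (!nrow(ctl)) return(character())
  .genesOf(model, ctl$controller[ctl$reaction == rid])
}

.unorderedPairs <- function(genes, tag) {
  genes <- sort(unique(genes))
  if (length(genes) < 2L)
    return(data.frame(a = character(), b = character(), rule = character()))
  p <- combn(genes, 2L)
  data.frame(a = p[1L, ], b = p[2L, ], rule = tag)
}

#' Reduce a pathway model to binary gene-gene interactions
#'
#' Applies the enabled reduction rules:
#' \describe{
#'   \item{IN_SAME_COMPLEX}{every pair of distinct genes among the
#'     (recursively flattened) members of a complex.}
#'   \item{REACTS_WITH}{every pair of distinct genes among the inputs of
#'     one reaction (co-substrates).}
#'   \item{STATE_CHANGE}{(controller gene, substrate gene) for every
#'     controlled reaction in which a gene occurs among both inputs and
#'     outputs -- i.e. the molecule changed state, as in a phosphorylation.}
#'   \item{SEQUENTIAL_CATALYSIS}{(controller of reaction i, controller of
#'     reaction j) whenever an output molecule of i is an input of j
#'     (molecule-level identity, not merely the same gene).}
#'   \item{CO_CONTROL}{every pair of distinct controller genes of the same
#'     reaction.}
#' }
#' Pairs whose two genes are equal are suppressed; molecules without a
#' gene reference (small molecules) never generate edges.
#'
#' @param model a [PathwayModel-class].
#' @param rules subset of the five rule tags to apply.
#' @return data.frame with columns \code{a}, \code{b}, \code{rule}; one row
#'   per emitted interaction (duplicates across rules retained -- collapse
#'   with [interactionsToNetwork()]).
#' @export
reducePathway <- function(model, rules = .RULE_TAGS) {
  stopifnot(is(model, "PathwayModel"))
  validObject(model)
  rules <- match.arg(rules, .RULE_TAGS, several.ok = TRUE)
  out <- list()
  empty <- data.frame(a = character(), b = character(), rule = character())

  if ("IN_SAME_COMPLEX" %in% rules) {
    for (cx in names(model@complexes)) {
      gg <- .genesOf(model, .flattenComplex(model, cx))
      out[[length(out) + 1L]] <- .unorderedPairs(gg, "IN_SAME_COMPLEX")
    }
  }
  if ("REACTS_WITH" %in% rules) {
    for (rid in names(model@reactions)) {
      gg <- .genesOf(model, model@reactions[[rid]]$inputs)
      out[[length(out) + 1L]] <- .unorderedPairs(gg, "REACTS_WITH")
    }
  }
  if ("STATE_CHANGE" %in% rules) {
    for (rid in names(model@reactions)) {
      r <- model@reactions[[rid]]
      ctrlGenes <- .controllerGenes(model, rid)
      if (!length(ctrlGenes)) next
      substrates <- intersect(.genesOf(model, r$inputs),
                              .genesOf(model, r$outputs))
      for (cg in ctrlGenes) for (sg in substrates) {
        if (cg == sg) next
        out[[length(out) + 1L]] <- data.frame(a = cg, b = sg,
                                              rule = "STATE_CHANGE")
      }
    }
  }
  if ("SEQUENTIAL_CATALYSIS" %in% rules) {
    rids <- names(model@reactions)
    for (ri in rids) for (rj in rids) {
      if (ri == rj) next
      if (!length(intersect(model@reactions[[ri]]$outputs,
                            model@reactions[[rj]]$inputs))) next
      gi <- .controllerGenes(model, ri); gj <- .controllerGenes(model, rj)
      for (a in gi) for (b in gj) {
        if (a == b) next
        out[[length(out) + 1L]] <- data.frame(a = a, b = b,
                                              rule = "SEQUENTIAL_CATALYSIS")
      }
    }
  }
  if ("CO_CONTROL" %in% rules) {
    for (rid in names(model@reactions)) {
      out[[length(out) + 1L]] <- .unorderedPairs(.controllerGenes(model, rid),
                                                 "CO_CONTROL")
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse binary interactions into an interaction network
#'
#' Gene-level collapse: redundant pairs become one edge whose annotations
#' accumulate the rule tags; self-pairs (e.g. homodimer complexes) are
#' dropped.
#'
#' @param interactions data.frame with columns \code{a}, \code{b} and a
#'   tag column \code{rule} (or \code{type}).
#' @return an [InteractionNetwork-class].
#' @export
interactionsToNetwork <- function(interactions) {
  df <- as.data.frame(interactions)
  if (!"type" %in% names(df))
    df$type <- if ("rule" %in% names(df)) df$rule else NA_character_
  .buildGraph(df[, c("a", "b", "type")])
}

setMethod("show", "PathwayModel", function(object) {
  cat("PathwayModel:", nrow(object@molecules), "molecule state(s),",
      length(object@complexes), "complex(es),",
      length(object@reactions), "reaction(s),",
      nrow(object@controls), "control(s)\n")
})
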