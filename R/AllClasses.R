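#' @import methods
NULL

#' InteractionNetwork: an undirected protein-interaction network with self-loops
#'
#' Container for a protein interaction network (PIN) over opaque gene
#' identifiers. Edges are canonical unordered pairs; a pair \code{(g, g)}
#' encodes a self-interaction (the protein product of \code{g} interacts with
#' an identical copy of itself, i.e. a homomer). The gene universe is the set
#' of interaction-bearing genes: genes appear in the network only through a
#' kept edge.
#'
#' @slot edges data.frame with character columns \code{from}, \code{to};
#'   canonicalized so that \code{from <= to} lexicographically and no pair is
#'   duplicated. Self-loops have \code{from == to}.
#' @slot genes character vector of gene ids, sorted, unique; exactly the ids
#'   appearing as edge endpoints.
#' @slot dropReport named list bookkeeping the load: \code{records_read},
#'   \code{kept}, \code{dropped_by_filter}, \code{duplicates_collapsed}.
#'
#' @seealso [loadNetwork()], [makeNetwork()], [selfInteractingGenes()],
#'   [geneDegree()], [degreeDistribution()]
#' @export
setClass("InteractionNetwork",
  representation(
    edges = "data.frame",
    genes = "character",
    dropReport = "list"
  )
)

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  msgs <- character(0)
  if (!all(c("from", "to") %in% names(e))) {
    return("edges must have 'from' and 'to' columns")
  }
  if (nrow(e)) {
    if (!is.character(e$from) || !is.character(e$to)) {
      msgs <- c(msgs, "edge endpoints must be character gene ids")
    }
    if (any(e$from > e$to)) {
      msgs <- c(msgs, "edges not canonicalized (need from <= to)")
    }
    key <- paste(e$from, e$to, sep = "\r")
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate edges present")
    endp <- unique(c(e$from, e$to))
    if (!setequal(endp, object@genes)) {
      msgs <- c(msgs, "gene universe must equal the set of edge endpoints")
    }
  } else if (length(object@genes)) {
    msgs <- c(msgs, "empty network must have an empty gene universe")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn InteractionNetwork compact summary of genes, edges and
#'   self-interactions
#' @param object an \code{InteractionNetwork}
#' @export
setMethod("show", "InteractionNetwork", function(object) {
  ns <- sum(object@edges$from == object@edges$to)
  cat("InteractionNetwork with", length(object@genes), "genes and",
      nrow(object@edges), "interactions\n")
  cat("  self-interactions:", ns, "\n")
  dr <- object@dropReport
  if (length(dr)) {
    cat("  load: read", dr$records_read, "| kept", dr$kept,
        "| dropped by filter", dr$dropped_by_filter,
        "| duplicates collapsed", dr$duplicates_collapsed, "\n")
  }
  invisible(NULL)
})
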