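## Network construction, self-interaction flags, degrees, degree distribution.

canonicalizeEdges <- function(from, to) {
  data.frame(
    from = pmin(from, to),
    to = pmax(from, to),
    stringsAsFactors = FALSE
  )
}

#' Build an interaction network from an edge table
#'
#' Canonicalizes interactions as unordered pairs (direction is ignored:
#' physical PPIs are undirected), collapses duplicate records, optionally
#' drops every interaction with an endpoint outside an id filter, and records
#' the bookkeeping in a drop report. Genes enter the network universe only
#' through a kept edge; ids present in the filter but absent from every kept
#' interaction are not part of the universe.
#'
#' @param edges data.frame (or matrix) whose first two columns are gene ids,
#'   one interaction per row. A row with both ids equal encodes a
#'   self-interaction.
#' @param idFilter optional character vector of valid gene ids; interactions
#'   with an endpoint outside it are dropped and counted.
#' @return an [InteractionNetwork-class] object.
#' @examples
#' net <- makeNetwork(data.frame(a = c("A", "B", "C"), b = c("B", "A", "C")))
#' net
#' @export
makeNetwork <- function(edges, idFilter = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edge table needs two id columns")
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  bad <- !nzchar(from) | !nzchar(to) | is.na(from) | is.na(to)
  if (any(bad)) {
    stop("empty gene id in edge record(s): ",
         paste(which(bad)[seq_len(min(5L, sum(bad)))], collapse = ", "))
  }
  nRead <- length(from)

  dropped <- 0L
  if (!is.null(idFilter)) {
    keep <- from %in% idFilter & to %in% idFilter
    dropped <- sum(!keep)
    from <- from[keep]
    to <- to[keep]
  }

  e <- canonicalizeEdges(from, to)
  key <- paste(e$from, e$to, sep = "\r")
  dup <- duplicated(key)
  nDup <- sum(dup)
  e <- e[!dup, , drop = FALSE]
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL

  new("InteractionNetwork",
      edges = e,
      genes = sort(unique(c(e$from, e$to))),
      dropReport = list(
        records_read = nRead,
        kept = nrow(e),
        dropped_by_filter = dropped,
        duplicates_collapsed = nDup
      ))
}

#' Load an interaction network from a tab-separated edge list
#'
#' Reads a 2-column tab-separated edge list (one interaction per line, lines
#' starting with \code{#} ignored, UTF-8), then builds the network via
#' [makeNetwork()]. A record with a field count other than two is a fatal
#' error reported with its line number. An empty file yields a valid empty
#' network.
#'
#' @param path path to the edge-list file.
#' @param idFilter optional path to a 1-column id list, or a character vector
#'   of ids; interactions with an endpoint outside it are dropped.
#' @return an [InteractionNetwork-class] object; its [dropReport()] records
#'   how many records were read, kept, filtered and collapsed.
#' @export
loadNetwork <- function(path, idFilter = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineNo <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- lineNo[nf != 2L][1L]
    stop("malformed edge record at line ", bad, ": expected 2 tab-separated ",
         "fields, got ", nf[nf != 2L][1L])
  }
  if (!length(fields)) {
    return(makeNetwork(data.frame(from = character(0), to = character(0))))
  }
  m <- do.call(rbind, fields)
  if (is.character(idFilter) && length(idFilter) == 1L && file.exists(idFilter)) {
    idFilter <- readIdList(idFilter)
  }
  makeNetwork(data.frame(from = m[, 1L], to = m[, 2L],
                         stringsAsFactors = FALSE),
              idFilter = idFilter)
}

#' Read a 1-column id list file
#'
#' @param path file with one id per line; \code{#} comment lines ignored.
#' @return character vector of ids.
#' @export
readIdList <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a network back to its edge-list form
#'
#' @param network an [InteractionNetwork-class]
#' @param path output path (2-column TSV, canonical order).
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(network, path) {
  stopifnot(is(network, "InteractionNetwork"))
  utils::write.table(network@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Accessors for InteractionNetwork
#'
#' \code{networkGenes} returns the gene universe; \code{networkEdges} the
#' canonical edge table; \code{numGenes}/\code{numEdges} their sizes;
#' \code{dropReport} the load bookkeeping.
#'
#' @param network an [InteractionNetwork-class]
#' @return see individual descriptions.
#' @export
networkGenes <- function(network) network@genes

#' @rdname networkGenes
#' @export
networkEdges <- function(network) network@edges

#' @rdname networkGenes
#' @export
numGenes <- function(network) length(network@genes)

#' @rdname networkGenes
#' @export
numEdges <- function(network) nrow(network@edges)

#' @rdname networkGenes
#' @export
dropReport <- function(network) network@dropReport

#' Genes whose protein product self-interacts
#'
#' A gene is self-interacting when the network contains the edge
#' \code{(g, g)}: its protein interacts with an identical copy of itself.
#'
#' @param network an [InteractionNetwork-class]
#' @return character vector of gene ids (sorted).
#' @export
selfInteractingGenes <- function(network) {
  e <- network@edges
  sort(unique(e$from[e$from == e$to]))
}

#' Number of distinct interaction partners (degree)
#'
#' Degree is the number of distinct interaction partners of a gene. A
#' self-interaction contributes the gene itself as one partner (+1, not +2);
#' this convention is applied consistently across the package and can be
#' switched off with \code{countSelf = FALSE} to rerun degree-based analyses
#' under the alternative reading.
#'
#' @param network an [InteractionNetwork-class]
#' @param genes gene ids to report; default all genes in the network. Unknown
#'   ids are an error naming the first offending id.
#' @param countSelf logical; count the self-loop as one partner (default TRUE).
#' @return named integer vector of degrees.
#' @export
geneDegree <- function(network, genes = NULL, countSelf = TRUE) {
  e <- network@edges
  univ <- network@genes
  if (is.null(genes)) genes <- univ
  unknown <- setdiff(genes, univ)
  if (length(unknown)) {
    stop("gene not in network: ", unknown[1L])
  }
  self <- e$from == e$to
  # Edges are deduplicated canonical pairs, so each incident non-self edge is
  # one distinct partner; a self-loop is the gene itself as a partner.
  idx <- c(e$from[!self], e$to[!self], if (countSelf) e$from[self])
  tab <- table(factor(idx, levels = univ))
  k <- as.integer(tab)
  names(k) <- univ
  k[genes]
}

#' Degree-distribution summary with log-log slope
#'
#' Tabulates (degree, count) over the network and fits an ordinary
#' least-squares line to log(count) versus log(degree) over non-zero-count,
#' non-zero degrees — a descriptive check that interactions follow an
#' approximate power law. The slope needs at least 3 distinct non-zero
#' degrees; otherwise it is reported as unavailable (\code{NA}) with
#' \code{slope_available = FALSE}.
#'
#' @param network an [InteractionNetwork-class]
#' @param countSelf passed to [geneDegree()].
#' @return list with \code{table} (data.frame degree/count), \code{slope},
#'   \code{slope_available}.
#' @export
degreeDistribution <- function(network, countSelf = TRUE) {
  k <- geneDegree(network, countSelf = countSelf)
  tab <- as.data.frame(table(k), stringsAsFactors = FALSE)
  names(tab) <- c("degree", "count")
  tab$degree <- as.integer(tab$degree)
  tab$count <- as.integer(tab$count)
  fit <- tab[tab$degree > 0 & tab$count > 0, , drop = FALSE]
  if (nrow(fit) >= 3L) {
    co <- stats::coef(stats::lm(log(count) ~ log(degree), data = fit))
    slope <- unname(co[2L])
    avail <- is.finite(slope)
  } else {
    slope <- NA_real_
    avail <- FALSE
  }
  list(table = tab, slope = slope, slope_available = avail)
}
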