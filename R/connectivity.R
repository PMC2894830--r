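## Degree-stratified analysis: equal-frequency bins, per-bin proportions of a
## marked subset, logistic regression of a binary outcome on degree, and
## Ks-binned mean connectivity.

#' Equal-frequency bins over a numeric variable
#'
#' Items are sorted by value (stable by id on ties) and split into
#' \code{nBins} contiguous groups of near-equal size; remainder items go to
#' the earliest bins. Equal values never straddle a bin boundary: a boundary
#' falling inside a run of ties is moved forward past the run, after which
#' the remaining items are re-split near-equally over the remaining bins.
#' Bin sizes may therefore deviate from equality on heavily tied data; the
#' realized sizes are part of the output.
#'
#' @param ids character vector of item ids.
#' @param values numeric vector, same length.
#' @param nBins number of bins, \code{1 <= nBins <= length(ids)}.
#' @return list of class \code{"freqBins"}: \code{assignment} (data.frame
#'   id/value/bin, in sorted order) and \code{summary} (data.frame
#'   bin/lo/hi/n).
#' @export
equalFrequencyBins <- function(ids, values, nBins) {
  stopifnot(length(ids) == length(values))
  if (nBins < 1L) stop("nBins must be >= 1")
  n <- length(ids)
  if (nBins > n) stop("nBins exceeds number of items")
  o <- order(values, ids)  # stable on ties by id
  v <- values[o]
  id <- ids[o]

  bin <- integer(n)
  start <- 1L
  for (b in seq_len(nBins)) {
    remaining <- n - start + 1L
    binsLeft <- nBins - b + 1L
    if (remaining <= 0L) break
    size <- ceiling(remaining / binsLeft)  # remainder to earliest bins
    end <- start + size - 1L
    # never split a run of equal values across the boundary
    while (end < n && v[end + 1L] == v[end]) end <- end + 1L
    bin[start:end] <- b
    start <- end + 1L
  }
  used <- sort(unique(bin))
  bin <- match(bin, used)  # renumber if trailing bins starved by tie spill

  assignment <- data.frame(id = id, value = v, bin = bin,
                           stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    vv <- v[bin == b]
    data.frame(bin = b, lo = min(vv), hi = max(vv), n = length(vv))
  }))
  structure(list(assignment = assignment, summary = summary),
            class = "freqBins")
}

#' @export
print.freqBins <- function(x, ...) {
  cat("Equal-frequency binning:", nrow(x$summary), "bins over",
      nrow(x$assignment), "items\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-bin proportion of a marked subset
#'
#' For each bin, the fraction of its members belonging to \code{marked} —
#' e.g. the proportion of WGD genes among all duplicates within each degree
#' bin.
#'
#' @param bins a \code{"freqBins"} object from [equalFrequencyBins()].
#' @param marked character vector of marked ids; must be a subset of the
#'   binned ids.
#' @return data.frame \code{bin, lo, hi, n, n_marked, proportion}.
#' @export
binProportions <- function(bins, marked) {
  a <- bins$assignment
  extra <- setdiff(marked, a$id)
  if (length(extra)) {
    stop("marked ids not among binned items: ", extra[1L])
  }
  isM <- a$id %in% marked
  out <- bins$summary
  out$n_marked <- as.integer(tapply(isM, a$bin, sum)[as.character(out$bin)])
  out$proportion <- out$n_marked / out$n
  out
}

#' Logistic regression of a binary outcome on degree
#'
#' Simple (single-predictor) logistic regression fitted by maximum
#' likelihood (IRLS via \code{stats::glm}), used to test whether e.g. the
#' probability of WGD membership rises with the number of interaction
#' partners. Fitting is per gene on raw degree; degree bins are display-only.
#' Complete separation is detected (fitted probabilities numerically 0/1 or
#' non-convergence) and flagged rather than crashing.
#'
#' @param outcome binary vector (0/1 or logical), one per gene.
#' @param predictor numeric vector (typically degree), same length, finite.
#' @return list of class \code{"logisticFit"}: \code{intercept}, \code{slope},
#'   \code{se_intercept}, \code{se_slope}, \code{p_intercept}, \code{p_slope}
#'   (Wald), \code{converged}, \code{separation}, \code{n}.
#' @export
fitDegreeLogistic <- function(outcome, predictor) {
  outcome <- as.integer(outcome)
  stopifnot(length(outcome) == length(predictor))
  if (!all(outcome %in% c(0L, 1L))) stop("outcome must be binary")
  if (length(unique(outcome)) < 2L) {
    stop("outcome has a single class; logistic regression undefined")
  }
  if (any(!is.finite(predictor))) stop("predictor must be finite")
  if (length(unique(predictor)) < 2L) {
    stop("constant predictor; slope undefined")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ predictor, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)$coefficients
  structure(list(
    intercept = unname(s[1L, 1L]),
    slope = unname(s[2L, 1L]),
    se_intercept = unname(s[1L, 2L]),
    se_slope = unname(s[2L, 2L]),
    p_intercept = unname(s[1L, 4L]),
    p_slope = unname(s[2L, 4L]),
    converged = fit$converged && !separation,
    separation = separation,
    n = length(outcome)
  ), class = "logisticFit")
}

#' @export
print.logisticFit <- function(x, ...) {
  cat("Logistic fit (n =", x$n, "):\n")
  cat(sprintf("  intercept %.4g (se %.3g), slope %.4g (se %.3g), Wald p = %.3g\n",
              x$intercept, x$se_intercept, x$slope, x$se_slope, x$p_slope))
  if (!x$converged) cat("  NOT converged",
                        if (x$separation) "(separation suspected)", "\n")
  invisible(x)
}

#' Read a per-duplicate-pair Ks table
#'
#' 3-column TSV \code{(gene1, gene2, ks)}: synonymous substitutions per
#' synonymous site between the members of a duplicate pair, a proxy for time
#' since duplication.
#'
#' @param path path to the TSV (no header; \code{#} comments ignored).
#' @return data.frame \code{gene1, gene2, ks}.
#' @export
readKsTable <- function(path) {
  k <- utils::read.table(path, sep = "\t", header = FALSE,
                         comment.char = "#", quote = "",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric"))
  if (ncol(k) != 3L) stop("Ks table must have 3 columns; got ", ncol(k))
  names(k) <- c("gene1", "gene2", "ks")
  if (any(k$ks < 0)) stop("negative Ks value")
  k
}

#' Mean connectivity per Ks bin
#'
#' Each pair's Ks value is attached to both member genes; the resulting
#' gene-level records are cut into equal-frequency Ks bins and the arithmetic
#' mean degree (total PPI partner count) is reported per bin. A gene in
#' several duplicate pairs contributes one record per pair.
#'
#' @param ksPairs data.frame as from [readKsTable()].
#' @param degrees named integer vector of gene degrees (from [geneDegree()]);
#'   every gene appearing in \code{ksPairs} must be present, otherwise the
#'   offending ids are listed in a fatal error.
#' @param nBins number of Ks bins.
#' @return data.frame \code{bin, lo, hi, n, mean_degree}.
#' @export
ksBinMeans <- function(ksPairs, degrees, nBins) {
  gene <- c(ksPairs$gene1, ksPairs$gene2)
  ks <- c(ksPairs$ks, ksPairs$ks)
  missing <- unique(gene[!gene %in% names(degrees)])
  if (length(missing)) {
    stop("no degree for gene(s): ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  # record ids unique per (pair, member) so ties order deterministically
  recId <- sprintf("%s#%06d", gene, seq_along(gene))
  bins <- equalFrequencyBins(recId, ks, nBins)
  a <- bins$assignment
  a$degree <- as.numeric(degrees[sub("#[0-9]+$", "", a$id)])
  out <- bins$summary
  out$mean_degree <- as.numeric(tapply(a$degree, a$bin,
                                       mean)[as.character(out$bin)])
  out
}
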