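## 2x2 association of self-interaction with binary gene partitions:
## contingency construction, Yates chi-square, printed-style proportions,
## odds ratios.

#' Build a 2x2 contingency table of a gene partition against self-interaction
#'
#' Rows are the two partition classes, columns are self-interacting / not.
#' Genes outside the partition are ignored; ambiguous and excluded genes must
#' therefore never be put into the partition in the first place.
#'
#' @param partition named character vector (or factor) mapping gene_id to one
#'   of exactly two class labels.
#' @param selfSet character vector of self-interacting gene ids.
#' @param classes optional length-2 character vector fixing row order;
#'   default: sorted unique labels.
#' @return 2x2 integer matrix with dimnames
#'   \code{list(class, c("self", "nonself"))}, carrying class
#'   \code{"contingency2x2"}.
#' @export
buildContingency <- function(partition, selfSet, classes = NULL) {
  if (!length(partition)) stop("partition is empty")
  lab <- as.character(partition)
  ids <- names(partition)
  if (is.null(ids)) stop("partition must be named by gene id")
  if (is.null(classes)) classes <- sort(unique(lab))
  if (length(classes) != 2L) {
    stop("partition must have exactly 2 classes; got ",
         length(unique(lab)))
  }
  isSelf <- ids %in% selfSet
  tab <- matrix(0L, 2L, 2L, dimnames = list(classes, c("self", "nonself")))
  for (i in 1:2) {
    inClass <- lab == classes[i]
    tab[i, 1L] <- sum(inClass & isSelf)
    tab[i, 2L] <- sum(inClass & !isSelf)
  }
  if (any(rowSums(tab) == 0L)) {
    stop("a partition class has zero genes; the test is undefined")
  }
  class(tab) <- c("contingency2x2", class(tab))
  tab
}

#' Construct a 2x2 contingency table from four counts
#'
#' Cell layout: \code{a} = row-1 self, \code{b} = row-1 non-self, \code{c} =
#' row-2 self, \code{d} = row-2 non-self.
#'
#' @param a,b,c,d non-negative integer counts.
#' @param rowNames length-2 character vector of row (class) labels.
#' @return a \code{contingency2x2} matrix as in [buildContingency()].
#' @export
contingency2x2 <- function(a, b, c, d, rowNames = c("row1", "row2")) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("empty table")
  tab <- matrix(as.integer(counts), 2L, 2L, byrow = TRUE,
                dimnames = list(rowNames, c("self", "nonself")))
  class(tab) <- c("contingency2x2", class(tab))
  tab
}

#' Chi-square test of association for a 2x2 table
#'
#' Pearson chi-square with Yates continuity correction on by default:
#' \deqn{\chi^2 = \sum (\max(|O - E| - 0.5, 0))^2 / E}
#' with expected counts from the marginal products over n, df = 1, and the
#' p-value from the upper tail of the chi-square distribution. The
#' \eqn{|O-E|-0.5} term is floored at 0 so near-proportional tables yield a
#' statistic of exactly zero. The uncorrected statistic is always reported
#' alongside for transparency. Any expected cell below 1 attaches a warning
#' flag to the result.
#'
#' @param table a \code{contingency2x2} (from [buildContingency()] or
#'   [contingency2x2()]) or any 2x2 numeric matrix.
#' @param yates logical; apply the continuity correction (default TRUE).
#' @return object of class \code{"chisqAssoc"}: list with \code{statistic},
#'   \code{df}, \code{p_value}, \code{correction},
#'   \code{statistic_uncorrected}, \code{p_uncorrected}, \code{expected},
#'   \code{low_expected_warning}, \code{table}.
#' @export
chiSquareTest <- function(table, yates = TRUE) {
  o <- unclass(table)
  stopifnot(is.matrix(o), all(dim(o) == 2L))
  n <- sum(o)
  if (n <= 0) stop("empty table")
  rs <- rowSums(o)
  cs <- colSums(o)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero marginal; chi-square test undefined")
  }
  e <- outer(rs, cs) / n
  statUn <- sum((o - e)^2 / e)
  statYates <- sum(pmax(abs(o - e) - 0.5, 0)^2 / e)
  stat <- if (yates) statYates else statUn
  res <- list(
    statistic = stat,
    df = 1L,
    p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
    correction = yates,
    statistic_uncorrected = statUn,
    p_uncorrected = stats::pchisq(statUn, df = 1L, lower.tail = FALSE),
    expected = e,
    low_expected_warning = any(e < 1),
    table = o
  )
  class(res) <- "chisqAssoc"
  res
}

#' @export
print.chisqAssoc <- function(x, ...) {
  cat("2x2 chi-square association test",
      if (x$correction) "(Yates continuity correction)" else "(uncorrected)",
      "\n")
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  uncorrected: X-squared = %.4g, p = %.3g\n",
              x$statistic_uncorrected, x$p_uncorrected))
  if (x$low_expected_warning) {
    cat("  warning: an expected cell count is below 1\n")
  }
  invisible(x)
}

#' Proportion, optionally as an integer percent
#'
#' With \code{asPercentInt = TRUE} the proportion is reported as an integer
#' percentage rounded half-away-from-zero (so 24.5\% prints as 25\%), the
#' convention used in the package's table output.
#'
#' @param selfCount numerator count, \code{0 <= selfCount <= total}.
#' @param total denominator count, \code{> 0}.
#' @param asPercentInt logical; return an integer percent (default FALSE:
#'   return the raw proportion).
#' @return numeric proportion in \[0, 1\], or integer percent.
#' @export
proportionSelf <- function(selfCount, total, asPercentInt = FALSE) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(selfCount < 0) || any(selfCount > total)) {
    stop("selfCount must lie in [0, total]")
  }
  p <- selfCount / total
  if (asPercentInt) as.integer(floor(p * 100 + 0.5)) else p
}

#' Odds ratio for a 2x2 table with a log-normal 95% interval
#'
#' Cross-product ratio \eqn{(a d)/(b c)} with interval
#' \eqn{\exp(\log OR \pm 1.96 \sqrt{1/a + 1/b + 1/c + 1/d})}. When any cell
#' is zero the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied and flagged.
#'
#' @param table a 2x2 contingency matrix (layout as [contingency2x2()]).
#' @return list with \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{haldane} (logical flag).
#' @export
oddsRatio <- function(table) {
  o <- as.numeric(unclass(table))  # column-major: a, c, b, d
  a <- o[1L]; c_ <- o[2L]; b <- o[3L]; d <- o[4L]
  haldane <- any(c(a, b, c_, d) == 0)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       haldane = haldane)
}

#' Association of self-interaction with a binary partition, in one step
#'
#' Convenience wrapper: builds the contingency table, runs the chi-square
#' test, and computes per-class printed-style proportions and the odds ratio.
#'
#' @inheritParams buildContingency
#' @param yates logical, passed to [chiSquareTest()].
#' @return list with \code{table}, \code{test}, \code{proportions}
#'   (data.frame class/self/total/percent), \code{odds_ratio}.
#' @export
associateSelf <- function(partition, selfSet, classes = NULL, yates = TRUE) {
  tab <- buildContingency(partition, selfSet, classes = classes)
  props <- data.frame(
    class = rownames(tab),
    self = tab[, "self"],
    total = rowSums(tab),
    percent = proportionSelf(tab[, "self"], rowSums(tab),
                             asPercentInt = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(table = tab,
       test = chiSquareTest(tab, yates = yates),
       proportions = props,
       odds_ratio = oddsRatio(tab))
}
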