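# Independent oracles and small fixture builders used across the suite.

# Naive canonical-edge-set construction: the reference for network loading.
oracleEdgeSet <- function(from, to) {
  key <- ifelse(from <= to, paste(from, to), paste(to, from))
  sort(unique(key))
}

# Adjacency-set degree oracle: distinct partners per gene, self counted once.
oracleDegrees <- function(edges, countSelf = TRUE) {
  genes <- sort(unique(c(edges$from, edges$to)))
  vapply(genes, function(g) {
    nb <- c(edges$to[edges$from == g], edges$from[edges$to == g])
    nb <- unique(nb)
    if (!countSelf) nb <- setdiff(nb, g)
    length(nb)
  }, integer(1L))
}

# Explicit sorted-walk partitioner, written independently of the package's
# binning code: walks the sorted values, closing each bin at its target
# quota but only on a value change.
oracleBinSizes <- function(values, nBins) {
  v <- sort(values)
  n <- length(v)
  sizes <- integer(0)
  start <- 1L
  b <- 0L
  while (start <= n && b < nBins) {
    b <- b + 1L
    quota <- ceiling((n - start + 1L) / (nBins - b + 1L))
    end <- start + quota - 1L
    while (end < n && v[end + 1L] == v[end]) end <- end + 1L
    sizes <- c(sizes, end - start + 1L)
    start <- end + 1L
  }
  sizes
}

# Textbook 2x2 chi-square shortcut with continuity correction:
# n(|ad-bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d)), correction floored at 0.
oracleYatesShortcut <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  num <- max(abs(a * d - b * c) - n / 2, 0)^2 * n
  num / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Exhaustive-enumeration check of the hypergeometric tail for all
# configurations up to maxN: enumerates every n-subset of 1..N, counts
# members <= K, and compares tail fractions against hypergeomTailP.
# Returns the largest absolute deviation observed.
hyperEnumerationMaxError <- function(maxN = 15) {
  worst <- 0
  for (N in 2:maxN) {
    for (n in 1:N) {
      subsets <- utils::combn(N, n)
      if (is.null(dim(subsets))) subsets <- matrix(subsets, nrow = n)
      for (K in 0:N) {
        counts <- colSums(subsets <= K)
        mu <- n * K / N
        for (obs in max(0, n + K - N):min(K, n)) {
          pEnum <- if (obs >= mu) mean(counts >= obs) else mean(counts <= obs)
          worst <- max(worst, abs(pEnum - hypergeomTailP(obs, K, N, n)))
        }
      }
    }
  }
  worst
}

# A random null annotation universe plus a uniformly drawn focal set;
# term K values are large so the hypergeometric null is near-continuous.
makeNullEnrichmentUniverse <- function(N = 2000, n = 1000, nTerms = 30) {
  genes <- sprintf("g%04d", seq_len(N))
  terms <- sprintf("T%02d", seq_len(nTerms))
  rates <- stats::runif(nTerms, 0.1, 0.3)
  ann <- do.call(rbind, lapply(seq_len(nTerms), function(i) {
    a <- stats::runif(N) < rates[i]
    data.frame(gene_id = genes[a], term_id = terms[i],
               stringsAsFactors = FALSE)
  }))
  tns <- data.frame(
    term_id = terms,
    namespace = rep(c("biological_process", "molecular_function"),
                    length.out = nTerms),
    stringsAsFactors = FALSE)
  list(genes = genes, annotations = ann, term_namespace = tns,
       focal = sample(genes, n))
}

# Minimal hit-table row(s) in the package's 14-column layout.
makeHits <- function(query, subject, evalue, bits = 100,
                     alen = 100, qlen = 200, slen = 200) {
  k <- length(query)
  data.frame(query_id = query, subject_id = subject,
             pident = rep(90, k), alignment_length = rep_len(alen, k),
             mismatch = 0L, gapopen = 0L, qstart = 1L,
             qend = rep_len(alen, k), sstart = 1L, send = rep_len(alen, k),
             evalue = evalue, bit_score = rep_len(bits, k),
             query_length = rep_len(qlen, k),
             subject_length = rep_len(slen, k),
             stringsAsFactors = FALSE)
}
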