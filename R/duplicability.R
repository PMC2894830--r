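## Duplicability classification: similarity-based singleton/duplicate calls,
## ortholog-cardinality calls, and WGD/SSD mechanism assignment.

#' Read an all-against-all similarity hit table
#'
#' Consumes a BLAST-tabular-style TSV: the 12 standard columns (qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore) extended with query_length and subject_length as columns
#' 13-14. Query/subject ids are gene ids (peptide-to-gene mapping happens
#' upstream). \code{#} comment lines are ignored.
#'
#' @param path path to the 14-column TSV (no header).
#' @return data.frame with columns \code{query_id, subject_id, pident,
#'   alignment_length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bit_score, query_length, subject_length}.
#' @export
readSimilarityHits <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "alignment_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bit_score", "query_length", "subject_length")
  hits <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#", quote = "",
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           rep("numeric", 12L)))
  if (ncol(hits) != 14L) {
    stop("similarity hit table must have 14 columns (BLAST tabular + ",
         "query_length, subject_length); got ", ncol(hits))
  }
  names(hits) <- cols
  validateHits(hits)
  hits
}

validateHits <- function(hits) {
  if (any(hits$evalue < 0)) stop("negative E-value in hit table")
  bad <- hits$alignment_length <= 0 | hits$query_length <= 0 |
    hits$subject_length <= 0
  if (any(bad)) {
    stop("non-positive length in hit record(s): ",
         paste(which(bad)[seq_len(min(5L, sum(bad)))], collapse = ", "))
  }
  invisible(hits)
}

# D9: when the table carries several peptides per query gene, the longest
# peptide represents the gene — keep only hits at the maximal query_length.
longestPeptideHits <- function(hits) {
  maxLen <- tapply(hits$query_length, hits$query_id, max)
  hits[hits$query_length == maxLen[hits$query_id], , drop = FALSE]
}

#' Best non-self similarity hit for one query gene
#'
#' Among hits whose subject differs from the query: minimal E-value, ties
#' broken by maximal bit score, then lexicographically smallest subject id —
#' deterministic and independent of input order. Returns \code{NULL} when no
#' non-self hit exists.
#'
#' @param hits data.frame of hits sharing one \code{query_id}
#'   (columns as in [readSimilarityHits()]).
#' @return single-row data.frame, or \code{NULL}.
#' @export
bestNonselfHit <- function(hits) {
  h <- hits[hits$subject_id != hits$query_id, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  o <- order(h$evalue, -h$bit_score, h$subject_id)
  h[o[1L], , drop = FALSE]
}

#' Classify genes as singleton / duplicate / ambiguous / excluded
#'
#' Similarity-based duplicability calls for a gene universe. A gene with no
#' hit at all (not even a self-hit; typically low-complexity-masked or
#' too-short peptides) is \emph{excluded} (reason \code{"unalignable"}). A
#' gene whose every non-self hit has E-value >= \code{eSingleton} is a
#' \emph{singleton}. A gene whose best non-self hit has E-value <=
#' \code{eDuplicate} and aligns at least \code{minAlignedFraction} of both
#' peptides (alignment_length / query_length and alignment_length /
#' subject_length, single top hit, HSPs not merged) is a \emph{duplicate}.
#' Everything else — intermediate E-values, or a strong hit failing the
#' aligned-fraction test — is \emph{ambiguous}.
#'
#' @param genes character vector of gene ids forming the universe to
#'   classify, or a data.frame whose first column is the gene id.
#' @param hits hit table as from [readSimilarityHits()] (may cover more genes
#'   than \code{genes}; extra queries are ignored).
#' @param eSingleton singleton threshold: no non-self hit with E-value below
#'   it (default 0.1).
#' @param eDuplicate duplicate threshold on the top non-self hit (default
#'   1e-20). Must satisfy \code{eDuplicate <= eSingleton}.
#' @param minAlignedFraction minimum aligned fraction of each peptide
#'   (default 0.5).
#' @return data.frame with one row per gene: \code{gene_id}, \code{verdict}
#'   in \{singleton, duplicate, ambiguous, excluded\}, \code{reason},
#'   evidence columns \code{best_subject}, \code{best_evalue},
#'   \code{best_bit_score}, \code{aligned_frac_query},
#'   \code{aligned_frac_subject} (NA when no non-self hit).
#' @export
classifySimilarity <- function(genes, hits,
                               eSingleton = 0.1,
                               eDuplicate = 1e-20,
                               minAlignedFraction = 0.5) {
  if (is.data.frame(genes)) genes <- as.character(genes[[1L]])
  stopifnot(eDuplicate <= eSingleton, minAlignedFraction >= 0)
  validateHits(hits)
  hits <- hits[hits$query_id %in% genes, , drop = FALSE]
  hits <- longestPeptideHits(hits)

  hasAnyHit <- genes %in% hits$query_id
  ns <- hits[hits$subject_id != hits$query_id, , drop = FALSE]
  # best non-self hit per query under the D5 ordering, vectorized
  o <- order(ns$query_id, ns$evalue, -ns$bit_score, ns$subject_id)
  ns <- ns[o, , drop = FALSE]
  best <- ns[!duplicated(ns$query_id), , drop = FALSE]
  rownames(best) <- best$query_id

  out <- data.frame(
    gene_id = genes,
    verdict = NA_character_,
    reason = NA_character_,
    best_subject = NA_character_,
    best_evalue = NA_real_,
    best_bit_score = NA_real_,
    aligned_frac_query = NA_real_,
    aligned_frac_subject = NA_real_,
    stringsAsFactors = FALSE
  )

  b <- best[match(genes, best$query_id), , drop = FALSE]
  hasNonself <- !is.na(b$query_id)
  out$best_subject <- b$subject_id
  out$best_evalue <- b$evalue
  out$best_bit_score <- b$bit_score
  out$aligned_frac_query <- b$alignment_length / b$query_length
  out$aligned_frac_subject <- b$alignment_length / b$subject_length

  out$verdict[!hasAnyHit] <- "excluded"
  out$reason[!hasAnyHit] <- "unalignable"

  onlySelf <- hasAnyHit & !hasNonself
  out$verdict[onlySelf] <- "singleton"
  out$reason[onlySelf] <- "no_nonself_hit"

  idx <- which(hasAnyHit & hasNonself)
  ev <- out$best_evalue[idx]
  fq <- out$aligned_frac_query[idx]
  fs <- out$aligned_frac_subject[idx]
  v <- ifelse(ev >= eSingleton, "singleton",
       ifelse(ev <= eDuplicate & fq >= minAlignedFraction &
                fs >= minAlignedFraction, "duplicate", "ambiguous"))
  r <- ifelse(ev >= eSingleton, "no_hit_below_singleton_threshold",
       ifelse(ev > eDuplicate, "intermediate_evalue", # includes D6 cell
       ifelse(fq >= minAlignedFraction & fs >= minAlignedFraction,
              "top_hit_passes", "low_aligned_fraction")))
  out$verdict[idx] <- v
  out$reason[idx] <- r
  out
}

#' Read a human-mouse ortholog map
#'
#' 3-column TSV \code{(human_id, mouse_id, relation)} with relation in
#' \{one2one, one2many, other\}, one row per (human, mouse) pair; ortholog
#' cardinality is derived by grouping rows per human gene.
#'
#' @param path path to the TSV (no header; \code{#} comments ignored).
#' @return data.frame with columns \code{human_id, mouse_id, relation}.
#' @export
readOrthologMap <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = FALSE,
                         comment.char = "#", quote = "",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(m) != 3L) stop("ortholog map must have 3 columns; got ", ncol(m))
  names(m) <- c("human_id", "mouse_id", "relation")
  bad <- !m$relation %in% c("one2one", "one2many", "other")
  if (any(bad)) {
    stop("unknown ortholog relation: ", unique(m$relation[bad])[1L])
  }
  m
}

#' Classify duplicability from human-mouse ortholog cardinality
#'
#' Comparative definition of duplicability in a sister lineage: a human gene
#' is a \emph{singleton} when it has a one-to-one ortholog in mouse, and a
#' \emph{duplicate} (mouse-lineage-specific duplication) when it has at least
#' two mouse co-orthologs (one2many). Genes with no ortholog record or with
#' any other relation are \emph{excluded} from the comparative analysis.
#'
#' @param genes character vector of gene ids to classify.
#' @param orthologMap data.frame as from [readOrthologMap()].
#' @return data.frame: \code{gene_id}, \code{verdict} in \{singleton,
#'   duplicate, excluded\}, \code{reason}, \code{n_mouse_orthologs}.
#' @export
classifyOrthology <- function(genes, orthologMap) {
  m <- orthologMap[orthologMap$human_id %in% genes, , drop = FALSE]
  rel <- tapply(m$relation, m$human_id, function(r) {
    u <- unique(r)
    if (length(u) == 1L) u else "other"  # mixed relations: not 1:1 nor 1:many
  })
  nMouse <- tapply(m$mouse_id, m$human_id, function(x) length(unique(x)))

  relG <- rel[match(genes, names(rel))]
  nG <- as.integer(nMouse[match(genes, names(nMouse))])
  nG[is.na(nG)] <- 0L

  bad <- !is.na(relG) & relG == "one2one" & nG != 1L
  if (any(bad)) {
    stop("one2one relation with ", nG[bad][1L], " mouse orthologs for gene ",
         genes[bad][1L])
  }
  bad <- !is.na(relG) & relG == "one2many" & nG < 2L
  if (any(bad)) {
    stop("one2many relation with fewer than 2 mouse orthologs for gene ",
         genes[bad][1L])
  }

  verdict <- rep("excluded", length(genes))
  reason <- rep("no_ortholog_record", length(genes))
  reason[!is.na(relG) & relG == "other"] <- "relation_other"
  verdict[!is.na(relG) & relG == "one2one"] <- "singleton"
  reason[!is.na(relG) & relG == "one2one"] <- "one2one"
  verdict[!is.na(relG) & relG == "one2many"] <- "duplicate"
  reason[!is.na(relG) & relG == "one2many"] <- "one2many"

  data.frame(gene_id = genes, verdict = verdict, reason = reason,
             n_mouse_orthologs = nG, stringsAsFactors = FALSE)
}

#' Partition duplicates into WGD and SSD via an ohnolog list
#'
#' Merges similarity-based duplicability calls with a precomputed ohnolog
#' (whole-genome-duplicate) id list: every universe gene on the ohnolog list
#' is WGD — with source \code{"reclassified"} when its similarity verdict was
#' not \emph{duplicate} (synteny evidence overrides the sequence-similarity
#' call) and \code{"ohnolog_list"} otherwise; every similarity-duplicate not
#' on the list is SSD (source \code{"similarity_only"}). Ohnolog ids absent
#' from the classified universe are skipped with a warning and counted.
#'
#' @param similarityCalls data.frame from [classifySimilarity()] covering the
#'   gene universe.
#' @param ohnologIds character vector of ohnolog gene ids.
#' @return data.frame with one row per WGD/SSD gene: \code{gene_id},
#'   \code{mechanism} in \{WGD, SSD\}, \code{source}, \code{prior_verdict};
#'   attributes \code{report} (named list: n_wgd, n_ssd, n_reclassified,
#'   reclassified_by_prior_verdict table, n_ohnolog_skipped).
#' @export
assignMechanism <- function(similarityCalls, ohnologIds) {
  ohnologIds <- unique(ohnologIds)
  univ <- similarityCalls$gene_id
  skip <- setdiff(ohnologIds, univ)
  if (length(skip)) {
    warning(length(skip), " ohnolog id(s) absent from the classified ",
            "universe; skipped")
  }
  ohno <- intersect(ohnologIds, univ)
  verdict <- similarityCalls$verdict[match(univ, similarityCalls$gene_id)]
  names(verdict) <- univ

  isWGD <- univ %in% ohno
  isSSD <- !isWGD & verdict == "duplicate"
  keep <- isWGD | isSSD

  gene <- univ[keep]
  mech <- ifelse(isWGD[keep], "WGD", "SSD")
  prior <- unname(verdict[gene])
  src <- ifelse(mech == "SSD", "similarity_only",
                ifelse(prior == "duplicate", "ohnolog_list", "reclassified"))

  out <- data.frame(gene_id = gene, mechanism = mech, source = src,
                    prior_verdict = prior, stringsAsFactors = FALSE)
  recl <- out$source == "reclassified"
  attr(out, "report") <- list(
    n_wgd = sum(mech == "WGD"),
    n_ssd = sum(mech == "SSD"),
    n_reclassified = sum(recl),
    reclassified_by_prior_verdict = table(out$prior_verdict[recl]),
    n_ohnolog_skipped = length(skip)
  )
  out
}

#' Write per-gene duplicability calls as TSV
#'
#' @param calls data.frame from [classifySimilarity()] (optionally merged
#'   with mechanism columns).
#' @param path output path; tab-separated with header.
#' @return \code{path}, invisibly.
#' @export
writeCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
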