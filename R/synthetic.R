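## Synthetic input bundles with planted effect sizes: gene universe,
## similarity hits, PPI network with self-loops, ortholog map, ohnolog list,
## Ks table, GO-slim-style annotations, plus per-gene ground truth.

# One global seed drives named sub-streams, one per generated file, so adding
# a new output never perturbs the streams of existing ones.
.streamOffsets <- c(universe = 1L, hits = 2L, network = 3L, orthologs = 4L,
                    ohnologs = 5L, ks = 6L, annotations = 7L)

subSeed <- function(seed, stream) {
  off <- .streamOffsets[[stream]]
  as.integer((as.numeric(seed) * 8191 + off * 127) %% 2147483647)
}

# Built-in GO-slim-style vocabulary with field-realistic base annotation
# rates; ids and names follow the human GO-slim broad categories.
slimVocabulary <- function() {
  data.frame(
    term_id = c("GO:0008219", "GO:0007154", "GO:0050789", "GO:0051704",
                "GO:0006928", "GO:0050896", "GO:0007610", "GO:0009987",
                "GO:0030154", "GO:0043170", "GO:0007275", "GO:0032501",
                "GO:0009058", "GO:0009056",
                "GO:0005515", "GO:0016301", "GO:0016740", "GO:0004871",
                "GO:0004872", "GO:0003676", "GO:0016787", "GO:0016491"),
    name = c("cell death", "cell communication",
             "regulation of biological process", "multi-organism process",
             "cell motion", "response to stimulus", "behavior",
             "cellular process", "cell differentiation",
             "macromolecule metabolic process",
             "multicellular organismal development",
             "multicellular organismal process", "biosynthetic process",
             "catabolic process",
             "protein binding", "kinase activity", "transferase activity",
             "signal transducer activity", "receptor activity",
             "nucleic acid binding", "hydrolase activity",
             "oxidoreductase activity"),
    namespace = c(rep("biological_process", 14L),
                  rep("molecular_function", 8L)),
    base_rate = c(0.06, 0.22, 0.35, 0.03, 0.035, 0.12, 0.025, 0.38, 0.08,
                  0.30, 0.15, 0.09, 0.18, 0.055,
                  0.40, 0.055, 0.065, 0.035, 0.075, 0.15, 0.095, 0.03),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the human PIN dataset the package models: 8881
#' interaction-bearing genes, ~4 mean degree, 21\% self-interacting, 62\%
#' similarity-duplicates with 7.4\% ambiguous and ~1.15\% unalignable genes,
#' half of the duplicates whole-genome-derived, a planted self-interaction
#' vs. duplicability odds ratio of 1.5, a 2.3\% mouse one2many rate (higher
#' for self-interacting genes), and older (higher-Ks) WGD than SSD pairs.
#' Every argument can be overridden; validity is checked on construction.
#'
#' @param n_genes number of genes in the universe.
#' @param seed integer master seed; named sub-streams per output file are
#'   derived from it.
#' @param fraction_duplicate,fraction_ambiguous planted class fractions
#'   (singletons take the remainder); must sum to at most 1.
#' @param unalignable_count genes with no similarity hit at all (planted
#'   \code{excluded}); default \code{round(0.0115 * n_genes)}.
#' @param fraction_wgd_of_duplicate fraction of planted duplicates that are
#'   whole-genome duplicates.
#' @param reclassified_count ohnolog-list entries drawn from planted
#'   non-duplicates (synteny-only WGD evidence); default
#'   \code{round(0.12 * planted WGD count)}.
#' @param self_interaction_base_rate baseline self-interaction probability.
#' @param planted_or_self_vs_duplicate odds ratio of self-interaction for
#'   duplicates versus non-duplicates.
#' @param edges_per_gene preferential-attachment edges added per gene.
#' @param degree_self_coupling log-odds of self-interaction per unit
#'   (non-self) degree.
#' @param degree_wgd_coupling log-odds of WGD (vs SSD) membership per unit
#'   degree among duplicates; plants the higher connectivity of
#'   whole-genome duplicates.
#' @param ortholog_coverage probability a gene has an ortholog record.
#' @param one2many_prob baseline probability of a one2many (mouse-duplicated)
#'   relation.
#' @param one2many_self_multiplier multiplier on \code{one2many_prob} for
#'   self-interacting genes (plants the comparative-duplicability effect).
#' @param other_relation_prob probability of an uninformative \code{other}
#'   relation.
#' @param ks_mean_wgd,ks_mean_ssd lognormal Ks means per mechanism (WGD
#'   pairs are older).
#' @param ks_sdlog lognormal log-scale SD of Ks.
#' @param enrichment_spec data.frame \code{(term_id, class, multiplier)}
#'   planting annotation-rate multipliers for a gene class (\code{"self"},
#'   \code{"duplicate"}, \code{"wgd"} or \code{"singleton"}); default plants
#'   kinase activity and cell death enriched among self-interacting genes.
#' @return validated list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(n_genes = 8881L,
                            seed = 1L,
                            fraction_duplicate = 0.62,
                            fraction_ambiguous = 0.074,
                            unalignable_count = NULL,
                            fraction_wgd_of_duplicate = 0.5,
                            reclassified_count = NULL,
                            self_interaction_base_rate = 0.21,
                            planted_or_self_vs_duplicate = 1.5,
                            edges_per_gene = 2L,
                            degree_self_coupling = 0.02,
                            degree_wgd_coupling = 0.08,
                            ortholog_coverage = 0.92,
                            one2many_prob = 0.023,
                            one2many_self_multiplier = 1.4,
                            other_relation_prob = 0.02,
                            ks_mean_wgd = 2.0,
                            ks_mean_ssd = 0.6,
                            ks_sdlog = 0.4,
                            enrichment_spec = NULL) {
  if (is.null(unalignable_count)) {
    unalignable_count <- round(0.0115 * n_genes)
  }
  if (is.null(enrichment_spec)) {
    enrichment_spec <- data.frame(
      term_id = c("GO:0016301", "GO:0008219"),
      class = c("self", "self"),
      multiplier = c(2.0, 1.8),
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(
    n_genes = as.integer(n_genes), seed = as.integer(seed),
    fraction_duplicate = fraction_duplicate,
    fraction_ambiguous = fraction_ambiguous,
    unalignable_count = as.integer(unalignable_count),
    fraction_wgd_of_duplicate = fraction_wgd_of_duplicate,
    reclassified_count = reclassified_count,
    self_interaction_base_rate = self_interaction_base_rate,
    planted_or_self_vs_duplicate = planted_or_self_vs_duplicate,
    edges_per_gene = as.integer(edges_per_gene),
    degree_self_coupling = degree_self_coupling,
    degree_wgd_coupling = degree_wgd_coupling,
    ortholog_coverage = ortholog_coverage,
    one2many_prob = one2many_prob,
    one2many_self_multiplier = one2many_self_multiplier,
    other_relation_prob = other_relation_prob,
    ks_mean_wgd = ks_mean_wgd, ks_mean_ssd = ks_mean_ssd,
    ks_sdlog = ks_sdlog,
    enrichment_spec = enrichment_spec
  )
  with(cfg, {
    stopifnot(n_genes > 0, edges_per_gene >= 1,
              fraction_duplicate >= 0, fraction_ambiguous >= 0,
              fraction_wgd_of_duplicate >= 0, fraction_wgd_of_duplicate <= 1,
              self_interaction_base_rate > 0, self_interaction_base_rate < 1,
              planted_or_self_vs_duplicate > 0,
              ortholog_coverage >= 0, ortholog_coverage <= 1,
              one2many_prob >= 0, one2many_prob <= 1,
              ks_mean_wgd > 0, ks_mean_ssd > 0, ks_sdlog > 0,
              unalignable_count >= 0)
    if (fraction_duplicate + fraction_ambiguous > 1) {
      stop("fraction_duplicate + fraction_ambiguous exceeds 1")
    }
    if (unalignable_count > n_genes) stop("unalignable_count exceeds n_genes")
  })
  structure(cfg, class = "syntheticConfig")
}

#' Generate the synthetic gene universe with planted labels
#'
#' Assigns each gene a planted duplicability class (singleton / duplicate /
#' ambiguous / excluded-unalignable), a mechanism (WGD/SSD) for duplicates,
#' a duplicate-pair partner within the same mechanism, and a peptide length
#' drawn from a lognormal (log-mean log(450), log-sd 0.45, floored at 30
#' residues).
#'
#' @param config a [syntheticConfig()].
#' @return data.frame \code{gene_id, peptide_length, class, mechanism,
#'   partner}.
#' @export
generateUniverse <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(subSeed(config$seed, "universe"))
  n <- config$n_genes
  ids <- sprintf("g%06d", seq_len(n))

  u <- stats::runif(n)
  cls <- ifelse(u < config$fraction_duplicate, "duplicate",
         ifelse(u < config$fraction_duplicate + config$fraction_ambiguous,
                "ambiguous", "singleton"))
  nonDup <- which(cls != "duplicate")
  k <- min(config$unalignable_count, length(nonDup))
  if (k > 0) cls[sample(nonDup, k)] <- "excluded"

  mech <- rep(NA_character_, n)
  dup <- which(cls == "duplicate")
  if (length(dup)) {
    mech[dup] <- ifelse(stats::runif(length(dup)) <
                          config$fraction_wgd_of_duplicate, "WGD", "SSD")
  }

  partner <- rep(NA_character_, n)
  for (m in c("WGD", "SSD")) {
    idx <- which(!is.na(mech) & mech == m)
    if (length(idx) < 2L) next
    idx <- sample(idx)  # random pairing within mechanism
    npair <- floor(length(idx) / 2)
    a <- idx[seq_len(npair) * 2L - 1L]
    b <- idx[seq_len(npair) * 2L]
    partner[a] <- ids[b]
    partner[b] <- ids[a]
    if (length(idx) %% 2 == 1L) {  # odd gene out joins the first pair
      partner[idx[length(idx)]] <- ids[idx[1L]]
    }
  }

  plen <- pmax(30L, as.integer(round(stats::rlnorm(n, log(450), 0.45))))
  data.frame(gene_id = ids, peptide_length = plen, class = cls,
             mechanism = mech, partner = partner, stringsAsFactors = FALSE)
}

#' Generate an all-against-all similarity hit table for a synthetic universe
#'
#' Plants hits that respect the classifier thresholds exactly: every
#' non-excluded gene gets a self-hit; planted duplicates get a top non-self
#' hit to their pair partner with E-value well below 1e-20 and both aligned
#' fractions above 0.5; planted ambiguous genes get a top hit with E-value
#' log-uniform strictly inside (1e-20, 0.1); planted singletons receive only
#' weak non-self hits (E-value >= 0.1) or none; planted excluded genes get no
#' hit at all. Weak decoy hits (E in \[0.5, 10\)) are added to a random third
#' of genes so top-hit selection is exercised.
#'
#' @param universe data.frame from [generateUniverse()].
#' @param config a [syntheticConfig()].
#' @return 14-column hit data.frame (layout of [readSimilarityHits()]).
#' @export
generateSimilarityHits <- function(universe, config) {
  set.seed(subSeed(config$seed, "hits"))
  n <- nrow(universe)
  plen <- stats::setNames(universe$peptide_length, universe$gene_id)

  mkRow <- function(q, s, ev, alen, bits) {
    data.frame(query_id = q, subject_id = s,
               pident = round(stats::runif(length(q), 25, 100), 1),
               alignment_length = as.integer(alen),
               mismatch = 0L, gapopen = 0L, qstart = 1L,
               qend = as.integer(alen), sstart = 1L, send = as.integer(alen),
               evalue = ev, bit_score = round(bits, 1),
               query_length = as.integer(plen[q]),
               subject_length = as.integer(plen[s]),
               stringsAsFactors = FALSE)
  }

  rows <- list()
  keep <- universe$class != "excluded"
  # self-hits
  g <- universe$gene_id[keep]
  rows$self <- mkRow(g, g, rep(0, length(g)), plen[g],
                     2 * plen[g])

  dup <- universe[universe$class == "duplicate", , drop = FALSE]
  if (nrow(dup)) {
    log10e <- stats::runif(nrow(dup), -120, -25)
    alen <- ceiling(stats::runif(nrow(dup), 0.65, 0.95) *
                      pmax(plen[dup$gene_id], plen[dup$partner]))
    rows$dup <- mkRow(dup$gene_id, dup$partner, 10^log10e, alen,
                      60 - 2 * log10e)
  }

  amb <- universe[universe$class == "ambiguous", , drop = FALSE]
  if (nrow(amb)) {
    subj <- universe$gene_id[sample.int(n, nrow(amb))]
    same <- subj == amb$gene_id
    subj[same] <- universe$gene_id[(match(amb$gene_id[same],
                                          universe$gene_id) %% n) + 1L]
    log10e <- stats::runif(nrow(amb), -19.5, -1.1)
    alen <- ceiling(stats::runif(nrow(amb), 0.2, 0.9) *
                      pmin(plen[amb$gene_id], plen[subj]))
    rows$amb <- mkRow(amb$gene_id, subj, 10^log10e, pmax(20, alen),
                      30 - 1.5 * log10e)
  }

  # weak decoys, safe for every class: E in [0.5, 10)
  decoyIdx <- which(keep & stats::runif(n) < 1 / 3)
  if (length(decoyIdx)) {
    dq <- universe$gene_id[decoyIdx]
    subj <- universe$gene_id[sample.int(n, length(dq))]
    same <- subj == dq
    subj[same] <- universe$gene_id[(match(dq[same], universe$gene_id) %% n) + 1L]
    rows$decoy <- mkRow(dq, subj, stats::runif(length(dq), 0.5, 10),
                        pmax(15, round(0.1 * plen[dq])), 25)
  }

  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  hits[order(hits$query_id, hits$evalue), , drop = FALSE]
}

#' Generate a PPI edge list with planted self-interaction structure
#'
#' Draws a preferential-attachment graph (power-law degrees) over the
#' universe, with gene ids assigned to vertices at random, then assigns each
#' gene a self-loop post hoc with
#' \deqn{\mathrm{logit}\, p = \mathrm{logit}(base) + c \cdot k +
#'   \log(OR) \cdot 1[\mathrm{duplicate}]}
#' where \eqn{k} is the gene's non-self degree, \eqn{c} the degree-self
#' coupling and \eqn{OR} the planted self-vs-duplicability odds ratio.
#' Assigning self-loops after graph growth makes the planted OR exact by
#' construction, conditional on degree. Among duplicate genes, WGD-labeled
#' genes preferentially occupy high-degree vertices (latent logistic score
#' with slope \code{degree_wgd_coupling}), planting the higher connectivity
#' of whole-genome duplicates.
#'
#' @param universe data.frame from [generateUniverse()].
#' @param config a [syntheticConfig()].
#' @return list: \code{edges} (2-column data.frame, self-loops included) and
#'   \code{truth} (data.frame \code{gene_id, degree, self_prob, self}).
#' @export
generateNetwork <- function(universe, config) {
  set.seed(subSeed(config$seed, "network"))
  n <- nrow(universe)
  gph <- igraph::sample_pa(n, power = 1, m = config$edges_per_gene,
                           directed = FALSE, algorithm = "psumtree")
  degV <- igraph::degree(gph, loops = FALSE)

  # Random gene-to-vertex assignment, except that among duplicate genes the
  # WGD-labeled ones preferentially take high-degree vertices: vertices are
  # ranked by a latent score c*k + Logistic noise and the WGD genes occupy
  # the top ranks, so P(WGD | k) among duplicates follows a logistic curve
  # with slope ~ degree_wgd_coupling.
  vertexGene <- character(n)
  perm <- sample.int(n)                     # gene i -> vertex perm[i]
  isDup <- universe$class == "duplicate"
  isWGD <- isDup & !is.na(universe$mechanism) & universe$mechanism == "WGD"
  dupV <- perm[isDup]
  if (any(isWGD) && any(isDup & !isWGD)) {
    score <- config$degree_wgd_coupling * degV[dupV] +
      stats::rlogis(length(dupV))
    ranked <- dupV[order(score, decreasing = TRUE)]
    perm[which(isWGD)] <- ranked[seq_len(sum(isWGD))]
    perm[which(isDup & !isWGD)] <- ranked[-seq_len(sum(isWGD))]
  }
  vertexGene[perm] <- universe$gene_id
  el <- igraph::as_edgelist(gph, names = FALSE)
  edges <- data.frame(from = vertexGene[el[, 1L]],
                      to = vertexGene[el[, 2L]],
                      stringsAsFactors = FALSE)
  k <- stats::setNames(degV, vertexGene)[universe$gene_id]

  logitP <- stats::qlogis(config$self_interaction_base_rate) +
    config$degree_self_coupling * k +
    log(config$planted_or_self_vs_duplicate) * isDup
  p <- stats::plogis(logitP)
  self <- stats::runif(n) < p
  if (any(self)) {
    edges <- rbind(edges,
                   data.frame(from = universe$gene_id[self],
                              to = universe$gene_id[self],
                              stringsAsFactors = FALSE))
  }
  list(edges = edges,
       truth = data.frame(gene_id = universe$gene_id,
                          degree = as.integer(unname(k)),
                          self_prob = unname(p), self = self,
                          stringsAsFactors = FALSE))
}

#' Generate a human-mouse ortholog map with a planted comparative effect
#'
#' Each gene has an ortholog record with probability
#' \code{ortholog_coverage}; a record is \code{other} with
#' \code{other_relation_prob}, \code{one2many} with \code{one2many_prob}
#' (multiplied by \code{one2many_self_multiplier} for self-interacting genes,
#' planting greater mouse-lineage duplicability of self-interacting genes),
#' else \code{one2one}. one2many genes get 2-4 mouse co-orthologs.
#'
#' @param universe universe data.frame augmented with a logical \code{self}
#'   column (as produced by [generateBundle()] from the network truth).
#' @param config a [syntheticConfig()].
#' @return data.frame \code{human_id, mouse_id, relation}.
#' @export
generateOrthologMap <- function(universe, config) {
  stopifnot("self" %in% names(universe))
  set.seed(subSeed(config$seed, "orthologs"))
  n <- nrow(universe)
  covered <- stats::runif(n) < config$ortholog_coverage
  u <- stats::runif(n)
  p1m <- pmin(1, config$one2many_prob *
                ifelse(universe$self, config$one2many_self_multiplier, 1))
  rel <- ifelse(u < config$other_relation_prob, "other",
         ifelse(u < config$other_relation_prob + p1m, "one2many", "one2one"))
  nMouse <- ifelse(rel == "one2many", 2L + stats::rpois(n, 0.5), 1L)

  idx <- which(covered)
  data.frame(
    human_id = rep(universe$gene_id[idx], nMouse[idx]),
    mouse_id = sprintf("m%06d_%d", rep(idx, nMouse[idx]),
                       sequence(nMouse[idx])),
    relation = rep(rel[idx], nMouse[idx]),
    stringsAsFactors = FALSE
  )
}

#' Generate an ohnolog id list
#'
#' The list holds every planted WGD duplicate plus \code{reclassified_count}
#' genes drawn from the planted non-duplicates (singleton/ambiguous),
#' emulating ohnologs supported only by synteny evidence that the
#' similarity classifier misses.
#'
#' @param universe data.frame from [generateUniverse()].
#' @param config a [syntheticConfig()].
#' @return character vector of gene ids (sorted).
#' @export
generateOhnologList <- function(universe, config) {
  set.seed(subSeed(config$seed, "ohnologs"))
  wgd <- universe$gene_id[!is.na(universe$mechanism) &
                            universe$mechanism == "WGD"]
  k <- config$reclassified_count
  if (is.null(k)) k <- round(0.12 * length(wgd))
  pool <- universe$gene_id[universe$class %in% c("singleton", "ambiguous")]
  k <- min(k, length(pool))
  extra <- if (k > 0) sample(pool, k) else character(0)
  sort(c(wgd, extra))
}

#' Generate a per-duplicate-pair Ks table
#'
#' One row per planted duplicate pair; Ks is lognormal with a
#' mechanism-specific median (\code{ks_mean_wgd} for the older
#' whole-genome-duplicated pairs, \code{ks_mean_ssd} for small-scale pairs)
#' and log-SD \code{ks_sdlog}.
#'
#' @param universe data.frame from [generateUniverse()].
#' @param config a [syntheticConfig()].
#' @return data.frame \code{gene1, gene2, ks}.
#' @export
generateKs <- function(universe, config) {
  set.seed(subSeed(config$seed, "ks"))
  dup <- universe[universe$class == "duplicate" & !is.na(universe$partner), ,
                  drop = FALSE]
  # each unordered pair once
  a <- pmin(dup$gene_id, dup$partner)
  b <- pmax(dup$gene_id, dup$partner)
  pairKey <- !duplicated(paste(a, b))
  a <- a[pairKey]; b <- b[pairKey]
  mech <- dup$mechanism[pairKey]
  mu <- ifelse(mech == "WGD", log(config$ks_mean_wgd),
               log(config$ks_mean_ssd))
  data.frame(gene1 = a, gene2 = b,
             ks = round(stats::rlnorm(length(a), mu, config$ks_sdlog), 4),
             stringsAsFactors = FALSE)
}

#' Generate annotations, a term-namespace map and a GO-slim mapping
#'
#' Annotates genes against the built-in GO-slim-style vocabulary at each
#' term's base rate, multiplied by the planted \code{enrichment_spec}
#' multipliers for genes of the targeted class. Annotations are written at a
#' fine-grained term level (three child terms per slim term) together with
#' the full-to-slim mapping, so the slim-collapsing step of the pipeline is
#' exercised.
#'
#' @param universe universe data.frame augmented with a logical \code{self}
#'   column.
#' @param config a [syntheticConfig()].
#' @return list: \code{annotations} (gene_id, term_id at fine level),
#'   \code{slim_map} (full_term_id, slim_term_id), \code{term_namespace}
#'   (slim term_id, namespace), \code{vocabulary}.
#' @export
generateAnnotations <- function(universe, config) {
  stopifnot("self" %in% names(universe))
  set.seed(subSeed(config$seed, "annotations"))
  vocab <- slimVocabulary()
  n <- nrow(universe)

  classMask <- function(cls) {
    switch(cls,
           self = universe$self,
           duplicate = universe$class == "duplicate",
           singleton = universe$class == "singleton",
           wgd = !is.na(universe$mechanism) & universe$mechanism == "WGD",
           stop("unknown enrichment_spec class: ", cls))
  }

  rows <- lapply(seq_len(nrow(vocab)), function(i) {
    rate <- rep(vocab$base_rate[i], n)
    spec <- config$enrichment_spec
    spec <- spec[spec$term_id == vocab$term_id[i], , drop = FALSE]
    for (j in seq_len(nrow(spec))) {
      mask <- classMask(spec$class[j])
      rate[mask] <- rate[mask] * spec$multiplier[j]
    }
    rate <- pmin(rate, 0.95)
    ann <- stats::runif(n) < rate
    if (!any(ann)) return(NULL)
    fine <- sprintf("%s.%d", vocab$term_id[i],
                    sample.int(3L, sum(ann), replace = TRUE))
    data.frame(gene_id = universe$gene_id[ann], term_id = fine,
               stringsAsFactors = FALSE)
  })
  annotations <- do.call(rbind, rows)
  rownames(annotations) <- NULL

  slimMap <- data.frame(
    full_term_id = sprintf("%s.%d", rep(vocab$term_id, each = 3L), 1:3),
    slim_term_id = rep(vocab$term_id, each = 3L),
    stringsAsFactors = FALSE
  )
  list(annotations = annotations,
       slim_map = slimMap,
       term_namespace = vocab[, c("term_id", "namespace")],
       vocabulary = vocab)
}

#' Generate a complete, mutually consistent synthetic input bundle
#'
#' Runs every generator in order, threading the network's self-interaction
#' truth into the ortholog and annotation generators, and assembles a
#' per-gene ground-truth table. Regeneration under the same config (and its
#' seed) is deterministic.
#'
#' @param config a [syntheticConfig()].
#' @return list of class \code{"syntheticBundle"}: \code{universe},
#'   \code{hits}, \code{edges}, \code{orthologs}, \code{ohnologs},
#'   \code{ks}, \code{annotations}, \code{slim_map}, \code{term_namespace},
#'   \code{truth}, \code{config}.
#' @export
generateBundle <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  universe <- generateUniverse(config)
  hits <- generateSimilarityHits(universe, config)
  net <- generateNetwork(universe, config)
  uAug <- merge(universe, net$truth, by = "gene_id", sort = TRUE)
  uAug <- uAug[match(universe$gene_id, uAug$gene_id), , drop = FALSE]
  orthologs <- generateOrthologMap(uAug, config)
  ohnologs <- generateOhnologList(universe, config)
  ks <- generateKs(universe, config)
  ann <- generateAnnotations(uAug, config)

  truth <- uAug
  truth$ohnolog <- truth$gene_id %in% ohnologs
  structure(list(universe = universe, hits = hits, edges = net$edges,
                 orthologs = orthologs, ohnologs = ohnologs, ks = ks,
                 annotations = ann$annotations, slim_map = ann$slim_map,
                 term_namespace = ann$term_namespace, truth = truth,
                 config = config),
            class = "syntheticBundle")
}

#' Write a synthetic bundle to a directory of plain-text inputs
#'
#' Emits the six pipeline inputs plus ground truth and a manifest:
#' \code{ppi_edges.tsv}, \code{similarity_hits.tsv}, \code{orthologs.tsv},
#' \code{ohnolog_ids.txt}, \code{annotations.tsv},
#' \code{term_namespace.tsv}, \code{go_slim_map.tsv}, \code{ks_pairs.tsv},
#' \code{ground_truth.tsv}, \code{manifest.tsv}. All files are UTF-8
#' tab-separated with LF newlines; rewriting the same bundle is
#' byte-identical.
#'
#' @param bundle a \code{"syntheticBundle"} from [generateBundle()].
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "syntheticBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, file, col.names = FALSE) {
    utils::write.table(x, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names, na = "NA")
  }
  w(bundle$edges, "ppi_edges.tsv")
  hits <- bundle$hits
  hits$evalue <- formatC(hits$evalue, format = "e", digits = 6)
  w(hits, "similarity_hits.tsv")
  w(bundle$orthologs, "orthologs.tsv")
  writeLines(bundle$ohnologs, file.path(dir, "ohnolog_ids.txt"))
  w(bundle$annotations, "annotations.tsv")
  w(bundle$term_namespace, "term_namespace.tsv")
  w(bundle$slim_map, "go_slim_map.tsv")
  w(bundle$ks, "ks_pairs.tsv")
  w(bundle$truth, "ground_truth.tsv", col.names = TRUE)

  cfg <- bundle$config
  cfgFlat <- vapply(cfg[names(cfg) != "enrichment_spec"],
                    function(x) paste(format(x), collapse = ","),
                    character(1L))
  spec <- cfg$enrichment_spec
  cfgFlat <- c(cfgFlat, enrichment_spec = paste(
    sprintf("%s:%s:%g", spec$term_id, spec$class, spec$multiplier),
    collapse = ";"))
  manifest <- data.frame(key = names(cfgFlat), value = unname(cfgFlat),
                         stringsAsFactors = FALSE)
  manifest <- rbind(manifest, data.frame(
    key = "checksum",
    value = as.character(sum(utf8ToInt(paste(cfgFlat, collapse = "|")))),
    stringsAsFactors = FALSE))
  w(manifest, "manifest.tsv")
  invisible(dir)
}
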