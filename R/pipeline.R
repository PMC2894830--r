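## Pipeline orchestration: config validation, full run over the six inputs,
## report tables mirroring the association / connectivity / enrichment
## analyses, and a run manifest.

#' Read and validate a pipeline configuration
#'
#' YAML schema (all paths relative to the config file's directory unless
#' absolute):
#' \preformatted{
#' inputs:
#'   edges: ppi_edges.tsv
#'   hits: similarity_hits.tsv
#'   orthologs: orthologs.tsv
#'   ohnologs: ohnolog_ids.txt
#'   annotations: annotations.tsv
#'   term_namespace: term_namespace.tsv
#'   slim_map: go_slim_map.tsv        # optional
#'   ks: ks_pairs.tsv
#'   id_filter: ids.txt               # optional
#' thresholds:
#'   e_singleton: 0.1
#'   e_duplicate: 1.0e-20
#'   min_aligned_fraction: 0.5
#' yates: true
#' n_bins: 10
#' enrichment: {n_sims: 10000, seed: 1, alpha: 0.05}
#' out_dir: results
#' }
#'
#' @param path path to the YAML config file, or an equivalent named list.
#' @return validated list of class \code{"pipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  if (is.character(path)) {
    cfg <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
  } else {
    cfg <- path
    base <- "."
  }
  defaults <- list(
    thresholds = list(e_singleton = 0.1, e_duplicate = 1e-20,
                      min_aligned_fraction = 0.5),
    yates = TRUE, n_bins = 10L,
    enrichment = list(n_sims = 10000L, seed = 1L, alpha = 0.05)
  )
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]])) {
      miss <- setdiff(names(defaults[[k]]), names(cfg[[k]]))
      cfg[[k]][miss] <- defaults[[k]][miss]
    }
  }
  req <- c("edges", "hits", "orthologs", "ohnologs", "annotations",
           "term_namespace", "ks")
  miss <- setdiff(req, names(cfg$inputs))
  if (length(miss)) {
    stop("pipeline config is missing input path(s): ",
         paste(miss, collapse = ", "))
  }
  cfg$inputs <- lapply(cfg$inputs, function(p) {
    if (!startsWith(p, "/")) p <- file.path(base, p)
    p
  })
  for (nm in names(cfg$inputs)) {
    if (!file.exists(cfg$inputs[[nm]])) {
      stop("pipeline input does not exist: ", nm, " = ", cfg$inputs[[nm]])
    }
  }
  th <- cfg$thresholds
  if (th$e_duplicate > th$e_singleton) {
    stop("invalid thresholds: e_duplicate (", th$e_duplicate,
         ") exceeds e_singleton (", th$e_singleton, ")")
  }
  if (th$min_aligned_fraction < 0 || th$min_aligned_fraction > 1) {
    stop("min_aligned_fraction must lie in [0, 1]")
  }
  if (is.null(cfg$out_dir)) stop("pipeline config needs an out_dir")
  if (!startsWith(cfg$out_dir, "/")) cfg$out_dir <- file.path(base, cfg$out_dir)
  structure(cfg, class = "pipelineConfig")
}

pipelineLog <- function(verbose, ...) {
  if (verbose) message("[dupliPIN] ", ...)
}

writeAssocBlock <- function(assoc, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("class\tself\ttotal\tpercent", con)
  p <- assoc$proportions
  writeLines(sprintf("%s\t%d\t%d\t%d", p$class, p$self, p$total, p$percent),
             con)
  t <- assoc$test
  writeLines(c(
    sprintf("statistic\t%.6g", t$statistic),
    sprintf("df\t%d", t$df),
    sprintf("p_value\t%.6g", t$p_value),
    sprintf("correction\t%s", tolower(as.character(t$correction))),
    sprintf("statistic_uncorrected\t%.6g", t$statistic_uncorrected),
    sprintf("p_uncorrected\t%.6g", t$p_uncorrected),
    sprintf("odds_ratio\t%.6g", assoc$odds_ratio$or),
    sprintf("or_ci95\t%.6g\t%.6g", assoc$odds_ratio$ci_low,
            assoc$odds_ratio$ci_high)
  ), con)
}

#' Run the full duplicability analysis pipeline
#'
#' Loads the six inputs, classifies the gene universe by similarity and by
#' ortholog cardinality, merges the ohnolog list into WGD/SSD mechanism
#' calls, and writes a report bundle: self-interaction association tables
#' with Yates chi-square for the similarity partition, the comparative
#' (mouse) partition, WGD vs SSD, WGD vs singleton and SSD vs singleton;
#' degree-bin series (proportion of WGD among duplicates, the same among
#' self-interacting duplicates, and Ks-binned mean connectivity); per-gene
#' calls; GO-slim enrichment of self-interacting versus all classified genes
#' and of duplicates versus the universe; and a run manifest. All outputs
#' are TSV; every number is produced by the corresponding module function.
#' On a stage failure, partial outputs are removed and the manifest records
#' the failure point.
#'
#' @param config a \code{"pipelineConfig"} from [readPipelineConfig()] (or a
#'   path to the YAML file).
#' @param verbose log stage progress and record counts to standard error
#'   (default TRUE).
#' @return invisible named list of the in-memory results (network, calls,
#'   mechanism, associations, bins, enrichments, manifest path).
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "pipelineConfig")) {
    config <- readPipelineConfig(config)
  }
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(outDir, "manifest.tsv")
  written <- character(0)
  manifest <- c(
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("dupliPIN"))),
    sprintf("input_%s\t%s", names(config$inputs),
            unlist(config$inputs)),
    sprintf("e_singleton\t%g", config$thresholds$e_singleton),
    sprintf("e_duplicate\t%g", config$thresholds$e_duplicate),
    sprintf("min_aligned_fraction\t%g",
            config$thresholds$min_aligned_fraction),
    sprintf("yates\t%s", tolower(as.character(config$yates))),
    sprintf("n_bins\t%d", as.integer(config$n_bins)),
    sprintf("enrichment_n_sims\t%d", as.integer(config$enrichment$n_sims)),
    sprintf("enrichment_seed\t%d", as.integer(config$enrichment$seed)),
    sprintf("enrichment_alpha\t%g", config$enrichment$alpha)
  )
  fail <- function(stage, e) {
    unlink(written)
    writeLines(c(manifest, sprintf("failed_at\t%s", stage),
                 sprintf("error\t%s", conditionMessage(e))), manifestPath)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(file) {
    written <<- c(written, file.path(outDir, file))
    file.path(outDir, file)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) fail(name, e))
    pipelineLog(verbose, name, " done in ",
                sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs")))
    r
  }

  res <- list()

  res$network <- stage("load_network", {
    idf <- config$inputs$id_filter
    net <- loadNetwork(config$inputs$edges,
                       idFilter = if (!is.null(idf)) readIdList(idf))
    pipelineLog(verbose, "network: ", numGenes(net), " genes, ",
                numEdges(net), " interactions, ",
                length(selfInteractingGenes(net)), " self-interacting")
    net
  })
  net <- res$network
  genes <- networkGenes(net)
  selfSet <- selfInteractingGenes(net)
  degrees <- geneDegree(net)

  res$similarity <- stage("classify_similarity", {
    hits <- readSimilarityHits(config$inputs$hits)
    classifySimilarity(genes, hits,
                       eSingleton = config$thresholds$e_singleton,
                       eDuplicate = config$thresholds$e_duplicate,
                       minAlignedFraction =
                         config$thresholds$min_aligned_fraction)
  })
  res$orthology <- stage("classify_orthology", {
    classifyOrthology(genes, readOrthologMap(config$inputs$orthologs))
  })
  res$mechanism <- stage("assign_mechanism", {
    assignMechanism(res$similarity, readIdList(config$inputs$ohnologs))
  })

  stage("write_calls", {
    calls <- res$similarity
    m <- res$mechanism
    calls$mechanism <- m$mechanism[match(calls$gene_id, m$gene_id)]
    calls$mechanism_source <- m$source[match(calls$gene_id, m$gene_id)]
    calls$orthology_verdict <-
      res$orthology$verdict[match(calls$gene_id, res$orthology$gene_id)]
    writeCalls(calls, emit("gene_calls.tsv"))
  })

  mkPartition <- function(ids, labels) stats::setNames(labels, ids)
  res$associations <- stage("association", {
    sim <- res$similarity
    out <- list()
    keep <- sim$verdict %in% c("singleton", "duplicate")
    out$similarity <- associateSelf(
      mkPartition(sim$gene_id[keep], sim$verdict[keep]), selfSet,
      classes = c("singleton", "duplicate"), yates = config$yates)
    orth <- res$orthology
    keepO <- orth$verdict %in% c("singleton", "duplicate")
    out$orthology <- associateSelf(
      mkPartition(orth$gene_id[keepO],
                  ifelse(orth$verdict[keepO] == "singleton",
                         "one2one", "one2many")), selfSet,
      classes = c("one2one", "one2many"), yates = config$yates)
    m <- res$mechanism
    out$mechanism <- associateSelf(
      mkPartition(m$gene_id, m$mechanism), selfSet,
      classes = c("WGD", "SSD"), yates = config$yates)
    # post-merge singleton set: similarity singletons not reclassified to WGD
    single <- setdiff(sim$gene_id[sim$verdict == "singleton"], m$gene_id)
    for (mech in c("WGD", "SSD")) {
      part <- mkPartition(
        c(m$gene_id[m$mechanism == mech], single),
        c(rep(mech, sum(m$mechanism == mech)),
          rep("singleton", length(single))))
      out[[paste0(tolower(mech), "_vs_singleton")]] <-
        associateSelf(part, selfSet, classes = c(mech, "singleton"),
                      yates = config$yates)
    }
    writeAssocBlock(out$similarity, emit("table1_similarity.tsv"))
    writeAssocBlock(out$orthology, emit("table1_orthology.tsv"))
    writeAssocBlock(out$mechanism, emit("table2_mechanism.tsv"))
    writeAssocBlock(out$wgd_vs_singleton, emit("wgd_vs_singleton.tsv"))
    writeAssocBlock(out$ssd_vs_singleton, emit("ssd_vs_singleton.tsv"))
    out
  })

  res$connectivity <- stage("connectivity", {
    m <- res$mechanism
    wgd <- m$gene_id[m$mechanism == "WGD"]
    dupAll <- m$gene_id
    out <- list()
    nb <- min(as.integer(config$n_bins), length(dupAll))
    binsAll <- equalFrequencyBins(dupAll, unname(degrees[dupAll]), nb)
    out$wgd_by_degree <- binProportions(binsAll, wgd)
    selfDup <- intersect(dupAll, selfSet)
    if (length(selfDup) >= 2L) {
      nbS <- min(as.integer(config$n_bins), length(selfDup))
      binsSelf <- equalFrequencyBins(selfDup, unname(degrees[selfDup]), nbS)
      out$wgd_self_by_degree <- binProportions(binsSelf,
                                               intersect(wgd, selfDup))
    }
    out$logistic_all <- fitDegreeLogistic(dupAll %in% wgd,
                                          unname(degrees[dupAll]))
    if (length(selfDup) >= 2L &&
        length(unique(selfDup %in% wgd)) == 2L) {
      out$logistic_self <- fitDegreeLogistic(selfDup %in% wgd,
                                             unname(degrees[selfDup]))
    }
    ks <- readKsTable(config$inputs$ks)
    ks <- ks[ks$gene1 %in% genes & ks$gene2 %in% genes, , drop = FALSE]
    if (nrow(ks)) {
      nbK <- min(as.integer(config$n_bins), 2L * nrow(ks))
      out$ks_means <- ksBinMeans(ks, degrees, nbK)
      utils::write.table(out$ks_means, emit("fig3c_ks_connectivity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(out$wgd_by_degree, emit("fig3a_wgd_by_degree.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$wgd_self_by_degree)) {
      utils::write.table(out$wgd_self_by_degree,
                         emit("fig3b_wgd_self_by_degree.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    lg <- out$logistic_all
    writeLines(c("parameter\testimate\tse\tp",
                 sprintf("intercept\t%.6g\t%.6g\t%.6g", lg$intercept,
                         lg$se_intercept, lg$p_intercept),
                 sprintf("slope\t%.6g\t%.6g\t%.6g", lg$slope, lg$se_slope,
                         lg$p_slope),
                 sprintf("converged\t%s\t\t", tolower(lg$converged))),
               emit("logistic_wgd_degree.tsv"))
    out
  })

  res$enrichment <- stage("enrichment", {
    ann <- readAnnotations(config$inputs$annotations)
    if (!is.null(config$inputs$slim_map)) {
      ann <- applyGoSlim(ann, config$inputs$slim_map)
    }
    tns <- readTermNamespace(config$inputs$term_namespace)
    sim <- res$similarity
    classified <- sim$gene_id[sim$verdict %in% c("singleton", "duplicate")]
    en <- config$enrichment
    out <- list()
    out$self_vs_all <- runEnrichment(
      intersect(selfSet, classified), classified, ann, tns,
      nSims = en$n_sims, seed = en$seed, alpha = en$alpha)
    out$duplicate_vs_all <- runEnrichment(
      sim$gene_id[sim$verdict == "duplicate"], classified, ann, tns,
      nSims = en$n_sims, seed = en$seed + 1L, alpha = en$alpha)
    m <- res$mechanism
    selfWGD <- intersect(selfSet, m$gene_id[m$mechanism == "WGD"])
    selfDup <- intersect(selfSet, m$gene_id)
    if (length(selfWGD) && length(selfDup) > length(selfWGD)) {
      out$self_wgd_vs_self_dup <- runEnrichment(
        selfWGD, selfDup, ann, tns,
        nSims = en$n_sims, seed = en$seed + 2L, alpha = en$alpha)
    }
    writeEnrichment(out$self_vs_all, emit("table3_self_enrichment.tsv"))
    writeEnrichment(out$duplicate_vs_all,
                    emit("table4_duplicate_enrichment.tsv"))
    if (!is.null(out$self_wgd_vs_self_dup)) {
      writeEnrichment(out$self_wgd_vs_self_dup,
                      emit("table5_selfwgd_enrichment.tsv"))
    }
    out
  })

  dr <- dropReport(net)
  mrep <- attr(res$mechanism, "report")
  manifest <- c(manifest,
    sprintf("n_genes\t%d", numGenes(net)),
    sprintf("n_interactions\t%d", numEdges(net)),
    sprintf("n_self_interacting\t%d", length(selfSet)),
    sprintf("records_read\t%d", dr$records_read),
    sprintf("dropped_by_filter\t%d", dr$dropped_by_filter),
    sprintf("duplicates_collapsed\t%d", dr$duplicates_collapsed),
    sprintf("n_singleton\t%d", sum(res$similarity$verdict == "singleton")),
    sprintf("n_duplicate\t%d", sum(res$similarity$verdict == "duplicate")),
    sprintf("n_ambiguous\t%d", sum(res$similarity$verdict == "ambiguous")),
    sprintf("n_excluded\t%d", sum(res$similarity$verdict == "excluded")),
    sprintf("n_wgd\t%d", mrep$n_wgd),
    sprintf("n_ssd\t%d", mrep$n_ssd),
    sprintf("n_reclassified\t%d", mrep$n_reclassified),
    "failed_at\tnone")
  writeLines(manifest, manifestPath)
  res$manifest <- manifestPath
  pipelineLog(verbose, "pipeline complete; outputs in ", outDir)
  invisible(res)
}
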