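#' Assemble a pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis in one
#' plain list that is serialized verbatim into the output directory, so a
#' run is fully described by its emitted config.
#'
#' @param seed Global seed; per-stage seeds are derived from it
#'   deterministically.
#' @param sim A [simConfig()] for the synthetic input (its own seed is
#'   overridden by the derived simulate-stage seed).
#' @param qc A [qcThresholds()].
#' @param n_pcs Principal components for the embedding (default 50).
#' @param resolutions Clustering resolutions (default
#'   c(0.5, 0.8, 1.0, 1.5, 2.0)).
#' @param cluster_resolution Resolution used for downstream stages
#'   (default 1.0).
#' @param k_neighbors SNN neighbors (default 20).
#' @param hvg Highly variable genes for the embedding (default 2000).
#' @param alpha DE significance threshold on adjusted p (default 0.05).
#' @param max_other_frac Candidate-marker cap on the fraction expressing
#'   in the other group (default 0.40).
#' @param top_n Markers kept per cluster for networks (default 10).
#' @param transfer A [transferConfig()].
#' @param top_frac AUC scoring top fraction (default 0.05).
#' @param n_trees,top_links,top_k Network inference parameters (defaults
#'   500, 300, 20).
#' @param n_bins Spatial histogram bins (default 50).
#' @param domain_boundary Dorsal/ventral boundary on the axis (default
#'   2/3).
#' @return Named list of class \code{pipeline_config}.
#' @export
pipelineConfig <- function(seed = 1L,
                           sim = simConfig(),
                           qc = qcThresholds(),
                           n_pcs = 50,
                           resolutions = c(0.5, 0.8, 1.0, 1.5, 2.0),
                           cluster_resolution = 1.0,
                           k_neighbors = 20,
                           hvg = 2000,
                           alpha = 0.05,
                           max_other_frac = 0.40,
                           top_n = 10,
                           transfer = transferConfig(),
                           top_frac = 0.05,
                           n_trees = 500,
                           top_links = 300,
                           top_k = 20,
                           n_bins = 50,
                           domain_boundary = 2 / 3) {
  structure(list(seed = as.integer(seed), sim = sim, qc = qc, n_pcs = n_pcs,
                 resolutions = resolutions,
                 cluster_resolution = cluster_resolution,
                 k_neighbors = k_neighbors, hvg = hvg, alpha = alpha,
                 max_other_frac = max_other_frac, top_n = top_n,
                 transfer = transfer, top_frac = top_frac, n_trees = n_trees,
                 top_links = top_links, top_k = top_k, n_bins = n_bins,
                 domain_boundary = domain_boundary),
            class = "pipeline_config")
}

.log_stage <- function(log_path, stage, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "\t", stage, "\t",
                 paste(..., collapse = " "))
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the full analysis on synthetic data
#'
#' Executes simulate -> QC/demultiplex -> preprocess (normalize, embed,
#' cluster, cell cycle) -> markers -> regional transfer -> composite
#' scoring -> network inference -> spatial quantification, writing each
#' stage's tables under \code{out_dir} together with the effective config,
#' a stage log, and an md5 manifest of every artifact. Stages re-use the
#' single global seed through a fixed per-stage derivation, so a config +
#' seed pair reproduces the run.
#'
#' @param config A [pipelineConfig()].
#' @param out_dir Output directory (created; must be empty or absent
#'   unless \code{overwrite}).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisible list of in-memory stage results.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir,
                        overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("out_dir exists and is not empty; set overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  jsonlite::write_json(
    list(seed = config$seed,
         qc = unclass(config$qc),
         transfer = unclass(config$transfer),
         n_pcs = config$n_pcs, resolutions = config$resolutions,
         cluster_resolution = config$cluster_resolution,
         alpha = config$alpha, max_other_frac = config$max_other_frac,
         top_n = config$top_n, top_frac = config$top_frac,
         n_trees = config$n_trees, top_links = config$top_links,
         top_k = config$top_k, n_bins = config$n_bins,
         domain_boundary = config$domain_boundary),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)

  ## -- simulate ------------------------------------------------------------
  sim_cfg <- config$sim
  sim_cfg@seed <- .derive_seed(config$seed, "simulate")
  sim <- simulateLineageCounts(sim_cfg)
  bc <- simulateBarcodeCounts(sim, sim_cfg)
  writeCountsMTX(sim, file.path(out_dir, "counts"))
  write.csv(as.data.frame(SummarizedExperiment::colData(sim)),
            file.path(out_dir, "truth.csv"))
  .log_stage(log_path, "simulate", "cells:", ncol(sim), "genes:", nrow(sim))

  ## -- qc + demux ----------------------------------------------------------
  mito <- grep("^mt-", rownames(sim), value = TRUE)
  qcres <- qcFilter(sim, config$qc, mito_gene_set = mito)
  calls <- classifyBarcodes(bc)
  report <- addDoubletCounts(qcres$report, calls)
  keep <- colnames(qcres$counts)[calls[colnames(qcres$counts), "call"] == "singlet"]
  sce <- qcres$counts[, keep]
  writeLines(qcSummary(report), file.path(out_dir, "qc_report.txt"))
  jsonlite::write_json(
    list(n_input = report@n_input,
         n_removed_by_rule = as.list(report@n_removed_by_rule),
         n_retained = report@n_retained,
         doublet_count = report@doublet_count,
         doublet_percent = as.numeric(percentTruncated(
           report@doublet_count, report@n_input, percent_sign = FALSE))),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  .log_stage(log_path, "qc", "retained singlets:", ncol(sce))

  ## -- preprocess ----------------------------------------------------------
  sce <- logNormalize(sce)
  expr <- SummarizedExperiment::assay(sce, "logcounts")
  hvg <- selectHVG(expr, config$hvg)
  emb <- embedCells(expr, config$n_pcs, features = hvg)
  pre_seed <- .derive_seed(config$seed, "preprocess")
  clusters <- data.frame(cell = colnames(sce))
  for (r in config$resolutions)
    clusters[[sprintf("res_%g", r)]] <-
      clusterCells(emb, r, config$k_neighbors, seed = pre_seed)
  labels <- clusters[[sprintf("res_%g", config$cluster_resolution)]]
  pg <- S4Vectors::metadata(sim)$program_genes
  cc <- cellCycleScore(expr, pg$s_phase, pg$g2m, seed = pre_seed)
  clusters$phase <- cc$phase
  write.csv(clusters, file.path(out_dir, "clusters.csv"), row.names = FALSE)
  .log_stage(log_path, "preprocess", "clusters at working resolution:",
             length(unique(labels)))

  ## -- markers (dorsal vs ventral truth groups among B cells) --------------
  truth <- SummarizedExperiment::colData(sim)[colnames(sce), ]
  is_b <- truth$stage %in% c("B_quiescent", "B_active")
  de <- wilcoxonDE(expr[, is_b],
                   which(truth$region[is_b] == "dorsal"),
                   which(truth$region[is_b] == "ventral"))
  cand_d <- candidateMarkers(de, config$alpha, config$max_other_frac)
  de_v <- de
  de_v$log_fc <- -de_v$log_fc
  tmp <- de_v$pct_1; de_v$pct_1 <- de_v$pct_2; de_v$pct_2 <- tmp
  cand_v <- candidateMarkers(de_v, config$alpha, config$max_other_frac)
  write.csv(de, file.path(out_dir, "markers_dorsal_vs_ventral.csv"),
            row.names = FALSE)
  .log_stage(log_path, "markers", "dorsal candidates:", length(cand_d),
             "ventral candidates:", length(cand_v))

  ## -- regional transfer (nucleus reference -> whole-cell query) -----------
  nuc <- simulateNucleusSamples(sim, sim_cfg)
  ref_counts <- do.call(cbind, lapply(names(nuc), function(nm) {
    m <- SummarizedExperiment::assay(nuc[[nm]], "counts")
    colnames(m) <- paste(nm, colnames(m), sep = "_")
    m
  }))
  ref_sample <- rep(names(nuc), vapply(nuc, ncol, integer(1)))
  ref_region <- combineDissections(ref_sample)
  tcfg <- config$transfer
  tcfg$seed <- .derive_seed(config$seed, "transfer")
  nz <- colSums(ref_counts) > 0
  ref_counts <- ref_counts[, nz]; ref_region <- ref_region[nz]
  sel <- downsampleReference(ref_region, colSums(ref_counts > 0), tcfg)
  ref_expr <- logNormalize(ref_counts[, sel])
  query_cells <- colnames(sce)[is_b]
  emb_joint <- buildSharedEmbedding(ref_expr, expr[, query_cells], tcfg)
  anchors <- findAnchors(emb_joint, tcfg)
  pred <- transferLabels(anchors, ref_region[sel], tcfg)
  pred_df <- data.frame(cell = query_cells, classScores(pred),
                        net_score = netScore(pred),
                        predicted_class = predictedClass(pred))
  write.csv(pred_df, file.path(out_dir, "predicted_identity.csv"),
            row.names = FALSE)
  .log_stage(log_path, "transfer",
             paste(names(predictedClassCounts(pred)),
                   predictedClassCounts(pred), collapse = " "))

  ## -- composite scoring ---------------------------------------------------
  sc_seed <- .derive_seed(config$seed, "scoring")
  dset <- if (length(cand_d)) cand_d else pg$dorsal
  vset <- if (length(cand_v)) cand_v else pg$ventral
  auc_d <- aucScore(expr, dset, config$top_frac, seed = sc_seed)
  auc_v <- aucScore(expr, vset, config$top_frac, seed = sc_seed)
  hs <- highScoreSelection(minmaxNormalize(auc_d$auc),
                           minmaxNormalize(auc_v$auc))
  write.csv(data.frame(cell = colnames(sce), dorsal_auc = auc_d$auc,
                       ventral_auc = auc_v$auc, high_score = hs),
            file.path(out_dir, "composite_scores.csv"), row.names = FALSE)
  .log_stage(log_path, "scoring", "HighDorsal:", sum(hs == "HighDorsal"),
             "HighVentral:", sum(hs == "HighVentral"))

  ## -- networks ------------------------------------------------------------
  grn_seed <- .derive_seed(config$seed, "grn")
  net_genes <- unique(c(head(dset, config$top_n), head(vset, config$top_n),
                        selectHVG(expr, 50)))
  links <- inferLinks(expr[net_genes, ], n_trees = config$n_trees,
                      seed = grn_seed)
  net <- buildMarkerNetwork(links, head(dset, config$top_n),
                            config$top_links)
  metrics <- networkMetrics(net)
  write.table(links, file.path(out_dir, "links.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  .log_stage(log_path, "grn", "links:", nrow(links), "clustering:",
             signif(metrics$clustering_coefficient, 3))

  ## -- spatial -------------------------------------------------------------
  sp_seed <- .derive_seed(config$seed, "spatial")
  axis <- cbind(c(0, 200, 350), c(0, 50, 200))
  spots <- simulateSpots(2000, shape1 = 5, shape2 = 2, axis = axis,
                         colabel_prob = 0.7, seed = sp_seed)
  spots <- normalizePositions(spots, axis)
  prof <- densityProfile(spots$t, config$n_bins)
  dom <- domainAssign(spots$t, config$domain_boundary)
  colab <- colabelFraction(spots$colabel, spots$nucleus, dom)
  write.csv(spots, file.path(out_dir, "spots.csv"), row.names = FALSE)
  jsonlite::write_json(list(median_t = prof$median, colabel = as.list(colab)),
                       file.path(out_dir, "spatial_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage(log_path, "spatial", "median t:", signif(prof$median, 3))

  ## -- manifest ------------------------------------------------------------
  files <- setdiff(dir(out_dir, recursive = TRUE), "manifest.csv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)

  invisible(list(sim = sim, report = report, clusters = clusters, de = de,
                 candidates = list(dorsal = cand_d, ventral = cand_v),
                 prediction = pred, high_score = hs, links = links,
                 network_metrics = metrics,
                 spatial = list(profile = prof, colabel = colab)))
}
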