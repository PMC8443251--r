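# Shared fixtures, built in code at test time.

## small but fully structured generator config
smallSimConfig <- function(seed = 1L, effect_size = 2, doublet_rate = 0.1,
                           n_cells_scale = 1) {
  simConfig(
    seed = seed, n_genes = 600L,
    stage_sizes = round(c(B_quiescent = 80, B_active = 40, C = 60,
                          A_dividing = 60, A_migrating = 80) * n_cells_scale),
    effect_size = effect_size, doublet_rate = doublet_rate
  )
}

## one-stage two-region config used by the label-transfer recovery checks
regionOnlyConfig <- function(seed, n_cells = 500, effect_size = 2) {
  simConfig(seed = seed, n_genes = 600L,
            stage_sizes = c(B_quiescent = n_cells, B_active = 0, C = 0,
                            A_dividing = 0, A_migrating = 0),
            region_fractions = c(dorsal = 0.5, ventral = 0.5),
            doublet_rate = 0, effect_size = effect_size)
}

## named random expression matrix (genes x cells)
randomExpr <- function(n_genes, n_cells, seed = 1L, rfun = stats::rexp) {
  set.seed(seed)
  matrix(rfun(n_genes * n_cells), n_genes, n_cells,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("c%04d", seq_len(n_cells))))
}

## normalized expression + truth for a simulated dataset, after QC
simulatedExpr <- function(config) {
  sim <- simulateLineageCounts(config)
  expr <- log1p(sweep(as.matrix(SummarizedExperiment::assay(sim, "counts")),
                      2, 1e4 / Matrix::colSums(
                        SummarizedExperiment::assay(sim, "counts")), "*"))
  list(sim = sim, expr = expr,
       truth = as.data.frame(SummarizedExperiment::colData(sim)),
       programs = S4Vectors::metadata(sim)$program_genes)
}

## run the full label-transfer stack on a ref/query pair of simulations
runTransfer <- function(seed, n_cells = 500, effect_size = 2,
                        config = transferConfig()) {
  cfg <- regionOnlyConfig(seed, n_cells, effect_size)
  ref <- simulateLineageCounts(cfg)
  cfg@seed <- cfg@seed + 5000L
  qry <- simulateLineageCounts(cfg)
  ref_e <- logNormalize(as.matrix(SummarizedExperiment::assay(ref, "counts")))
  qry_e <- logNormalize(as.matrix(SummarizedExperiment::assay(qry, "counts")))
  emb <- buildSharedEmbedding(ref_e, qry_e, config)
  anchors <- findAnchors(emb, config)
  pred <- transferLabels(
    anchors, ifelse(ref$region == "dorsal", "Dorsal", "Ventral"), config)
  list(pred = pred, truth_region = qry$region, anchors = anchors)
}
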