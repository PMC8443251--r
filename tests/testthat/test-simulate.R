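test_that("generator is reproducible and truth bookkeeping is sound", {
  cfg <- smallSimConfig(seed = 7L)
  a <- simulateLineageCounts(cfg)
  b <- simulateLineageCounts(cfg)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  truth <- as.data.frame(SummarizedExperiment::colData(a))
  expect_true(all(SummarizedExperiment::assay(a, "counts") >= 0))
  expect_equal(nrow(truth), ncol(a))
  ## doublets carry two distinct barcodes, singlets one
  expect_true(all(is.na(truth$barcode_2[!truth$doublet])))
  expect_true(all(!is.na(truth$barcode_2[truth$doublet])))
  expect_true(all(truth$barcode_1[truth$doublet] !=
                    truth$barcode_2[truth$doublet]))
  ## program sets are disjoint and inside the universe
  pg <- S4Vectors::metadata(a)$program_genes
  all_prog <- unlist(pg)
  expect_equal(anyDuplicated(all_prog), 0L)
  expect_true(all(all_prog %in% rownames(a)))
})

test_that("library sizes follow the configured lognormal depth", {
  ## closed form: E[total] = exp(meanlog) * exp(sdlog^2 / 2)
  cfg <- simConfig(seed = 3L, n_genes = 600L,
                   stage_sizes = c(B_quiescent = 400L, B_active = 400L,
                                   C = 400L, A_dividing = 400L,
                                   A_migrating = 400L),
                   doublet_rate = 0,
                   depth_lognormal = c(log(5000), 0.35))
  sim <- simulateLineageCounts(cfg)
  totals <- Matrix::colSums(SummarizedExperiment::assay(sim, "counts"))
  expected <- 5000 * exp(0.35^2 / 2)
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("per-stage program genes exceed background by about the effect size", {
  cfg <- smallSimConfig(seed = 5L, doublet_rate = 0)
  sim <- simulateLineageCounts(cfg)
  pg <- S4Vectors::metadata(sim)$program_genes
  counts <- SummarizedExperiment::assay(sim, "counts")
  cpm <- sweep(as.matrix(counts), 2, 1e6 / colSums(counts), "*")
  truth <- as.data.frame(SummarizedExperiment::colData(sim))
  bg <- setdiff(rownames(sim), c(unlist(pg)))
  for (st in c("B_quiescent", "C", "A_migrating")) {
    cells <- truth$stage == st
    prog <- pg[[paste0("stage_", st)]]
    ## oracle: recompute the expected ratio directly from truth labels;
    ## program genes share the baseline distribution with background genes,
    ## so the mean ratio estimates effect_size
    ratio <- mean(cpm[prog, cells]) / mean(cpm[bg, cells])
    expect_gt(ratio, cfg@effect_size * 0.7)
    expect_lt(ratio, cfg@effect_size * 1.4)
  }
})

test_that("no-signal configuration makes regions exchangeable", {
  cfg <- regionOnlyConfig(seed = 9L, n_cells = 300, effect_size = 1)
  res <- simulatedExpr(cfg)
  auc_d <- aucScore(res$expr, res$programs$dorsal, top_frac = 0.1, seed = 1)$auc
  auc_v <- aucScore(res$expr, res$programs$ventral, top_frac = 0.1, seed = 1)$auc
  net <- minmaxNormalize(auc_d) - minmaxNormalize(auc_v)
  dorsal <- res$truth$region == "dorsal"
  ## net score distribution does not separate the regions
  expect_gt(t.test(net[dorsal], net[!dorsal])$p.value, 0.01)
})

test_that("barcode counts mark doublets on two barcodes and respect SNR", {
  cfg <- smallSimConfig(seed = 11L, doublet_rate = 0.1)
  sim <- simulateLineageCounts(cfg)
  bc <- simulateBarcodeCounts(sim, cfg)
  truth <- as.data.frame(SummarizedExperiment::colData(sim))
  expect_equal(dim(bc), c(cfg@n_barcodes, ncol(sim)))
  sing <- which(!truth$doublet)[1:20]
  for (j in sing) {
    own <- truth$barcode_1[j]
    expect_gt(bc[own, j], max(bc[-own, j]))
  }
  ## doublet count within binomial 99% interval of the configured rate
  n_emitted <- ncol(sim)
  n_doub <- sum(truth$doublet)
  ci <- qbinom(c(0.005, 0.995), n_emitted, 0.1)
  expect_gte(n_doub, ci[1] - 1)
  expect_lte(n_doub, ci[2] + 1)
})

test_that("zero doublet rate yields no double-barcoded cells", {
  cfg <- smallSimConfig(seed = 2L, doublet_rate = 0)
  sim <- simulateLineageCounts(cfg)
  bc <- simulateBarcodeCounts(sim, cfg)
  calls <- classifyBarcodes(bc)
  expect_equal(sum(calls$call == "doublet"), 0L)
})

test_that("nucleus samples honour allocations and the depth factor", {
  cfg <- smallSimConfig(seed = 13L, doublet_rate = 0, n_cells_scale = 2)
  sim <- simulateLineageCounts(cfg)
  nuc <- simulateNucleusSamples(sim, cfg)
  expect_named(nuc, c("AD", "AV", "PD", "PV"))
  truth <- as.data.frame(SummarizedExperiment::colData(sim))
  n_d <- sum(truth$region == "dorsal" & !truth$doublet)
  n_v <- sum(truth$region == "ventral" & !truth$doublet)
  kept_d <- round(cfg@nucleus_dorsal_cell_fraction * n_d)
  ## exact bookkeeping: dorsal cells downsampled then split into halves
  expect_equal(ncol(nuc$AD) + ncol(nuc$PD), kept_d)
  expect_equal(ncol(nuc$AV) + ncol(nuc$PV), n_v)
  expect_equal(ncol(nuc$AD), length(seq_len(kept_d)[seq_len(kept_d) %% 2 == 1]))
  ## dorsal mean library size ~ depth_factor x ventral (per-cell depth is
  ## lognormal, so compare against the per-cell expectation ratio)
  mu <- SummarizedExperiment::assay(sim, "mu")
  lib_ratio <- function(s, region) {
    obs <- colSums(SummarizedExperiment::assay(nuc[[s]], "counts"))
    exp_ <- colSums(mu[, colnames(nuc[[s]])]) *
      cfg@nucleus_region_depth_factor[[region]]
    mean(obs / exp_)
  }
  expect_lt(abs(lib_ratio("AD", "dorsal") - 1), 0.05)
  expect_lt(abs(lib_ratio("AV", "ventral") - 1), 0.05)
})

test_that("spot positions follow the Beta law on the axis", {
  sp <- simulateSpots(4000, shape1 = 1, shape2 = 1, seed = 3)
  expect_lt(abs(median(sp$t_true) - 0.5), 0.03)
  sp2 <- simulateSpots(4000, shape1 = 5, shape2 = 2, seed = 4)
  ## analytic Beta median via the quantile function; 99% bootstrap interval
  target <- qbeta(0.5, 5, 2)
  boot <- replicate(200, median(sample(sp2$t_true, replace = TRUE)))
  ci <- quantile(boot, c(0.005, 0.995))
  expect_gte(target, ci[[1]] - 0.01)
  expect_lte(target, ci[[2]] + 0.01)
  sp3 <- simulateSpots(100, colabel_prob = 1, seed = 5)
  expect_true(all(sp3$colabel))
  expect_error(simulateSpots(10, shape1 = -1), "Beta")
})
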