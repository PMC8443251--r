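#' Build a synthetic-data generator configuration
#'
#' Constructs a validated [SimConfig-class]. Defaults describe the study
#' conditions the generator emulates: a neurogenic lineage of quiescent and
#' activated B cells, transit-amplifying C cells, and dividing plus
#' migrating A cells; persistent dorsal/ventral transcriptional programs; a
#' mitochondrial gene set; S and G2M phase programs confined to
#' proliferative stages; four multiplexed sample barcodes with an 11.7\%
#' doublet rate; and dorsally under-sampled but more deeply sequenced
#' nucleus dissections.
#'
#' @param seed Integer seed.
#' @param n_genes Size of the gene universe.
#' @param stage_sizes Named vector of cells per stage.
#' @param region_fractions Named dorsal/ventral fractions, summing to 1.
#' @param program_genes Named vector of program sizes (\code{stage} is per
#'   lineage stage; \code{mito} defaults to the 13 protein-coding
#'   mitochondrial genes).
#' @param effect_size Fold-change of program genes in expressing cells.
#' @param nb_dispersion Negative-binomial dispersion.
#' @param depth_lognormal \code{(meanlog, sdlog)} of library size.
#' @param doublet_rate Fraction of emitted cells that are doublets.
#' @param n_barcodes Number of sample barcodes.
#' @param barcode_signal_to_noise On-/off-target barcode count ratio.
#' @param nucleus_region_depth_factor Named per-region depth multiplier for
#'   nucleus samples.
#' @param nucleus_dorsal_cell_fraction Fraction of dorsal cells retained in
#'   nucleus samples.
#' @return A \code{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, n_genes = 300,
#'                  stage_sizes = c(B_quiescent = 50, B_active = 30, C = 40,
#'                                  A_dividing = 40, A_migrating = 60))
#' @export
simConfig <- function(seed = 1L,
                      n_genes = 1000L,
                      stage_sizes = c(B_quiescent = 500L, B_active = 250L,
                                      C = 350L, A_dividing = 350L,
                                      A_migrating = 550L),
                      region_fractions = c(dorsal = 0.35, ventral = 0.65),
                      program_genes = c(stage = 50L, dorsal = 50L,
                                        ventral = 50L, mito = 13L,
                                        s_phase = 40L, g2m = 50L),
                      effect_size = 2,
                      nb_dispersion = 0.3,
                      depth_lognormal = c(meanlog = log(5000), sdlog = 0.35),
                      doublet_rate = 0.117,
                      n_barcodes = 4L,
                      barcode_signal_to_noise = 50,
                      nucleus_region_depth_factor = c(dorsal = 2, ventral = 1),
                      nucleus_dorsal_cell_fraction = 0.6) {
  new("SimConfig",
      seed = as.integer(seed),
      n_genes = as.integer(n_genes),
      stage_sizes = setNames(as.integer(stage_sizes), names(stage_sizes)),
      region_fractions = region_fractions,
      program_genes = setNames(as.integer(program_genes), names(program_genes)),
      effect_size = effect_size,
      nb_dispersion = nb_dispersion,
      depth_lognormal = unname(depth_lognormal),
      doublet_rate = doublet_rate,
      n_barcodes = as.integer(n_barcodes),
      barcode_signal_to_noise = barcode_signal_to_noise,
      nucleus_region_depth_factor = nucleus_region_depth_factor,
      nucleus_dorsal_cell_fraction = nucleus_dorsal_cell_fraction)
}

.stage_order <- c("B_quiescent", "B_active", "C", "A_dividing", "A_migrating")

## Per-gene stage-amplitude profiles for the regional programs. Shapes cycle
## through constant / ramp-up / ramp-down / peak / trough; each stage's
## amplitude column is rescaled to mean 1 over the program's genes, so the
## composite (mean over genes) regional amplitude is constant along the
## lineage while individual genes are dynamic.
.stage_profiles <- function(n_genes) {
  s <- seq(0, 1, length.out = length(.stage_order))
  shapes <- list(
    constant  = rep(1, length(s)),
    ramp_up   = 0.5 + s,
    ramp_down = 1.5 - s,
    peak      = 1.5 - 2 * abs(s - 0.5),
    trough    = 0.5 + 2 * abs(s - 0.5)
  )
  prof <- t(vapply(seq_len(n_genes),
                   function(g) shapes[[(g - 1L) %% length(shapes) + 1L]],
                   numeric(length(s))))
  colnames(prof) <- .stage_order
  sweep(prof, 2, colMeans(prof), "/")
}

## gene universe with disjoint program assignments
.assign_programs <- function(config) {
  pg <- config@program_genes
  n <- config@n_genes
  ids <- sprintf("gene%04d", seq_len(n))
  sets <- list()
  cursor <- 0L
  take <- function(k) {
    idx <- cursor + seq_len(k)
    cursor <<- cursor + k
    idx
  }
  for (st in .stage_order) sets[[paste0("stage_", st)]] <- take(pg[["stage"]])
  sets$dorsal <- take(pg[["dorsal"]])
  sets$ventral <- take(pg[["ventral"]])
  sets$mito <- take(pg[["mito"]])
  sets$s_phase <- take(pg[["s_phase"]])
  sets$g2m <- take(pg[["g2m"]])
  if (cursor > n) stop("program gene sets exceed gene universe; must be disjoint")
  ids[sets$mito] <- sprintf("mt-gene%02d", seq_along(sets$mito))
  list(ids = ids, sets = lapply(sets, function(i) ids[i]), idx = sets)
}

#' Simulate lineage-structured single-cell counts with ground truth
#'
#' Draws a genes x cells integer count matrix under the generative model:
#' per-gene baseline abundances (gamma-distributed, mitochondrial genes
#' scaled to a fixed share of the transcriptome), multiplicative program
#' effects for each cell's lineage stage, region, and cycle phase, a
#' lognormal library size per cell, and negative-binomial sampling with
#' shared dispersion. Doublets are sums of two randomly paired singlet
#' expectation profiles and carry two sample-barcode identities.
#'
#' Regional program genes follow per-gene stage-amplitude shapes
#' (constant/ramp/peak/trough) whose mean over genes is held at 1 in every
#' stage, so the composite regional signal is constant along the lineage
#' while individual genes are dynamic.
#'
#' @param config A [SimConfig-class].
#' @param region_profile \code{"dynamic"} (default) draws per-gene
#'   stage-amplitude shapes whose mean over genes is 1 in every stage;
#'   \code{"constant"} holds every regional program gene at amplitude 1 in
#'   all stages.
#' @return A [SingleCellExperiment::SingleCellExperiment] with assays
#'   \code{counts} (integer) and \code{mu} (expected counts); ground truth
#'   in \code{colData} (\code{stage}, \code{region}, \code{phase},
#'   \code{doublet}, \code{barcode_1}, \code{barcode_2}); program gene sets
#'   and the config in \code{metadata}.
#' @examples
#' sim <- simulateLineageCounts(simConfig(seed = 1, n_genes = 300,
#'   stage_sizes = c(B_quiescent = 40, B_active = 20, C = 30,
#'                   A_dividing = 30, A_migrating = 40)))
#' table(sim$stage, sim$region)
#' @export
simulateLineageCounts <- function(config,
                                  region_profile = c("dynamic", "constant")) {
  region_profile <- match.arg(region_profile)
  validObject(config)
  set.seed(config@seed)
  uni <- .assign_programs(config)
  n_genes <- config@n_genes
  n_sing <- sum(config@stage_sizes)
  if (n_sing < 1L) stop("stage_sizes must allocate at least one cell")

  ## per-gene baseline relative abundance; mitochondrial share fixed at 5%
  base <- rgamma(n_genes, shape = 0.6, rate = 1) + 0.05
  mito_idx <- uni$idx$mito
  mito_share <- 0.05
  base[mito_idx] <- base[mito_idx] *
    (mito_share / (1 - mito_share)) * sum(base[-mito_idx]) / sum(base[mito_idx])

  stage <- rep(.stage_order, times = config@stage_sizes[.stage_order])
  region <- sample(names(config@region_fractions), n_sing, replace = TRUE,
                   prob = config@region_fractions)
  ## proliferative stages cycle; others are G1
  phase <- rep("G1", n_sing)
  prolif <- stage %in% c("C", "A_dividing")
  phase[prolif] <- sample(c("S", "G2M", "G1"), sum(prolif), replace = TRUE,
                          prob = c(0.6, 0.25, 0.15))
  barcode <- sample(seq_len(config@n_barcodes), n_sing, replace = TRUE)

  eff <- config@effect_size
  flat <- function(n) matrix(1, n, length(.stage_order),
                             dimnames = list(NULL, .stage_order))
  reg_prof <- if (region_profile == "dynamic") {
    list(dorsal = .stage_profiles(length(uni$idx$dorsal)),
         ventral = .stage_profiles(length(uni$idx$ventral)))
  } else {
    list(dorsal = flat(length(uni$idx$dorsal)),
         ventral = flat(length(uni$idx$ventral)))
  }

  cell_mu_rel <- function(st, rg, ph) {
    m <- base
    m[uni$idx[[paste0("stage_", st)]]] <- m[uni$idx[[paste0("stage_", st)]]] * eff
    ridx <- uni$idx[[rg]]
    m[ridx] <- m[ridx] * (1 + (eff - 1) * reg_prof[[rg]][, st])
    if (ph == "S") m[uni$idx$s_phase] <- m[uni$idx$s_phase] * eff
    if (ph == "G2M") m[uni$idx$g2m] <- m[uni$idx$g2m] * eff
    m
  }

  rel <- matrix(0, n_genes, n_sing)
  for (j in seq_len(n_sing))
    rel[, j] <- cell_mu_rel(stage[j], region[j], phase[j])
  rel <- sweep(rel, 2, colSums(rel), "/")

  ## doublets: sums of two random singlet profiles, two distinct barcodes
  n_doub <- round(config@doublet_rate * n_sing / (1 - config@doublet_rate))
  truth <- data.frame(
    stage = stage, region = region, phase = phase,
    doublet = rep(FALSE, n_sing),
    barcode_1 = barcode, barcode_2 = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (n_doub > 0) {
    p1 <- sample(n_sing, n_doub, replace = TRUE)
    p2 <- sample(n_sing, n_doub, replace = TRUE)
    rel_d <- (rel[, p1, drop = FALSE] + rel[, p2, drop = FALSE]) / 2
    bcs <- t(vapply(seq_len(n_doub),
                    function(i) sample(seq_len(config@n_barcodes), 2L),
                    integer(2)))
    truth_d <- data.frame(
      stage = stage[p1], region = region[p1], phase = phase[p1],
      doublet = TRUE, barcode_1 = bcs[, 1], barcode_2 = bcs[, 2],
      stringsAsFactors = FALSE
    )
    rel <- cbind(rel, rel_d)
    truth <- rbind(truth, truth_d)
  }
  n_cells <- nrow(truth)

  lib <- rlnorm(n_cells, config@depth_lognormal[1], config@depth_lognormal[2])
  ## doublets carry roughly twice the mRNA of a singlet
  lib[truth$doublet] <- lib[truth$doublet] * 2
  mu <- sweep(rel, 2, lib, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config@nb_dispersion),
                   n_genes, n_cells)

  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(uni$ids, cell_ids)
  dimnames(mu) <- dimnames(counts)
  rownames(truth) <- cell_ids

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts, mu = mu),
    colData = S4Vectors::DataFrame(truth),
    metadata = list(program_genes = uni$sets, config = config)
  )
}

#' Simulate sample-barcode counts for demultiplexing
#'
#' Emits a barcodes x cells count matrix: each singlet receives Poisson
#' counts centered on a high on-target rate for its own barcode, doublets
#' on both of their barcodes, and every cell receives off-target counts at
#' the on-target rate divided by \code{barcode_signal_to_noise}.
#'
#' @param dataset Output of [simulateLineageCounts()].
#' @param config The [SimConfig-class] used to generate it.
#' @param on_target_rate Expected on-target barcode count (default 200).
#' @return Integer matrix, barcodes x cells.
#' @export
simulateBarcodeCounts <- function(dataset, config, on_target_rate = 200) {
  validObject(config)
  truth <- SummarizedExperiment::colData(dataset)
  if (config@n_barcodes < max(truth$barcode_1, truth$barcode_2, na.rm = TRUE))
    stop("n_barcodes smaller than the number of distinct sample identities")
  set.seed(config@seed + 1L)
  n_cells <- nrow(truth)
  off_rate <- on_target_rate / config@barcode_signal_to_noise
  lam <- matrix(off_rate, config@n_barcodes, n_cells)
  for (j in seq_len(n_cells)) {
    lam[truth$barcode_1[j], j] <- on_target_rate
    if (!is.na(truth$barcode_2[j])) lam[truth$barcode_2[j], j] <- on_target_rate
  }
  bc <- matrix(rpois(length(lam), lam), config@n_barcodes, n_cells)
  dimnames(bc) <- list(sprintf("BC%02d", seq_len(config@n_barcodes)),
                       colnames(dataset))
  bc
}

#' Simulate region-dissected nucleus samples
#'
#' Splits the dataset's singlet cells into four dissection samples
#' (anterior/posterior x dorsal/ventral). Dorsal samples are down-sampled
#' in cells (dorsal dissections recover fewer nuclei) and re-drawn at
#' higher depth via the per-region depth multiplier, emulating dissections
#' with fewer cells but deeper sequencing.
#'
#' @param dataset Output of [simulateLineageCounts()].
#' @param config The matching [SimConfig-class].
#' @return Named list of four \code{SingleCellExperiment}s (\code{AD},
#'   \code{AV}, \code{PD}, \code{PV}) with counts re-sampled at
#'   region-scaled depth and truth carried in \code{colData}.
#' @export
simulateNucleusSamples <- function(dataset, config) {
  validObject(config)
  truth <- SummarizedExperiment::colData(dataset)
  mu <- SummarizedExperiment::assay(dataset, "mu")
  set.seed(config@seed + 2L)
  singlets <- which(!truth$doublet)
  out <- list()
  for (rg in c("dorsal", "ventral")) {
    cells <- singlets[truth$region[singlets] == rg]
    if (!length(cells)) {
      warning("region '", rg, "' has no cells; emitting empty samples")
    }
    if (rg == "dorsal" && length(cells)) {
      keep <- sort(sample(cells, round(config@nucleus_dorsal_cell_fraction *
                                         length(cells))))
    } else keep <- cells
    ## alternate assignment gives deterministic anterior/posterior halves
    ant <- keep[seq_along(keep) %% 2L == 1L]
    post <- keep[seq_along(keep) %% 2L == 0L]
    fac <- config@nucleus_region_depth_factor[[rg]]
    for (half in c("A", "P")) {
      idx <- if (half == "A") ant else post
      nm <- paste0(half, toupper(substr(rg, 1, 1)))
      m <- mu[, idx, drop = FALSE] * fac
      cnt <- matrix(rnbinom(length(m), mu = m, size = 1 / config@nb_dispersion),
                    nrow(m), ncol(m), dimnames = dimnames(m))
      out[[nm]] <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cnt),
        colData = truth[idx, , drop = FALSE],
        metadata = list(sample = nm, region = rg, depth_factor = fac)
      )
    }
  }
  out[c("AD", "AV", "PD", "PV")]
}

#' Simulate in situ hybridization spots along a normalized axis
#'
#' Draws true axis positions t in [0, 1] from a Beta distribution, maps
#' them onto a 2-D reference polyline by arclength, and assigns channel
#' flags (a nucleus marker plus a cell-type co-label drawn per spot).
#'
#' @param n_spots Number of spots.
#' @param shape1,shape2 Beta shape parameters of the position distribution
#'   (both > 0); \code{Beta(1, 1)} is uniform along the axis.
#' @param axis Two-column matrix of polyline vertices ordered from the
#'   ventral-most point to the dorso-lateral wedge tip. Default: a straight
#'   unit segment.
#' @param colabel_prob Probability that a spot carries the cell-type
#'   co-label; may be a single value or a function of t.
#' @param seed Integer seed.
#' @return \code{data.frame} with \code{spot_id}, \code{x}, \code{y},
#'   \code{t_true}, \code{nucleus}, \code{colabel}.
#' @export
simulateSpots <- function(n_spots, shape1 = 1, shape2 = 1,
                          axis = cbind(c(0, 1), c(0, 0)),
                          colabel_prob = 0.5, seed = 1L) {
  if (shape1 <= 0 || shape2 <= 0) stop("Beta shape parameters must be > 0")
  set.seed(seed)
  t_true <- rbeta(n_spots, shape1, shape2)
  xy <- .point_at_arclength(axis, t_true)
  p <- if (is.function(colabel_prob)) colabel_prob(t_true) else
    rep(colabel_prob, n_spots)
  data.frame(
    spot_id = sprintf("spot%05d", seq_len(n_spots)),
    x = xy[, 1], y = xy[, 2], t_true = t_true,
    nucleus = TRUE,
    colabel = runif(n_spots) < p
  )
}

## point on a polyline at normalized arclength t in [0,1]
.point_at_arclength <- function(axis, t) {
  axis <- as.matrix(axis)
  seg <- diff(axis)
  len <- sqrt(rowSums(seg^2))
  if (sum(len) <= 0) stop("axis polyline has zero length")
  cum <- c(0, cumsum(len)) / sum(len)
  out <- matrix(NA_real_, length(t), 2)
  for (i in seq_along(t)) {
    k <- findInterval(t[i], cum, rightmost.closed = TRUE)
    k <- min(max(k, 1L), nrow(seg))
    f <- (t[i] - cum[k]) / (cum[k + 1] - cum[k])
    out[i, ] <- axis[k, ] + f * seg[k, ]
  }
  out
}
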