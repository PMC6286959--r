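#' Simulate a promoter tiling-array track with planted differential regions
#'
#' Emulates a NimbleGen-style promoter tiling array (histone-acetylation
#' ChIP-chip or MeDIP-chip DNA methylation): ordered probes tiled across
#' each gene's promoter, with per-sample log2 signals. A fraction of genes
#' receives a contiguous hyper (+) or hypo (-) region in every test
#' treatment cell during the dosing phase; among genes carrying a region on
#' the last treatment day, exactly `floor(persistence_fraction * n)` keep a
#' same-direction region after washout, and an equal number of fresh
#' recovery-only regions is planted on previously unaffected genes so that
#' the recovery-phase call set has the persistent fraction the generator
#' was asked for under both the "fraction of T5 genes" and the "fraction of
#' R3 calls" readings.
#'
#' When `ge_truth` is supplied, the planted effect sizes of the genes that
#' also carry a planted expression change are rank-coupled to their
#' expression log2 fold changes through a Gaussian copula targeting
#' Spearman `coupling_rho`, so epigenome-transcriptome correlation recovery
#' can be tested against a known target.
#'
#' @param design A `study_design`.
#' @param gene_promoters Either an integer (number of genes; a regular
#'   promoter layout is generated) or a data.frame with columns `gene`,
#'   `chrom`, `start`, `end` (1-based inclusive promoter intervals).
#' @param probes_per_promoter,probe_spacing_bp,probe_width_bp Layout of the
#'   generated probes: default 20 probes per promoter at 100 bp spacing,
#'   50 bp probes (1.9 kb span).
#' @param region_fraction Fraction of genes given a differential region.
#' @param effect_size Log2 effect magnitude of uncoupled regions (and the
#'   scale of coupled effects).
#' @param region_width_probes Number of consecutive probes the planted
#'   region covers (centred in the promoter).
#' @param persistence_fraction Fraction of last-treatment-day region genes
#'   whose region persists post-washout.
#' @param coupling_rho Target Spearman correlation between planted region
#'   effects and planted expression LFCs (requires `ge_truth`).
#' @param ge_truth Optional `sim_truth` from [simulate_expression()].
#' @param layer `"HA"` or `"DM"`.
#' @param noise_sd Per-probe, per-array Gaussian noise sd (log2 scale).
#' @param min_probes Promoters with fewer probes are excluded (warning).
#' @param seed Integer seed; mandatory.
#'
#' @return List with `track` (a `tiling_track`) and `truth` (a `sim_truth`
#'   with `epi_regions`, `persistence_set`, `coupling_rho`).
#' @export
simulate_tiling <- function(design, gene_promoters = 200,
                            probes_per_promoter = 20,
                            probe_spacing_bp = 100, probe_width_bp = 50,
                            region_fraction = 0.1, effect_size = 1,
                            region_width_probes = 10,
                            persistence_fraction = 0.3,
                            coupling_rho = NA, ge_truth = NULL,
                            layer = c("HA", "DM"), noise_sd = 0.2,
                            min_probes = 7, seed) {
  validate_design(design)
  layer <- match.arg(layer)
  stopifnot(probe_spacing_bp > 0,
            region_fraction >= 0, region_fraction <= 1,
            persistence_fraction >= 0, persistence_fraction <= 1)
  if (!is.na(coupling_rho) && (coupling_rho < -1 || coupling_rho > 1))
    stop("coupling_rho must be in [-1, 1]")
  if (missing(seed)) stop("seed is a mandatory argument")
  set.seed(as.integer(seed))

  if (is.numeric(gene_promoters) && length(gene_promoters) == 1) {
    n_genes <- as.integer(gene_promoters)
    span <- (probes_per_promoter - 1) * probe_spacing_bp + probe_width_bp
    gene_promoters <- data.frame(
      gene = sprintf("gene%05d", seq_len(n_genes)),
      chrom = "chr1",
      start = (seq_len(n_genes) - 1) * (span + 5000) + 1,
      end = (seq_len(n_genes) - 1) * (span + 5000) + span,
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_promoters)))

  # one probe row per (promoter, position)
  probes <- do.call(rbind, lapply(seq_len(nrow(gene_promoters)), function(i) {
    p <- gene_promoters[i, ]
    n_fit <- max(0L, (p$end - p$start + 1 - probe_width_bp) %/%
                   probe_spacing_bp + 1L)
    n_fit <- min(n_fit, probes_per_promoter)
    if (n_fit == 0) return(NULL)
    start <- p$start + (seq_len(n_fit) - 1L) * probe_spacing_bp
    data.frame(chrom = p$chrom, start = start,
               end = start + probe_width_bp - 1L,
               probe_id = sprintf("%s_p%02d", p$gene, seq_len(n_fit)),
               gene = p$gene, stringsAsFactors = FALSE)
  }))
  n_per_gene <- table(probes$gene)
  short <- names(n_per_gene)[n_per_gene < min_probes]
  short <- union(short, setdiff(gene_promoters$gene, probes$gene))
  if (length(short)) {
    warning("excluding ", length(short), " promoter(s) with < ",
            min_probes, " probes: ", paste(utils::head(short, 5), collapse = ", "))
    probes <- probes[!(probes$gene %in% short), , drop = FALSE]
    gene_promoters <- gene_promoters[!(gene_promoters$gene %in% short), ,
                                     drop = FALSE]
  }
  genes <- gene_promoters$gene
  n_genes <- length(genes)

  timepoints <- attr(design, "timepoints")
  recovery <- attr(design, "recovery_timepoints")
  dosing <- setdiff(timepoints, recovery)
  control <- attr(design, "control")

  ## --- choose region genes and effects -------------------------------
  coupled_genes <- character(0)
  effects <- numeric(0)
  if (!is.null(ge_truth) && length(ge_truth$de_genes) &&
        !is.na(coupling_rho)) {
    coupled_genes <- intersect(names(ge_truth$de_genes), genes)
    ge_lfc <- vapply(ge_truth$de_genes[coupled_genes],
                     function(g) g[[1]], numeric(1))
    z <- rank_couple(ge_lfc, coupling_rho)
    # strictly monotone transform of the latent effect: keeps the Spearman
    # target exactly while bounding |effect| away from zero so planted
    # regions are detectable at any coupling strength
    effects <- sign(z) * (0.5 + abs(z)) * effect_size
    names(effects) <- coupled_genes
  }
  n_target <- floor(region_fraction * n_genes)
  pool <- setdiff(genes, coupled_genes)
  n_extra <- max(0L, n_target - length(coupled_genes))
  extra <- if (n_extra > 0) sample(pool, min(n_extra, length(pool))) else character(0)
  extra_eff <- stats::setNames(
    sample(c(-1, 1), length(extra), replace = TRUE) * effect_size, extra)
  region_genes <- c(coupled_genes, extra)
  effects <- c(effects, extra_eff)

  ## --- persistence layout --------------------------------------------
  n_t5 <- length(region_genes)
  n_pers <- floor(persistence_fraction * n_t5)
  persistent <- if (n_pers > 0) sample(region_genes, n_pers) else character(0)
  null_pool <- setdiff(genes, region_genes)
  n_new <- min(n_t5 - n_pers, length(null_pool))
  new_r3 <- if (n_new > 0) sample(null_pool, n_new) else character(0)
  new_eff <- stats::setNames(
    sample(c(-1, 1), length(new_r3), replace = TRUE) * effect_size, new_r3)

  ## --- build signals ---------------------------------------------------
  n_probes <- nrow(probes)
  affinity <- stats::rnorm(n_probes, 0, 0.3)  # probe-specific offset
  sig <- matrix(stats::rnorm(n_probes * nrow(design), 0, noise_sd),
                nrow = n_probes) + affinity
  dimnames(sig) <- list(probes$probe_id, design$sample_id)

  region_probe_idx <- function(gene) {
    idx <- which(probes$gene == gene)
    w <- min(region_width_probes, length(idx))
    off <- (length(idx) - w) %/% 2
    idx[(off + 1):(off + w)]
  }
  add_effect <- function(gene, eff, tps) {
    cols <- design$sample_id[design$treatment != control &
                               design$timepoint %in% tps]
    idx <- region_probe_idx(gene)
    sig[idx, cols] <<- sig[idx, cols] + eff
    idx
  }

  epi_regions <- list()
  for (g in region_genes) {
    tps <- if (g %in% persistent) timepoints else dosing
    idx <- add_effect(g, effects[[g]], tps)
    epi_regions[[g]] <- list(
      layer = layer,
      timepoints = stats::setNames(
        lapply(tps, function(tp) list(direction = ifelse(effects[[g]] > 0, "+", "-"),
                                      effect = effects[[g]])), tps),
      extent_bp = probes$end[idx[length(idx)]] - probes$start[idx[1]] + 1)
  }
  for (g in new_r3) {
    idx <- add_effect(g, new_eff[[g]], recovery)
    epi_regions[[g]] <- list(
      layer = layer,
      timepoints = stats::setNames(
        lapply(recovery, function(tp) list(direction = ifelse(new_eff[[g]] > 0, "+", "-"),
                                           effect = new_eff[[g]])), recovery),
      extent_bp = probes$end[idx[length(idx)]] - probes$start[idx[1]] + 1)
  }

  truth <- structure(list(
    de_genes = if (is.null(ge_truth)) list() else ge_truth$de_genes,
    epi_regions = epi_regions,
    persistence_set = sort(persistent),
    region_genes = sort(region_genes),
    r3_only_genes = sort(new_r3),
    coupling_rho = coupling_rho,
    seed = as.integer(seed)), class = "sim_truth")

  list(track = tiling_track(probes, sig, gene_promoters, design),
       truth = truth)
}

# Gaussian-copula rank coupling: returns standard-normal effect values whose
# Spearman correlation with `x` targets rho (Pearson latent r = 2 sin(pi rho/6)).
rank_couple <- function(x, rho) {
  n <- length(x)
  r <- 2 * sin(pi * rho / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  # pair the k-th smallest x with the k-th smallest z1's partner
  z2[order(z1)][rank(x, ties.method = "first")]
}

#' Construct a tiling track
#'
#' @param probes data.frame `chrom`, `start`, `end`, `probe_id`, `gene`,
#'   1-based inclusive, sorted by (chrom, start) within each promoter.
#' @param signals Numeric matrix probes x samples (log2 scale), rownames =
#'   probe ids, colnames = design sample ids.
#' @param promoters data.frame `gene`, `chrom`, `start`, `end`.
#' @param design A `study_design`.
#' @export
tiling_track <- function(probes, signals, promoters, design) {
  validate_design(design)
  stopifnot(all(c("chrom", "start", "end", "probe_id", "gene") %in% names(probes)),
            identical(rownames(signals), probes$probe_id))
  missing_cols <- setdiff(design$sample_id, colnames(signals))
  if (length(missing_cols))
    stop("signals missing design samples: ", paste(missing_cols, collapse = ", "))
  signals <- signals[, design$sample_id, drop = FALSE]
  ord <- order(probes$chrom, probes$start)
  probes <- probes[ord, , drop = FALSE]
  signals <- signals[ord, , drop = FALSE]
  structure(list(probes = probes, signals = signals,
                 promoters = promoters, design = design),
            class = "tiling_track")
}

#' @export
print.tiling_track <- function(x, ...) {
  cat("tiling_track:", nrow(x$probes), "probes over",
      length(unique(x$probes$gene)), "promoters,",
      ncol(x$signals), "samples\n")
  invisible(x)
}
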