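#' Default pipeline configuration
#'
#' All analysis defaults mirror the windowed promoter-array convention
#' (7-probe / 750 bp windows at FDR < 0.01), the mRNA raw-p 0.001 and
#' miRNA FDR 0.05 reporting cutoffs, the 0.58 |LFC| concordance filter,
#' Sidak posttests and 3 biological replicates.
#'
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param ... Overrides for any default element.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    treatments = c("control", "OTA", "KBrO3"),
    timepoints = c("T1", "T3", "T5", "R3"),
    n_reps = 3,
    synthetic = list(
      n_genes = 2000, de_fraction = 0.1,
      d0 = 4, s0_sq = 0.02,
      n_mirna = 300, mirna_de_fraction = 0.05,
      tiling_genes = 2000, region_fraction = 0.1, effect_size = 1,
      persistence_fraction = 0.3, coupling_rho = 0.75,
      probes_per_promoter = 20, probe_spacing_bp = 100,
      n_metabolites = 40, drift_amplitude = 0.3, qc_every = 10),
    cutoffs = list(mrna_p = 0.001, mirna_fdr = 0.05, tiling_fdr = 0.01,
                   concordance_lfc = 0.58),
    windows = list(n_probes = 7, max_span_bp = 750),
    qc_rlsc_span = 0.75,
    posttest = "sidak",
    positive_control = "KBrO3",
    test_treatment = "OTA")
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
    else cfg[[nm]] <- overrides[[nm]]
  }
  with(cfg$cutoffs, stopifnot(mrna_p > 0, mrna_p <= 1, mirna_fdr > 0,
                              mirna_fdr <= 1, tiling_fdr > 0, tiling_fdr <= 1))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration (YAML, JSON fallback)
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, c(list(seed = cfg$seed %||% 1L),
                             cfg[setdiff(names(cfg), "seed")]))
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(unclass(config), path)
  else
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic-data pipeline
#'
#' Simulation -> differential expression (mRNA, miRNA) -> tiling region
#' calls (HA, DM) -> QC-RLSC metabolomics -> integration, writing every
#' intermediate table, a provenance manifest (config hash + seeds) and a
#' Markdown report to `out_dir`. Deterministic: the same config yields
#' byte-identical outputs.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results.
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed
  syn <- config$synthetic
  log_msg <- function(...) message("[run_all] ", ...)

  log_msg("simulate")
  design <- stage("simulate", generate_design(
    config$treatments, config$timepoints, config$n_reps, seed = seed))
  expr <- stage("simulate", simulate_expression(
    design, n_genes = syn$n_genes, de_fraction = syn$de_fraction,
    effect_size_dist = function(n) sample(c(-1, 1), n, TRUE) *
      stats::runif(n, 0.5, 2),
    d0 = syn$d0, s0_sq = syn$s0_sq, seed = seed + 1L))
  mirna <- stage("simulate", simulate_expression(
    design, n_genes = syn$n_mirna, de_fraction = syn$mirna_de_fraction,
    d0 = syn$d0, s0_sq = syn$s0_sq, seed = seed + 2L))
  rownames(mirna$matrix) <- sub("^gene", "mir", rownames(mirna$matrix))
  names(mirna$truth$de_genes) <- sub("^gene", "mir",
                                     names(mirna$truth$de_genes))
  ha <- stage("simulate", simulate_tiling(
    design, gene_promoters = syn$tiling_genes,
    probes_per_promoter = syn$probes_per_promoter,
    probe_spacing_bp = syn$probe_spacing_bp,
    region_fraction = syn$region_fraction, effect_size = syn$effect_size,
    persistence_fraction = syn$persistence_fraction,
    coupling_rho = syn$coupling_rho, ge_truth = expr$truth,
    layer = "HA", seed = seed + 3L))
  dm <- stage("simulate", simulate_tiling(
    design, gene_promoters = syn$tiling_genes,
    probes_per_promoter = syn$probes_per_promoter,
    probe_spacing_bp = syn$probe_spacing_bp,
    region_fraction = syn$region_fraction / 2,
    effect_size = syn$effect_size,
    persistence_fraction = syn$persistence_fraction,
    layer = "DM", seed = seed + 4L))
  metab <- stage("simulate", simulate_metabolomics(
    design, n_metabolites = syn$n_metabolites,
    drift_amplitude = syn$drift_amplitude, qc_every = syn$qc_every,
    seed = seed + 5L))

  log_msg("diff-expr")
  de <- stage("diff-expr", diff_all_contrasts(
    quantile_normalize(expr$matrix), design))
  de_mirna <- stage("diff-expr", diff_all_contrasts(
    quantile_normalize(mirna$matrix), design))

  log_msg("diff-tiling")
  w <- config$windows
  ha_calls <- stage("diff-tiling", regions_all_contrasts(
    ha$track, "HA", config$cutoffs$tiling_fdr, w$n_probes, w$max_span_bp))
  dm_calls <- stage("diff-tiling", regions_all_contrasts(
    dm$track, "DM", config$cutoffs$tiling_fdr, w$n_probes, w$max_span_bp))

  log_msg("metab")
  corrected <- stage("metab", qc_rlsc(metab$run, config$qc_rlsc_span))
  met_lfc <- stage("metab", metabolite_lfc(corrected))
  met_tests <- stage("metab", metab_posttests(corrected, config$posttest))
  met_table <- merge(met_lfc, met_tests,
                     by = c("metabolite", "treatment", "timepoint"),
                     all.x = TRUE, sort = TRUE)

  log_msg("integrate")
  records <- stage("integrate", integration_records(de, ha_calls, dm_calls))
  counts <- stage("integrate", impact_counts(de, rbind(ha_calls, dm_calls),
                                             de_mirna))
  cor_tab <- stage("integrate", correlation_table(
    records, treatments = setdiff(config$treatments, config$treatments[1]),
    timepoints = config$timepoints,
    ge_p_cutoff = config$cutoffs$mrna_p))
  pers_list <- list(); conc_list <- list()
  for (tr in setdiff(config$treatments, config$treatments[1])) {
    for (ly in c("HA", "DM")) {
      calls <- if (ly == "HA") ha_calls else dm_calls
      p <- persistence(calls[calls$treatment == tr & calls$timepoint == "T5", ],
                       calls[calls$treatment == tr & calls$timepoint == "R3", ])
      pers_list[[paste(tr, ly)]] <- p
      if (ly == "HA") {
        pg <- unlist(attr(p, "persistent_genes"), use.names = FALSE)
        pc <- calls[calls$treatment == tr & calls$timepoint == "R3" &
                      calls$gene %in% pg, ]
        conc_list[[tr]] <- concordance(
          pc, de[de$treatment == tr & de$timepoint == "R3", ],
          lfc_cutoff = config$cutoffs$concordance_lfc,
          ge_p_cutoff = config$cutoffs$mrna_p)
      }
    }
  }
  pers_tab <- do.call(rbind, c(pers_list, make.row.names = FALSE))
  # synthetic stress pathway: planted positives plus unaffected genes
  pathway <- sort(c(utils::head(names(expr$truth$de_genes), 15),
                    utils::head(setdiff(de$gene[de$timepoint == "T1"],
                                        names(expr$truth$de_genes)), 5)))
  ranking <- stage("integrate", rank_pathway(
    de, pathway, config$positive_control, config$test_treatment,
    setdiff(config$timepoints, attr(design, "recovery_timepoints")),
    p_cutoff = config$cutoffs$mrna_p))
  overlap <- stage("integrate", mirna_overlap(
    de_mirna, config$positive_control, "T5", config$test_treatment))

  log_msg("write outputs")
  out <- function(f) file.path(out_dir, f)
  write_design_tsv(design, out("design.tsv"))
  write_matrix_tsv(expr$matrix, out("expression.tsv"))
  write_matrix_tsv(mirna$matrix, out("mirna.tsv"))
  write_tiling_track(ha$track, out("ha_probes.gff3"), out("ha_signals.tsv"),
                     out("promoters.bed"))
  write_tiling_track(dm$track, out("dm_probes.gff3"), out("dm_signals.tsv"))
  write_metabolomics_csv(metab$run, out("metabolomics_raw.csv"))
  write_metabolomics_csv(corrected, out("metabolomics_corrected.csv"))
  write_calls_tsv(de, out("de_mrna.tsv"))
  write_calls_tsv(de_mirna, out("de_mirna.tsv"))
  write_calls_tsv(ha_calls, out("regions_ha.tsv"))
  write_calls_tsv(dm_calls, out("regions_dm.tsv"))
  write_calls_tsv(met_table, out("metabolite_lfc.tsv"))
  write_calls_tsv(counts, out("impact_counts.tsv"))
  write_calls_tsv(cor_tab, out("correlation.tsv"))
  write_calls_tsv(pers_tab, out("persistence.tsv"))
  write_calls_tsv(ranking, out("pathway_ranking.tsv"))
  write_truth_json(expr$truth, out("truth_expression.json"))
  write_truth_json(ha$truth, out("truth_ha.json"))

  cfg_path <- out("config.json")
  write_config(config, cfg_path)
  manifest <- list(
    package = "washomics",
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  res <- list(design = design, de = de, de_mirna = de_mirna,
              ha_calls = ha_calls, dm_calls = dm_calls,
              metab_table = met_table, counts = counts,
              correlation = cor_tab, persistence = pers_tab,
              concordance = conc_list, ranking = ranking, overlap = overlap,
              truth = list(expr = expr$truth, mirna = mirna$truth,
                           ha = ha$truth, dm = dm$truth,
                           metab = metab$truth))
  write_report(res, out("report.md"))
  invisible(res)
}

# per-metabolite two-way ANOVA + posttest on log2 corrected areas
metab_posttests <- function(run, method = "sidak") {
  design <- run$design
  inj <- run$injections
  smp <- which(!inj$is_qc)
  ids <- inj$sample_id[smp]
  i <- match(ids, design$sample_id)
  trt <- factor(design$treatment[i], levels = attr(design, "treatments"))
  tim <- factor(design$timepoint[i], levels = attr(design, "timepoints"))
  rows <- list()
  for (m in rownames(run$peak_areas)) {
    v <- log2(run$peak_areas[m, smp])
    pt <- two_way_anova_posttest(v, trt, tim, method = method)
    rows[[m]] <- cbind(metabolite = m,
                       pt[, c("treatment", "timepoint", "p_adj", "significant")])
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Validate on-disk input formats
#'
#' Light-weight structural checks with line numbers: GFF3 probe files
#' (1-based, start <= end, 9 columns), BED promoter maps (0-based
#' half-open, start < end), matrix-vs-design sample agreement, and
#' injection-order monotonicity of metabolomics CSVs. Unreadable files
#' yield fail entries, not exceptions.
#'
#' @param gff3,bed,matrix,design,metab Optional file paths; `matrix` is
#'   checked against `design` when both are given.
#' @return data.frame `file`, `check`, `pass`, `detail`.
#' @export
validate_formats <- function(gff3 = NULL, bed = NULL, matrix = NULL,
                             design = NULL, metab = NULL) {
  res <- list()
  add <- function(file, check, pass, detail = "") {
    res[[length(res) + 1]] <<- data.frame(
      file = file, check = check, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  try_read <- function(path, what) {
    tryCatch(readLines(path, warn = FALSE), error = function(e) {
      add(path, what, FALSE, paste("unreadable:", conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(gff3)) {
    ln <- try_read(gff3, "gff3")
    if (!is.null(ln)) {
      body <- which(!startsWith(ln, "#") & nzchar(ln))
      bad <- body[vapply(ln[body], function(l) {
        f <- strsplit(l, "\t")[[1]]
        length(f) < 8 || is.na(suppressWarnings(as.integer(f[4]))) ||
          as.integer(f[4]) < 1 || as.integer(f[4]) > as.integer(f[5])
      }, logical(1))]
      add(gff3, "gff3 1-based coordinates", !length(bad),
          if (length(bad)) paste("line", bad[1]) else "")
    }
  }
  if (!is.null(bed)) {
    ln <- try_read(bed, "bed")
    if (!is.null(ln)) {
      body <- which(!startsWith(ln, "#") & !startsWith(ln, "track") & nzchar(ln))
      bad <- body[vapply(ln[body], function(l) {
        f <- strsplit(l, "\t")[[1]]
        length(f) < 3 || is.na(suppressWarnings(as.integer(f[2]))) ||
          as.integer(f[2]) < 0 || as.integer(f[2]) >= as.integer(f[3])
      }, logical(1))]
      add(bed, "bed half-open intervals", !length(bad),
          if (length(bad)) paste("line", bad[1]) else "")
    }
  }
  if (!is.null(matrix) && !is.null(design)) {
    ok <- tryCatch({
      m <- read_matrix_tsv(matrix)
      d <- read_design_tsv(design)
      extra <- setdiff(colnames(m), d$sample_id)
      add(matrix, "matrix samples in design", !length(extra),
          if (length(extra)) paste("unknown sample", extra[1]) else "")
      TRUE
    }, error = function(e) {
      add(matrix, "matrix samples in design", FALSE, conditionMessage(e))
      FALSE
    })
  }
  if (!is.null(metab)) {
    ok <- tryCatch({
      df <- suppressWarnings(utils::read.csv(metab, stringsAsFactors = FALSE))
      mono <- all(diff(df$injection_index) > 0)
      add(metab, "injection order strictly increasing", mono,
          if (!mono) paste("line", which(diff(df$injection_index) <= 0)[1] + 2)
          else "")
      TRUE
    }, error = function(e) {
      add(metab, "injection order strictly increasing", FALSE,
          conditionMessage(e))
      FALSE
    })
  }
  do.call(rbind, c(res, make.row.names = FALSE))
}

# Markdown summary report of a run_all result
write_report <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  tab <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    w(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"))
    apply(df, 1, function(r) w(paste("|", paste(r, collapse = " | "), "|")))
    w("")
  }
  w("# Repeat-dose / washout multi-omics report", "")
  w("## Impact counts (features affected per condition)", "")
  tab(res$counts)
  w("## Epigenome-transcriptome Spearman correlation", "")
  tab(res$correlation)
  w("## Post-washout persistence of epigenetic calls", "")
  tab(res$persistence)
  w("## Concordance of persistent HA marks with expression", "")
  for (tr in names(res$concordance)) {
    cc <- res$concordance[[tr]]
    w(sprintf("- %s: %d genes (%d consistent, %d inconsistent)", tr, nrow(cc),
              attr(cc, "n_consistent"), attr(cc, "n_inconsistent")))
  }
  w("", "## Stress pathway ranking (positive-control gated)", "")
  tab(res$ranking)
  w("## miRNA cross-treatment overlap", "")
  tab(res$overlap$overlap)
  invisible(path)
}
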