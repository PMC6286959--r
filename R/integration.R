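#' Per-condition impact counts across omics layers
#'
#' Counts the number of features affected per endpoint, treatment,
#' timepoint and direction: up/down-regulated genes (mRNA, raw p < 0.001
#' preset) and miRNAs (FDR < 0.05 preset), hyper/hypo acetylated or
#' methylated genes (windowed FDR < 0.01, direction by the median rule).
#'
#' @param de_calls `diff_calls` for mRNA (all contrasts; unfiltered).
#' @param region_calls Combined `region_calls` (HA and/or DM; already
#'   FDR-filtered by [call_regions()]).
#' @param mirna_calls Optional `diff_calls` for miRNA.
#' @param mrna_preset,mirna_preset Significance presets for [call_de()].
#' @return data.frame `endpoint`, `treatment`, `timepoint`, `direction`,
#'   `n`, with direction `+` (up/hyper) or `-` (down/hypo).
#' @export
impact_counts <- function(de_calls, region_calls = NULL, mirna_calls = NULL,
                          mrna_preset = "mrna_fig2", mirna_preset = "mirna") {
  count_tab <- function(df, endpoint) {
    if (is.null(df) || !nrow(df))
      return(NULL)
    ag <- stats::aggregate(list(n = rep(1L, nrow(df))),
                           by = list(treatment = df$treatment,
                                     timepoint = df$timepoint,
                                     direction = df$direction), FUN = sum)
    ag <- ag[ag$direction %in% c("+", "-"), , drop = FALSE]
    if (!nrow(ag)) return(NULL)
    cbind(endpoint = endpoint, ag)
  }
  pieces <- list(count_tab(call_de(de_calls, preset = mrna_preset), "mRNA"))
  if (!is.null(mirna_calls))
    pieces <- c(pieces, list(count_tab(call_de(mirna_calls, preset = mirna_preset),
                                       "miRNA")))
  if (!is.null(region_calls) && nrow(region_calls))
    for (ly in unique(region_calls$layer))
      pieces <- c(pieces, list(
        count_tab(region_calls[region_calls$layer == ly, ], ly)))
  out <- do.call(rbind, c(pieces, make.row.names = FALSE))
  if (is.null(out))
    out <- data.frame(endpoint = character(0), treatment = character(0),
                      timepoint = character(0), direction = character(0),
                      n = integer(0))
  out[order(out$endpoint, out$treatment, out$timepoint, out$direction), ,
      drop = FALSE]
}

#' Gene-level integration records
#'
#' Merges expression differential calls with epigenetic region calls into
#' one row per (gene, treatment, timepoint): expression LFC/p/FDR plus the
#' HA and DM direction and score where a region was called.
#'
#' @param de_calls `diff_calls` (mRNA, unfiltered: every gene/contrast).
#' @param ha_calls,dm_calls `region_calls` for the two epigenetic layers.
#' @return data.frame with columns `gene`, `treatment`, `timepoint`,
#'   `ge_lfc`, `ge_p`, `ge_fdr`, `ha_direction`, `ha_score`,
#'   `dm_direction`, `dm_score` (epigenetic fields `NA` when no call).
#' @export
integration_records <- function(de_calls, ha_calls = NULL, dm_calls = NULL) {
  rec <- data.frame(gene = de_calls$gene, treatment = de_calls$treatment,
                    timepoint = de_calls$timepoint, ge_lfc = de_calls$lfc,
                    ge_p = de_calls$p, ge_fdr = de_calls$fdr,
                    stringsAsFactors = FALSE)
  add_layer <- function(rec, calls, prefix) {
    dcol <- paste0(prefix, "_direction"); scol <- paste0(prefix, "_score")
    if (is.null(calls) || !nrow(calls)) {
      rec[[dcol]] <- NA_character_; rec[[scol]] <- NA_real_
      return(rec)
    }
    key <- paste(rec$gene, rec$treatment, rec$timepoint)
    ckey <- paste(calls$gene, calls$treatment, calls$timepoint)
    i <- match(key, ckey)
    rec[[dcol]] <- calls$direction[i]
    rec[[scol]] <- calls$score[i]
    rec
  }
  rec <- add_layer(rec, ha_calls, "ha")
  add_layer(rec, dm_calls, "dm")
}

#' Spearman correlation between epigenetic scores and expression changes
#'
#' For one layer, treatment and timepoint, correlates the gene-level
#' epigenetic region score with the expression log2 fold change over the
#' genes carrying both a significant expression call and an epigenetic
#' region call (or all epigenetically called genes when
#' `universe = "epi"`). P-values follow the exact Spearman null
#' distribution for n <= 9 without ties and the t-approximation otherwise.
#'
#' @param records Output of [integration_records()].
#' @param layer `"ha"` or `"dm"`.
#' @param treatment,timepoint The condition.
#' @param universe `"both"` (DE and epi call required; default) or
#'   `"epi"` (all epigenetically called genes).
#' @param ge_p_cutoff Expression significance cutoff for `universe="both"`.
#' @return List `rho`, `p`, `n`, `stars`; `NULL` (with a message) when
#'   fewer than 4 genes qualify.
#' @export
correlate_epi_ge <- function(records, layer = c("ha", "dm"), treatment,
                             timepoint, universe = c("both", "epi"),
                             ge_p_cutoff = 0.001) {
  layer <- match.arg(layer)
  universe <- match.arg(universe)
  scol <- paste0(layer, "_score")
  sel <- records$treatment == treatment & records$timepoint == timepoint &
    !is.na(records[[scol]])
  if (universe == "both") sel <- sel & records$ge_p < ge_p_cutoff
  d <- records[sel, , drop = FALSE]
  if (nrow(d) < 4) {
    message("correlate_epi_ge: only ", nrow(d),
            " gene(s) with both calls; no result")
    return(NULL)
  }
  spearman_rho(d$ge_lfc, d[[scol]])
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Average-rank ties; two-sided p from the exact Spearman null
#' distribution for n <= 9 without ties, t-approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List `rho`, `p`, `n`, `stars`.
#' @examples
#' spearman_rho(c(1, 2, 3), c(3, 1, 2))$rho  # -0.5
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  ct <- suppressWarnings(stats::cor.test(
    x, y, method = "spearman", exact = n <= 9, alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       stars = p_stars(ct$p.value))
}

#' Spearman coupling table across layers and timepoints
#'
#' @inheritParams correlate_epi_ge
#' @param layers,treatments,timepoints Conditions to tabulate (defaults:
#'   both layers, all test treatments/timepoints present in `records`).
#' @return data.frame `layer`, `treatment`, `timepoint`, `rho`, `p`, `n`,
#'   `stars` (rows with < 4 genes carry `NA`).
#' @export
correlation_table <- function(records, layers = c("ha", "dm"),
                              treatments = NULL, timepoints = NULL,
                              universe = "both", ge_p_cutoff = 0.001) {
  if (is.null(treatments)) treatments <- unique(records$treatment)
  if (is.null(timepoints)) timepoints <- unique(records$timepoint)
  rows <- list()
  for (ly in layers) for (tr in treatments) for (tp in timepoints) {
    r <- suppressMessages(
      correlate_epi_ge(records, ly, tr, tp, universe, ge_p_cutoff))
    rows[[paste(ly, tr, tp)]] <- data.frame(
      layer = toupper(ly), treatment = tr, timepoint = tp,
      rho = if (is.null(r)) NA_real_ else r$rho,
      p = if (is.null(r)) NA_real_ else r$p,
      n = if (is.null(r)) 0L else r$n,
      stars = if (is.null(r)) "" else r$stars,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Post-washout persistence of epigenetic calls
#'
#' For each direction, the fraction of recovery-phase (R3) region calls
#' that were already present on the last treatment day (T5) with the same
#' direction -- epigenetic marks surviving compound washout.
#'
#' @param calls_t5,calls_r3 `region_calls` of one layer and treatment at
#'   the two timepoints.
#' @return data.frame per direction: `layer`, `treatment`, `direction`,
#'   `n_R3`, `n_persistent`, `pct_persistent` (0 when `n_R3` = 0);
#'   attribute `persistent_genes` maps direction -> gene set.
#' @export
persistence <- function(calls_t5, calls_r3) {
  layer <- unique(c(calls_t5$layer, calls_r3$layer))
  treatment <- unique(c(calls_t5$treatment, calls_r3$treatment))
  if (length(layer) > 1 || length(treatment) > 1)
    stop("call sets must come from one layer and one treatment")
  genes_dir <- function(calls, d) unique(calls$gene[calls$direction == d])
  per_dir <- list()
  for (d in c("+", "-")) {
    r3 <- genes_dir(calls_r3, d)
    t5 <- genes_dir(calls_t5, d)
    pers <- intersect(r3, t5)
    per_dir[[d]] <- list(
      row = data.frame(layer = if (length(layer)) layer else NA,
                       treatment = if (length(treatment)) treatment else NA,
                       direction = d, n_R3 = length(r3),
                       n_persistent = length(pers),
                       pct_persistent =
                         if (length(r3)) 100 * length(pers) / length(r3) else 0,
                       stringsAsFactors = FALSE),
      genes = sort(pers))
  }
  out <- do.call(rbind, c(lapply(per_dir, `[[`, "row"),
                          make.row.names = FALSE))
  attr(out, "persistent_genes") <- lapply(per_dir, `[[`, "genes")
  out
}

#' Concordance of persistent histone marks with expression direction
#'
#' Restricts to genes with a persistent mark (same direction at T5 and R3)
#' whose mRNA is significantly altered at R3 with |LFC| at or above the
#' cutoff, and labels each gene consistent -- up-regulated with a hyper
#' mark or down-regulated with a hypo mark -- or inconsistent.
#'
#' @param persistent_calls `region_calls` rows at R3 restricted to the
#'   persistent genes (direction column used as the mark direction).
#' @param ge_calls_r3 `diff_calls` at R3 for the same treatment
#'   (unfiltered; significance applied here).
#' @param lfc_cutoff Minimum |expression LFC| (default 0.58, i.e. 1.5-fold).
#' @param ge_p_cutoff Expression significance cutoff (raw p, default 0.001).
#' @return data.frame `gene`, `ge_lfc`, `mark_direction`, `consistent`;
#'   counts in attributes `n_consistent`, `n_inconsistent`.
#' @export
concordance <- function(persistent_calls, ge_calls_r3, lfc_cutoff = 0.58,
                        ge_p_cutoff = 0.001) {
  ge <- ge_calls_r3[ge_calls_r3$p < ge_p_cutoff &
                      abs(ge_calls_r3$lfc) >= lfc_cutoff, , drop = FALSE]
  i <- match(persistent_calls$gene, ge$gene)
  keep <- !is.na(i)
  out <- data.frame(
    gene = persistent_calls$gene[keep],
    ge_lfc = ge$lfc[i[keep]],
    mark_direction = persistent_calls$direction[keep],
    stringsAsFactors = FALSE)
  out$consistent <- (out$ge_lfc > 0 & out$mark_direction == "+") |
    (out$ge_lfc < 0 & out$mark_direction == "-")
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_consistent") <- sum(out$consistent)
  attr(out, "n_inconsistent") <- sum(!out$consistent)
  out
}

#' Positive-control-gated stress pathway ranking
#'
#' For a pathway gene list, computes each gene's average expression LFC
#' over the treatment timepoints for the positive-control and the test
#' compound, removes genes never significantly modulated by the positive
#' control at any treatment timepoint, and ranks the rest by the test
#' compound's average LFC (descending).
#'
#' @param de_calls `diff_calls` covering both treatments (unfiltered).
#' @param pathway_genes Character vector of gene symbols. Example lists
#'   for the oxidative-stress (Nrf2), DNA-damage (p53) and unfolded
#'   protein response pathways ship under
#'   `system.file("extdata", package = "washomics")` (one symbol per
#'   line).
#' @param positive_control,test_treatment Treatment labels.
#' @param treatment_timepoints Timepoints averaged (default T1, T3, T5).
#' @param p_cutoff Significance gate for the positive control (raw p).
#' @return data.frame `gene`, per-timepoint LFCs for the test compound,
#'   `avg_control`, `avg_test`, sorted descending by `avg_test`. Pathway
#'   genes absent from the calls are retained with `NA` values at the
#'   bottom (flagged via the `missing` column).
#' @export
rank_pathway <- function(de_calls, pathway_genes, positive_control,
                         test_treatment,
                         treatment_timepoints = c("T1", "T3", "T5"),
                         p_cutoff = 0.001) {
  stopifnot(length(pathway_genes) > 0)
  for (tr in c(positive_control, test_treatment))
    if (!any(de_calls$treatment == tr))
      stop("treatment absent from calls: ", tr)
  sub <- de_calls[de_calls$gene %in% pathway_genes &
                    de_calls$timepoint %in% treatment_timepoints, , drop = FALSE]
  rows <- lapply(pathway_genes, function(g) {
    gc <- sub[sub$gene == g, , drop = FALSE]
    if (!nrow(gc)) {
      message("rank_pathway: pathway gene absent from calls: ", g)
      r <- data.frame(gene = g, avg_control = NA_real_, avg_test = NA_real_,
                      gated_out = NA, missing = TRUE, stringsAsFactors = FALSE)
      for (tp in treatment_timepoints) r[[paste0("lfc_", tp)]] <- NA_real_
      return(r)
    }
    ctl <- gc[gc$treatment == positive_control, ]
    tst <- gc[gc$treatment == test_treatment, ]
    r <- data.frame(gene = g,
                    avg_control = mean(ctl$lfc),
                    avg_test = mean(tst$lfc),
                    gated_out = !any(ctl$p < p_cutoff),
                    missing = FALSE, stringsAsFactors = FALSE)
    for (tp in treatment_timepoints)
      r[[paste0("lfc_", tp)]] <- if (any(tst$timepoint == tp))
        tst$lfc[tst$timepoint == tp][1] else NA_real_
    r
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  kept <- out[!out$missing & !out$gated_out, , drop = FALSE]
  kept <- kept[order(-kept$avg_test), , drop = FALSE]
  miss <- out[out$missing, , drop = FALSE]
  out <- rbind(kept, miss)
  rownames(out) <- NULL
  out
}

#' Cross-treatment miRNA overlap
#'
#' Takes the miRNAs significant for a reference treatment at a reference
#' timepoint and tabulates their LFC and significance across every
#' timepoint of the other treatment, plus per-timepoint intersection
#' sizes.
#'
#' @param mirna_calls `diff_calls` for miRNA covering >= 2 treatments
#'   (unfiltered).
#' @param ref_treatment,ref_timepoint The reference condition.
#' @param other_treatment The compared treatment.
#' @param preset Significance preset (default `"mirna"`, FDR < 0.05).
#' @return List: `table` (one row per reference miRNA x other timepoint:
#'   `mirna`, `timepoint`, `lfc`, `fdr`, `significant`, `direction`) and
#'   `overlap` (per timepoint: `n_ref`, `n_other`, `n_shared`).
#' @export
mirna_overlap <- function(mirna_calls, ref_treatment, ref_timepoint,
                          other_treatment, preset = "mirna") {
  if (length(unique(mirna_calls$treatment)) < 2)
    stop("need calls for >= 2 treatments")
  sig <- call_de(mirna_calls, preset = preset)
  ref <- unique(sig$feature[sig$treatment == ref_treatment &
                              sig$timepoint == ref_timepoint])
  other <- mirna_calls[mirna_calls$treatment == other_treatment, , drop = FALSE]
  timepoints <- unique(other$timepoint)
  tab <- list(); ov <- list()
  for (tp in timepoints) {
    ot <- other[other$timepoint == tp, , drop = FALSE]
    osig <- unique(sig$feature[sig$treatment == other_treatment &
                                 sig$timepoint == tp])
    i <- match(ref, ot$feature)
    if (length(ref))
      tab[[tp]] <- data.frame(
        mirna = ref, timepoint = tp,
        lfc = ot$lfc[i], fdr = ot$fdr[i],
        significant = ref %in% osig,
        direction = ifelse(is.na(ot$lfc[i]), NA,
                           ifelse(ot$lfc[i] > 0, "+", "-")),
        stringsAsFactors = FALSE)
    ov[[tp]] <- data.frame(timepoint = tp, n_ref = length(ref),
                           n_other = length(osig),
                           n_shared = length(intersect(ref, osig)),
                           stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, c(tab, make.row.names = FALSE)),
       overlap = do.call(rbind, c(ov, make.row.names = FALSE)))
}
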