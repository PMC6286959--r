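#' Sliding probe windows within promoters
#'
#' Enumerates every run of `n_probes` consecutive probes inside one
#' promoter whose genomic span (last end - first start + 1, 1-based
#' inclusive) does not exceed `max_span_bp`, advancing by `step` probes.
#' Windows never cross promoter boundaries. The defaults implement the
#' classic 750 bp / 7-probe windowed analysis of NimbleGen promoter
#' tiling arrays.
#'
#' @param track A `tiling_track`.
#' @param n_probes Probes per window (>= 2).
#' @param max_span_bp Maximum genomic span of a window.
#' @param step Probe increment between consecutive windows.
#' @return data.frame `window_id`, `gene`, `first` and `last` (row indices
#'   into `track$probes`), `span_bp`. Promoters with fewer than `n_probes`
#'   probes contribute no windows (message emitted).
#' @export
make_windows <- function(track, n_probes = 7, max_span_bp = 750, step = 1) {
  stopifnot(inherits(track, "tiling_track"), n_probes >= 2, step >= 1)
  probes <- track$probes
  res <- list()
  short <- 0L
  idx_by_gene <- split(seq_len(nrow(probes)), probes$gene)
  for (g in unique(probes$gene)) {
    idx <- idx_by_gene[[g]]
    if (length(idx) < n_probes) { short <- short + 1L; next }
    starts <- seq(1L, length(idx) - n_probes + 1L, by = step)
    first <- idx[starts]
    last <- idx[starts + n_probes - 1L]
    span <- probes$end[last] - probes$start[first] + 1L
    keep <- span <= max_span_bp
    if (!any(keep)) next
    res[[g]] <- data.frame(gene = g, first = first[keep], last = last[keep],
                           span_bp = span[keep], stringsAsFactors = FALSE)
  }
  if (short > 0)
    message("make_windows: ", short, " promoter(s) with < ", n_probes,
            " probes yield no windows")
  if (!length(res))
    return(data.frame(window_id = character(0), gene = character(0),
                      first = integer(0), last = integer(0),
                      span_bp = integer(0)))
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out$window_id <- sprintf("%s_w%03d", out$gene,
                           stats::ave(seq_len(nrow(out)), out$gene,
                                      FUN = seq_along))
  out[, c("window_id", "gene", "first", "last", "span_bp")]
}

#' One-way ANOVA on per-array window means
#'
#' Each array's window value is the mean of its probe signals over the
#' window; the ANOVA compares treatment arrays against control arrays
#' (arrays are the biological replicates, not probes). With two groups
#' \eqn{F = t^2} and the p-value equals the two-sample pooled t-test's.
#'
#' @param window_signals Numeric matrix, probes-in-window x samples.
#' @param treatment_samples,control_samples Column names of the two groups
#'   (>= 2 each).
#' @return List `F`, `p`, `mean_diff` (treatment minus control on window
#'   means), `degenerate` (TRUE when within-group variance is zero with a
#'   nonzero between-group difference; then p = 0 by convention, while
#'   identical groups give F = 0, p = 1).
#' @export
window_anova <- function(window_signals, treatment_samples, control_samples) {
  stopifnot(length(treatment_samples) >= 2, length(control_samples) >= 2)
  m <- colMeans(window_signals[, c(treatment_samples, control_samples),
                               drop = FALSE])
  grp <- rep(c("t", "c"), c(length(treatment_samples), length(control_samples)))
  anova_groups(m, grp)
}

# one-way ANOVA on a vector with group labels; handles the degenerate cases
anova_groups <- function(y, grp) {
  grp <- as.factor(grp)
  k <- nlevels(grp)
  n <- length(y)
  gm <- tapply(y, grp, mean)
  gn <- tapply(y, grp, length)
  ssb <- sum(gn * (gm[levels(grp)] - mean(y))^2)
  ssw <- sum((y - gm[grp])^2)
  df1 <- k - 1; df2 <- n - k
  mean_diff <- if (k == 2) unname(gm["t"] - gm["c"]) else NA_real_
  if (ssw <= .Machine$double.eps * sum(y^2)) {
    if (ssb <= .Machine$double.eps * max(1, sum(y^2)))
      return(list(F = 0, p = 1, mean_diff = mean_diff, degenerate = FALSE))
    message("window_anova: zero within-group variance with nonzero difference")
    return(list(F = Inf, p = 0, mean_diff = mean_diff, degenerate = TRUE))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       mean_diff = mean_diff, degenerate = FALSE)
}

# vectorized two-group pooled F over many windows (rows of win_means matrices)
window_f_vec <- function(w1, w2) {
  n1 <- ncol(w1); n2 <- ncol(w2)
  m1 <- rowMeans(w1); m2 <- rowMeans(w2)
  ssw <- rowSums((w1 - m1)^2) + rowSums((w2 - m2)^2)
  df2 <- n1 + n2 - 2
  se2 <- (ssw / df2) * (1 / n1 + 1 / n2)
  f <- (m1 - m2)^2 / se2
  zero_w <- ssw <= .Machine$double.eps * pmax(1, rowSums(w1^2) + rowSums(w2^2))
  zero_b <- abs(m1 - m2) <= .Machine$double.eps * pmax(1, abs(m1) + abs(m2))
  f[zero_w & zero_b] <- 0
  f[zero_w & !zero_b] <- Inf
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  p[zero_w & zero_b] <- 1
  p[zero_w & !zero_b] <- 0
  list(F = f, p = p, mean_diff = m1 - m2)
}

#' Gene-level direction by the median rule
#'
#' Sign of (median of the treatment signals minus median of the control
#' signals), pooling all probes of the gene and all arrays of each group;
#' `"0"` on an exact tie.
#'
#' @param gene_probe_signals Matrix probes x samples for one gene.
#' @param treatment_samples,control_samples Non-empty sample sets.
#' @return `"+"`, `"-"` or `"0"`.
#' @export
direction_by_median <- function(gene_probe_signals, treatment_samples,
                                control_samples) {
  if (!length(treatment_samples) || !length(control_samples))
    stop("empty sample group")
  d <- stats::median(gene_probe_signals[, treatment_samples]) -
    stats::median(gene_probe_signals[, control_samples])
  if (d > 0) "+" else if (d < 0) "-" else "0"
}

#' Differential region calling on a tiling track
#'
#' The windowed ANOVA pipeline: per-array window means for every sliding
#' window, a two-group ANOVA per window (treatment vs time-matched
#' control), Benjamini-Hochberg FDR across all windows of the contrast, and
#' gene-level collapse: a gene is called when at least one of its windows
#' passes the FDR threshold. The gene score is the median, over all probes
#' lying in the gene's significant windows, of (median treatment signal -
#' median control signal); its sign gives the hyper (+) / hypo (-)
#' direction.
#'
#' @param track A `tiling_track`.
#' @param treatment,timepoint The contrast versus time-matched control.
#' @param layer Label stored with the calls (`"HA"` or `"DM"`).
#' @param fdr_threshold Windowed FDR cutoff (default 0.01).
#' @param n_probes,max_span_bp,step Window parameters, see [make_windows()].
#' @return A `region_calls` data.frame: `gene`, `layer`, `treatment`,
#'   `timepoint`, `direction`, `score`, `best_window_p`, `fdr` (the
#'   smallest window FDR of the gene), one row per called gene. Attribute
#'   `n_windows` records how many windows were tested.
#' @export
call_regions <- function(track, treatment, timepoint, layer = "HA",
                         fdr_threshold = 0.01, n_probes = 7,
                         max_span_bp = 750, step = 1) {
  stopifnot(inherits(track, "tiling_track"))
  design <- track$design
  g1 <- design_samples(design, treatment, timepoint)
  g2 <- design_samples(design, attr(design, "control"), timepoint)
  win <- make_windows(track, n_probes, max_span_bp, step)
  empty <- data.frame(gene = character(0), layer = character(0),
                      treatment = character(0), timepoint = character(0),
                      direction = character(0), score = numeric(0),
                      best_window_p = numeric(0), fdr = numeric(0))
  class(empty) <- c("region_calls", "data.frame")
  if (!nrow(win)) {
    message("call_regions: no windows; empty call set")
    attr(empty, "n_windows") <- 0L
    return(empty)
  }
  sig <- track$signals
  # per-array window means, windows x samples; windows are contiguous probe
  # runs so cumulative sums give all window means in one pass
  wmean <- function(cols) {
    cs <- rbind(0, apply(sig[, cols, drop = FALSE], 2, cumsum))
    (cs[win$last + 1L, , drop = FALSE] - cs[win$first, , drop = FALSE]) /
      (win$last - win$first + 1L)
  }
  w1 <- wmean(g1); w2 <- wmean(g2)
  av <- window_f_vec(w1, w2)
  fdr <- bh_adjust(av$p)
  sig_win <- which(fdr < fdr_threshold)
  if (!length(sig_win)) {
    attr(empty, "n_windows") <- nrow(win)
    return(empty)
  }
  min_p_by_gene <- tapply(av$p, win$gene, min)
  calls <- lapply(split(sig_win, win$gene[sig_win]), function(ix) {
    probe_rows <- sort(unique(unlist(lapply(ix, function(i)
      win$first[i]:win$last[i]))))
    diffs <- apply(sig[probe_rows, g1, drop = FALSE], 1, stats::median) -
      apply(sig[probe_rows, g2, drop = FALSE], 1, stats::median)
    score <- stats::median(diffs)
    g <- win$gene[ix[1]]
    data.frame(gene = g, layer = layer,
               treatment = treatment, timepoint = timepoint,
               direction = if (score > 0) "+" else if (score < 0) "-" else "0",
               score = score,
               best_window_p = unname(min_p_by_gene[g]),
               fdr = min(fdr[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(calls, make.row.names = FALSE))
  out <- out[out$direction != "0", , drop = FALSE]  # exact-tie score: no direction
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_calls", "data.frame")
  attr(out, "n_windows") <- nrow(win)
  out
}

#' Region calls for every test contrast of a design
#'
#' @inheritParams call_regions
#' @param treatments,timepoints Optional subsets.
#' @return Combined `region_calls` across all test contrasts (BH applied
#'   per contrast, matching the per-dataset windowed analysis).
#' @export
regions_all_contrasts <- function(track, layer = "HA", fdr_threshold = 0.01,
                                  n_probes = 7, max_span_bp = 750, step = 1,
                                  treatments = NULL, timepoints = NULL) {
  design <- track$design
  if (is.null(treatments))
    treatments <- setdiff(attr(design, "treatments"), attr(design, "control"))
  if (is.null(timepoints)) timepoints <- attr(design, "timepoints")
  res <- list()
  for (tr in treatments)
    for (tp in timepoints)
      res[[paste(tr, tp)]] <- suppressMessages(
        call_regions(track, tr, tp, layer, fdr_threshold,
                     n_probes, max_span_bp, step))
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  class(out) <- c("region_calls", "data.frame")
  out
}
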