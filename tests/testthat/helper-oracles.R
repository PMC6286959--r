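# Independent oracles and tiny fixture builders used across the suite.
# These deliberately re-derive results from definitions (step-up rule,
# direct t-tests, exhaustive window enumeration) rather than calling the
# package's own code paths.

# Benjamini-Hochberg by the step-up definition:
# fdr_i = min over j with p_(j) >= p_(i) of min(1, m * p_(j) / j)
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, m * p[o] / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# brute-force differential-region calling: enumerate all n-probe runs,
# test each with a direct pooled t-test on per-array window means, apply
# the step-up rule, collapse to genes with the median-score rule
oracle_region_calls <- function(track, treatment, timepoint,
                                fdr_threshold = 0.01, n_probes = 7,
                                max_span_bp = 750) {
  probes <- track$probes
  design <- track$design
  g1 <- design_samples(design, treatment, timepoint)
  g2 <- design_samples(design, attr(design, "control"), timepoint)
  wins <- list()
  for (g in unique(probes$gene)) {
    idx <- which(probes$gene == g)
    if (length(idx) < n_probes) next
    for (s in seq_len(length(idx) - n_probes + 1)) {
      ii <- idx[s:(s + n_probes - 1)]
      if (probes$end[ii[n_probes]] - probes$start[ii[1]] + 1 > max_span_bp)
        next
      m1 <- colMeans(track$signals[ii, g1, drop = FALSE])
      m2 <- colMeans(track$signals[ii, g2, drop = FALSE])
      p <- stats::t.test(m1, m2, var.equal = TRUE)$p.value
      wins[[length(wins) + 1]] <- data.frame(
        gene = g, p = p, first = ii[1], last = ii[n_probes],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(wins)) return(NULL)
  w <- do.call(rbind, wins)
  w$fdr <- bh_stepup_oracle(w$p)
  sig <- w[w$fdr < fdr_threshold, , drop = FALSE]
  if (!nrow(sig)) return(NULL)
  out <- lapply(split(sig, sig$gene), function(s) {
    rows <- sort(unique(unlist(mapply(seq, s$first, s$last,
                                      SIMPLIFY = FALSE))))
    diffs <- apply(track$signals[rows, g1, drop = FALSE], 1, median) -
      apply(track$signals[rows, g2, drop = FALSE], 1, median)
    score <- median(diffs)
    data.frame(gene = s$gene[1],
               direction = if (score > 0) "+" else "-",
               score = score, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$gene), , drop = FALSE]
}

# two-group design used throughout the quick tests
tiny_design <- function(timepoints = c("T1", "T3", "T5", "R3"), n_reps = 3) {
  generate_design(c("control", "trtA"), timepoints, n_reps, seed = 1)
}

# hand-built track: given per-gene probe count and a signal function
# f(gene_index, probe_index, sample_id) -> log2 value
build_track <- function(design, n_genes = 2, probes_per_gene = 10,
                        spacing = 100, width = 50, signal_fn = NULL,
                        seed = 1) {
  set.seed(seed)
  probes <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    start <- (g - 1) * 10000 + (seq_len(probes_per_gene) - 1) * spacing + 1
    data.frame(chrom = "chr1", start = start, end = start + width - 1,
               probe_id = sprintf("g%d_p%02d", g, seq_len(probes_per_gene)),
               gene = sprintf("g%d", g), stringsAsFactors = FALSE)
  }))
  sig <- matrix(0, nrow(probes), nrow(design),
                dimnames = list(probes$probe_id, design$sample_id))
  for (i in seq_len(nrow(probes)))
    for (s in design$sample_id)
      sig[i, s] <- if (is.null(signal_fn)) rnorm(1, 0, 0.2) else
        signal_fn(match(probes$gene[i], unique(probes$gene)),
                  i, s)
  promoters <- do.call(rbind, lapply(split(probes, probes$gene), function(p)
    data.frame(gene = p$gene[1], chrom = "chr1", start = min(p$start),
               end = max(p$end), stringsAsFactors = FALSE)))
  tiling_track(probes, sig, promoters, design)
}

# minimal diff_calls / region_calls builders for integration tests
make_diff_calls <- function(gene, treatment, timepoint, lfc, p,
                            fdr = bh_adjust(p)) {
  structure(data.frame(feature = gene, gene = gene, treatment = treatment,
                       timepoint = timepoint, lfc = lfc, t = NA_real_,
                       p = p, fdr = fdr,
                       direction = ifelse(lfc > 0, "+", "-"),
                       stringsAsFactors = FALSE),
            class = c("diff_calls", "data.frame"))
}

make_region_calls <- function(gene, direction, treatment = "trtA",
                              timepoint = "T5", layer = "HA",
                              score = ifelse(direction == "+", 1, -1)) {
  structure(data.frame(gene = gene, layer = layer, treatment = treatment,
                       timepoint = timepoint, direction = direction,
                       score = score, best_window_p = 1e-5, fdr = 1e-4,
                       stringsAsFactors = FALSE),
            class = c("region_calls", "data.frame"))
}
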