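#' @importFrom rtracklayer import export
#' @importFrom GenomicRanges GRanges seqnames start end mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols<-
NULL

#' Write / read a feature matrix as TSV
#'
#' Features x samples, first column `feature`, header = sample ids.
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write a tiling track: probe GFF3 plus wide signal TSV
#'
#' The GFF3 carries one probe per line (1-based inclusive coordinates,
#' score = mean log2 signal across samples, `ID` = probe id, `gene`
#' attribute); the per-sample signals go to a companion wide TSV keyed by
#' probe id. The promoter map is written as BED (0-based half-open).
#'
#' @param track A `tiling_track`.
#' @param gff3_path,signals_path,bed_path Output paths (`NULL` to skip).
#' @export
write_tiling_track <- function(track, gff3_path, signals_path,
                               bed_path = NULL) {
  p <- track$probes
  gr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start, p$end))
  S4Vectors::mcols(gr)$source <- "washomics"
  S4Vectors::mcols(gr)$type <- "microarray_probe"
  S4Vectors::mcols(gr)$score <- rowMeans(track$signals)
  S4Vectors::mcols(gr)$ID <- p$probe_id
  S4Vectors::mcols(gr)$gene <- p$gene
  rtracklayer::export(gr, gff3_path, format = "gff3")
  write_matrix_tsv(track$signals, signals_path)
  if (!is.null(bed_path)) {
    pr <- track$promoters
    gpr <- GenomicRanges::GRanges(pr$chrom, IRanges::IRanges(pr$start, pr$end))
    S4Vectors::mcols(gpr)$name <- pr$gene
    rtracklayer::export(gpr, bed_path, format = "bed")
  }
  invisible(gff3_path)
}

#' Read a tiling track from GFF3 + signal TSV (+ promoter BED)
#'
#' @param gff3_path Probe GFF3 (1-based inclusive; `ID` and `gene`
#'   attributes required).
#' @param signals_path Wide signal TSV written by [write_tiling_track()].
#' @param bed_path Promoter BED (0-based half-open; converted on read).
#' @param design A `study_design` for the signal columns.
#' @return A `tiling_track`.
#' @export
read_tiling_track <- function(gff3_path, signals_path, bed_path, design) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  probes <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    probe_id = S4Vectors::mcols(gr)$ID,
    gene = S4Vectors::mcols(gr)$gene,
    stringsAsFactors = FALSE)
  sig <- read_matrix_tsv(signals_path)
  sig <- sig[probes$probe_id, , drop = FALSE]
  bed <- rtracklayer::import(bed_path, format = "bed")  # 1-based on import
  promoters <- data.frame(
    gene = S4Vectors::mcols(bed)$name,
    chrom = as.character(GenomicRanges::seqnames(bed)),
    start = GenomicRanges::start(bed),
    end = GenomicRanges::end(bed),
    stringsAsFactors = FALSE)
  tiling_track(probes, sig, promoters, design)
}

#' Write / read differential call tables as TSV
#' @param calls A `diff_calls` or `region_calls` data.frame.
#' @param path File path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @param class_hint Class to stamp on the table (`"diff_calls"` or
#'   `"region_calls"`).
#' @export
read_calls_tsv <- function(path, class_hint = "diff_calls") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if ("direction" %in% names(df)) df$direction <- as.character(df$direction)
  class(df) <- c(class_hint, "data.frame")
  df
}

#' Write / read a metabolomics run as CSV
#'
#' Columns: `injection_index`, `sample_id`, `is_qc`, then one column per
#' metabolite.
#' @param run A `metabolomics_run`.
#' @param path File path.
#' @export
write_metabolomics_csv <- function(run, path) {
  df <- cbind(run$injections, as.data.frame(t(run$peak_areas)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolomics_csv
#' @param design A `study_design`.
#' @export
read_metabolomics_csv <- function(path, design) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- c("injection_index", "sample_id", "is_qc")
  stopifnot(all(meta_cols %in% names(df)))
  areas <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  colnames(areas) <- NULL
  inj <- df[, meta_cols]
  inj$is_qc <- as.logical(inj$is_qc)
  inj$sample_id[inj$is_qc] <- NA
  metabolomics_run(inj, areas, design)
}

#' Serialize simulation truth to JSON
#' @param truth A `sim_truth`.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$drift_fn <- NULL  # closures do not serialize; amplitude is retained
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
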