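#' Generate a fully crossed repeat-dose/recovery study design
#'
#' Builds the sample map of a washout study: every treatment (a vehicle
#' control plus one or more test compounds) is observed at every timepoint
#' with a fixed number of biological replicates. Timepoints whose label
#' starts with `"R"` are flagged as post-washout recovery samples; the
#' default layout is five days of repeat dosing sampled at days 1, 3 and 5
#' (`T1`, `T3`, `T5`) followed by day 3 of recovery (`R3`).
#'
#' @param n_treatments Total number of treatment groups including the
#'   control, or a character vector of treatment labels whose first element
#'   is the control. Default `c("control", "OTA", "KBrO3")`.
#' @param timepoints Ordered character vector of timepoint labels.
#' @param n_reps Biological replicates per (treatment, timepoint) cell;
#'   must be at least 2 so within-cell variance is estimable.
#' @param seed Integer seed recorded with the design (sample labelling is
#'   deterministic; the seed anchors downstream simulation).
#'
#' @return A `study_design`: a data.frame with columns `sample_id`,
#'   `treatment`, `timepoint`, `replicate` and attributes `treatments`,
#'   `timepoints`, `control`, `recovery_timepoints`, `seed`.
#' @examples
#' d <- generate_design(2, c("T1", "T3", "T5", "R3"), 3, seed = 1)
#' nrow(d)  # 24
#' @export
generate_design <- function(n_treatments = c("control", "OTA", "KBrO3"),
                            timepoints = c("T1", "T3", "T5", "R3"),
                            n_reps = 3, seed = 1L) {
  if (is.numeric(n_treatments)) {
    stopifnot(n_treatments >= 1)
    treatments <- if (n_treatments == 1) "control" else
      c("control", paste0("trt", seq_len(n_treatments - 1)))
  } else {
    treatments <- as.character(n_treatments)
  }
  if (anyDuplicated(treatments))
    stop("treatment labels must be unique")
  if (length(timepoints) < 1)
    stop("timepoints must be non-empty")
  if (n_reps < 2)
    stop("invalid design: n_reps must be >= 2 (no within-cell variance possible)")

  grid <- expand.grid(replicate = seq_len(n_reps),
                      timepoint = timepoints,
                      treatment = treatments,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("treatment", "timepoint", "replicate")]
  grid$sample_id <- sprintf("%s_%s_r%d", grid$treatment, grid$timepoint,
                            grid$replicate)
  stopifnot(!anyDuplicated(grid$sample_id))
  structure(grid,
            class = c("study_design", "data.frame"),
            treatments = treatments,
            timepoints = timepoints,
            control = treatments[1],
            recovery_timepoints = timepoints[startsWith(timepoints, "R")],
            seed = as.integer(seed))
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(attr(x, "treatments")), "treatments x",
      length(attr(x, "timepoints")), "timepoints,",
      nrow(x), "samples\n")
  cat("  treatments:", paste(attr(x, "treatments"), collapse = ", "),
      "(control =", paste0(attr(x, "control"), ")"), "\n")
  cat("  timepoints:", paste(attr(x, "timepoints"), collapse = ", "), "\n")
  rec <- attr(x, "recovery_timepoints")
  if (length(rec))
    cat("  post-washout:", paste(rec, collapse = ", "), "\n")
  invisible(x)
}

#' Samples of one (treatment, timepoint) cell
#'
#' @param design A `study_design`.
#' @param treatment,timepoint Cell coordinates.
#' @return Character vector of sample ids.
#' @export
design_samples <- function(design, treatment, timepoint) {
  stopifnot(inherits(design, "study_design"))
  design$sample_id[design$treatment == treatment &
                     design$timepoint == timepoint]
}

# validate the invariants the rest of the pipeline relies on
validate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  tab <- table(design$treatment, design$timepoint)
  if (any(tab < 2))
    stop("invalid design: some (treatment, timepoint) cell has < 2 replicates")
  ctl <- attr(design, "control")
  if (!all(attr(design, "timepoints") %in%
             design$timepoint[design$treatment == ctl]))
    stop("invalid design: control series missing for some timepoint")
  if (anyDuplicated(design$sample_id))
    stop("invalid design: duplicated sample ids")
  invisible(design)
}

#' Write / read a study design as TSV
#'
#' The TSV keeps the sample map plus a header comment with the ordered
#' treatment and timepoint levels so the design round-trips losslessly.
#' @param design A `study_design`.
#' @param path Output file.
#' @export
write_design_tsv <- function(design, path) {
  validate_design(design)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# treatments: ", paste(attr(design, "treatments"), collapse = ",")),
    paste0("# timepoints: ", paste(attr(design, "timepoints"), collapse = ",")),
    paste0("# seed: ", attr(design, "seed"))), con)
  utils::write.table(as.data.frame(design), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @param path Input file written by `write_design_tsv`.
#' @export
read_design_tsv <- function(path) {
  hdr <- readLines(path, n = 3)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    strsplit(sub(paste0("^# ", key, ": "), "", ln), ",")[[1]]
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  treatments <- get("treatments")
  timepoints <- get("timepoints")
  if (is.null(treatments)) treatments <- unique(df$treatment)
  if (is.null(timepoints)) timepoints <- unique(df$timepoint)
  seed <- suppressWarnings(as.integer(get("seed")))
  structure(df,
            class = c("study_design", "data.frame"),
            treatments = treatments,
            timepoints = timepoints,
            control = treatments[1],
            recovery_timepoints = timepoints[startsWith(timepoints, "R")],
            seed = if (length(seed)) seed else NA_integer_)
}
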