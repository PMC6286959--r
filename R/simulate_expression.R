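#' Simulate a log2 expression matrix with planted differential genes
#'
#' Generates gene-level (or probe-level) log2 intensities for every sample
#' of a design. Gene-wise true variances are drawn from a scaled
#' inverse-chi-square prior with `d0` prior degrees of freedom and scale
#' `s0_sq` -- the same hierarchical model the moderated t-test assumes --
#' so hyperparameter recovery can be checked against known truth. A
#' fraction of genes receives a signed log2 fold change in every test
#' treatment cell relative to the time-matched control.
#'
#' @param design A `study_design`.
#' @param n_genes Number of features.
#' @param de_fraction Fraction of genes planted as differential.
#' @param effect_size_dist Function `n -> n` signed log2 fold changes for
#'   the planted genes. Default: equiprobable +1 / -1.
#' @param d0 Prior degrees of freedom of the variance prior.
#' @param s0_sq Prior scale (typical gene variance on the log2 scale).
#' @param baseline_mean,baseline_sd Normal distribution of gene baseline
#'   log2 intensities.
#' @param seed Integer seed; mandatory, no hidden global state.
#'
#' @return List with `matrix` (a `feature_matrix`: genes x samples with the
#'   design attached) and `truth` (a `sim_truth` list: `de_genes` mapping
#'   gene -> timepoint -> signed LFC, plus the prior parameters and seed).
#' @examples
#' d <- generate_design(2, c("T1", "R3"), 3, seed = 1)
#' sim <- simulate_expression(d, n_genes = 100, de_fraction = 0.1, seed = 1)
#' dim(sim$matrix)
#' @export
simulate_expression <- function(design, n_genes = 2000, de_fraction = 0.1,
                                effect_size_dist = function(n)
                                  sample(c(-1, 1), n, replace = TRUE),
                                d0 = 4, s0_sq = 0.02,
                                baseline_mean = 7, baseline_sd = 1.5,
                                seed) {
  validate_design(design)
  stopifnot(d0 > 0, s0_sq > 0, de_fraction >= 0, de_fraction <= 1)
  if (missing(seed)) stop("seed is a mandatory argument")
  set.seed(as.integer(seed))

  genes <- sprintf("gene%05d", seq_len(n_genes))
  mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  # scaled inverse-chi-square(d0, s0_sq): s2 = d0 * s0_sq / chisq_d0
  sigma2 <- d0 * s0_sq / stats::rchisq(n_genes, df = d0)

  n_de <- floor(n_genes * de_fraction)
  if (de_fraction > 0 && n_de < 1) {
    warning("n_genes * de_fraction < 1: zero differential genes planted")
    n_de <- 0
  }
  de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
  lfc <- if (n_de > 0) effect_size_dist(n_de) else numeric(0)

  treatments <- attr(design, "treatments")
  control <- attr(design, "control")
  timepoints <- attr(design, "timepoints")

  mat <- matrix(stats::rnorm(n_genes * nrow(design), mean = 0, sd = 1),
                nrow = n_genes)
  mat <- mat * sqrt(sigma2) + mu
  dimnames(mat) <- list(genes, design$sample_id)
  is_test <- design$treatment != control
  if (n_de > 0 && any(is_test))
    mat[de_idx, is_test] <- mat[de_idx, is_test] + lfc

  de_genes <- stats::setNames(lapply(seq_along(de_idx), function(i) {
    stats::setNames(as.list(rep(lfc[i], length(timepoints))), timepoints)
  }), genes[de_idx])

  truth <- structure(list(
    de_genes = de_genes,
    epi_regions = list(),
    persistence_set = character(0),
    coupling_rho = NA_real_,
    d0 = d0, s0_sq = s0_sq,
    sigma2 = stats::setNames(sigma2, genes),
    seed = as.integer(seed)), class = "sim_truth")

  list(matrix = feature_matrix(mat, design), truth = truth)
}

#' Construct a feature matrix bound to a design
#'
#' A `feature_matrix` is a plain numeric matrix (features x samples) whose
#' columns are exactly the design's samples, with an optional feature ->
#' gene annotation for many-to-one probe sets.
#'
#' @param values Numeric matrix, features x samples; column names must
#'   match the design's `sample_id`s.
#' @param design A `study_design`.
#' @param annotation Optional data.frame with columns `feature`, `gene`.
#' @export
feature_matrix <- function(values, design, annotation = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  validate_design(design)
  missing_cols <- setdiff(design$sample_id, colnames(values))
  if (length(missing_cols))
    stop("matrix is missing design samples: ",
         paste(missing_cols, collapse = ", "))
  values <- values[, design$sample_id, drop = FALSE]
  if (!is.null(annotation)) {
    stopifnot(all(c("feature", "gene") %in% names(annotation)))
    unknown <- setdiff(annotation$feature, rownames(values))
    if (length(unknown))
      stop("annotation refers to unknown features: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(values, class = c("feature_matrix", class(values)),
            design = design, annotation = annotation)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x), "features x", ncol(x), "samples\n")
  invisible(x)
}
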