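#' Quantile normalization of a log2 intensity matrix
#'
#' Forces every column to share the same empirical distribution: each value
#' is replaced by the cross-sample mean of the values holding the same rank,
#' with ties within a column receiving the mean of the reference values over
#' the ranks they span.
#'
#' @param mat Numeric matrix, features x samples.
#' @return Matrix of the same shape, all columns having identical sorted
#'   value multisets. Idempotent.
#' @examples
#' quantile_normalize(cbind(s1 = c(1, 2), s2 = c(3, 4)))
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)
    stop("non-finite values at e.g. [",
         paste(apply(utils::head(bad, 3), 1, paste, collapse = ","),
               collapse = "], ["), "]")
  }
  if (ncol(mat) < 2) return(mat)
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(col) {
    tmp <- numeric(length(col))
    tmp[order(col)] <- ref
    # tied values share the mean of the reference values their ranks span
    stats::ave(tmp, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Reduce a probe-level matrix to one probe per gene
#'
#' For each gene, keeps the probe with the highest sample variance across
#' the given condition's arrays; exact ties are broken by the
#' lexicographically smallest probe id. Genes with no annotated probe are
#' absent from the output (message emitted).
#'
#' @param mat Probe-level matrix (probes x samples).
#' @param annotation data.frame with columns `feature` (probe id matching
#'   rownames of `mat`) and `gene`.
#' @param condition_samples Sample columns defining "the condition"
#'   (typically treatment + time-matched control arrays).
#' @return Gene-level matrix; rownames are gene symbols, attribute
#'   `chosen_probe` maps gene -> retained probe id.
#' @export
reduce_probes <- function(mat, annotation, condition_samples = colnames(mat)) {
  stopifnot(all(c("feature", "gene") %in% names(annotation)))
  stopifnot(all(condition_samples %in% colnames(mat)))
  genes_all <- unique(annotation$gene)
  annotation <- annotation[annotation$feature %in% rownames(mat), , drop = FALSE]
  dropped <- setdiff(genes_all, unique(annotation$gene))
  if (length(dropped))
    message("reduce_probes: ", length(dropped),
            " gene(s) with no annotated probe dropped")
  v <- apply(mat[annotation$feature, condition_samples, drop = FALSE], 1,
             stats::var)
  ann <- annotation[order(annotation$gene, -v, annotation$feature), ]
  keep <- ann[!duplicated(ann$gene), ]
  out <- mat[keep$feature, , drop = FALSE]
  rownames(out) <- keep$gene
  attr(out, "chosen_probe") <- stats::setNames(keep$feature, keep$gene)
  out
}

#' Empirical-Bayes moderated t-test versus time-matched control
#'
#' Two-group moderated t with variance shrinkage: per feature, the pooled
#' two-group residual variance \eqn{s^2} (df \eqn{d = n_1 + n_2 - 2}) is
#' shrunk toward a prior scale \eqn{s_0^2} with prior df \eqn{d_0},
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' and \eqn{\tilde t = \mathrm{LFC} / (\tilde s \sqrt{1/n_1 + 1/n_2})} is
#' referred to a t distribution on \eqn{d_0 + d} df. The hyperparameters
#' are estimated by matching the first two moments of \eqn{\log s^2} to a
#' scaled inverse-chi-square prior (digamma/trigamma inversion); when the
#' spread of \eqn{\log s^2} does not exceed its theoretical sampling
#' minimum, \eqn{d_0 = \infty} and every variance collapses to \eqn{s_0^2}.
#'
#' @param mat Feature matrix (log2), features x samples.
#' @param design A `study_design` covering the matrix columns.
#' @param treatment,timepoint The contrast: `treatment` at `timepoint`
#'   versus the design's control at the same timepoint.
#' @param d0,s0_sq Optional hyperparameter overrides (e.g. `d0 = 0`
#'   recovers the classical pooled t; `d0 = Inf` fixes every variance at
#'   `s0_sq`). Estimated from the data when `NULL`.
#' @return A `diff_calls` data.frame: `feature`, `gene`, `treatment`,
#'   `timepoint`, `lfc`, `t`, `p`, `fdr`, `direction`, with the estimated
#'   `d0`/`s0_sq` as attributes. `direction` is `+`/`-` for features with
#'   p below 0.05 (provisional; use [call_de()] for preset cutoffs), else `0`.
#' @export
moderated_t <- function(mat, design, treatment, timepoint,
                        d0 = NULL, s0_sq = NULL) {
  validate_design(design)
  g1 <- design_samples(design, treatment, timepoint)
  g2 <- design_samples(design, attr(design, "control"), timepoint)
  if (length(g1) < 2 || length(g2) < 2)
    stop("need >= 2 replicates per group in the contrast")
  x1 <- mat[, g1, drop = FALSE]
  x2 <- mat[, g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  d <- n1 + n2 - 2
  if (d <= 0) stop("zero residual degrees of freedom")

  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  lfc <- m1 - m2
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / d
  ok <- is.finite(s2)
  if (!all(ok)) {
    message("moderated_t: dropping ", sum(!ok), " feature(s) with non-finite variance")
    s2 <- s2[ok]; lfc <- lfc[ok]
  }

  if (is.null(d0) || is.null(s0_sq)) {
    hp <- estimate_variance_prior(s2, d)
    if (is.null(d0)) d0 <- hp$d0
    if (is.null(s0_sq)) s0_sq <- hp$s0_sq
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- lfc / se
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  fdr <- bh_adjust(p)

  ids <- names(s2) %||% paste0("f", which(ok))
  out <- data.frame(
    feature = ids,
    gene = ids,
    treatment = treatment, timepoint = timepoint,
    lfc = lfc, t = t_mod, p = p, fdr = fdr,
    direction = ifelse(p < 0.05, ifelse(lfc > 0, "+", "-"), "0"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("diff_calls", "data.frame"),
            d0 = d0, s0_sq = s0_sq, df_residual = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Moment-matching of log s^2 to a scaled inverse-chi-square prior.
# With e_g = log s2_g - digamma(d/2) + log(d/2):
#   E[e] = log s0^2 + log(d0/2) - digamma(d0/2)   (E of log sigma^2)
#   Var[e] = trigamma(d/2) + trigamma(d0/2)
estimate_variance_prior <- function(s2, d) {
  s2 <- s2[s2 > 0 & is.finite(s2)]
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ev <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0)
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(ev)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of trigamma on (0, Inf); y > 0
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Validating wrapper over the step-up procedure: `fdr_i` is the smallest
#' over all `j` with `p_(j) >= p_(i)` of `min(1, m p_(j) / j)`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted p-values, order-preserving and monotone in `p`.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.05))  # 0.04 0.05 0.05 0.05
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance calls at preset or explicit cutoffs
#'
#' Filters a `diff_calls` table to features passing all provided cutoffs
#' and assigns `direction = sign(lfc)`. Presets reflect the reporting
#' conventions of the study design this package targets:
#' `mrna_fig2` = raw p < 0.001 with no fold-change cutoff;
#' `mirna` = FDR < 0.05; `mirna_fig5` = FDR <= 0.1.
#'
#' @param calls A `diff_calls` data.frame.
#' @param preset One of `"mrna_fig2"`, `"mirna"`, `"mirna_fig5"`, or `NULL`
#'   to use explicit cutoffs.
#' @param p_cutoff,fdr_cutoff,lfc_cutoff Explicit cutoffs (raw p strictly
#'   below, FDR strictly below, |LFC| at or above). At least one must be
#'   provided when no preset is used.
#' @return The significant subset with `direction` in `{+, -}`.
#' @export
call_de <- function(calls, preset = NULL, p_cutoff = NULL, fdr_cutoff = NULL,
                    lfc_cutoff = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("mrna_fig2", "mirna", "mirna_fig5"))
    cut <- switch(preset,
                  mrna_fig2 = list(p = 0.001, fdr = NULL, lfc = NULL, fdr_le = FALSE),
                  mirna     = list(p = NULL, fdr = 0.05, lfc = NULL, fdr_le = FALSE),
                  mirna_fig5 = list(p = NULL, fdr = 0.1, lfc = NULL, fdr_le = TRUE))
    p_cutoff <- cut$p; fdr_cutoff <- cut$fdr; lfc_cutoff <- cut$lfc
    fdr_le <- cut$fdr_le
  } else fdr_le <- FALSE
  if (is.null(p_cutoff) && is.null(fdr_cutoff) && is.null(lfc_cutoff))
    stop("no cutoff provided: give a preset or at least one of p/fdr/lfc cutoffs")
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(p_cutoff)) keep <- keep & calls$p < p_cutoff
  if (!is.null(fdr_cutoff))
    keep <- keep & (if (fdr_le) calls$fdr <= fdr_cutoff else calls$fdr < fdr_cutoff)
  if (!is.null(lfc_cutoff)) keep <- keep & abs(calls$lfc) >= lfc_cutoff
  out <- calls[keep, , drop = FALSE]
  out$direction <- ifelse(out$lfc > 0, "+", ifelse(out$lfc < 0, "-", "0"))
  out
}

#' Differential calls for every test contrast of a design
#'
#' Runs [moderated_t()] for each (test treatment, timepoint) cell against
#' the time-matched control and binds the results.
#'
#' @inheritParams moderated_t
#' @param treatments,timepoints Subsets to restrict to (defaults: all test
#'   treatments, all timepoints).
#' @return A combined `diff_calls` data.frame.
#' @export
diff_all_contrasts <- function(mat, design, treatments = NULL,
                               timepoints = NULL) {
  validate_design(design)
  if (is.null(treatments))
    treatments <- setdiff(attr(design, "treatments"), attr(design, "control"))
  if (is.null(timepoints)) timepoints <- attr(design, "timepoints")
  res <- list()
  for (tr in treatments)
    for (tp in timepoints)
      res[[paste(tr, tp)]] <- moderated_t(mat, design, tr, tp)
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  class(out) <- c("diff_calls", "data.frame")
  out
}

#' Significance stars for a p-value
#' @param p Numeric vector.
#' @return `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, else "".
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
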