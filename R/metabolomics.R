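#' Simulate an injection-ordered GC-MS metabolomics run
#'
#' Produces peak areas for every design sample plus repeated quality-control
#' (QC) injections of one pooled reference sample, in injection order. A QC
#' occupies the first injection, every `qc_every`-th injection thereafter,
#' and the final injection. A smooth multiplicative instrument drift
#' (default linear, rising by `drift_amplitude` over the run) is applied
#' identically to QCs and samples, on top of multiplicative log-normal
#' measurement noise. A fraction of metabolites carries a planted log2 fold
#' change in all test-treatment samples.
#'
#' @param design A `study_design`.
#' @param n_metabolites Number of metabolites.
#' @param drift_amplitude Fractional signal change from first to last
#'   injection (0.3 = 30 percent rise).
#' @param qc_every Injection period of the QC sample (>= 2).
#' @param noise_cv Log-normal measurement coefficient of variation.
#' @param de_fraction,lfc_size Fraction of metabolites planted with a
#'   signed log2 fold change of magnitude `lfc_size` in test treatments.
#' @param seed Integer seed; mandatory.
#' @return List with `run` (a `metabolomics_run`) and `truth` (`sim_truth`
#'   with `metab_lfc` and the drift function).
#' @export
simulate_metabolomics <- function(design, n_metabolites = 40,
                                  drift_amplitude = 0.3, qc_every = 10,
                                  noise_cv = 0.1, de_fraction = 0.2,
                                  lfc_size = 1.5, seed) {
  validate_design(design)
  stopifnot(qc_every >= 2, drift_amplitude >= 0)
  if (missing(seed)) stop("seed is a mandatory argument")
  set.seed(as.integer(seed))

  # injection layout: QC, (qc_every - 1) samples, QC, ..., final QC
  sample_ids <- design$sample_id
  inj <- character(0)
  i <- 1
  while (i <= length(sample_ids)) {
    inj <- c(inj, "QC", sample_ids[i:min(i + qc_every - 2, length(sample_ids))])
    i <- i + qc_every - 1
  }
  if (utils::tail(inj, 1) != "QC") inj <- c(inj, "QC")
  n_inj <- length(inj)
  is_qc <- inj == "QC"
  if (sum(is_qc) < 5)
    stop("fewer than 5 QC injections in the batch; insufficient for drift fit")

  mets <- sprintf("met%03d", seq_len(n_metabolites))
  base <- stats::setNames(exp(stats::runif(n_metabolites, 11, 14)), mets)
  n_de <- floor(n_metabolites * de_fraction)
  de_idx <- if (n_de > 0) sort(sample.int(n_metabolites, n_de)) else integer(0)
  lfc <- stats::setNames(
    sample(c(-1, 1), n_de, replace = TRUE) * lfc_size, mets[de_idx])

  drift_fn <- function(t) 1 + drift_amplitude * (t - 1) / max(1, n_inj - 1)
  control <- attr(design, "control")
  test_samples <- design$sample_id[design$treatment != control]
  sdlog <- sqrt(log(1 + noise_cv^2))

  areas <- matrix(NA_real_, n_metabolites, n_inj,
                  dimnames = list(mets, NULL))
  for (j in seq_len(n_inj)) {
    mu <- base
    if (!is_qc[j] && inj[j] %in% test_samples && n_de > 0)
      mu[de_idx] <- mu[de_idx] * 2^lfc
    areas[, j] <- mu * drift_fn(j) *
      exp(stats::rnorm(n_metabolites, -sdlog^2 / 2, sdlog))
  }

  run <- metabolomics_run(
    injections = data.frame(injection_index = seq_len(n_inj),
                            sample_id = ifelse(is_qc, NA, inj),
                            is_qc = is_qc, stringsAsFactors = FALSE),
    peak_areas = areas, design = design)
  truth <- structure(list(
    metab_lfc = as.list(lfc),
    drift_amplitude = drift_amplitude,
    drift_fn = drift_fn,
    seed = as.integer(seed)), class = "sim_truth")
  list(run = run, truth = truth)
}

#' Construct a metabolomics run
#'
#' @param injections data.frame `injection_index` (strictly increasing),
#'   `sample_id` (NA for QCs), `is_qc` (logical).
#' @param peak_areas Matrix metabolites x injections, non-negative.
#' @param design A `study_design` covering all non-QC samples.
#' @export
metabolomics_run <- function(injections, peak_areas, design) {
  validate_design(design)
  stopifnot(all(diff(injections$injection_index) > 0),
            ncol(peak_areas) == nrow(injections),
            all(peak_areas >= 0, na.rm = TRUE))
  qc_pos <- injections$injection_index[injections$is_qc]
  smp_pos <- injections$injection_index[!injections$is_qc]
  if (length(qc_pos) < 5)
    stop("need >= 5 QC injections")
  if (min(qc_pos) > min(smp_pos) || max(qc_pos) < max(smp_pos))
    stop("QC injections must span the batch (first and last positions)")
  missing_s <- setdiff(stats::na.omit(injections$sample_id), design$sample_id)
  if (length(missing_s))
    stop("injections reference unknown samples: ",
         paste(missing_s, collapse = ", "))
  structure(list(injections = injections, peak_areas = peak_areas,
                 design = design),
            class = "metabolomics_run")
}

#' @export
print.metabolomics_run <- function(x, ...) {
  cat("metabolomics_run:", nrow(x$peak_areas), "metabolites,",
      ncol(x$peak_areas), "injections (",
      sum(x$injections$is_qc), "QCs )\n")
  invisible(x)
}

#' QC-RLSC drift correction
#'
#' Quality-control-based robust LOESS signal correction: per metabolite, a
#' LOESS curve (degree 1) is fit to the QC peak areas against injection
#' index; every injection's value is divided by the curve value at its
#' index normalized to the QC median, so the QC trend is flattened while
#' the metabolite's scale is preserved. Injections outside the QC range use
#' the curve value at the nearest QC (clamped extrapolation, flagged).
#' Metabolites with fewer than 5 usable QC measurements are left
#' uncorrected and flagged.
#'
#' @param run A `metabolomics_run`.
#' @param loess_span LOESS span on the QC points (default 0.75).
#' @return A corrected `metabolomics_run` with attributes `uncorrected`
#'   (metabolites left untouched) and `extrapolated` (injection indices
#'   outside the QC range).
#' @export
qc_rlsc <- function(run, loess_span = 0.75) {
  stopifnot(inherits(run, "metabolomics_run"))
  inj <- run$injections
  qc_cols <- which(inj$is_qc)
  x_all <- inj$injection_index
  x_qc <- x_all[qc_cols]
  out <- run$peak_areas
  uncorrected <- character(0)
  extrapolated <- x_all[x_all < min(x_qc) | x_all > max(x_qc)]
  for (m in rownames(out)) {
    y_qc <- run$peak_areas[m, qc_cols]
    ok <- is.finite(y_qc) & y_qc > 0
    if (sum(ok) < 5) {
      uncorrected <- c(uncorrected, m)
      next
    }
    # with few QCs a small span makes the local fits singular/interpolating;
    # widen so every local regression sees at least 7 QC points (or all)
    span_eff <- max(loess_span, min(1, 7 / sum(ok)))
    fit <- stats::loess(y ~ x, data.frame(x = x_qc[ok], y = y_qc[ok]),
                        span = span_eff, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    x_eval <- pmin(pmax(x_all, min(x_qc[ok])), max(x_qc[ok]))  # clamp ends
    curve <- stats::predict(fit, data.frame(x = x_eval))
    med <- stats::median(y_qc[ok])
    factor <- curve / med
    factor[!is.finite(factor) | factor <= 0] <- 1
    out[m, ] <- run$peak_areas[m, ] / factor
  }
  if (length(uncorrected))
    message("qc_rlsc: ", length(uncorrected),
            " metabolite(s) with < 5 usable QCs left uncorrected")
  res <- metabolomics_run(inj, out, run$design)
  attr(res, "uncorrected") <- uncorrected
  attr(res, "extrapolated") <- extrapolated
  res
}

#' QC coefficient of variation per metabolite
#' @param run A `metabolomics_run`.
#' @return Named numeric vector sd/mean over QC injections.
#' @export
qc_cv <- function(run) {
  qc <- run$peak_areas[, run$injections$is_qc, drop = FALSE]
  apply(qc, 1, function(v) stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE))
}

#' Log2 fold change over time-matched control per metabolite
#'
#' @param run A (corrected) `metabolomics_run`.
#' @return data.frame `metabolite`, `treatment`, `timepoint`, `lfc` =
#'   log2(mean treatment / mean time-matched control); `NA` when the
#'   control mean is non-positive or a cell has < 2 usable replicates.
#' @export
metabolite_lfc <- function(run) {
  design <- run$design
  inj <- run$injections
  control <- attr(design, "control")
  tests <- setdiff(attr(design, "treatments"), control)
  timepoints <- attr(design, "timepoints")
  col_of <- function(ids) which(inj$sample_id %in% ids)
  cell_mean <- function(m, ids) {
    v <- run$peak_areas[m, col_of(ids)]
    v <- v[is.finite(v)]
    if (length(v) < 2) return(NA_real_)
    mean(v)
  }
  rows <- list()
  for (tr in tests) for (tp in timepoints) {
    ids_t <- design_samples(design, tr, tp)
    ids_c <- design_samples(design, control, tp)
    for (m in rownames(run$peak_areas)) {
      mt <- cell_mean(m, ids_t); mc <- cell_mean(m, ids_c)
      lfc <- if (is.na(mt) || is.na(mc) || mc <= 0) NA_real_ else log2(mt / mc)
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = m, treatment = tr, timepoint = tp, lfc = lfc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Two-way ANOVA with Sidak or Bonferroni posttest
#'
#' Cell-means two-way ANOVA (treatment, time, interaction) followed by a
#' treatment-versus-control contrast at each timepoint using the pooled
#' residual mean square, in the style of GraphPad Prism's repeated
#' comparisons. The per-family correction uses m = number of timepoint
#' comparisons: Sidak \eqn{p' = 1 - (1 - p)^m}, Bonferroni
#' \eqn{p' = \min(1, m p)}.
#'
#' @param values Numeric response vector.
#' @param factor_treatment,factor_time Factors of the same length;
#'   `factor_treatment`'s first level (or `control`) is the control.
#' @param method `"sidak"` or `"bonferroni"`.
#' @param control Control level of `factor_treatment`.
#' @param alpha Significance level for the `significant` flag.
#' @return data.frame `treatment`, `timepoint`, `diff`, `t`, `p_raw`,
#'   `p_adj`, `significant`; ANOVA table as attribute `anova`.
#' @examples
#' # Sidak on p = 0.01, m = 3: 1 - 0.99^3 = 0.029701
#' @export
two_way_anova_posttest <- function(values, factor_treatment, factor_time,
                                   method = c("sidak", "bonferroni"),
                                   control = NULL, alpha = 0.05) {
  method <- match.arg(method)
  trt <- as.factor(factor_treatment)
  tim <- as.factor(factor_time)
  if (is.null(control)) control <- levels(trt)[1]
  stopifnot(control %in% levels(trt))
  cells <- table(trt, tim)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("missing cell: treatment=", rownames(cells)[bad[1]],
         " time=", colnames(cells)[bad[2]])
  }
  if (any(cells < 2)) stop("every cell needs >= 2 replicates")

  fit <- if (nlevels(tim) > 1) stats::lm(values ~ trt * tim) else
    stats::lm(values ~ trt)   # single timepoint: one-way layout
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]

  tests <- setdiff(levels(trt), control)
  timepoints <- levels(tim)
  m <- length(timepoints)
  rows <- list()
  for (tr in tests) for (tp in timepoints) {
    y1 <- values[trt == tr & tim == tp]
    y0 <- values[trt == control & tim == tp]
    dif <- mean(y1) - mean(y0)
    se <- sqrt(mse * (1 / length(y1) + 1 / length(y0)))
    tv <- dif / se
    p <- 2 * stats::pt(-abs(tv), df_res)
    p_adj <- if (method == "sidak") 1 - (1 - p)^m else pmin(1, m * p)
    rows[[paste(tr, tp)]] <- data.frame(
      treatment = tr, timepoint = tp, diff = dif, t = tv,
      p_raw = p, p_adj = p_adj, significant = p_adj <= alpha,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "anova") <- an
  attr(out, "method") <- method
  out
}
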