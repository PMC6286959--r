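test_that("window enumeration honors the probe count and span rules", {
  d <- tiny_design("T1", 3)
  # 10 probes at 100 bp spacing, 50 bp probes: 7-probe span = 650 <= 750
  tr <- build_track(d, n_genes = 1, probes_per_gene = 10, spacing = 100)
  w <- make_windows(tr, n_probes = 7, max_span_bp = 750)
  expect_equal(nrow(w), 4)
  expect_true(all(w$span_bp == 650))

  # 200 bp spacing: span 1250 > 750 -> no windows
  tr2 <- build_track(d, n_genes = 1, probes_per_gene = 10, spacing = 200)
  expect_equal(nrow(make_windows(tr2)), 0)

  # exactly 7 probes spanning exactly 750 bp: boundary inclusive, 1 window
  tr3 <- build_track(d, n_genes = 1, probes_per_gene = 7,
                     spacing = 115, width = 60)
  span <- tr3$probes$end[7] - tr3$probes$start[1] + 1
  expect_equal(span, 750)
  expect_equal(nrow(make_windows(tr3)), 1)

  # promoters with < n_probes yield no windows
  tr4 <- build_track(d, n_genes = 1, probes_per_gene = 5)
  expect_message(w4 <- make_windows(tr4), "no windows")
  expect_equal(nrow(w4), 0)

  # never more than probes - n_probes + 1 windows, spans always in bound
  tr5 <- build_track(d, n_genes = 3, probes_per_gene = 12)
  w5 <- make_windows(tr5)
  expect_true(all(table(w5$gene) <= 12 - 7 + 1))
  expect_true(all(w5$span_bp <= 750))
})

test_that("window ANOVA reproduces the hand-computed example", {
  # group means (1.0, 1.2, 0.8) vs (2.0, 2.2, 1.8): F = 37.5, p ~ 0.0036
  m <- rbind(a = c(1.0, 1.2, 0.8, 2.0, 2.2, 1.8))
  colnames(m) <- paste0("s", 1:6)
  res <- window_anova(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res$F, 37.5)
  expect_equal(res$p, 0.0036, tolerance = 1e-3)
  expect_equal(res$mean_diff, -1)

  # identical groups: F = 0, p = 1
  m0 <- rbind(x = rep(c(1, 2, 3), 2))
  colnames(m0) <- paste0("s", 1:6)
  res0 <- window_anova(m0, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
})

test_that("two-group window F equals the squared pooled t", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(rnorm(7 * 6), 7, 6, dimnames = list(NULL, paste0("s", 1:6)))
    res <- window_anova(m, paste0("s", 1:3), paste0("s", 4:6))
    tt <- stats::t.test(colMeans(m[, 1:3]), colMeans(m[, 4:6]),
                        var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-12)
    expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("median-rule direction is signed, tied and antisymmetric", {
  m <- rbind(p1 = c(2, 2.2, 1.8, 1, 1.1, 0.9),
             p2 = c(2.1, 2, 1.9, 1, 0.9, 1.1))
  colnames(m) <- paste0("s", 1:6)
  trt <- paste0("s", 1:3); ctl <- paste0("s", 4:6)
  expect_equal(direction_by_median(m, trt, ctl), "+")
  expect_equal(direction_by_median(-m, trt, ctl), "-")
  expect_equal(direction_by_median(m, trt, trt), "0")
  expect_error(direction_by_median(m, character(0), ctl), "empty")
})

test_that("region calls match the brute-force oracle on small tracks", {
  d <- tiny_design("T1", 3)
  trt <- design_samples(d, "trtA", "T1")
  # 3 promoters x 12 probes; plant +1 on gene 1, -0.8 on gene 3
  sfn <- function(g, i, s) {
    eff <- if (s %in% trt) c(1, 0, -0.8)[g] else 0
    set.seed(i * 131 + match(s, d$sample_id))
    eff + rnorm(1, 0, 0.2)
  }
  track <- build_track(d, n_genes = 3, probes_per_gene = 12,
                       signal_fn = sfn)
  got <- call_regions(track, "trtA", "T1", fdr_threshold = 0.01)
  oracle <- oracle_region_calls(track, "trtA", "T1", fdr_threshold = 0.01)
  expect_equal(got$gene, oracle$gene)
  expect_equal(got$direction, oracle$direction)
  expect_equal(got$score, oracle$score, tolerance = 1e-12)
  expect_setequal(got$gene, c("g1", "g3"))
  expect_equal(got$direction[got$gene == "g1"], "+")
  expect_equal(got$direction[got$gene == "g3"], "-")
})

test_that("region calling is deterministic and sample-order invariant", {
  d <- tiny_design("T1", 3)
  set.seed(55)
  track <- build_track(d, n_genes = 2, probes_per_gene = 10, seed = 55)
  a <- call_regions(track, "trtA", "T1")
  b <- call_regions(track, "trtA", "T1")
  expect_identical(a, b)
  # shuffling the signal columns does not change the calls
  perm <- sample(ncol(track$signals))
  track2 <- tiling_track(track$probes, track$signals[, perm],
                         track$promoters, d)
  expect_equal(as.data.frame(call_regions(track2, "trtA", "T1")),
               as.data.frame(a))
})

test_that("planted regions are recovered with the planted direction", {
  d <- tiny_design()
  s <- simulate_tiling(d, 60, region_fraction = 0.2, effect_size = 1,
                       noise_sd = 0.2, persistence_fraction = 1, seed = 61)
  rc <- call_regions(s$track, "trtA", "T5")
  truth_dir <- vapply(s$truth$epi_regions, function(r)
    r$timepoints[["T5"]]$direction, character(1))
  hits <- intersect(rc$gene, names(truth_dir))
  expect_gte(length(hits) / length(truth_dir), 0.9)
  expect_equal(rc$direction[match(hits, rc$gene)],
               unname(truth_dir[hits]))
  # sign symmetry held implicitly: both planted directions appear
  expect_setequal(unique(unname(truth_dir[hits])), c("+", "-"))
})

test_that("persistent planted marks survive to the recovery timepoint", {
  d <- tiny_design()
  s <- simulate_tiling(d, 200, region_fraction = 0.15, effect_size = 1,
                       persistence_fraction = 0.3, noise_sd = 0.2, seed = 62)
  t5 <- call_regions(s$track, "trtA", "T5")
  r3 <- call_regions(s$track, "trtA", "R3")
  pers <- persistence(t5, r3)
  rec <- unlist(attr(pers, "persistent_genes"), use.names = FALSE)
  expect_gte(length(intersect(rec, s$truth$persistence_set)) /
               length(s$truth$persistence_set), 0.9)
})
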