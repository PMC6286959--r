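test_that("quantile normalization follows the rank-mean definition", {
  m <- cbind(s1 = c(1, 2), s2 = c(3, 4))
  rownames(m) <- c("f1", "f2")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(2, 3), c(2, 3)))

  # identical columns are untouched
  m2 <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2)

  # single column is returned unchanged
  m3 <- matrix(c(9, 2, 4), dimnames = list(NULL, "only"))
  expect_equal(quantile_normalize(m3), m3)

  # within-column ties share the mean of the reference values they span
  mt <- cbind(a = c(1, 1, 5), b = c(2, 4, 6))
  qt <- quantile_normalize(mt)
  ref <- rowMeans(cbind(sort(mt[, 1]), sort(mt[, 2])))
  expect_equal(unname(qt[1:2, 1]), rep(mean(ref[1:2]), 2))
})

test_that("quantile normalization is idempotent", {
  set.seed(1)
  m <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("f", 1:10),
                                                paste0("s", 1:6)))
  q1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  # all columns share one sorted multiset
  sorted <- apply(q1, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("non-finite input to quantile normalization names the cell", {
  m <- cbind(a = c(1, NA), b = c(2, 3))
  expect_error(quantile_normalize(m), "non-finite")
})

test_that("probe reduction keeps the most variable probe per gene", {
  d <- tiny_design("T1", 3)
  set.seed(2)
  m <- rbind(p1 = rnorm(6, sd = 0.5), p2 = rnorm(6, sd = 2),
             p3 = rnorm(6))
  colnames(m) <- d$sample_id
  ann <- data.frame(feature = c("p1", "p2", "p3"),
                    gene = c("G", "G", "H"))
  red <- reduce_probes(m, ann)
  expect_equal(rownames(red), c("G", "H"))
  expect_equal(unname(attr(red, "chosen_probe")["G"]),
               c("p1", "p2")[which.max(c(var(m["p1", ]), var(m["p2", ])))])

  # exact variance tie: lexicographically smaller probe id wins
  m2 <- rbind(pB = c(1, 2, 3, 1, 2, 3), pA = c(3, 2, 1, 3, 2, 1))
  colnames(m2) <- d$sample_id
  ann2 <- data.frame(feature = c("pB", "pA"), gene = "G")
  red2 <- reduce_probes(m2, ann2)
  expect_equal(unname(attr(red2, "chosen_probe")["G"]), "pA")

  # single-probe gene passes through; unprobed gene dropped with message
  ann3 <- data.frame(feature = c("p1", "zz"), gene = c("solo", "ghost"))
  expect_message(red3 <- reduce_probes(m, ann3), "ghost|dropped")
  expect_equal(rownames(red3), "solo")
})

test_that("moderated t reduces to the classical pooled t when d0 = 0", {
  d <- tiny_design()
  s <- simulate_expression(d, 50, 0.2, seed = 21)
  mt <- moderated_t(s$matrix, d, "trtA", "T3", d0 = 0, s0_sq = 1)
  g1 <- design_samples(d, "trtA", "T3")
  g2 <- design_samples(d, "control", "T3")
  classical <- apply(s$matrix, 1, function(r)
    stats::t.test(r[g1], r[g2], var.equal = TRUE)$statistic)
  expect_equal(mt$t, unname(classical), tolerance = 1e-12)
})

test_that("infinite prior df collapses every variance to the prior scale", {
  d <- tiny_design()
  s <- simulate_expression(d, 30, 0, seed = 22)
  mt <- moderated_t(s$matrix, d, "trtA", "T1", d0 = Inf, s0_sq = 0.04)
  g1 <- design_samples(d, "trtA", "T1")
  g2 <- design_samples(d, "control", "T1")
  lfc <- rowMeans(s$matrix[, g1]) - rowMeans(s$matrix[, g2])
  expect_equal(mt$t, unname(lfc / sqrt(0.04 * (2 / 3))), tolerance = 1e-12)
})

test_that("moderated t agrees with the limma empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  d <- tiny_design()
  s <- simulate_expression(d, 400, 0.1, seed = 23)
  mt <- moderated_t(s$matrix, d, "trtA", "T5")
  g1 <- design_samples(d, "trtA", "T5")
  g2 <- design_samples(d, "control", "T5")
  X <- cbind(intercept = 1, trt = rep(1:0, each = 3))
  fit <- limma::eBayes(limma::lmFit(s$matrix[, c(g1, g2)], X))
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(mt, "s0_sq"), fit$s2.prior, tolerance = 0.01)
  expect_equal(mt$t, unname(fit$t[, "trt"]), tolerance = 1e-10)
  expect_equal(mt$p, unname(fit$p.value[, "trt"]), tolerance = 1e-10)
})

test_that("LFC equals the difference of group means regardless of moderation", {
  d <- tiny_design()
  s <- simulate_expression(d, 40, 0.5, seed = 24)
  g1 <- design_samples(d, "trtA", "T1")
  g2 <- design_samples(d, "control", "T1")
  expected <- rowMeans(s$matrix[, g1]) - rowMeans(s$matrix[, g2])
  for (prior in list(list(d0 = 0, s0 = 1), list(d0 = 10, s0 = 0.01),
                     list(d0 = Inf, s0 = 5))) {
    mt <- moderated_t(s$matrix, d, "trtA", "T1",
                      d0 = prior$d0, s0_sq = prior$s0)
    expect_equal(mt$lfc, unname(expected))
  }
})

test_that("variance prior recovery is within 30% at 5000 features", {
  d <- tiny_design("T1", 3)
  s <- simulate_expression(d, 5000, 0, d0 = 4, s0_sq = 0.02, seed = 25)
  mt <- moderated_t(s$matrix, d, "trtA", "T1")
  expect_lt(abs(attr(mt, "d0") - 4) / 4, 0.3)
  expect_lt(abs(attr(mt, "s0_sq") - 0.02) / 0.02, 0.3)
})

test_that("BH adjustment matches the step-up definition and the worked example", {
  p <- c(0.01, 0.04, 0.03, 0.05)
  expect_equal(bh_adjust(p), c(0.04, 0.05, 0.05, 0.05))
  expect_equal(bh_adjust(p), bh_stepup_oracle(p))

  expect_equal(bh_adjust(0.02), 0.02)           # single p unchanged
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))  # all equal: fdr = p

  set.seed(3)
  pr <- runif(200)
  expect_equal(bh_adjust(pr), bh_stepup_oracle(pr))
  # monotone in p and bounded by p and m*p
  o <- order(pr)
  expect_true(all(diff(bh_adjust(pr)[o]) >= -1e-15))
  expect_true(all(bh_adjust(pr) >= pr - 1e-15))
  expect_true(all(bh_adjust(pr) <= pmin(1, length(pr) * pr) + 1e-15))

  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance presets implement the reporting cutoffs", {
  calls <- make_diff_calls(paste0("g", 1:4), "trtA", "T1",
                           lfc = c(0.2, 3.0, -1, 0.9),
                           p = c(5e-4, 0.01, 2e-4, 0.2),
                           fdr = c(0.04, 0.08, 0.03, 0.5))
  fig2 <- call_de(calls, preset = "mrna_fig2")
  expect_setequal(fig2$gene, c("g1", "g3"))   # p < 0.001 only; no LFC cutoff
  expect_equal(fig2$direction[fig2$gene == "g3"], "-")

  mir <- call_de(calls, preset = "mirna")
  expect_setequal(mir$gene, c("g1", "g3"))    # fdr < 0.05
  mir5 <- call_de(calls, preset = "mirna_fig5")
  expect_setequal(mir5$gene, c("g1", "g2", "g3"))  # fdr <= 0.1 includes 0.08

  expect_error(call_de(calls), "no cutoff")
})

test_that("detection rate rises with planted effect size", {
  d <- tiny_design("T1", 3)
  rates <- vapply(c(0.3, 0.7, 1.2), function(ef) {
    s <- simulate_expression(d, 600, 0.2,
                             effect_size_dist = function(n)
                               sample(c(-ef, ef), n, TRUE),
                             seed = 31)
    sig <- call_de(moderated_t(s$matrix, d, "trtA", "T1"),
                   fdr_cutoff = 0.05)
    mean(names(s$truth$de_genes) %in% sig$feature)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.8)
})
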