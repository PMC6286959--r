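test_that("Spearman correlation matches the hand example and definition", {
  r <- spearman_rho(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$rho, -0.5)   # 1 - 6*6/(3*8)

  expect_equal(spearman_rho(1:8, (1:8)^3)$rho, 1)  # monotone increasing
  # invariance under strictly monotone transforms
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_rho(x, y)$rho, spearman_rho(exp(x), y^3 + y)$rho)
})

test_that("correlation over records requires >= 4 genes and finds coupling", {
  calls <- make_diff_calls(paste0("g", 1:6), "trtA", "T1",
                           lfc = c(2, 1.5, 1, -1, -1.5, -2),
                           p = rep(1e-5, 6))
  rc <- make_region_calls(paste0("g", 1:6), rep(c("+", "-"), each = 3),
                          timepoint = "T1",
                          score = c(1.9, 1.4, 0.9, -0.9, -1.4, -1.9))
  rec <- integration_records(calls, rc)
  r <- correlate_epi_ge(rec, "ha", "trtA", "T1")
  expect_equal(r$rho, 1)
  expect_equal(r$n, 6)

  small <- integration_records(calls[1:3, ], rc[1:3, ])
  expect_message(r2 <- correlate_epi_ge(small, "ha", "trtA", "T1"),
                 "no result")
  expect_null(r2)
})

test_that("persistence follows the R3-denominator definition", {
  t5 <- make_region_calls(c("A", "B"), c("+", "-"), timepoint = "T5")
  r3 <- make_region_calls(c("A", "B", "C"), c("+", "+", "-"),
                          timepoint = "R3")
  p <- persistence(t5, r3)
  hyper <- p[p$direction == "+", ]
  hypo <- p[p$direction == "-", ]
  expect_equal(hyper$n_R3, 2)
  expect_equal(hyper$n_persistent, 1)      # A persists; B flipped
  expect_equal(hyper$pct_persistent, 50)
  expect_equal(hypo$n_R3, 1)
  expect_equal(hypo$n_persistent, 0)
  expect_equal(hypo$pct_persistent, 0)

  # T5 = R3 -> 100% in both directions
  same <- make_region_calls(c("A", "B"), c("+", "-"), timepoint = "T5")
  same_r3 <- make_region_calls(c("A", "B"), c("+", "-"), timepoint = "R3")
  p2 <- persistence(same, same_r3)
  expect_equal(p2$pct_persistent, c(100, 100))

  # disjoint sets -> 0%
  p3 <- persistence(make_region_calls("X", "+", timepoint = "T5"),
                    make_region_calls("Y", "+", timepoint = "R3"))
  expect_equal(p3$pct_persistent[p3$direction == "+"], 0)

  # persistent set is contained in T5 and R3 with matching direction
  genes <- attr(p, "persistent_genes")
  expect_true(all(genes[["+"]] %in% intersect(t5$gene[t5$direction == "+"],
                                              r3$gene[r3$direction == "+"])))
})

test_that("removing T5 calls never increases the persistent count", {
  set.seed(2)
  genes <- paste0("g", 1:40)
  t5 <- make_region_calls(genes, sample(c("+", "-"), 40, TRUE),
                          timepoint = "T5")
  r3 <- make_region_calls(sample(genes, 25), sample(c("+", "-"), 25, TRUE),
                          timepoint = "R3")
  full <- sum(persistence(t5, r3)$n_persistent)
  for (k in c(30, 20, 10)) {
    shrunk <- sum(persistence(t5[seq_len(k), ], r3)$n_persistent)
    expect_lte(shrunk, full)
    full <- shrunk
  }
})

test_that("concordance applies the LFC filter and partitions its set", {
  pers <- make_region_calls(c("up_ok", "down_ok", "clash", "weak", "ns"),
                            c("+", "-", "+", "+", "+"), timepoint = "R3")
  ge <- make_diff_calls(c("up_ok", "down_ok", "clash", "weak", "ns"),
                        "trtA", "R3",
                        lfc = c(1.0, -1.0, -1.0, 0.5, 2.0),
                        p = c(1e-5, 1e-5, 1e-5, 1e-5, 0.5))
  cc <- concordance(pers, ge, lfc_cutoff = 0.58, ge_p_cutoff = 0.001)
  expect_setequal(cc$gene, c("up_ok", "down_ok", "clash"))
  expect_true(cc$consistent[cc$gene == "up_ok"])     # GE+ with HA+
  expect_true(cc$consistent[cc$gene == "down_ok"])   # GE- with HA-
  expect_false(cc$consistent[cc$gene == "clash"])    # GE- with HA+
  expect_equal(attr(cc, "n_consistent") + attr(cc, "n_inconsistent"),
               nrow(cc))
})

test_that("pathway ranking gates on the positive control and sorts by test LFC", {
  genes <- c("strong", "mid", "ungated", "absent")
  rows <- list()
  for (tp in c("T1", "T3", "T5")) {
    rows[[paste0("pc", tp)]] <- make_diff_calls(
      genes[1:3], "KBrO3", tp, lfc = c(2, 1, 0.1),
      p = c(1e-5, 1e-4, 0.5))   # "ungated" never significant under control
    rows[[paste0("t", tp)]] <- make_diff_calls(
      genes[1:3], "OTA", tp,
      lfc = c(c(2, 1, 0)[match(tp, c("T1", "T3", "T5"))], 3, 1),
      p = rep(1e-4, 3))
  }
  calls <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(calls) <- c("diff_calls", "data.frame")
  expect_message(rk <- rank_pathway(calls, genes, "KBrO3", "OTA"),
                 "absent")
  kept <- rk[!rk$missing, ]
  expect_false("ungated" %in% kept$gene)       # removed by the gate
  expect_equal(kept$gene, c("mid", "strong"))  # avg test LFC 3 then 1
  expect_equal(kept$avg_test[kept$gene == "strong"], 1)  # mean(2,1,0)
  expect_true(rk$missing[rk$gene == "absent"])
})

test_that("impact counts partition into up plus down per condition", {
  d <- tiny_design("T1", 3)
  s <- simulate_expression(d, 400, 0.2, seed = 71)
  de <- diff_all_contrasts(s$matrix, d)
  counts <- impact_counts(de)
  sig <- call_de(de, preset = "mrna_fig2")
  expect_equal(sum(counts$n), nrow(sig))
  for (tp in unique(counts$timepoint)) {
    tot <- sum(counts$n[counts$timepoint == tp])
    expect_equal(tot, sum(sig$timepoint == tp))
  }
})

test_that("miRNA overlap reports shared significant features", {
  calls <- rbind(
    make_diff_calls(paste0("mir", 1:6), "KBrO3", "T5",
                    lfc = c(1, 1, 1, -1, 0.2, 0.1),
                    p = c(1e-6, 1e-6, 1e-6, 1e-6, 0.5, 0.9),
                    fdr = c(1e-4, 1e-4, 1e-4, 1e-4, 0.6, 0.95)),
    make_diff_calls(paste0("mir", 1:6), "OTA", "T5",
                    lfc = c(1, -1, 0.1, 0.3, 1, 0.2),
                    p = c(1e-6, 1e-6, 0.8, 0.4, 1e-6, 0.7),
                    fdr = c(1e-4, 1e-4, 0.9, 0.5, 1e-4, 0.8)))
  class(calls) <- c("diff_calls", "data.frame")
  ov <- mirna_overlap(calls, "KBrO3", "T5", "OTA")
  t5 <- ov$overlap[ov$overlap$timepoint == "T5", ]
  expect_equal(t5$n_ref, 4)                    # mir1..mir4 under KBrO3
  expect_equal(t5$n_shared, 2)                 # mir1, mir2 also under OTA
  tab <- ov$table
  expect_true(tab$significant[tab$mirna == "mir1"])
  expect_equal(tab$direction[tab$mirna == "mir2"], "-")

  # disjoint significant sets -> zero overlap
  calls2 <- calls
  calls2$fdr[calls2$treatment == "OTA"] <- 0.9
  ov2 <- mirna_overlap(calls2, "KBrO3", "T5", "OTA")
  expect_equal(ov2$overlap$n_shared, 0)
})
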