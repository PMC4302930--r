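test_that("annotation generation respects gene count, exon floor and determinism", {
  ann1 <- generate_annotation(simulation_config(n_genes = 1, fraction_marked = 0, n_targets_up = 0, n_targets_down = 0, n_unmarked_de = 0, seed = 3))
  expect_equal(nrow(ann1), 1L)

  ann <- generate_annotation(simulation_config(n_genes = 1000, seed = 3))
  expect_equal(nrow(ann), 1000L)
  expect_true(all(ann$exonic_length >= 200))
  expect_true(all(ann$end > ann$start))
  expect_true(all(ann$strand %in% c("+", "-")))
  expect_equal(ann$tss, ifelse(ann$strand == "+", ann$start, ann$end))
  # exons inside the gene span, half-open, non-overlapping
  ok <- vapply(seq_len(nrow(ann)), function(i) {
    es <- ann$exon_starts[[i]]; ee <- ann$exon_ends[[i]]
    all(es >= ann$start[i]) && all(ee <= ann$end[i]) && all(ee > es) &&
      (length(es) < 2 || all(es[-1] >= ee[-length(ee)]))
  }, logical(1))
  expect_true(all(ok))

  expect_identical(ann, generate_annotation(simulation_config(n_genes = 1000, seed = 3)))
})

test_that("config validation names the offending field", {
  expect_error(simulation_config(n_genes = 0), "n_genes",
               class = "derepressr_config_error")
  expect_error(simulation_config(replicates_per_condition = 1),
               "replicates_per_condition", class = "derepressr_config_error")
  expect_error(simulation_config(n_genes = 100, fraction_marked = 0.1,
                                 n_targets_up = 20, n_targets_down = 0),
               "n_targets_up", class = "derepressr_config_error")
  expect_error(simulation_config(chip_background_rate = 0),
               "chip_background_rate", class = "derepressr_config_error")
})

test_that("truth table marks exactly the configured fraction and target classes", {
  cfg <- simulation_config(n_genes = 500, fraction_marked = 0.18,
                           n_targets_up = 12, n_targets_down = 3,
                           n_unmarked_de = 5, seed = 11)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  expect_equal(sum(truth$is_marked), round(0.18 * 500))
  expect_equal(sum(truth$target_class == "up"), 12L)
  expect_equal(sum(truth$target_class == "down"), 3L)
  # direct-target classes only occur on marked genes
  expect_true(all(truth$is_marked[truth$target_class != "none"]))
  # nonzero fold change iff responder (marked target or unmarked-DE gene)
  expect_equal(sum(truth$true_log2fc != 0), 12L + 3L + 5L)
  expect_true(all(truth$true_log2fc[truth$target_class == "up"] > 0))
  expect_true(all(truth$true_log2fc[truth$target_class == "down"] < 0))
})

test_that("RNA-seq counts are reproducible and centred on the null when effects are zero", {
  cfg <- simulation_config(n_genes = 400, n_targets_up = 0, n_targets_down = 0,
                           n_unmarked_de = 0, seed = 19)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  rna <- simulate_rnaseq_counts(ann, truth, cfg)
  expect_identical(rna$counts, simulate_rnaseq_counts(ann, truth, cfg)$counts)
  expect_setequal(rna$design$condition, c("control", "mutant"))
  expect_equal(nrow(rna$design), 2 * cfg$replicates_per_condition)

  m <- as.matrix(rna$counts[rna$design$sample])
  a <- rowMeans(m[, rna$design$condition == "mutant"])
  b <- rowMeans(m[, rna$design$condition == "control"])
  lr <- log2((a + 1) / (b + 1))
  expect_lt(abs(mean(lr)), 0.05)
})

test_that("a log2 fold change of 3 yields an eightfold count ratio (Monte Carlo)", {
  # 10000 independent NB draws per condition via 10000 genes with lfc 3
  n <- 10000
  cfg <- simulation_config(n_genes = n, fraction_marked = 0, n_targets_up = 0,
                           n_targets_down = 0, n_unmarked_de = 0,
                           baseline_log_sd = 0.01, library_size = 5e6, seed = 7)
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  truth$true_log2fc <- rep(3, n)
  rna <- simulate_rnaseq_counts(ann, truth, cfg)
  m <- as.matrix(rna$counts[rna$design$sample])
  a <- mean(m[, rna$design$condition == "mutant"])
  b <- mean(m[, rna$design$condition == "control"])
  expect_equal(a / b, 8, tolerance = 0.02)
})

test_that("ChIP tags separate marked from unmarked TSS windows only under enrichment", {
  # enrichment 1: marked and unmarked windows statistically indistinguishable
  cfg0 <- simulation_config(n_genes = 400, chip_enrichment_factor = 1,
                            chip_background_rate = 2e-3, seed = 13)
  ann <- generate_annotation(cfg0)
  truth <- simulate_truth(ann, cfg0)
  tags <- simulate_chip_tags(ann, truth, cfg0)
  raw <- count_tss_tags(tags, ann, window_bp = cfg0$tss_window_bp)$raw_count
  wt <- wilcox.test(raw[truth$is_marked], raw[!truth$is_marked], exact = FALSE)
  expect_gt(wt$p.value, 0.01)

  # enrichment 20 over a small background: every marked window count
  # exceeds the unmarked median
  cfg1 <- simulation_config(n_genes = 200, n_targets_up = 4, n_targets_down = 1,
                            n_unmarked_de = 2, chip_enrichment_factor = 20,
                            chip_background_rate = 1e-4, seed = 13)
  ann1 <- generate_annotation(cfg1)
  truth1 <- simulate_truth(ann1, cfg1)
  tags1 <- simulate_chip_tags(ann1, truth1, cfg1)
  raw1 <- count_tss_tags(tags1, ann1, window_bp = cfg1$tss_window_bp)$raw_count
  expect_true(all(raw1[truth1$is_marked] > median(raw1[!truth1$is_marked])))

  # empty annotation -> empty tag set
  empty <- simulate_chip_tags(ann1[0, ], truth1[0, ], cfg1)
  expect_equal(nrow(empty), 0L)

  # determinism
  expect_identical(tags1, simulate_chip_tags(ann1, truth1, cfg1))
})
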