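make_de_table <- function(gene_id, status, diffrat = NULL, p_adj = NULL) {
  tibble::tibble(
    gene_id = gene_id,
    diffrat = diffrat %||% ifelse(status == "down", -1, ifelse(status == "up", 1, 0)),
    p_adj = p_adj %||% ifelse(status == "ns", 1, 0.001),
    status = status
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_marks_table <- function(gene_id, mark_class) {
  tibble::tibble(gene_id = gene_id,
                 scaled = ifelse(mark_class == "high", 8, 0.5),
                 mark_class = mark_class)
}

test_that("cross-referencing partitions the gene universe into six categories", {
  ids <- sprintf("g%d", 1:6)
  de <- make_de_table(ids, c("up", "down", "ns", "up", "down", "ns"))
  mk <- make_marks_table(ids, c(rep("high", 3), rep("low", 3)))
  it <- cross_reference(de, mk)
  expect_equal(unname(it$counts),
               c(1L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(it$counts), length(ids))
  expect_equal(it$table$category[1], "marked_up")

  all_ns <- cross_reference(make_de_table(ids, rep("ns", 6)), mk)
  expect_equal(unname(all_ns$counts["marked_up"]), 0L)
  expect_equal(sum(all_ns$counts), 6L)

  expect_error(cross_reference(de[c(1, 1:6), ], mk), "duplicated",
               class = "derepressr_key_error")
  expect_error(cross_reference(de, mk[1:5, ]), "g6",
               class = "derepressr_key_error")
})

test_that("direct-target extraction returns marked DE genes and nothing else", {
  ids <- sprintf("g%d", 1:8)
  de <- make_de_table(ids, c("up", "up", "down", "ns", "up", "down", "ns", "ns"))
  mk <- make_marks_table(ids, c("high", "high", "high", "high", rep("low", 4)))
  it <- cross_reference(de, mk)
  tg <- extract_direct_targets(it)
  expect_equal(tg$up, c("g1", "g2"))
  expect_equal(tg$down, "g3")
  expect_true(all(tg$up %in% de$gene_id[de$status == "up"]))

  none_marked <- cross_reference(de, make_marks_table(ids, rep("low", 8)))
  expect_equal(extract_direct_targets(none_marked)$up, character())
})

test_that("rank-sum test reports no difference under the null and detects depression", {
  withr::with_seed(31, {
    n <- 2000
    ids <- sprintf("g%04d", 1:n)
    marked <- rep(c("high", "low"), c(360, n - 360))
    design <- tibble::tibble(sample = c("control_1", "mutant_1"),
                             condition = c("control", "mutant"))
    # null: identical distributions in both classes
    expr0 <- rlnorm(n, 4, 1)
    fpkm0 <- tibble::tibble(gene_id = ids, control_1 = expr0, mutant_1 = expr0)
    r0 <- mark_vs_expression_test(fpkm0, make_marks_table(ids, sample(marked)), design)
    expect_true(all(r0$p > 0.01))

    # marked genes at 4x lower baseline
    expr1 <- rlnorm(n, 4, 1) * ifelse(marked == "high", 0.25, 1)
    fpkm1 <- tibble::tibble(gene_id = ids, control_1 = expr1, mutant_1 = expr1)
    mk <- make_marks_table(ids, marked)
    r1 <- mark_vs_expression_test(fpkm1, mk, design)
    expect_true(all(r1$p < 0.01))
    expect_true(all(r1$median_marked < r1$median_unmarked))

    # swapping the class labels flips direction, same p
    flipped <- mk
    flipped$mark_class <- ifelse(mk$mark_class == "high", "low", "high")
    r2 <- mark_vs_expression_test(fpkm1, flipped, design)
    expect_equal(r2$p, r1$p)
    expect_true(all(r2$median_marked > r2$median_unmarked))

    # a single class present: degenerate, p undefined
    allhigh <- mark_vs_expression_test(fpkm1, make_marks_table(ids, rep("high", n)), design)
    expect_true(all(allhigh$degenerate))
    expect_true(all(is.na(allhigh$p)))
  })
})

test_that("mark/DE association is null under independence and matches Fisher exactly", {
  withr::with_seed(17, {
    n <- 2000
    ids <- sprintf("g%04d", 1:n)
    status <- sample(c("up", "ns"), n, replace = TRUE, prob = c(0.1, 0.9))
    mark <- sample(c("high", "low"), n, replace = TRUE, prob = c(0.18, 0.82))
    it <- cross_reference(make_de_table(ids, status), make_marks_table(ids, mark))
    res <- mark_vs_de_association(it)
    expect_gt(res$p, 0.01)
    expect_gt(res$odds_ratio, 0.6)
    expect_lt(res$odds_ratio, 1.6)
    expect_equal(res$marked_de + res$marked_not_de + res$unmarked_de + res$unmarked_not_de, n)
  })
})

test_that("default synthetic fixture recovers the derepressed direct targets", {
  sim <- simulate_dataset(simulation_config(seed = 1))
  de <- diff_expression(sim$counts, sim$design, sim$annotation, seed = 1)
  marks <- tss_density(sim$tags, sim$annotation)
  it <- cross_reference(de, marks)
  expect_equal(sum(it$counts), nrow(sim$truth))

  # marked_up count within +/-20% of the number of true marked-up targets
  expect_gte(it$counts[["marked_up"]], 0.8 * 50)
  expect_lte(it$counts[["marked_up"]], 1.2 * 50)

  rec <- recovery_metrics(extract_direct_targets(it), sim$truth)
  expect_gte(rec$up$sensitivity, 0.9)
  expect_gte(rec$up$precision, 0.9)
})
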