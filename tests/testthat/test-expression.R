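test_that("FPKM follows its definition and is invariant to joint rescaling", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           s_1 = c(10L, 0L), s_2 = c(20L, 5L))
  ann <- tibble::tibble(gene_id = c("g1", "g2"), exonic_length = c(1000L, 500L))
  ls <- c(s_1 = 1e6, s_2 = 2e6)
  fpkm <- compute_fpkm(counts, ann, library_size = ls)
  expect_equal(fpkm$s_1, c(10, 0))             # 10 frags / 1 kb / 1 M
  expect_equal(fpkm$s_2, c(10, 5))

  doubled <- counts
  doubled$s_1 <- doubled$s_1 * 2L; doubled$s_2 <- doubled$s_2 * 2L
  fpkm2 <- compute_fpkm(doubled, ann, library_size = ls * 2)
  expect_equal(fpkm2, fpkm)

  expect_error(compute_fpkm(counts, ann[1, ], library_size = ls), "g2",
               class = "derepressr_key_error")
  expect_error(compute_fpkm(counts, ann, library_size = c(s_1 = 0, s_2 = 1e6)),
               "positive")
})

test_that("condition means are per-condition averages, invariant to sample order", {
  fpkm <- tibble::tibble(gene_id = "g1", m_1 = 2, m_2 = 4, c_1 = 7)
  design <- tibble::tibble(sample = c("m_1", "m_2", "c_1"),
                           condition = c("mutant", "mutant", "control"))
  cm <- condition_means(fpkm, design)
  expect_equal(cm$a, 3)
  expect_equal(cm$b, 7)   # single sample: mean equals that sample
  shuffled <- fpkm[, c("gene_id", "c_1", "m_2", "m_1")]
  expect_equal(condition_means(shuffled, design), cm)
  design$condition[1] <- "treated"
  expect_error(condition_means(fpkm, design), "treated")
})

test_that("diffrat matches hand-evaluated values and its algebraic contract", {
  expect_equal(diffrat_score(5, 5), 0)
  expect_equal(diffrat_score(3, 0), 6)          # 3 * log2(4)
  expect_equal(diffrat_score(0, 3), -6)
  expect_equal(diffrat_score(7, 1), 12)         # 6 * log2(4)
  expect_error(diffrat_score(-1, 2), class = "derepressr_domain_error")
  expect_error(diffrat_score(1, Inf), class = "derepressr_domain_error")

  withr::with_seed(99, {
    a <- runif(1e4, 0, 1e3)
    b <- runif(1e4, 0, 1e3)
    expect_equal(diffrat_score(a, b), -diffrat_score(b, a))
    expect_true(all((diffrat_score(a, b) == 0) == (a == b)))
    # strictly increasing in a for fixed b on a > b
    b0 <- 2
    agrid <- sort(runif(500, b0 + 1e-6, 1e3))
    expect_true(all(diff(diffrat_score(agrid, b0)) > 0))
  })
})

test_that("per-gene permutation p-values equal exhaustive enumeration", {
  withr::with_seed(21, {
    shapes <- list(c(2, 2), c(2, 3), c(3, 3), c(4, 4), c(5, 5), c(4, 6))
    for (sh in shapes) {
      cond <- rep(c("control", "mutant"), sh)
      m <- matrix(rnbinom(12 * sum(sh), mu = 50, size = 5), nrow = 12)
      fx <- fpkm_tibble(m, cond)
      got <- permutation_significance(fx$fpkm, fx$design, n_permutations = 1000,
                                      null = "per_gene")
      expect_equal(got$p_raw, unname(oracle_pergene_perm(m, cond)),
                   label = paste(sh, collapse = "v"))
    }
  })
})

test_that("a maximally separated gene attains the minimal exhaustive p of 1/10 at 3v3", {
  cond <- rep(c("control", "mutant"), each = 3)
  m <- matrix(5, nrow = 2000, ncol = 6)     # constant null genes
  m[1, ] <- c(0, 0, 0, 100, 100, 100)       # condition means 0 vs 100
  fx <- fpkm_tibble(m, cond)
  got <- permutation_significance(fx$fpkm, fx$design, n_permutations = 1000,
                                  null = "per_gene")
  expect_equal(got$p_raw[1], 1 / 10)
  expect_equal(got$p_raw[-1], rep(1, 1999))   # all-constant genes: p = 1
  expect_true(all(got$p_raw > 0 & got$p_raw <= 1))
  # BH is monotone non-decreasing in the p-value ranks
  ord <- order(got$p_raw)
  expect_true(all(diff(got$p_adj[ord]) >= 0))
})

test_that("permutation machinery validates its inputs and is seed-deterministic", {
  cond <- rep(c("control", "mutant"), each = 2)
  m <- matrix(runif(40, 0, 100), nrow = 10)
  fx <- fpkm_tibble(m, cond)
  expect_error(permutation_significance(fx$fpkm, fx$design, n_permutations = 10),
               ">= 100")
  solo <- fpkm_tibble(m[, c(1, 3, 4)], c("control", "mutant", "mutant"))
  expect_error(permutation_significance(solo$fpkm, solo$design),
               "2 replicates")

  # sampled assignments (choose(12,6) = 924 > 500) are reproducible by seed
  cond12 <- rep(c("control", "mutant"), each = 6)
  m12 <- matrix(rnbinom(50 * 12, mu = 40, size = 5), nrow = 50)
  fx12 <- fpkm_tibble(m12, cond12)
  r1 <- permutation_significance(fx12$fpkm, fx12$design, n_permutations = 500,
                                 null = "per_gene", seed = 4)
  r2 <- permutation_significance(fx12$fpkm, fx12$design, n_permutations = 500,
                                 null = "per_gene", seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1$p_raw >= 1 / 501))
})

test_that("status calls apply the alpha threshold to the signed score", {
  tab <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    diffrat = c(4, 4, -2, 0),
    p_adj = c(0.009, 0.011, 0.005, 0.001)
  )
  out <- call_differential(tab, alpha = 0.01)
  expect_equal(out$status, c("up", "ns", "down", "ns"))
})

test_that("pooled-null calling controls the false-call rate on a global-null fixture", {
  cfg <- simulation_config(n_targets_up = 0, n_targets_down = 0,
                           n_unmarked_de = 0, seed = 23)
  sim <- simulate_dataset(cfg)
  de <- diff_expression(sim$counts, sim$design, sim$annotation,
                        n_permutations = 1000, null = "pooled", seed = 23)
  expect_lte(mean(de$table$p_adj <= 0.01), 0.02)
})
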