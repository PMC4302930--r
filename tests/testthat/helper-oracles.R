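# Independent brute-force oracles, deliberately written with different
# primitives from the package implementation.

# Per-gene exhaustive permutation p-values for the diffrat statistic:
# enumerate every way of labelling `n_mut` of the samples as mutant and count
# the fraction of labelings whose |score| reaches the observed one.
oracle_pergene_perm <- function(expr_matrix, condition) {
  n <- ncol(expr_matrix)
  n_mut <- sum(condition == "mutant")
  splits <- utils::combn(n, n_mut, simplify = FALSE)
  obs_mut <- which(condition == "mutant")
  score <- function(row, mut_idx) {
    a <- mean(row[mut_idx])
    b <- mean(row[-mut_idx])
    abs(a - b) * log2((a + 1) / (b + 1))
  }
  apply(expr_matrix, 1, function(row) {
    obs <- abs(score(row, obs_mut))
    perm <- vapply(splits, function(ix) abs(score(row, ix)), numeric(1))
    mean(perm >= obs - 1e-9 * max(obs, 1))
  })
}

# Two-sided Fisher p for a 2x2 table from first principles: enumerate all
# tables with the observed margins, probabilities from binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# tiny simulation config for fast tests
small_config <- function(...) {
  simulation_config(n_genes = 60, n_targets_up = 4, n_targets_down = 2,
                    n_unmarked_de = 3, library_size = 2e5, seed = 42, ...)
}

# FPKM tibble straight from a matrix, for permutation tests that do not
# need the annotation machinery
fpkm_tibble <- function(m, conditions) {
  stopifnot(ncol(m) == length(conditions))
  samples <- sprintf("%s_%d", conditions, stats::ave(seq_along(conditions),
                                                     conditions, FUN = seq_along))
  colnames(m) <- samples
  list(
    fpkm = dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(m)))),
                            tibble::as_tibble(m)),
    design = tibble::tibble(sample = samples, condition = conditions)
  )
}
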