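#' Simulation configuration for the synthetic endothelial dataset
#'
#' Bundles and validates every knob of the synthetic-data generator: the gene
#' universe, the H3K27me3-marked fraction, how many marked genes truly respond
#' to methyltransferase loss, the RNA-seq count model, and the ChIP tag model.
#'
#' The defaults describe a desk-scale sorted-endothelium experiment: 2000
#' genes of which 18% carry the repressive mark, 50 marked genes truly
#' upregulated in the knockout, 6 truly downregulated, a further 50
#' differentially expressed genes without the mark, and three per-embryo
#' replicate libraries per genotype. These proportions mirror the structure of
#' a genome-scale dataset (thousands of marked genes, an order of magnitude
#' more marked-up than marked-down responders) at a size where exact oracles
#' and permutation tests run in seconds.
#'
#' @param n_genes Number of genes in the synthetic genome.
#' @param fraction_marked Proportion of genes carrying H3K27me3 at the TSS.
#' @param n_targets_up Marked genes truly upregulated in the mutant
#'   (derepressed direct targets).
#' @param n_targets_down Marked genes truly downregulated in the mutant.
#' @param n_unmarked_de Differentially expressed genes without the mark.
#' @param replicates_per_condition RNA-seq libraries per genotype (one per
#'   embryo); at least 2 so condition labels are exchangeable under the null.
#' @param baseline_log_mean,baseline_log_sd Meanlog/sdlog of the log-normal
#'   distribution of relative baseline expression.
#' @param marked_expression_factor Multiplier applied to the baseline of
#'   marked genes (repressed genes sit at lower expression; default 0.25,
#'   i.e. 4-fold depression).
#' @param nb_dispersion Negative-binomial dispersion of RNA-seq counts
#'   (variance = mu + dispersion * mu^2).
#' @param target_log2fc_mean,target_log2fc_sd Mean and sd of the absolute
#'   log2 fold change of true responder genes.
#' @param prop_unmarked_up Fraction of the unmarked DE genes that go up.
#' @param chip_background_rate Genome-wide ChIP tag background, tags per bp.
#' @param chip_enrichment_factor Fold enrichment of tag rate inside the TSS
#'   windows of marked genes. The quantile-anchored 0-10 log scale with its
#'   high/low boundary at 2 implies marked windows must out-count background
#'   windows by roughly (background + 1)^5, hence the large default.
#' @param library_size Mapped fragments per RNA-seq library.
#' @param tss_window_bp Half-width of the TSS window the ChIP model enriches
#'   (matched to the scoring window downstream).
#' @param seed Integer seed; the same seed yields bit-identical fixtures.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- simulation_config(n_genes = 100, seed = 1)
#' cfg$n_genes
#' @export
simulation_config <- function(n_genes = 2000,
                              fraction_marked = 0.18,
                              n_targets_up = 50,
                              n_targets_down = 6,
                              n_unmarked_de = 50,
                              replicates_per_condition = 3,
                              baseline_log_mean = log(300),
                              baseline_log_sd = 1.2,
                              marked_expression_factor = 0.25,
                              nb_dispersion = 0.05,
                              target_log2fc_mean = 2,
                              target_log2fc_sd = 0.25,
                              prop_unmarked_up = 0.8,
                              chip_background_rate = 5e-5,
                              chip_enrichment_factor = 500,
                              library_size = 2e6,
                              tss_window_bp = 2000,
                              seed = 1L) {
  cfg <- list(
    n_genes = n_genes,
    fraction_marked = fraction_marked,
    n_targets_up = n_targets_up,
    n_targets_down = n_targets_down,
    n_unmarked_de = n_unmarked_de,
    replicates_per_condition = replicates_per_condition,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    marked_expression_factor = marked_expression_factor,
    nb_dispersion = nb_dispersion,
    target_log2fc_mean = target_log2fc_mean,
    target_log2fc_sd = target_log2fc_sd,
    prop_unmarked_up = prop_unmarked_up,
    chip_background_rate = chip_background_rate,
    chip_enrichment_factor = chip_enrichment_factor,
    library_size = library_size,
    tss_window_bp = tss_window_bp,
    seed = seed
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  check_scalar <- function(field, ok, what) {
    x <- cfg[[field]]
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || !ok(x)) {
      abort(
        sprintf("invalid simulation config: `%s` must be %s", field, what),
        class = "derepressr_config_error"
      )
    }
  }
  check_scalar("n_genes", function(x) x >= 1 && x == trunc(x), "a positive integer")
  check_scalar("fraction_marked", function(x) x >= 0 && x <= 1, "a proportion in [0, 1]")
  check_scalar("n_targets_up", function(x) x >= 0 && x == trunc(x), "a non-negative integer")
  check_scalar("n_targets_down", function(x) x >= 0 && x == trunc(x), "a non-negative integer")
  check_scalar("n_unmarked_de", function(x) x >= 0 && x == trunc(x), "a non-negative integer")
  check_scalar("replicates_per_condition", function(x) x >= 2 && x == trunc(x),
               "an integer >= 2 (the permutation test needs exchangeable replicates)")
  check_scalar("baseline_log_sd", function(x) x > 0, "> 0")
  check_scalar("baseline_log_mean", function(x) is.finite(x), "finite")
  check_scalar("marked_expression_factor", function(x) x > 0, "> 0")
  check_scalar("nb_dispersion", function(x) x > 0, "> 0")
  check_scalar("target_log2fc_sd", function(x) x >= 0, ">= 0")
  check_scalar("prop_unmarked_up", function(x) x >= 0 && x <= 1, "a proportion in [0, 1]")
  check_scalar("chip_background_rate", function(x) x > 0, "> 0 (tags per bp)")
  check_scalar("chip_enrichment_factor", function(x) x > 0, "> 0")
  check_scalar("library_size", function(x) x > 0, "> 0")
  check_scalar("tss_window_bp", function(x) x > 0, "> 0")
  check_scalar("seed", function(x) x == trunc(x), "an integer")

  n_marked <- round(cfg$fraction_marked * cfg$n_genes)
  if (cfg$n_targets_up + cfg$n_targets_down > n_marked) {
    abort(
      paste0("invalid simulation config: `n_targets_up` + `n_targets_down` (",
             cfg$n_targets_up + cfg$n_targets_down,
             ") exceeds the number of marked genes (", n_marked, ")"),
      class = "derepressr_config_error"
    )
  }
  if (cfg$n_unmarked_de > cfg$n_genes - n_marked) {
    abort("invalid simulation config: `n_unmarked_de` exceeds the number of unmarked genes",
          class = "derepressr_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  n_marked <- round(x$fraction_marked * x$n_genes)
  cat(sprintf("  genes: %d (%d marked, %.0f%%)\n", x$n_genes, n_marked,
              100 * x$fraction_marked))
  cat(sprintf("  true targets: %d up / %d down (marked), %d DE unmarked\n",
              x$n_targets_up, x$n_targets_down, x$n_unmarked_de))
  cat(sprintf("  RNA-seq: %d v %d replicates, library %.3g, NB dispersion %.3g\n",
              x$replicates_per_condition, x$replicates_per_condition,
              x$library_size, x$nb_dispersion))
  cat(sprintf("  ChIP: background %.3g tags/bp, enrichment x%g in +/-%d bp TSS windows\n",
              x$chip_background_rate, x$chip_enrichment_factor, x$tss_window_bp))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
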