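#' Generate a synthetic gene annotation
#'
#' Lays out `n_genes` multi-exon gene models over a small set of synthetic
#' chromosomes. Coordinates follow the BED convention (0-based, half-open);
#' the transcription start site is the `start` coordinate for `+` genes and
#' the `end` coordinate for `-` genes. Exonic lengths are at least 200 bp.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss` (0-based), `exonic_length`, and list-columns
#'   `exon_starts` / `exon_ends` (absolute, 0-based half-open).
#' @examples
#' ann <- generate_annotation(simulation_config(n_genes = 5, seed = 1))
#' ann$exonic_length
#' @export
generate_annotation <- function(config) {
  config <- validate_sim_config(unclass(config))
  n <- config$n_genes
  withr::with_seed(config$seed, {
    genes_per_chrom <- 600L
    chrom_idx <- (seq_len(n) - 1L) %/% genes_per_chrom + 1L
    chrom <- sprintf("chrS%d", chrom_idx)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    rows <- vector("list", n)
    cursor <- 1000L         # per-chromosome placement cursor
    cur_chrom <- 1L
    for (i in seq_len(n)) {
      if (chrom_idx[i] != cur_chrom) {
        cur_chrom <- chrom_idx[i]
        cursor <- 1000L
      }
      n_exons <- sample(1:8, 1L)
      exon_sizes <- sample(80:900, n_exons, replace = TRUE)
      # guarantee the 200 bp exonic-length floor even for single short exons
      if (sum(exon_sizes) < 200L) exon_sizes[1L] <- exon_sizes[1L] + 200L
      intron_sizes <- if (n_exons > 1L) sample(200:3000, n_exons - 1L, replace = TRUE) else integer()
      offsets <- cumsum(c(0L, head(exon_sizes, -1L) + intron_sizes))
      start <- cursor
      exon_starts <- start + offsets
      exon_ends <- exon_starts + exon_sizes
      end <- exon_ends[n_exons]
      rows[[i]] <- list(start = start, end = end,
                        exon_starts = as.integer(exon_starts),
                        exon_ends = as.integer(exon_ends))
      cursor <- end + sample(2000:10000, 1L)
    }

    start <- vapply(rows, `[[`, integer(1), "start")
    end <- vapply(rows, `[[`, integer(1), "end")
    tibble(
      gene_id = sprintf("gene%04d", seq_len(n)),
      chrom = chrom,
      start = start,
      end = end,
      strand = strand,
      tss = ifelse(strand == "+", start, end),
      exonic_length = vapply(rows, function(r) sum(r$exon_ends - r$exon_starts), integer(1)),
      exon_starts = lapply(rows, `[[`, "exon_starts"),
      exon_ends = lapply(rows, `[[`, "exon_ends")
    )
  })
}

#' Simulate the ground-truth table
#'
#' Assigns each gene its H3K27me3 status, its true response to
#' methyltransferase loss, and its baseline expression level. Exactly
#' `round(fraction_marked * n_genes)` genes are marked; `n_targets_up` /
#' `n_targets_down` of them are true responders (the derepressed
#' direct-target analogs), and `n_unmarked_de` unmarked genes respond too.
#' Marked genes sit at `marked_expression_factor` times the unmarked
#' baseline, reflecting their repressed state.
#'
#' @param annotation Tibble from [generate_annotation()].
#' @param config A [simulation_config()].
#' @return A tibble: `gene_id`, `is_marked`, `target_class`
#'   (`"up"`/`"down"`/`"none"`), `true_log2fc`,
#'   `baseline_mean_expression`.
#' @export
simulate_truth <- function(annotation, config) {
  config <- validate_sim_config(unclass(config))
  n <- nrow(annotation)
  if (n != config$n_genes) {
    abort("`annotation` does not match `config$n_genes`")
  }
  n_marked <- round(config$fraction_marked * n)
  withr::with_seed(config$seed + 1L, {
    marked_idx <- sample.int(n, n_marked)
    is_marked <- logical(n)
    is_marked[marked_idx] <- TRUE

    target_class <- rep("none", n)
    resp <- sample(marked_idx, config$n_targets_up + config$n_targets_down)
    up_idx <- head(resp, config$n_targets_up)
    down_idx <- resp[seq_len(config$n_targets_down) + config$n_targets_up]
    target_class[up_idx] <- "up"
    target_class[down_idx] <- "down"

    unmarked_idx <- setdiff(seq_len(n), marked_idx)
    de_unmarked <- sample(unmarked_idx, config$n_unmarked_de)
    n_up_unmarked <- round(config$prop_unmarked_up * config$n_unmarked_de)
    sign_unmarked <- rep(-1, config$n_unmarked_de)
    sign_unmarked[seq_len(n_up_unmarked)] <- 1

    true_log2fc <- numeric(n)
    draw_lfc <- function(k) abs(rnorm(k, config$target_log2fc_mean, config$target_log2fc_sd))
    true_log2fc[up_idx] <- draw_lfc(length(up_idx))
    true_log2fc[down_idx] <- -draw_lfc(length(down_idx))
    true_log2fc[de_unmarked] <- sign_unmarked * draw_lfc(length(de_unmarked))

    baseline <- rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
    baseline[is_marked] <- baseline[is_marked] * config$marked_expression_factor

    tibble(
      gene_id = annotation$gene_id,
      is_marked = is_marked,
      target_class = target_class,
      true_log2fc = true_log2fc,
      baseline_mean_expression = baseline
    )
  })
}

#' Simulate RNA-seq fragment counts
#'
#' Draws negative-binomial counts for every gene in every replicate library.
#' Control-condition means are proportional to the truth table's baseline
#' expression (scaled so a library totals about `library_size` fragments);
#' mutant-condition means are the baseline times `2^true_log2fc`. Sample ids
#' encode the genotype (`control_1`, ..., `mutant_1`, ...), one library per
#' embryo.
#'
#' @param annotation Tibble from [generate_annotation()].
#' @param truth Tibble from [simulate_truth()]; must cover every gene.
#' @param config A [simulation_config()].
#' @return A list with `counts` (tibble: `gene_id` plus one integer column
#'   per sample) and `design` (tibble: `sample`, `condition`,
#'   `library_size`).
#' @export
simulate_rnaseq_counts <- function(annotation, truth, config) {
  config <- validate_sim_config(unclass(config))
  if (config$replicates_per_condition < 2) {
    abort("`replicates_per_condition` must be >= 2")
  }
  if (!setequal(truth$gene_id, annotation$gene_id)) {
    abort("`truth` must cover exactly the genes in `annotation`")
  }
  truth <- truth[match(annotation$gene_id, truth$gene_id), ]
  r <- config$replicates_per_condition
  samples <- c(sprintf("control_%d", seq_len(r)), sprintf("mutant_%d", seq_len(r)))
  condition <- rep(c("control", "mutant"), each = r)

  w <- truth$baseline_mean_expression / sum(truth$baseline_mean_expression)
  mu_control <- config$library_size * w
  mu_mutant <- mu_control * 2^truth$true_log2fc
  size <- 1 / config$nb_dispersion

  withr::with_seed(config$seed + 2L, {
    counts <- matrix(0L, nrow = nrow(annotation), ncol = 2L * r)
    for (j in seq_along(samples)) {
      mu <- if (condition[j] == "control") mu_control else mu_mutant
      counts[, j] <- rnbinom(length(mu), mu = mu, size = size)
    }
    colnames(counts) <- samples
    list(
      counts = dplyr::bind_cols(tibble(gene_id = annotation$gene_id),
                                as_tibble(counts)),
      design = tibble(sample = samples, condition = condition,
                      library_size = config$library_size)
    )
  })
}

#' Simulate H3K27me3 ChIP-seq tag positions
#'
#' Scatters Poisson background tags uniformly over each synthetic chromosome
#' at `chip_background_rate` tags/bp, then adds extra tags inside the
#' TSS +/- `tss_window_bp` windows of marked genes so the total rate there is
#' `chip_enrichment_factor` times background. Tag strand is random: a histone
#' mark is strand-agnostic.
#'
#' @inheritParams simulate_rnaseq_counts
#' @return A tibble of tags: `chrom`, `pos` (0-based), `strand`, sorted by
#'   chromosome and position.
#' @export
simulate_chip_tags <- function(annotation, truth, config) {
  config <- validate_sim_config(unclass(config))
  if (nrow(annotation) == 0L) {
    return(tibble(chrom = character(), pos = integer(), strand = character()))
  }
  truth <- truth[match(annotation$gene_id, truth$gene_id), ]
  chrom_len <- annotation |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end) + 10000L, .groups = "drop")

  withr::with_seed(config$seed + 3L, {
    bg <- purrr::pmap(chrom_len, function(chrom, len) {
      k <- rpois(1L, config$chip_background_rate * len)
      tibble(chrom = chrom, pos = as.integer(floor(runif(k, 0, len))))
    })
    w <- config$tss_window_bp
    marked <- annotation[truth$is_marked, ]
    extra_rate <- config$chip_background_rate * (config$chip_enrichment_factor - 1)
    enr <- if (nrow(marked) > 0L && extra_rate > 0) {
      k <- rpois(nrow(marked), extra_rate * 2 * w)
      lo <- pmax(marked$tss - w, 0L)
      hi <- marked$tss + w
      purrr::pmap(list(marked$chrom, lo, hi, k), function(chrom, lo, hi, k) {
        tibble(chrom = chrom, pos = as.integer(floor(runif(k, lo, hi))))
      })
    } else {
      list()
    }
    tags <- dplyr::bind_rows(c(bg, enr))
    tags$strand <- sample(c("+", "-"), nrow(tags), replace = TRUE)
    dplyr::arrange(tags, .data$chrom, .data$pos)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_annotation()], [simulate_truth()],
#' [simulate_rnaseq_counts()] and [simulate_chip_tags()].
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_dataset`: `annotation`, `truth`, `counts`,
#'   `design`, `tags`, `config`.
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 50, n_targets_up = 3,
#'                                           n_targets_down = 1, n_unmarked_de = 2,
#'                                           seed = 7))
#' names(sim)
#' @export
simulate_dataset <- function(config = simulation_config()) {
  config <- validate_sim_config(unclass(config))
  annotation <- generate_annotation(config)
  truth <- simulate_truth(annotation, config)
  rna <- simulate_rnaseq_counts(annotation, truth, config)
  tags <- simulate_chip_tags(annotation, truth, config)
  structure(
    list(annotation = annotation, truth = truth, counts = rna$counts,
         design = rna$design, tags = tags, config = config),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>\n")
  cat(sprintf("  %d genes, %d marked; %d samples; %d ChIP tags; seed %d\n",
              nrow(x$annotation), sum(x$truth$is_marked),
              nrow(x$design), nrow(x$tags), x$config$seed))
  invisible(x)
}
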