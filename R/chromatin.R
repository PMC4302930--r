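#' Count ChIP tags around transcription start sites
#'
#' For each gene, counts tag positions `p` with
#' `tss - window_bp <= p < tss + window_bp` (0-based, half-open on the
#' right), i.e. a 2 * `window_bp` window centred on the strand-aware TSS.
#' Tags on either strand count: a histone mark has no strand. Genes on
#' chromosomes absent from the tag set get a count of 0 with a warning.
#'
#' @param tags Tag tibble (`chrom`, `pos`, `strand`).
#' @param annotation Annotation tibble with `chrom` and `tss`.
#' @param window_bp Window half-width in bp (default 2000).
#' @return A tibble: `gene_id`, `raw_count`.
#' @examples
#' tags <- tibble::tibble(chrom = "chr1", pos = c(8500L, 11900L), strand = "+")
#' ann <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 10000L)
#' count_tss_tags(tags, ann)  # both tags inside 10000 +/- 2000
#' @export
count_tss_tags <- function(tags, annotation, window_bp = 2000) {
  if (window_bp <= 0) abort("`window_bp` must be positive")
  unknown <- setdiff(unique(annotation$chrom), unique(tags$chrom))
  if (length(unknown) && nrow(tags)) {
    warn(paste0("no tags on chromosome(s): ", paste(unknown, collapse = ", "),
                "; affected genes get count 0"))
  }
  if (nrow(tags) == 0L) {
    return(tibble(gene_id = annotation$gene_id, raw_count = rep(0L, nrow(annotation))))
  }
  # 0-based half-open [tss - w, tss + w) == 1-based closed [tss - w + 1, tss + w]
  levels <- union(unique(annotation$chrom), unique(tags$chrom))
  windows <- GenomicRanges::GRanges(
    seqnames = factor(annotation$chrom, levels),
    ranges = IRanges::IRanges(start = annotation$tss - window_bp + 1L,
                              end = annotation$tss + window_bp)
  )
  tag_gr <- GenomicRanges::GRanges(
    seqnames = factor(tags$chrom, levels),
    ranges = IRanges::IRanges(start = tags$pos + 1L, width = 1L)
  )
  counts <- GenomicRanges::countOverlaps(windows, tag_gr, ignore.strand = TRUE)
  tibble(gene_id = annotation$gene_id, raw_count = as.integer(counts))
}

#' Scale raw tag counts to the quantile-anchored 0-10 log scale
#'
#' Log-transforms pseudocounted raw counts and rescales them so that the
#' value capturing 95% of the data (the `capture_quantile` empirical
#' quantile of the raw counts) maps to exactly `scale_max`; larger counts
#' are clipped to `scale_max`. If the anchor quantile is 0 every scaled
#' value is 0. The base of the logarithm cancels in the ratio.
#'
#' @param raw_counts Integer vector of per-gene tag counts (>= 0).
#' @param capture_quantile Quantile that anchors the top of the scale
#'   (default 0.95).
#' @param scale_max Top of the scale (default 10).
#' @return Numeric vector of scaled values in `[0, scale_max]`.
#' @export
scale_to_ten <- function(raw_counts, capture_quantile = 0.95, scale_max = 10) {
  if (length(raw_counts) == 0L) abort("`raw_counts` must contain at least one gene")
  if (any(raw_counts < 0)) abort("`raw_counts` must be non-negative")
  if (!(capture_quantile > 0 && capture_quantile < 1)) {
    abort("`capture_quantile` must be in (0, 1)")
  }
  q <- quantile(raw_counts, capture_quantile, names = FALSE, type = 7)
  if (q == 0) return(rep(0, length(raw_counts)))
  pmin(scale_max, scale_max * log2(raw_counts + 1) / log2(q + 1))
}

#' Classify genes as having high or low H3K27me3 signal
#'
#' On the 0-10 scale, values of `threshold` (default 2) or less are `low`;
#' values strictly greater are `high`.
#'
#' @param scaled Numeric vector of scaled values in `[0, scale_max]`.
#' @param threshold Class boundary (default 2).
#' @param scale_max Top of the scale (default 10).
#' @return Character vector, `"low"` or `"high"`.
#' @export
classify_mark <- function(scaled, threshold = 2, scale_max = 10) {
  if (any(scaled < 0 | scaled > scale_max)) {
    abort("`scaled` values must lie in [0, scale_max]; upstream scaling bug?")
  }
  if (!(threshold > 0 && threshold < scale_max)) {
    abort("`threshold` must be strictly between 0 and `scale_max`")
  }
  ifelse(scaled > threshold, "high", "low")
}

#' TSS H3K27me3 tag-density scoring and high/low mark calls
#'
#' Full chromatin stage: window counting at each TSS, quantile-anchored
#' 0-10 log scaling, and the high/low call at 2/10.
#'
#' @inheritParams count_tss_tags
#' @inheritParams scale_to_ten
#' @inheritParams classify_mark
#' @return An object of class `derep_marks`: list with `table` (tibble:
#'   `gene_id`, `raw_count`, `scaled`, `mark_class`) and `params`.
#' @export
tss_density <- function(tags, annotation, window_bp = 2000,
                        capture_quantile = 0.95, scale_max = 10,
                        threshold = 2) {
  table <- count_tss_tags(tags, annotation, window_bp = window_bp)
  table$scaled <- scale_to_ten(table$raw_count, capture_quantile = capture_quantile,
                               scale_max = scale_max)
  table$mark_class <- classify_mark(table$scaled, threshold = threshold,
                                    scale_max = scale_max)
  structure(
    list(table = table,
         params = list(window_bp = window_bp, capture_quantile = capture_quantile,
                       scale_max = scale_max, threshold = threshold)),
    class = "derep_marks"
  )
}

#' @export
print.derep_marks <- function(x, ...) {
  n_high <- sum(x$table$mark_class == "high")
  cat("<derep_marks> TSS H3K27me3 tag density\n")
  cat(sprintf("  %d genes: %d high, %d low (window +/-%d bp, threshold %g/%g)\n",
              nrow(x$table), n_high, nrow(x$table) - n_high,
              x$params$window_bp, x$params$threshold, x$params$scale_max))
  invisible(x)
}

#' @rdname tss_density
#' @param x A `derep_marks` object.
#' @param ... Unused.
#' @export
tidy.derep_marks <- function(x, ...) x$table

#' @rdname tss_density
#' @export
glance.derep_marks <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_high = sum(x$table$mark_class == "high"),
    n_low = sum(x$table$mark_class == "low"),
    window_bp = x$params$window_bp,
    capture_quantile = x$params$capture_quantile,
    threshold = x$params$threshold
  )
}
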