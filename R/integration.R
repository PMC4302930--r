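#' Cross-reference DE status with H3K27me3 mark class
#'
#' Joins the differential-expression calls and the TSS mark classes on a
#' shared gene universe and assigns each gene one of six categories:
#' `marked_up`, `marked_down`, `marked_ns`, `unmarked_up`, `unmarked_down`,
#' `unmarked_ns` (mark class `high` = "marked"). The categories partition
#' the gene universe.
#'
#' @param de A `derep_de` object or its tidied table (needs `gene_id`,
#'   `diffrat`, `status`).
#' @param marks A `derep_marks` object or its tidied table (needs
#'   `gene_id`, `scaled`, `mark_class`).
#' @return An object of class `derep_integration`: list with `table`
#'   (tibble: `gene_id`, `diffrat`, `p_adj`, `status`, `scaled`,
#'   `mark_class`, `category`) and `counts` (named category counts).
#' @export
cross_reference <- function(de, marks) {
  de_tab <- if (inherits(de, "derep_de")) de$table else as_tibble(de)
  mk_tab <- if (inherits(marks, "derep_marks")) marks$table else as_tibble(marks)
  if (anyDuplicated(de_tab$gene_id) || anyDuplicated(mk_tab$gene_id)) {
    abort("duplicated gene ids", class = "derepressr_key_error")
  }
  only_de <- setdiff(de_tab$gene_id, mk_tab$gene_id)
  only_mk <- setdiff(mk_tab$gene_id, de_tab$gene_id)
  if (length(only_de) || length(only_mk)) {
    abort(paste0(
      "gene universes differ; only in DE table: ",
      paste(head(only_de, 5), collapse = ", "),
      if (length(only_de) > 5) " ...", " | only in marks table: ",
      paste(head(only_mk, 5), collapse = ", "),
      if (length(only_mk) > 5) " ..."
    ), class = "derepressr_key_error")
  }
  keep_de <- intersect(c("gene_id", "a", "b", "diffrat", "p_adj", "status"), names(de_tab))
  keep_mk <- intersect(c("gene_id", "raw_count", "scaled", "mark_class"), names(mk_tab))
  tab <- dplyr::inner_join(de_tab[keep_de], mk_tab[keep_mk], by = "gene_id") |>
    dplyr::mutate(category = paste0(
      ifelse(.data$mark_class == "high", "marked_", "unmarked_"), .data$status
    ))
  lev <- c("marked_up", "marked_down", "marked_ns",
           "unmarked_up", "unmarked_down", "unmarked_ns")
  counts <- table(factor(tab$category, levels = lev))
  structure(list(table = tab, counts = setNames(as.integer(counts), lev)),
            class = "derep_integration")
}

#' @export
print.derep_integration <- function(x, ...) {
  cat("<derep_integration> DE x H3K27me3 cross-reference\n")
  print(x$counts)
  invisible(x)
}

#' @rdname cross_reference
#' @param x A `derep_integration` object.
#' @param ... Unused.
#' @export
tidy.derep_integration <- function(x, ...) x$table

#' @rdname cross_reference
#' @export
glance.derep_integration <- function(x, ...) {
  dplyr::bind_cols(tibble(n_genes = nrow(x$table)),
                   as_tibble(as.list(x$counts)))
}

#' Extract derepressed direct-target calls
#'
#' Direct targets of the repressor are genes that carry the H3K27me3 mark
#' and respond to its loss: `marked_up` genes are the derepressed
#' direct-target analogs, `marked_down` the repressed ones.
#'
#' @param integrated A `derep_integration` object.
#' @return A list with character vectors `up` (marked & upregulated) and
#'   `down` (marked & downregulated).
#' @export
extract_direct_targets <- function(integrated) {
  tab <- integrated$table
  list(
    up = tab$gene_id[tab$category == "marked_up"],
    down = tab$gene_id[tab$category == "marked_down"]
  )
}

#' Are marked genes expressed at lower levels?
#'
#' Two-sided Wilcoxon rank-sum comparison of per-gene mean FPKM between
#' high- and low-marked genes, run separately within each condition.
#'
#' @param fpkm FPKM tibble (`gene_id` + sample columns).
#' @param marks A `derep_marks` object or its tidied table.
#' @param design Design tibble (`sample`, `condition`).
#' @return A tibble with one row per condition: `condition`,
#'   `median_marked`, `median_unmarked`, `statistic` (rank-sum W), `p`,
#'   `degenerate` (TRUE when one class is empty; `statistic`/`p` are NA
#'   then).
#' @export
mark_vs_expression_test <- function(fpkm, marks, design) {
  mk_tab <- if (inherits(marks, "derep_marks")) marks$table else as_tibble(marks)
  if (!setequal(fpkm$gene_id, mk_tab$gene_id)) {
    abort("`fpkm` and `marks` must cover the same genes", class = "derepressr_key_error")
  }
  marked <- mk_tab$mark_class[match(fpkm$gene_id, mk_tab$gene_id)] == "high"
  purrr::map_dfr(unique(design$condition), function(cc) {
    samp <- design$sample[design$condition == cc]
    mean_expr <- rowMeans(as.matrix(fpkm[samp]))
    if (!any(marked) || all(marked)) {
      return(tibble(condition = cc,
                    median_marked = median(mean_expr[marked]),
                    median_unmarked = median(mean_expr[!marked]),
                    statistic = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    wt <- wilcox.test(mean_expr[marked], mean_expr[!marked], exact = FALSE)
    tibble(condition = cc,
           median_marked = median(mean_expr[marked]),
           median_unmarked = median(mean_expr[!marked]),
           statistic = unname(wt$statistic), p = wt$p.value, degenerate = FALSE)
  })
}

#' Is the mark associated with differential expression at all?
#'
#' Builds the 2x2 table of mark class (high/low) against DE status
#' (`status != "ns"` vs `ns`) and applies the two-sided Fisher's exact
#' test ([fisher_exact_2x2()]).
#'
#' @param integrated A `derep_integration` object.
#' @return A tibble: cell counts (`marked_de`, `marked_not_de`,
#'   `unmarked_de`, `unmarked_not_de`), `odds_ratio` (sample odds ratio),
#'   `p`.
#' @export
mark_vs_de_association <- function(integrated) {
  tab <- integrated$table
  marked <- tab$mark_class == "high"
  de <- tab$status != "ns"
  m <- matrix(c(sum(marked & de), sum(marked & !de),
                sum(!marked & de), sum(!marked & !de)),
              nrow = 2, byrow = TRUE)
  ft <- fisher_exact_2x2(m)
  tibble(
    marked_de = m[1, 1], marked_not_de = m[1, 2],
    unmarked_de = m[2, 1], unmarked_not_de = m[2, 2],
    odds_ratio = ft$odds_ratio, p = ft$p
  )
}
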