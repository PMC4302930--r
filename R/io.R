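annotation_to_granges <- function(annotation) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L, end = annotation$end),
    strand = annotation$strand
  )
  names(gr) <- annotation$gene_id
  blocks <- IRanges::IRangesList(purrr::pmap(
    list(annotation$exon_starts, annotation$exon_ends, annotation$start),
    function(es, ee, s) IRanges::IRanges(start = es - s + 1L, end = ee - s)
  ))
  S4Vectors::mcols(gr)$blocks <- blocks
  gr
}

granges_to_annotation <- function(gr) {
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) {
    exon_starts <- as.list(start0)
    exon_ends <- as.list(end0)
  } else {
    exon_starts <- purrr::map2(as.list(IRanges::start(blocks)), start0, function(b, s) b + s - 1L)
    exon_ends <- purrr::map2(as.list(IRanges::end(blocks)), start0, function(b, s) b + s)
  }
  ids <- names(gr)
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$name
  tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = end0,
    strand = strand,
    tss = ifelse(strand == "+", start0, end0),
    exonic_length = vapply(seq_along(exon_starts),
                           function(i) sum(exon_ends[[i]] - exon_starts[[i]]),
                           integer(1)),
    exon_starts = exon_starts,
    exon_ends = exon_ends
  )
}

#' Read a gene annotation from BED12 or GTF
#'
#' BED12 files are taken at face value (one gene model per line, exon
#' structure from the block fields). For GTF, exon records are grouped by
#' `gene_id`; the gene span is the exon envelope and the exonic length is the
#' length of the union of exon intervals. All returned coordinates are
#' 0-based half-open; `tss` is the strand-aware transcription start.
#'
#' @param path Path to a `.bed` (BED12) or `.gtf` file; gzip accepted.
#' @return An annotation tibble (see [generate_annotation()] for columns).
#' @export
read_annotation <- function(path) {
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed"
  if (fmt == "bed") {
    return(granges_to_annotation(rtracklayer::import(path, format = "bed")))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(ex) == 0L) abort("GTF contains no exon records")
  by_gene <- GenomicRanges::split(ex, S4Vectors::mcols(ex)$gene_id)
  red <- GenomicRanges::reduce(by_gene)
  strand <- vapply(as.list(red), function(g) as.character(GenomicRanges::strand(g))[1], character(1))
  start0 <- vapply(as.list(red), function(g) min(GenomicRanges::start(g)) - 1L, integer(1))
  end0 <- vapply(as.list(red), function(g) max(GenomicRanges::end(g)), integer(1))
  tibble(
    gene_id = names(red),
    chrom = vapply(as.list(red), function(g) as.character(GenomicRanges::seqnames(g))[1], character(1)),
    start = start0,
    end = end0,
    strand = strand,
    tss = ifelse(strand == "+", start0, end0),
    exonic_length = vapply(as.list(red), function(g) sum(GenomicRanges::width(g)), integer(1)),
    exon_starts = purrr::map(as.list(red), function(g) GenomicRanges::start(g) - 1L),
    exon_ends = purrr::map(as.list(red), function(g) GenomicRanges::end(g))
  )
}

#' Write / read ChIP tag positions as BED6
#'
#' Each tag occupies a single base: `start = pos`, `end = pos + 1` in BED's
#' 0-based half-open convention.
#'
#' @param tags Tibble with `chrom`, `pos`, `strand`.
#' @param path Output/input `.bed` path.
#' @return `write_tags()` returns `path` invisibly; `read_tags()` returns a
#'   tag tibble.
#' @export
write_tags <- function(tags, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(tags)) tags$chrom else character(),
    ranges = IRanges::IRanges(start = tags$pos + 1L, width = 1L),
    strand = if (nrow(tags)) tags$strand else character()
  )
  names(gr) <- if (nrow(tags)) sprintf("tag%d", seq_len(nrow(tags))) else character()
  S4Vectors::mcols(gr)$score <- rep(0L, nrow(tags))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_tags
#' @export
read_tags <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    strand = strand
  )
}

#' Derive the sample design from count-matrix column names
#'
#' Fixture count matrices encode the genotype in the sample id
#' (`control_1`, `mutant_2`, ...); this reconstructs the design tibble.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param library_size Mapped fragments per library (scalar or one per
#'   sample); defaults to the column sums.
#' @return A design tibble: `sample`, `condition`, `library_size`.
#' @export
design_from_samples <- function(counts, library_size = NULL) {
  samples <- setdiff(names(counts), "gene_id")
  condition <- sub("_.*$", "", samples)
  bad <- setdiff(unique(condition), c("control", "mutant"))
  if (length(bad)) {
    abort(paste0("cannot infer condition from sample name(s): ",
                 paste(samples[condition %in% bad], collapse = ", ")))
  }
  if (is.null(library_size)) {
    library_size <- vapply(counts[samples], sum, numeric(1))
  }
  tibble(sample = samples, condition = condition,
         library_size = rep(library_size, length.out = length(samples)))
}

#' Write a synthetic dataset to disk
#'
#' Serializes a [simulate_dataset()] result as plain-text files: BED12
#' annotation, TSV counts (conditions encoded in column names), BED6 tags,
#' TSV truth table and a YAML config, plus a JSON manifest recording the
#' file list and seed. Two runs with the same seed produce byte-identical
#' files.
#'
#' @param sim A `sim_dataset`.
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly (list with `files` and `seed`).
#' @export
write_fixture <- function(sim, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) abort(paste0("cannot create directory: ", outdir))
  }
  files <- c(annotation = "annotation.bed", counts = "counts.tsv",
             tags = "tags.bed", truth = "truth.tsv", config = "config.yaml")
  rtracklayer::export(annotation_to_granges(sim$annotation),
                      file.path(outdir, files["annotation"]), format = "bed")
  readr::write_tsv(sim$counts, file.path(outdir, files["counts"]))
  write_tags(sim$tags, file.path(outdir, files["tags"]))
  readr::write_tsv(sim$truth, file.path(outdir, files["truth"]))
  yaml::write_yaml(unclass(sim$config), file.path(outdir, files["config"]),
                   precision = 17L)
  manifest <- list(files = unname(files), seed = sim$config$seed)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a synthetic dataset written by [write_fixture()]
#'
#' @param dir Fixture directory containing `manifest.json`.
#' @return A `sim_dataset` list (annotation, truth, counts, design, tags,
#'   config).
#' @export
read_fixture <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) abort(paste0("no manifest.json in ", dir))
  config <- validate_sim_config(yaml::read_yaml(file.path(dir, "config.yaml")))
  annotation <- read_annotation(file.path(dir, "annotation.bed"))
  counts <- readr::read_tsv(file.path(dir, "counts.tsv"), show_col_types = FALSE)
  counts <- dplyr::mutate(counts, dplyr::across(-"gene_id", as.integer))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  tags <- read_tags(file.path(dir, "tags.bed"))
  structure(
    list(annotation = annotation, truth = truth, counts = counts,
         design = design_from_samples(counts, library_size = config$library_size),
         tags = tags, config = config),
    class = "sim_dataset"
  )
}
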