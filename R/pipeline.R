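#' Assemble and validate a pipeline configuration
#'
#' A pipeline run takes either a `simulation` block (arguments for
#' [simulation_config()]) or an `inputs` block with file paths
#' (`annotation` BED12/GTF, `counts` TSV, `tags` BED, optional `design`
#' TSV), never neither. Stage parameters live in optional `expression`
#' (`alpha`, `n_permutations`, `null`) and `chromatin` (`window_bp`,
#' `capture_quantile`, `scale_max`, `threshold`) blocks.
#'
#' @param config A named list, or the path of a YAML file holding one.
#' @param outdir Output directory (overrides `config$outdir`).
#' @param seed Integer seed (overrides `config$seed`).
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), outdir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs) {
    abort("config must contain a `simulation` block or an `inputs` block",
          class = "derepressr_config_error")
  }
  if (has_sim && has_inputs) {
    abort("config must not contain both `simulation` and `inputs` blocks",
          class = "derepressr_config_error")
  }
  if (has_inputs) {
    needed <- c("annotation", "counts", "tags")
    missing <- setdiff(needed, names(config$inputs))
    if (length(missing)) {
      abort(paste0("`inputs` block lacks: ", paste(missing, collapse = ", ")),
            class = "derepressr_config_error")
    }
    for (f in intersect(c(needed, "design"), names(config$inputs))) {
      if (!file.exists(config$inputs[[f]])) {
        abort(paste0("input file does not exist: ", config$inputs[[f]]),
              class = "derepressr_config_error")
      }
    }
  } else {
    sim_args <- config$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    config$simulation <- unclass(do.call(simulation_config, sim_args))
  }
  config$expression <- utils::modifyList(
    list(alpha = 0.01, n_permutations = 1000, null = "pooled"),
    config$expression %||% list()
  )
  config$chromatin <- utils::modifyList(
    list(window_bp = 2000, capture_quantile = 0.95, scale_max = 10, threshold = 2),
    config$chromatin %||% list()
  )
  if (is.null(config$outdir)) abort("config needs an `outdir`",
                                    class = "derepressr_config_error")
  structure(config, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full derepression pipeline
#'
#' Orchestrates simulate/load, differential expression, TSS mark scoring,
#' cross-referencing and the association analyses, writing every stage
#' output under `outdir` plus a `report.json`. When ground truth is
#' available (simulated data) the report also carries recovery metrics for
#' the derepressed direct-target calls.
#'
#' @inheritParams pipeline_config
#' @return The report, invisibly (named list mirroring `report.json`).
#' @examples
#' \donttest{
#' cfg <- list(simulation = list(n_genes = 300, n_targets_up = 8,
#'                               n_targets_down = 2, n_unmarked_de = 8),
#'             outdir = file.path(tempdir(), "derep-demo"), seed = 11)
#' rep <- run_pipeline(cfg)
#' rep$category_counts
#' }
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  config <- pipeline_config(config, outdir = outdir, seed = seed)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  stage <- "load inputs"
  report <- tryCatch({
    if (!is.null(config$simulation)) {
      sim <- simulate_dataset(validate_sim_config(config$simulation))
      write_fixture(sim, file.path(outdir, "fixture"))
      annotation <- sim$annotation; counts <- sim$counts
      design <- sim$design; tags <- sim$tags; truth <- sim$truth
    } else {
      annotation <- read_annotation(config$inputs$annotation)
      counts <- readr::read_tsv(config$inputs$counts, show_col_types = FALSE)
      tags <- read_tags(config$inputs$tags)
      design <- if (!is.null(config$inputs$design)) {
        readr::read_tsv(config$inputs$design, show_col_types = FALSE)
      } else {
        design_from_samples(counts)
      }
      truth <- NULL
    }

    stage <- "expression"
    de <- diff_expression(counts, design, annotation,
                          alpha = config$expression$alpha,
                          n_permutations = config$expression$n_permutations,
                          null = config$expression$null,
                          seed = config$seed)
    readr::write_tsv(de$table, file.path(outdir, "diff_expression.tsv"))

    stage <- "chromatin"
    marks <- tss_density(tags, annotation,
                         window_bp = config$chromatin$window_bp,
                         capture_quantile = config$chromatin$capture_quantile,
                         scale_max = config$chromatin$scale_max,
                         threshold = config$chromatin$threshold)
    readr::write_tsv(marks$table, file.path(outdir, "tss_density.tsv"))

    stage <- "integration"
    integ <- cross_reference(de, marks)
    readr::write_tsv(integ$table, file.path(outdir, "integrated.tsv"))
    targets <- extract_direct_targets(integ)
    writeLines(targets$up, file.path(outdir, "targets_up.txt"))
    writeLines(targets$down, file.path(outdir, "targets_down.txt"))
    expr_test <- mark_vs_expression_test(de$fpkm, marks, design)
    assoc <- mark_vs_de_association(integ)

    report <- list(
      seed = config$seed,
      parameters = list(expression = config$expression,
                        chromatin = config$chromatin),
      category_counts = as.list(integ$counts),
      n_de = sum(de$table$status != "ns"),
      n_marked = sum(marks$table$mark_class == "high"),
      direct_targets = list(up = targets$up, down = targets$down),
      mark_vs_expression = purrr::transpose(expr_test),
      mark_vs_de = as.list(assoc)
    )
    if (!is.null(truth)) {
      report$recovery <- recovery_metrics(targets, truth)
    }
    report
  }, error = function(e) {
    abort(paste0("pipeline failed at stage [", stage, "]: ", conditionMessage(e)),
          class = "derepressr_pipeline_error", parent = e)
  })

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Sensitivity and precision of direct-target calls against ground truth
#'
#' @param targets List with `up`/`down` gene-id vectors
#'   ([extract_direct_targets()] output).
#' @param truth Truth tibble ([simulate_truth()] output).
#' @return Named list of sensitivity/precision for the up and down calls.
#' @export
recovery_metrics <- function(targets, truth) {
  score <- function(called, class) {
    true_set <- truth$gene_id[truth$target_class == class & truth$is_marked]
    tp <- length(intersect(called, true_set))
    list(
      n_called = length(called),
      n_true = length(true_set),
      sensitivity = if (length(true_set)) tp / length(true_set) else NA_real_,
      precision = if (length(called)) tp / length(called) else NA_real_
    )
  }
  list(up = score(targets$up, "up"), down = score(targets$down, "down"))
}
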