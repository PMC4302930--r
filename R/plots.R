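#' Plot methods for pipeline results
#'
#' `autoplot.derep_de()` draws the diffrat score against mean expression
#' coloured by call status; `autoplot.derep_marks()` the distribution of
#' scaled TSS tag densities with the high/low boundary;
#' `autoplot.derep_integration()` the signature scatter of differential
#' expression against TSS mark score, highlighting derepressed direct
#' targets.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name derep-plots
NULL

#' @rdname derep-plots
#' @export
autoplot.derep_de <- function(object, ...) {
  tab <- object$table
  tab$mean_expr <- (tab$a + tab$b) / 2
  ggplot2::ggplot(tab, ggplot2::aes(x = log2(.data$mean_expr + 1),
                                    y = .data$diffrat,
                                    colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2(mean FPKM + 1)", y = "diffrat",
                  colour = NULL,
                  title = "Differential expression by diffrat score") +
    ggplot2::theme_minimal()
}

#' @rdname derep-plots
#' @export
autoplot.derep_marks <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$scaled)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$params$threshold,
                        linetype = "dashed", colour = "#c0392b") +
    ggplot2::labs(x = "scaled TSS tag density (0-10)", y = "genes",
                  title = "H3K27me3 TSS signal, quantile-anchored scale") +
    ggplot2::theme_minimal()
}

#' @rdname derep-plots
#' @export
autoplot.derep_integration <- function(object, ...) {
  tab <- object$table
  tab$highlight <- dplyr::case_when(
    tab$category == "marked_up" ~ "marked & up (direct target)",
    tab$category == "marked_down" ~ "marked & down",
    tab$status != "ns" ~ "DE only",
    .default = "other"
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$scaled, y = .data$diffrat,
                                    colour = .data$highlight)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::geom_vline(xintercept = 2, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(
      "marked & up (direct target)" = "#c0392b",
      "marked & down" = "#2980b9",
      "DE only" = "#e67e22",
      "other" = "grey70"
    )) +
    ggplot2::labs(x = "scaled TSS H3K27me3 (0-10)", y = "diffrat",
                  colour = NULL,
                  title = "Differential expression vs TSS H3K27me3") +
    ggplot2::theme_minimal()
}
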