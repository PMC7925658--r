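# ggplot2 displays for each result type.

#' Boxplot of Cq distributions per gene
#'
#' @param data a long Cq tibble.
#' @return A ggplot.
#' @export
plot_cq_distribution <- function(data) {
  data <- as_cq_df(data)
  ord <- data |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(m = stats::median(.data$cq)) |>
    dplyr::arrange(.data$m)
  ggplot2::ggplot(data, ggplot2::aes(
    x = factor(.data$gene, levels = ord$gene), y = .data$cq
  )) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "Cq (cycles)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

stability_barplot <- function(df, value_col, ylab) {
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$gene, .data[[value_col]]),
    y = .data[[value_col]]
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.genorm_fit <- function(object, ...) {
  stability_barplot(object$stability, "m", "geNorm M (lower = more stable)")
}

#' @export
autoplot.normfinder_fit <- function(object, ...) {
  stability_barplot(object$stability, "sv", "NormFinder SV (lower = more stable)")
}

#' @export
autoplot.bestkeeper_fit <- function(object, ...) {
  stability_barplot(object$stability, "mad_cq", "BestKeeper SD[±Cq] (cycles)")
}

#' @export
autoplot.deltact_fit <- function(object, ...) {
  stability_barplot(object$stability, "stability", "Mean pairwise SD of ΔCq (cycles)")
}

#' @export
autoplot.reffinder_fit <- function(object, ...) {
  stability_barplot(object, "geomean", "Geometric mean of method ranks")
}

#' @export
autoplot.pairwise_variation <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(
    x = paste0("V", .data$n, "/", .data$n + 1), y = .data$v
  )) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Pairwise variation V") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.relative_expression <- function(object, ...) {
  ggplot2::ggplot(object$groups, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$se,
        ymax = .data$mean + .data$se
      ),
      width = 0.2
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$letter, y = .data$mean + .data$se),
      vjust = -0.5
    ) +
    ggplot2::labs(
      x = NULL, y = "Relative expression (fraction of peak group)",
      title = paste0(
        object$target, " / {",
        paste(object$refs, collapse = ", "), "}"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scheme_panel <- function(object, ...) {
  df <- purrr::imap_dfr(object$results, function(res, nm) {
    dplyr::mutate(res$groups, scheme = nm)
  }) |>
    dplyr::mutate(scheme = factor(.data$scheme, levels = names(object$results)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$se,
        ymax = .data$mean + .data$se
      ),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(
      x = NULL, y = "Relative expression (fraction of peak group)",
      title = paste0("Target ", object$target, " under each normalization scheme")
    ) +
    ggplot2::theme_minimal()
}
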