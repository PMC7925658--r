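# broom-style tidiers for fitted objects.

#' @rdname refstab-tidiers
#' @name refstab-tidiers
#' @title Tidy and glance methods for refstab fits
#' @description One-row-per-gene `tidy()` tibbles and one-row `glance()`
#'   summaries for the stability fits and validation results.
#' @param x a fitted object.
#' @param ... unused.
NULL

#' @rdname refstab-tidiers
#' @export
tidy.genorm_fit <- function(x, ...) x$stability

#' @rdname refstab-tidiers
#' @export
glance.genorm_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$stability),
    final_pair = paste(x$final_pair, collapse = ","),
    mean_m_final = tail(x$mean_m_path, 1)
  )
}

#' @rdname refstab-tidiers
#' @export
tidy.normfinder_fit <- function(x, ...) x$stability

#' @rdname refstab-tidiers
#' @export
glance.normfinder_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$stability),
    mode = x$mode,
    gamma_sq = if (x$mode == "grouped") x$gamma_sq else NA_real_
  )
}

#' @rdname refstab-tidiers
#' @export
tidy.bestkeeper_fit <- function(x, ...) x$stability

#' @rdname refstab-tidiers
#' @export
glance.bestkeeper_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$stability),
    rank_by = x$rank_by,
    index_sd = sd(x$index$index)
  )
}

#' @rdname refstab-tidiers
#' @export
tidy.deltact_fit <- function(x, ...) x$stability

#' @rdname refstab-tidiers
#' @export
glance.deltact_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$stability),
    mean_stability = mean(x$stability$stability)
  )
}

#' @rdname refstab-tidiers
#' @export
tidy.reffinder_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "reffinder_fit")
  out
}

#' @rdname refstab-tidiers
#' @export
tidy.relative_expression <- function(x, ...) x$groups

#' @rdname refstab-tidiers
#' @export
glance.relative_expression <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    n_refs = length(x$refs),
    anova_f = x$anova_f,
    anova_p = x$anova_p
  )
}

#' @rdname refstab-tidiers
#' @export
tidy.scheme_panel <- function(x, ...) x$summary
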