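# Internal helpers shared across modules.

geo_mean <- function(x) exp(mean(log(x)))

#' Round half away from zero
#'
#' Displays like the spreadsheet tools of this field (2.345 -> 2.35), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Pivot a collapsed Cq table into a genes x samples matrix. Stability
# statistics need every (gene, sample) cell filled exactly once.
cq_matrix <- function(data, drop_incomplete = FALSE) {
  data <- as_cq_df(data)
  dup <- data |>
    dplyr::count(.data$gene, .data$sample) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "multiple Cq records per (gene, sample) cell; collapse technical ",
      "replicates first (e.g. ", dup$gene[1], " / ", dup$sample[1], ")"
    ))
  }
  wide <- data |>
    dplyr::select("gene", "sample", "cq") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "cq")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  if (anyNA(m)) {
    bad_samples <- colnames(m)[colSums(is.na(m)) > 0]
    if (drop_incomplete) {
      m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
      if (ncol(m) < 2) abort("fewer than 2 complete samples remain after dropping incomplete ones")
    } else {
      abort(paste0(
        "incomplete dataset: samples missing one or more genes: ",
        paste(head(bad_samples, 5), collapse = ", "),
        if (length(bad_samples) > 5) ", ..." else "",
        ". Use drop_incomplete = TRUE to drop them."
      ))
    }
  }
  m
}

# Resolve per-gene amplification efficiencies to fold-per-cycle values
# (E = 2 means perfect doubling). Accepts NULL (all 2), a single number,
# a named numeric vector of folds, or a gene_efficiency table (e_percent).
resolve_efficiencies <- function(genes, efficiencies = NULL) {
  if (is.null(efficiencies)) {
    e <- rep(2, length(genes))
  } else if (inherits(efficiencies, "data.frame")) {
    if (!all(c("gene", "e_percent") %in% names(efficiencies))) {
      abort("efficiency table must have columns 'gene' and 'e_percent'")
    }
    idx <- match(genes, efficiencies$gene)
    if (anyNA(idx)) {
      abort(paste0(
        "no efficiency for gene(s): ",
        paste(genes[is.na(idx)], collapse = ", ")
      ))
    }
    e <- 1 + efficiencies$e_percent[idx] / 100
  } else if (is.numeric(efficiencies) && length(efficiencies) == 1 && is.null(names(efficiencies))) {
    e <- rep(efficiencies, length(genes))
  } else if (is.numeric(efficiencies)) {
    idx <- match(genes, names(efficiencies))
    if (anyNA(idx)) {
      abort(paste0(
        "no efficiency for gene(s): ",
        paste(genes[is.na(idx)], collapse = ", ")
      ))
    }
    e <- unname(efficiencies[idx])
  } else {
    abort("efficiencies must be NULL, a number, a named numeric vector, or an efficiency table")
  }
  if (any(e <= 1)) {
    abort("amplification efficiency must exceed 1 fold per cycle (E > 1)")
  }
  setNames(e, genes)
}

# Resolve a grouping specification ("tissue", "stage", "tissue:stage" or a
# character vector of column names) to a factor over rows of `data`.
group_factor <- function(data, group_by) {
  cols <- unlist(strsplit(group_by, ":", fixed = TRUE))
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("grouping column(s) not in data: ", paste(missing, collapse = ", ")))
  }
  interaction(data[cols], drop = TRUE, sep = ":")
}
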