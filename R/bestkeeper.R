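# BestKeeper descriptive index statistics and the comparative delta-Ct
# pairwise-SD stability.

#' BestKeeper stability statistics
#'
#' Works directly on the Cq scale. Per gene it reports the mean Cq, the
#' BestKeeper "SD (+/- Cq)" — the mean absolute deviation of Cq about the
#' mean, as the original spreadsheet applet computes it — the corresponding
#' CV (100 * MAD / mean Cq), and the Pearson correlation of the gene's Cq
#' with the BestKeeper index (the per-sample geometric mean of all candidate
#' genes' Cq). The default stability ranking is ascending by MAD; ranking by
#' descending |r| is available via `rank_by = "abs_r"`.
#'
#' @param data a collapsed, complete Cq tibble.
#' @param rank_by `"mad"` (default) or `"abs_r"`.
#' @param index_excludes_self if `TRUE`, each gene is correlated against the
#'   index of the other genes only (default `FALSE`, the applet behaviour).
#' @return A `bestkeeper_fit` object: list with `stability` (tibble `gene`,
#'   `mean_cq`, `mad_cq`, `cv_percent`, `r_index`, `rank`), `index` (tibble
#'   `sample`, `index`), and `rank_by`. Zero-variance genes get `NA` for
#'   `r_index` and are ranked by MAD regardless of `rank_by`.
#' @export
bestkeeper <- function(data, rank_by = c("mad", "abs_r"),
                       index_excludes_self = FALSE) {
  rank_by <- match.arg(rank_by)
  m <- cq_matrix(data)
  if (nrow(m) < 2) abort("BestKeeper requires at least 2 genes")
  mean_cq <- rowMeans(m)
  mad_cq <- rowMeans(abs(m - mean_cq))
  index <- apply(m, 2, geo_mean)
  r_index <- vapply(seq_len(nrow(m)), function(i) {
    idx <- if (index_excludes_self) {
      apply(m[-i, , drop = FALSE], 2, geo_mean)
    } else {
      index
    }
    if (sd(m[i, ]) == 0 || sd(idx) == 0) NA_real_ else stats::cor(m[i, ], idx)
  }, numeric(1))

  stab <- tibble::tibble(
    gene = rownames(m),
    mean_cq = unname(mean_cq),
    mad_cq = unname(mad_cq),
    cv_percent = unname(100 * mad_cq / mean_cq),
    r_index = r_index
  )
  ranks <- if (rank_by == "mad" || anyNA(r_index)) {
    competition_ranks(stab$mad_cq, "lower_better")
  } else {
    competition_ranks(abs(stab$r_index), "higher_better")
  }
  out <- list(
    stability = dplyr::mutate(stab, rank = ranks),
    index = tibble::tibble(sample = colnames(m), index = unname(index)),
    rank_by = rank_by
  )
  class(out) <- "bestkeeper_fit"
  out
}

#' @export
print.bestkeeper_fit <- function(x, ...) {
  cat("BestKeeper stability (ranked by ", x$rank_by, ")\n", sep = "")
  print(dplyr::arrange(x$stability, .data$rank))
  invisible(x)
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (i, l), the per-sample Cq difference
#' \eqn{\Delta Cq_j = Cq_{ij} - Cq_{lj}} is formed and its sample standard
#' deviation (n-1) computed; gene i's stability is the mean of these pair
#' SDs over all partners. With all efficiencies equal to 2 this is exactly
#' the first-round geNorm M.
#'
#' @param data a collapsed, complete Cq tibble.
#' @return A `deltact_fit` object: list with `stability` (tibble `gene`,
#'   `stability`, `rank`) and `pair_sd` (symmetric genes-by-genes matrix of
#'   pair SDs, zero diagonal).
#' @export
deltact_stability <- function(data) {
  m <- cq_matrix(data)
  k <- nrow(m)
  if (k < 2) abort("delta-Ct stability requires at least 2 genes")
  pair_sd <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1)) {
    for (l in (i + 1):k) {
      s <- sd(m[i, ] - m[l, ])
      pair_sd[i, l] <- s
      pair_sd[l, i] <- s
    }
  }
  stability <- rowSums(pair_sd) / (k - 1)
  out <- list(
    stability = tibble::tibble(
      gene = rownames(m),
      stability = unname(stability),
      rank = competition_ranks(stability, "lower_better")
    ),
    pair_sd = pair_sd
  )
  class(out) <- "deltact_fit"
  out
}

#' @export
print.deltact_fit <- function(x, ...) {
  cat("Comparative delta-Ct stability\n")
  print(dplyr::arrange(x$stability, .data$rank))
  invisible(x)
}
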