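# NormFinder: model-based stability via variance decomposition.
#
# Working scale is log2 relative expression x(i,j) = log2(E_i) *
# (mean_j Cq(i,.) - Cq(i,j)); with E = 2 this is the gene-centered negative
# Cq. Global per-sample effects (loading, RT yield) sit in the column means
# and are removed by two-way centering; what remains per gene is its own
# noise plus a leakage of the other genes' noise through the column means.
# The bias correction below inverts that leakage exactly:
#   E[v_i] = sigma_i^2 (1 - 2/k) + mean(sigma^2)/k
#   => sigma_i^2 = (k/(k-2)) (v_i - vbar/(k-1))  is unbiased.

normfinder_x <- function(data, efficiencies = NULL) {
  m <- cq_matrix(data)
  e <- resolve_efficiencies(rownames(m), efficiencies)
  log2(e) * (rowMeans(m) - m)
}

# Unclamped per-gene variance estimates from one homogeneous block of
# samples (two-way centering + leakage correction).
normfinder_var_block <- function(x) {
  k <- nrow(x)
  n <- ncol(x)
  r <- x - rowMeans(x) - rep(colMeans(x), each = k) + mean(x)
  v <- rowSums(r^2) / (n - 1)
  (k / (k - 2)) * (v - mean(v) / (k - 1))
}

#' NormFinder stability values
#'
#' Model-based expression stability. In ungrouped mode each gene's stability
#' value (SV) is the square root of its estimated expression variance on the
#' log2 scale, after removing global sample effects by two-way centering and
#' correcting for the leakage of the other candidates' noise through the
#' per-sample means (see Details). In grouped mode the candidate's SV
#' combines its shrunken systematic between-group deviation with its
#' within-group sampling error, so genes that are quiet within groups but
#' biased between groups are still penalised.
#'
#' @details
#' Ungrouped: with k genes and n samples, residuals
#' \eqn{r_{ij} = x_{ij} - \bar x_{i\cdot} - \bar x_{\cdot j} + \bar x_{\cdot\cdot}}
#' give \eqn{v_i = \sum_j r_{ij}^2/(n-1)} and the unbiased variance estimate
#' \eqn{\hat\sigma^2_i = (k/(k-2)) (v_i - \bar v/(k-1))}, clamped at 0 before
#' the square root: \eqn{SV_i = \sqrt{\max(\hat\sigma^2_i, 0)}}.
#'
#' Grouped (factor with G levels, group g holding \eqn{n_g} samples): the
#' ungrouped estimator is applied within each group to give
#' \eqn{\hat\sigma^2_{ig}}; inter-group deviations
#' \eqn{d_{ig}} are the double-centered gene-by-group mean table; the
#' between-group variance component
#' \eqn{\hat\gamma^2 = \max(\sum d_{ig}^2 / ((k-1)(G-1)) -
#' \mathrm{mean}(\hat\sigma^2_{ig}/n_g), 0)} shrinks the deviations,
#' \eqn{\tilde d_{ig} = d_{ig}\,\hat\gamma^2/(\hat\gamma^2 +
#' \hat\sigma^2_{ig}/n_g)}, and
#' \eqn{SV_i = (1/G)\sum_g [\,|\tilde d_{ig}| +
#' \sqrt{\hat\gamma^2 (\hat\sigma^2_{ig}/n_g) / (\hat\gamma^2 +
#' \hat\sigma^2_{ig}/n_g)}\,]}.
#'
#' @inheritParams relative_quantities
#' @param group_by optional grouping: a column name (`"tissue"`, `"stage"`)
#'   or `"tissue:stage"` for the interaction. `NULL` runs ungrouped.
#' @return A `normfinder_fit` object: list with `stability` (tibble `gene`,
#'   `sv`, `var_est` — in ungrouped mode the unclamped variance estimate —
#'   and `rank`), `mode`, and in grouped mode `groups` (tibble `gene`, `group`,
#'   `intragroup_var`, `intergroup_dev`, `shrunken_dev`) and `gamma_sq`.
#' @export
normfinder_stability <- function(data, group_by = NULL, efficiencies = NULL) {
  x <- normfinder_x(data, efficiencies)
  k <- nrow(x)
  if (k < 3) abort("NormFinder needs at least 3 genes (bias correction requires k > 2)")
  genes <- rownames(x)

  if (is.null(group_by)) {
    var_est <- normfinder_var_block(x)
    sv <- sqrt(pmax(var_est, 0))
    stab <- tibble::tibble(gene = genes, sv = unname(sv), var_est = unname(var_est))
    out <- list(
      stability = dplyr::mutate(stab, rank = competition_ranks(.data$sv, "lower_better")),
      mode = "ungrouped"
    )
  } else {
    data <- as_cq_df(data)
    sample_info <- dplyr::distinct(data, .data$sample, .keep_all = TRUE)
    g <- group_factor(sample_info, group_by)
    g <- setNames(as.character(g), sample_info$sample)[colnames(x)]
    tab <- table(g)
    if (length(tab) < 2) abort("grouped NormFinder needs at least 2 groups")
    if (any(tab < 2)) {
      abort(paste0("group '", names(tab)[tab < 2][1], "' has fewer than 2 samples"))
    }
    groups <- names(tab)
    G <- length(groups)
    n_g <- as.numeric(tab[groups])

    sigma2 <- vapply(groups, function(gr) {
      pmax(normfinder_var_block(x[, g == gr, drop = FALSE]), 0)
    }, numeric(k)) # k x G
    xbar <- vapply(groups, function(gr) rowMeans(x[, g == gr, drop = FALSE]), numeric(k))
    d <- xbar - rowMeans(xbar) - rep(colMeans(xbar), each = k) + mean(xbar)
    err <- sweep(sigma2, 2, n_g, "/") # sigma^2_ig / n_g
    gamma_sq <- max(sum(d^2) / ((k - 1) * (G - 1)) - mean(err), 0)
    d_shrunk <- d * gamma_sq / (gamma_sq + err)
    d_shrunk[is.nan(d_shrunk)] <- 0 # gamma_sq = 0 and err = 0
    post_sd <- sqrt(gamma_sq * err / (gamma_sq + err))
    post_sd[is.nan(post_sd)] <- 0
    sv <- rowMeans(abs(d_shrunk) + post_sd)
    stab <- tibble::tibble(gene = genes, sv = unname(sv), var_est = NA_real_)
    out <- list(
      stability = dplyr::mutate(stab, rank = competition_ranks(.data$sv, "lower_better")),
      mode = "grouped",
      group_by = group_by,
      gamma_sq = gamma_sq,
      groups = tibble::tibble(
        gene = rep(genes, G),
        group = rep(groups, each = k),
        intragroup_var = as.vector(sigma2),
        intergroup_dev = as.vector(d),
        shrunken_dev = as.vector(d_shrunk)
      )
    )
  }
  class(out) <- "normfinder_fit"
  out
}

#' @export
print.normfinder_fit <- function(x, ...) {
  cat("NormFinder stability (", x$mode,
    if (x$mode == "grouped") paste0(" by ", x$group_by), ")\n",
    sep = ""
  )
  print(dplyr::arrange(x$stability, .data$rank))
  invisible(x)
}
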