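# geNorm: M values, iterative-exclusion ranking, and pairwise variation.

#' Relative quantities from Cq values
#'
#' Converts Cq to relative quantities per gene via the efficiency-corrected
#' delta-Cq transform \eqn{q = E^{Cq_{min} - Cq}} with the gene-wise minimum
#' Cq as calibrator, so each gene's most abundant sample has q = 1 and all
#' quantities lie in (0, 1].
#'
#' @param data a collapsed, complete Cq tibble.
#' @param efficiencies per-gene amplification efficiency as fold per cycle:
#'   `NULL` (all 2, i.e. 100%), a single number, a named vector, or a
#'   [gene_efficiency][amplification_efficiency] table (converted via
#'   E = 1 + e_percent/100).
#' @return A tibble with columns `gene`, `sample`, `q`.
#' @export
relative_quantities <- function(data, efficiencies = NULL) {
  m <- cq_matrix(data)
  e <- resolve_efficiencies(rownames(m), efficiencies)
  q <- e^(apply(m, 1, min) - m)
  tibble::tibble(
    gene = rep(rownames(q), ncol(q)),
    sample = rep(colnames(q), each = nrow(q)),
    q = as.vector(q)
  )
}

# genes x samples matrix of log2 relative quantities
log2_q_matrix <- function(data, efficiencies = NULL) {
  m <- cq_matrix(data)
  e <- resolve_efficiencies(rownames(m), efficiencies)
  log2(e) * (apply(m, 1, min) - m) # log2(q) = log2(E) * (Cqmin - Cq), rowwise
}

genorm_m_from_log2q <- function(lq) {
  k <- nrow(lq)
  vapply(seq_len(k), function(j) {
    mean(vapply(
      setdiff(seq_len(k), j),
      function(l) sd(lq[j, ] - lq[l, ]),
      numeric(1)
    ))
  }, numeric(1))
}

#' geNorm expression-stability measure M
#'
#' For each gene j, M is the arithmetic mean over all other genes k of the
#' sample standard deviation (n-1 denominator) of the log2 expression ratios
#' \eqn{A_{jk} = \log_2(q_j / q_k)}. Lower M means more stable expression.
#'
#' @inheritParams relative_quantities
#' @param genes optional subset of genes to compute M within.
#' @return A tibble with columns `gene`, `m`.
#' @export
genorm_m <- function(data, efficiencies = NULL, genes = NULL) {
  lq <- log2_q_matrix(data, efficiencies)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(lq))
    if (length(missing) > 0) {
      abort(paste0("gene(s) not in data: ", paste(missing, collapse = ", ")))
    }
    lq <- lq[genes, , drop = FALSE]
  }
  if (nrow(lq) < 2) abort("M undefined for fewer than 2 genes")
  if (ncol(lq) < 2) abort("at least 2 samples required")
  tibble::tibble(gene = rownames(lq), m = genorm_m_from_log2q(lq))
}

#' geNorm ranking by iterative exclusion
#'
#' Repeatedly computes M on the surviving gene set and removes the gene with
#' the largest M (ties broken deterministically by removing the later gene in
#' input order) until two genes remain. The final pair cannot be resolved
#' further and shares rank 1; earlier exclusions receive ranks 3, 4, ... in
#' reverse exclusion order (competition ranking).
#'
#' @inheritParams relative_quantities
#' @return A `genorm_fit` object: a list with
#'   \describe{
#'     \item{stability}{tibble `gene`, `m_all` (first-round M on the full
#'       panel), `m` (M on the surviving subset at exclusion; the final pair
#'       shares its mutual M), `rank`.}
#'     \item{exclusion_order}{genes from least to most stable context (the
#'       order in which they were removed).}
#'     \item{final_pair}{the two genes that survive to the end.}
#'     \item{mean_m_path}{average M of the surviving set at each round;
#'       non-increasing along the exclusion path.}
#'   }
#' @export
genorm_rank <- function(data, efficiencies = NULL) {
  lq <- log2_q_matrix(data, efficiencies)
  k <- nrow(lq)
  if (k < 3) abort("geNorm ranking requires at least 3 genes")
  genes <- rownames(lq)
  m_all <- setNames(genorm_m_from_log2q(lq), genes)

  surviving <- genes
  excluded <- character(0)
  m_at_exclusion <- setNames(numeric(length(genes)), genes)
  mean_m_path <- numeric(0)
  while (length(surviving) > 2) {
    m <- setNames(genorm_m_from_log2q(lq[surviving, , drop = FALSE]), surviving)
    mean_m_path <- c(mean_m_path, mean(m))
    worst_idx <- max(which(m == max(m))) # tie: remove the later gene in input order
    worst <- surviving[worst_idx]
    m_at_exclusion[worst] <- m[worst_idx]
    excluded <- c(excluded, worst)
    surviving <- setdiff(surviving, worst)
  }
  m_pair <- genorm_m_from_log2q(lq[surviving, , drop = FALSE])
  mean_m_path <- c(mean_m_path, mean(m_pair))
  m_at_exclusion[surviving] <- m_pair # identical by construction

  ranks <- setNames(integer(length(genes)), genes)
  ranks[surviving] <- 1L
  if (length(excluded) > 0) {
    # last-excluded gene is the 3rd most stable, first-excluded the least
    ranks[rev(excluded)] <- seq(3L, length.out = length(excluded))
  }
  out <- list(
    stability = tibble::tibble(
      gene = genes,
      m_all = unname(m_all),
      m = unname(m_at_exclusion[genes]),
      rank = unname(ranks[genes])
    ),
    exclusion_order = excluded,
    final_pair = surviving,
    mean_m_path = mean_m_path
  )
  class(out) <- "genorm_fit"
  out
}

#' @export
print.genorm_fit <- function(x, ...) {
  cat("geNorm stability ranking (", nrow(x$stability), " genes)\n", sep = "")
  cat("Most stable pair:", paste(x$final_pair, collapse = ", "), "\n")
  print(dplyr::arrange(x$stability, .data$rank))
  invisible(x)
}

#' geNorm pairwise variation: how many reference genes are enough
#'
#' For n = 2 .. k-1 builds normalization factors NF_n as the per-sample
#' geometric mean of the relative quantities of the n most stable genes, and
#' computes \eqn{V_{n/n+1}} as the sample standard deviation of
#' \eqn{\log_2(NF_n / NF_{n+1})}. The smallest n with V below the cutoff
#' (0.15 by convention) is the recommended number of reference genes: adding
#' an (n+1)-th gene no longer changes the normalization factor appreciably.
#'
#' @inheritParams relative_quantities
#' @param ranking the genes ordered most stable first; defaults to the
#'   [genorm_rank()] ordering. A `genorm_fit` is also accepted.
#' @param threshold the V cutoff (default 0.15).
#' @return A `pairwise_variation` tibble with columns `n`, `v`,
#'   `below_threshold`, and attributes `recommended_n` (integer, or `NA` when
#'   no V falls below the cutoff) and `threshold`.
#' @export
pairwise_variation <- function(data, efficiencies = NULL, ranking = NULL,
                               threshold = 0.15) {
  lq <- log2_q_matrix(data, efficiencies)
  k <- nrow(lq)
  if (k < 3) abort("pairwise variation requires at least 3 genes")
  if (is.null(ranking)) {
    fit <- genorm_rank(data, efficiencies)
    ranking <- c(fit$final_pair, rev(fit$exclusion_order))
  } else if (inherits(ranking, "genorm_fit")) {
    ranking <- c(ranking$final_pair, rev(ranking$exclusion_order))
  }
  if (!setequal(ranking, rownames(lq)) || length(ranking) != k) {
    abort("ranking must be a permutation of the genes in the data")
  }
  lq <- lq[ranking, , drop = FALSE]
  # log2 NF_n = mean of log2 q over top-n genes
  log_nf <- function(n) colMeans(lq[seq_len(n), , drop = FALSE])
  v <- vapply(2:(k - 1), function(n) sd(log_nf(n) - log_nf(n + 1)), numeric(1))
  out <- tibble::tibble(
    n = 2:(k - 1),
    v = v,
    below_threshold = v < threshold
  )
  rec <- if (any(out$below_threshold)) out$n[which(out$below_threshold)[1]] else NA_integer_
  attr(out, "recommended_n") <- rec
  attr(out, "threshold") <- threshold
  class(out) <- c("pairwise_variation", class(out))
  out
}

#' Recommended number of reference genes from a pairwise-variation table
#'
#' @param v a [pairwise_variation()] result.
#' @return The smallest n with V below the cutoff, or `NA` if never reached.
#' @export
recommended_n <- function(v) {
  attr(v, "recommended_n")
}
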