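# Comprehensive ranking: per-method competition ranks aggregated by their
# geometric mean, plus top-k overlap comparison across conditions.

#' Competition (min-tie) ranks
#'
#' Tied values share the smallest applicable rank and the next distinct
#' value's rank is 1 + the number of strictly better items, so two genes
#' tied at the top are both rank 1 and the next gene is rank 3.
#'
#' @param values finite numeric vector.
#' @param orientation `"lower_better"` (stability measures) or
#'   `"higher_better"` (e.g. |r|).
#' @return Integer ranks.
#' @examples
#' competition_ranks(c(0.077, 0.077, 0.146), "lower_better") # 1 1 3
#' @export
competition_ranks <- function(values, orientation = c("lower_better", "higher_better")) {
  orientation <- match.arg(orientation)
  if (length(values) == 0) abort("cannot rank an empty vector")
  if (!all(is.finite(values))) abort("values must be finite")
  x <- if (orientation == "lower_better") values else -values
  as.integer(rank(x, ties.method = "min"))
}

#' Build a per-method stability table
#'
#' Standardises one stability method's output into the common table consumed
#' by [reffinder_aggregate()]: gene, stability value, orientation, and
#' competition rank. Accepts a fitted object from any of the four engines
#' ([genorm_rank()], [normfinder_stability()], [bestkeeper()],
#' [deltact_stability()]) or a plain data frame with `gene` plus a value or
#' rank column.
#'
#' @param x a fit object or data frame.
#' @param method method label (`"genorm"`, `"normfinder"`, `"bestkeeper"`,
#'   `"deltact"`, or free text); inferred from fit objects.
#' @param value_col,orientation for data-frame input: the value column and
#'   its orientation. If `x` already has a `rank` column it is kept;
#'   otherwise ranks are computed from the values.
#' @return A `stability_table` tibble: `method`, `gene`, `value`,
#'   `orientation`, `rank`.
#' @export
stability_table <- function(x, method = NULL, value_col = "value",
                            orientation = "lower_better") {
  if (inherits(x, "genorm_fit")) {
    tab <- tibble::tibble(
      method = method %||% "genorm", gene = x$stability$gene,
      value = x$stability$m, orientation = "lower_better",
      rank = as.integer(x$stability$rank)
    )
  } else if (inherits(x, "normfinder_fit")) {
    tab <- tibble::tibble(
      method = method %||% "normfinder", gene = x$stability$gene,
      value = x$stability$sv, orientation = "lower_better",
      rank = as.integer(x$stability$rank)
    )
  } else if (inherits(x, "bestkeeper_fit")) {
    tab <- tibble::tibble(
      method = method %||% "bestkeeper", gene = x$stability$gene,
      value = x$stability$mad_cq, orientation = "lower_better",
      rank = as.integer(x$stability$rank)
    )
  } else if (inherits(x, "deltact_fit")) {
    tab <- tibble::tibble(
      method = method %||% "deltact", gene = x$stability$gene,
      value = x$stability$stability, orientation = "lower_better",
      rank = as.integer(x$stability$rank)
    )
  } else if (is.data.frame(x)) {
    if (!"gene" %in% names(x)) abort("stability table needs a 'gene' column")
    value <- if (value_col %in% names(x)) x[[value_col]] else NA_real_
    rank <- if ("rank" %in% names(x)) {
      as.integer(x$rank)
    } else if (value_col %in% names(x)) {
      competition_ranks(x[[value_col]], orientation)
    } else {
      abort(paste0("data frame needs a 'rank' or '", value_col, "' column"))
    }
    tab <- tibble::tibble(
      method = method %||% (if ("method" %in% names(x)) x$method[1] else "custom"),
      gene = x$gene,
      value = value,
      orientation = if ("orientation" %in% names(x)) x$orientation else orientation,
      rank = rank
    )
  } else {
    abort("cannot build a stability table from this object")
  }
  class(tab) <- c("stability_table", class(tab))
  tab
}

#' Aggregate stability tables by the geometric mean of ranks
#'
#' The comprehensive (RefFinder-style) ranking: each gene's per-method
#' competition ranks are combined as their geometric mean
#' \eqn{(\prod_m r_{im})^{1/M}}, reported half-up to 2 decimals for display;
#' the final ranking is the competition rank of the geometric mean
#' (ascending, full precision).
#'
#' @param tables a list of [stability_table()] tibbles (or fit objects,
#'   which are converted). All must cover the same gene set. Typically 4
#'   (geNorm, NormFinder, BestKeeper, delta-Ct) but any number >= 2 works.
#' @return A `reffinder_fit` tibble: `gene`, one `rank_<method>` column per
#'   table, `geomean` (full precision), `geomean_display` (2 decimals,
#'   half-up), `final_rank`.
#' @examples
#' # two genes tied at rank 1 in one method still aggregate cleanly
#' t1 <- stability_table(data.frame(gene = c("A", "B"), value = c(1, 2)), "m1")
#' t2 <- stability_table(data.frame(gene = c("A", "B"), value = c(2, 1)), "m2")
#' reffinder_aggregate(list(t1, t2))
#' @export
reffinder_aggregate <- function(tables) {
  if (!is.list(tables) || length(tables) < 2) {
    abort("need a list of at least 2 stability tables")
  }
  tables <- purrr::map(tables, stability_table)
  genes <- tables[[1]]$gene
  for (t in tables[-1]) {
    if (!setequal(t$gene, genes) || length(t$gene) != length(genes)) {
      diff <- union(setdiff(t$gene, genes), setdiff(genes, t$gene))
      abort(paste0(
        "stability tables cover different gene sets; symmetric difference: ",
        paste(diff, collapse = ", ")
      ))
    }
  }
  methods <- purrr::map_chr(tables, ~ .x$method[1])
  if (anyDuplicated(methods)) {
    methods <- make.unique(methods, sep = "_")
  }
  rank_mat <- vapply(tables, function(t) t$rank[match(genes, t$gene)], integer(length(genes)))
  rank_mat <- matrix(rank_mat, nrow = length(genes))
  geomean <- apply(rank_mat, 1, function(r) exp(mean(log(r))))
  out <- tibble::as_tibble(as.data.frame(rank_mat)) |>
    stats::setNames(paste0("rank_", methods)) |>
    dplyr::mutate(
      gene = genes,
      geomean = geomean,
      geomean_display = round_half_up(geomean, 2),
      final_rank = competition_ranks(geomean, "lower_better"),
      .before = 1
    ) |>
    dplyr::relocate("gene")
  class(out) <- c("reffinder_fit", class(out))
  out
}

# top-k genes by final rank, including all ties at the k-th geomean
top_k_genes <- function(ranking, k) {
  if (inherits(ranking, "reffinder_fit") || (is.data.frame(ranking) && "geomean" %in% names(ranking))) {
    ord <- dplyr::arrange(ranking, .data$geomean)
    if (nrow(ord) <= k) return(list(genes = ord$gene, tie_expanded = FALSE))
    cutoff <- ord$geomean[k]
    genes <- ord$gene[ord$geomean <= cutoff]
    list(genes = genes, tie_expanded = length(genes) > k)
  } else if (is.character(ranking)) {
    list(genes = head(ranking, k), tie_expanded = FALSE)
  } else {
    abort("ranking must be a reffinder_fit or a character vector of genes (best first)")
  }
}

#' Compare top-k gene sets across conditions or species
#'
#' Extracts the top-k genes of each comprehensive ranking (ties at the k-th
#' position are all included and flagged) and reports every pairwise
#' intersection plus the global intersection — the genes recommended under
#' every condition.
#'
#' @param rankings a named list of [reffinder_aggregate()] results, or of
#'   character vectors of genes ordered best first.
#' @param k how many top genes per ranking (default 3).
#' @return A `top_k_overlap` object: list with `sets` (named list of top-k
#'   gene sets), `tie_expanded` (logical per set), `pairwise` (tibble
#'   `ranking_a`, `ranking_b`, `shared`, `n_shared`), and `global`
#'   (character vector of genes shared by all rankings).
#' @export
compare_top_k <- function(rankings, k = 3) {
  if (k < 1) abort("k must be at least 1")
  if (!is.list(rankings) || length(rankings) < 2) {
    abort("need at least 2 rankings to compare")
  }
  nm <- names(rankings) %||% paste0("ranking", seq_along(rankings))
  if (any(nm == "")) nm[nm == ""] <- paste0("ranking", which(nm == ""))
  tops <- purrr::map(rankings, top_k_genes, k = k)
  sets <- purrr::map(tops, "genes")
  names(sets) <- nm
  pairs <- utils::combn(seq_along(sets), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]
    b <- pairs[2, p]
    shared <- intersect(sets[[a]], sets[[b]])
    tibble::tibble(
      ranking_a = nm[a], ranking_b = nm[b],
      shared = paste(shared, collapse = ","), n_shared = length(shared)
    )
  })
  out <- list(
    sets = sets,
    tie_expanded = purrr::map_lgl(tops, "tie_expanded"),
    pairwise = pairwise,
    global = purrr::reduce(sets, intersect),
    k = k
  )
  class(out) <- "top_k_overlap"
  out
}

#' @export
print.top_k_overlap <- function(x, ...) {
  cat("Top-", x$k, " overlap across ", length(x$sets), " rankings\n", sep = "")
  for (nm in names(x$sets)) {
    cat("  ", nm, ": ", paste(x$sets[[nm]], collapse = ", "), "\n", sep = "")
  }
  cat(
    "Shared by all: ",
    if (length(x$global)) paste(x$global, collapse = ", ") else "(none)", "\n"
  )
  invisible(x)
}

#' Published comprehensive-ranking benchmark table
#'
#' Per-method competition ranks and comprehensive (geometric-mean) stability
#' values transcribed from a published spatio-temporal reference-gene study
#' of two Glycyrrhiza (licorice) species: 14 candidate genes under three
#' experimental conditions (developmental stages, tissues, and their
#' interaction) per species. Used as a benchmark that the rank-aggregation
#' arithmetic reproduces the published comprehensive values exactly.
#'
#' @return A tibble with columns `species`, `condition`, `gene`,
#'   `genorm_rank`, `normfinder_rank`, `bestkeeper_rank`, `deltact_rank`,
#'   `comprehensive_value` (published, 2 decimals), `final_rank`.
#' @export
published_component_ranks <- function() {
  path <- system.file("extdata", "published_component_ranks.csv", package = "refstab")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
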