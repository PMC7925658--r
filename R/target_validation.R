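# Target-gene normalization validation: normalization factors, relative
# expression under alternative reference schemes, one-way ANOVA with a
# compact letter display.

#' Per-sample normalization factor
#'
#' The geNorm-standard normalization factor: the per-sample geometric mean
#' of the relative quantities (see [relative_quantities()]) of the chosen
#' reference genes. Duplicated reference names are deduplicated.
#'
#' @param data a collapsed, complete Cq tibble.
#' @param refs character vector of reference gene names.
#' @inheritParams relative_quantities
#' @return A tibble with columns `sample`, `nf`.
#' @export
normalization_factor <- function(data, refs, efficiencies = NULL) {
  refs <- unique(refs)
  if (length(refs) == 0) abort("refs must name at least one reference gene")
  q <- relative_quantities(data, efficiencies)
  missing <- setdiff(refs, unique(q$gene))
  if (length(missing) > 0) {
    abort(paste0("reference gene(s) not in data: ", paste(missing, collapse = ", ")))
  }
  q |>
    dplyr::filter(.data$gene %in% refs) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(nf = geo_mean(.data$q), .groups = "drop")
}

# Compact letter display from a symmetric p-value matrix (insert-absorb).
# Groups are assumed ordered as rownames(p); groups sharing a letter are not
# significantly different at alpha.
cld_letters <- function(p, alpha = 0.05) {
  g <- rownames(p)
  n <- length(g)
  cols <- list(rep(TRUE, n)) # one letter covering everyone
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.na(p[i, j]) && p[i, j] < alpha) {
        new_cols <- list()
        for (col in cols) {
          if (col[i] && col[j]) {
            a <- col
            a[i] <- FALSE
            b <- col
            b[j] <- FALSE
            new_cols <- c(new_cols, list(a, b))
          } else {
            new_cols <- c(new_cols, list(col))
          }
        }
        # absorb columns contained in another
        keep <- rep(TRUE, length(new_cols))
        for (a in seq_along(new_cols)) {
          for (b in seq_along(new_cols)) {
            if (a != b && keep[a] && keep[b] &&
              all(new_cols[[a]] | !new_cols[[b]]) && !identical(new_cols[[a]], new_cols[[b]])) {
              keep[b] <- FALSE # b subset of a
            }
          }
        }
        keep[duplicated(new_cols)] <- FALSE
        cols <- new_cols[keep]
      }
    }
  }
  # letter "a" goes to the column containing the first (highest-mean) group
  cols <- cols[order(vapply(cols, function(col) which(col)[1], numeric(1)))]
  letters_out <- vapply(seq_len(n), function(i) {
    paste0(letters[which(vapply(cols, function(col) col[i], logical(1)))], collapse = "")
  }, character(1))
  setNames(letters_out, g)
}

#' Relative expression of a target gene under a reference scheme
#'
#' Normalizes a target gene against a set of reference genes
#' (\eqn{expr = q_{target} / NF}), scales so the largest group mean equals 1
#' (expression reads as a fraction of the peak group), summarises each
#' design group (mean, standard error over biological replicates), and runs
#' a one-way ANOVA across groups. Group separation letters come from
#' all-pairs Welch t-tests with Holm correction at `alpha`.
#'
#' @param data a collapsed, complete Cq tibble including the target gene.
#' @param target target gene name (must not be among `refs`).
#' @param refs reference gene names.
#' @inheritParams relative_quantities
#' @param group design factor to compare across: a column name
#'   (default `"tissue"`) or `"tissue:stage"`.
#' @param alpha significance level for the letter display.
#' @return A `relative_expression` object: list with `samples` (tibble
#'   `sample`, `group`, `expression`, `expression_raw`), `groups` (tibble
#'   `group`, `n`, `mean`, `se`, `letter`), `anova_f`, `anova_p`, `target`,
#'   `refs`, `group_by`.
#' @export
relative_expression <- function(data, target, refs, efficiencies = NULL,
                                group = "tissue", alpha = 0.05) {
  data <- as_cq_df(data)
  if (target %in% refs) abort("target cannot normalize itself")
  if (!target %in% data$gene) abort(paste0("target gene '", target, "' not in data"))
  nf <- normalization_factor(data, refs, efficiencies)
  q <- relative_quantities(data, efficiencies) |>
    dplyr::filter(.data$gene == target)
  sample_info <- dplyr::distinct(data, .data$sample, .keep_all = TRUE)
  grp <- setNames(as.character(group_factor(sample_info, group)), sample_info$sample)
  samples <- q |>
    dplyr::inner_join(nf, by = "sample") |>
    dplyr::transmute(
      sample = .data$sample,
      group = grp[.data$sample],
      expression_raw = .data$q / .data$nf
    )
  group_means_raw <- samples |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(m = mean(.data$expression_raw), .groups = "drop")
  scale_by <- max(group_means_raw$m)
  samples <- dplyr::mutate(samples, expression = .data$expression_raw / scale_by)

  groups <- samples |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$expression),
      se = if (dplyr::n() >= 2) sd(.data$expression) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )

  if (nrow(groups) >= 2) {
    fit <- aov(expression ~ factor(group), data = samples)
    at <- suppressWarnings(anova(fit)) # perfect fits handled below

    anova_f <- at$`F value`[1]
    anova_p <- at$`Pr(>F)`[1]
    if (at$`Sum Sq`[1] == 0) {
      # identical group means: no between-group signal at all
      anova_f <- 0
      anova_p <- 1
    }
    gn <- groups$group
    pmat <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
    pv <- tryCatch(
      suppressWarnings(pairwise.t.test(
        samples$expression, samples$group,
        p.adjust.method = "holm", pool.sd = FALSE
      )$p.value),
      error = function(e) NULL # e.g. essentially-constant data
    )
    if (!is.null(pv)) {
      for (a in rownames(pv)) {
        for (b in colnames(pv)) {
          if (!is.na(pv[a, b])) {
            pmat[a, b] <- pv[a, b]
            pmat[b, a] <- pv[a, b]
          }
        }
      }
    }
    # letters assigned with groups ordered by decreasing mean
    ord <- order(-groups$mean)
    lets <- cld_letters(pmat[gn[ord], gn[ord], drop = FALSE], alpha = alpha)
    groups$letter <- unname(lets[groups$group])
  } else {
    anova_f <- NA_real_
    anova_p <- NA_real_
    groups$letter <- "a"
  }

  out <- list(
    samples = samples,
    groups = groups,
    anova_f = anova_f,
    anova_p = anova_p,
    target = target,
    refs = unique(refs),
    group_by = group
  )
  class(out) <- "relative_expression"
  out
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(
    "Relative expression of ", x$target, " normalized by {",
    paste(x$refs, collapse = ", "), "}\n",
    sep = ""
  )
  print(x$groups)
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g\n", x$anova_f, x$anova_p))
  invisible(x)
}

# the seven canonical normalization schemes from a comprehensive ranking
build_schemes <- function(ranking) {
  ord <- dplyr::arrange(ranking, .data$geomean, .data$gene)$gene
  k <- length(ord)
  if (k < 3) abort("scheme panel needs at least 3 candidate reference genes")
  list(
    top1 = ord[1],
    top2 = ord[1:2],
    top3 = ord[1:3],
    worst1 = ord[k],
    worst2 = ord[(k - 1):k],
    worst3 = ord[(k - 2):k],
    all = ord
  )
}

#' Validate a target gene under the seven canonical normalization schemes
#'
#' Builds the seven reference schemes used to stress-test a stability
#' ranking — the most stable gene, top two, top three, the least stable,
#' bottom two, bottom three, and all candidates — and normalizes the target
#' gene under each, reporting group summaries and ANOVA per scheme.
#'
#' @inheritParams relative_expression
#' @param ranking a [reffinder_aggregate()] result over the candidate genes
#'   (must not include the target).
#' @return A `scheme_panel` object: list with `summary` (tibble `scheme`,
#'   `n_refs`, `refs`, `anova_f`, `anova_p`), `results` (named list of
#'   [relative_expression()] objects), `target`.
#' @export
scheme_panel <- function(data, target, ranking, efficiencies = NULL,
                         group = "tissue", alpha = 0.05) {
  if (target %in% ranking$gene) {
    abort("target cannot appear in the candidate ranking")
  }
  schemes <- build_schemes(ranking)
  results <- purrr::map(schemes, function(refs) {
    relative_expression(data, target, refs,
      efficiencies = efficiencies,
      group = group, alpha = alpha
    )
  })
  summary <- purrr::imap_dfr(results, function(res, nm) {
    tibble::tibble(
      scheme = nm,
      n_refs = length(res$refs),
      refs = paste(res$refs, collapse = ","),
      anova_f = res$anova_f,
      anova_p = res$anova_p
    )
  })
  out <- list(summary = summary, results = results, target = target)
  class(out) <- "scheme_panel"
  out
}

#' @export
print.scheme_panel <- function(x, ...) {
  cat("Normalization-scheme panel for target ", x$target, "\n", sep = "")
  print(x$summary)
  invisible(x)
}
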