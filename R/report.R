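# Combined workflows and file reports mirroring the classic four-method +
# comprehensive-ranking stability table.

#' Run all four stability methods and the comprehensive ranking
#'
#' One call per experimental condition: computes geNorm (iterative
#' exclusion), NormFinder (grouped by `condition` when one is given,
#' ungrouped otherwise), BestKeeper, and comparative delta-Ct on the same
#' collapsed dataset, aggregates the four rank vectors by geometric mean,
#' and runs the geNorm pairwise-variation analysis.
#'
#' @param data a collapsed, complete Cq tibble.
#' @param condition optional NormFinder grouping factor: `"tissue"`,
#'   `"stage"` or `"tissue:stage"`. All samples in `data` are analysed
#'   (pre-filter `data` to restrict the sample set).
#' @inheritParams relative_quantities
#' @param v_threshold geNorm pairwise-variation cutoff.
#' @return A `stability_analysis` object: list with `fits` (the four fitted
#'   objects), `tables` (their [stability_table()]s), `combined` (one row
#'   per gene: each method's value and rank, the rank geometric mean, and
#'   the final rank), `ranking` (the [reffinder_aggregate()] result),
#'   `pairwise_variation`, and `condition`.
#' @export
stability_workflow <- function(data, condition = NULL, efficiencies = NULL,
                               v_threshold = 0.15) {
  data <- as_cq_df(data)
  fits <- list(
    genorm = genorm_rank(data, efficiencies),
    normfinder = normfinder_stability(data, group_by = condition, efficiencies = efficiencies),
    bestkeeper = bestkeeper(data),
    deltact = deltact_stability(data)
  )
  tables <- purrr::map(fits, stability_table)
  ranking <- reffinder_aggregate(tables)
  pv <- pairwise_variation(data, efficiencies,
    ranking = fits$genorm, threshold = v_threshold
  )
  combined <- tibble::tibble(gene = tables$genorm$gene) |>
    dplyr::mutate(
      genorm_m = tables$genorm$value,
      genorm_rank = tables$genorm$rank,
      normfinder_sv = tables$normfinder$value[match(.data$gene, tables$normfinder$gene)],
      normfinder_rank = tables$normfinder$rank[match(.data$gene, tables$normfinder$gene)],
      bestkeeper_sd = tables$bestkeeper$value[match(.data$gene, tables$bestkeeper$gene)],
      bestkeeper_rank = tables$bestkeeper$rank[match(.data$gene, tables$bestkeeper$gene)],
      deltact_sd = tables$deltact$value[match(.data$gene, tables$deltact$gene)],
      deltact_rank = tables$deltact$rank[match(.data$gene, tables$deltact$gene)],
      geomean = ranking$geomean_display[match(.data$gene, ranking$gene)],
      final_rank = ranking$final_rank[match(.data$gene, ranking$gene)]
    ) |>
    dplyr::arrange(.data$final_rank, .data$gene)
  out <- list(
    fits = fits, tables = tables, combined = combined, ranking = ranking,
    pairwise_variation = pv,
    condition = condition %||% "ungrouped"
  )
  class(out) <- "stability_analysis"
  out
}

#' @export
print.stability_analysis <- function(x, ...) {
  cat("Stability analysis (condition: ", x$condition, ")\n", sep = "")
  print(x$combined)
  rec <- recommended_n(x$pairwise_variation)
  cat(
    "Recommended number of reference genes:",
    if (is.na(rec)) "not reached (no V below cutoff)" else rec, "\n"
  )
  invisible(x)
}

provenance_header <- function(config) {
  c(
    paste0("# refstab ", as.character(utils::packageVersion("refstab"))),
    paste0("# config_hash: ", rlang::hash(config)),
    paste0(
      "# config: ",
      paste(names(config), unname(purrr::map_chr(config, ~ paste(format(.x), collapse = ","))),
        sep = "=", collapse = "; "
      )
    )
  )
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, open = "wb") # binary mode: byte-stable newlines
  on.exit(close(con))
  writeLines(header, con)
  lines <- c(
    paste(names(df), collapse = "\t"),
    apply(df, 1, function(r) paste(trimws(format(r, digits = 15)), collapse = "\t"))
  )
  writeLines(lines, con)
  invisible(path)
}

#' Write a full stability report to disk
#'
#' Writes, for each requested condition, the combined four-method +
#' comprehensive-ranking table (TSV), the pairwise-variation table (TSV),
#' and a JSON bundle of everything. Every file carries a provenance header
#' (package version, config hash, configuration) and re-running with the
#' same inputs reproduces identical bytes.
#'
#' @inheritParams stability_workflow
#' @param conditions character vector of NormFinder groupings to analyse
#'   (e.g. `c("tissue", "stage", "tissue:stage")`); use `NA` for ungrouped.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a named list of `stability_analysis` objects (one per
#'   condition), with the written paths in attribute `"paths"`.
#' @export
stability_report <- function(data, conditions = c("tissue", "stage", "tissue:stage"),
                             efficiencies = NULL, v_threshold = 0.15,
                             out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  analyses <- list()
  for (cond in conditions) {
    cond_chr <- if (is.na(cond)) NULL else cond
    label <- if (is.na(cond)) "ungrouped" else gsub(":", "x", cond)
    an <- stability_workflow(data, cond_chr, efficiencies, v_threshold)
    config <- list(
      condition = label, v_threshold = v_threshold,
      efficiency_source = if (is.null(efficiencies)) "default2" else "table",
      n_genes = nrow(an$combined), n_samples = length(unique(data$sample))
    )
    hdr <- provenance_header(config)
    p1 <- file.path(out_dir, paste0("stability_", label, ".tsv"))
    write_tsv_with_header(an$combined, p1, hdr)
    pv <- tibble::as_tibble(an$pairwise_variation)
    p2 <- file.path(out_dir, paste0("pairwise_variation_", label, ".tsv"))
    write_tsv_with_header(pv, p2, hdr)
    p3 <- file.path(out_dir, paste0("stability_", label, ".json"))
    jsonlite::write_json(
      list(
        provenance = config,
        combined = an$combined,
        pairwise_variation = pv,
        recommended_n = recommended_n(an$pairwise_variation)
      ),
      p3,
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    paths <- c(paths, p1, p2, p3)
    analyses[[label]] <- an
  }
  attr(analyses, "paths") <- paths
  invisible(analyses)
}

#' Write an amplification-efficiency report
#'
#' @param series a dilution-series data frame (see
#'   [amplification_efficiency()]); genes whose fit fails are reported with
#'   the error message and the run continues.
#' @param low,high efficiency gate bounds in percent.
#' @param out_dir output directory.
#' @return Invisibly, the gated efficiency tibble (failed fits as NA rows).
#' @export
efficiency_report <- function(series, low = 90, high = 110, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_gene <- split(tibble::as_tibble(series), series$gene)
  rows <- purrr::imap_dfr(per_gene, function(df, g) {
    tryCatch(
      amplification_efficiency(df) |> dplyr::mutate(error = NA_character_),
      error = function(e) {
        tibble::tibble(
          gene = g, slope = NA_real_, intercept = NA_real_,
          e_percent = NA_real_, r_squared = NA_real_, n = nrow(df),
          error = conditionMessage(e)
        )
      }
    )
  })
  gated <- rows |>
    dplyr::mutate(pass = !is.na(.data$e_percent) & .data$e_percent >= low & .data$e_percent <= high)
  config <- list(low = low, high = high, n_genes = nrow(gated))
  write_tsv_with_header(
    gated, file.path(out_dir, "efficiency.tsv"),
    provenance_header(config)
  )
  invisible(gated)
}

#' Write a target-validation report (seven normalization schemes)
#'
#' @inheritParams scheme_panel
#' @param out_dir output directory.
#' @return Invisibly, the [scheme_panel()] object.
#' @export
validation_report <- function(data, target, ranking, efficiencies = NULL,
                              group = "tissue", out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- scheme_panel(data, target, ranking, efficiencies, group = group)
  config <- list(target = target, group = group, n_schemes = nrow(panel$summary))
  hdr <- provenance_header(config)
  summary <- purrr::imap_dfr(panel$results, function(res, nm) {
    dplyr::mutate(res$groups, scheme = nm, .before = 1)
  })
  write_tsv_with_header(
    panel$summary, file.path(out_dir, paste0("validation_", target, "_schemes.tsv")), hdr
  )
  write_tsv_with_header(
    summary, file.path(out_dir, paste0("validation_", target, "_groups.tsv")), hdr
  )
  jsonlite::write_json(
    list(provenance = config, schemes = panel$summary, groups = summary),
    file.path(out_dir, paste0("validation_", target, ".json")),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(panel)
}

#' Simulate a dataset and write it with its ground truth
#'
#' @param spec a [synthetic_spec()]; defaults to [licorice_preset()].
#' @param seed RNG seed.
#' @param out_dir output directory.
#' @return Invisibly, the [generate_cq()] result.
#' @export
simulation_report <- function(spec = licorice_preset(), seed = spec$seed,
                              out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cq(spec, seed = seed)
  write_cq_long(
    sim$data,
    file.path(out_dir, "cq.tsv"),
    design_path = file.path(out_dir, "design.tsv")
  )
  jsonlite::write_json(
    list(
      provenance = list(seed = seed, n_genes = nrow(spec$genes)),
      genes = sim$truth$genes,
      cell_means = sim$truth$cell_means
    ),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(sim)
}
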