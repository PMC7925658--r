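# Cq data model: reading, validation, technical-replicate collapsing,
# and per-gene descriptive statistics.

CQ_MAX <- 45

# Coerce/validate the canonical long Cq layout. Requires sample, gene, cq;
# bio_rep/tech_rep and the design columns (tissue, stage) are optional here
# and checked by the operations that need them.
as_cq_df <- function(data) {
  if (!is.data.frame(data)) abort("Cq data must be a data frame")
  need <- c("sample", "gene", "cq")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(data)
}

check_cq_values <- function(cq) {
  bad <- which(!is.finite(cq) | cq <= 0 | cq > CQ_MAX)
  if (length(bad) > 0) {
    abort(paste0(
      "Cq value out of range (0, ", CQ_MAX, "] or non-numeric at row ",
      bad[1], " (value: ", cq[bad[1]], "). Values above ", CQ_MAX,
      " are treated as non-detects and rejected."
    ))
  }
  invisible(cq)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
}

#' Read a long-format Cq table with its sample design
#'
#' Reads quantification-cycle (Cq) measurements in the canonical long layout
#' (`sample, gene, bio_rep, tech_rep, cq`; column names matched
#' case-insensitively) and a design table (`sample, tissue, stage`) mapping
#' each sample to its experimental factors, and returns a single validated
#' tibble with the design columns joined on.
#'
#' Cq values must be finite and lie in (0, 45]; values above 45 cycles are
#' treated as non-detects and rejected with the offending row number.
#'
#' @param path path to the Cq table (TSV, or CSV if the extension is `.csv`).
#' @param design_path path to the design table.
#' @param species_label optional free-text label stored as an attribute.
#' @return A tibble with columns `sample`, `gene`, `bio_rep`, `tech_rep`,
#'   `cq`, `tissue`, `stage`, rows in input order.
#' @seealso [write_cq_long()], [collapse_technical_replicates()]
#' @export
read_cq_long <- function(path, design_path, species_label = NULL) {
  raw <- read_delim_auto(path)
  names(raw) <- tolower(names(raw))
  need <- c("sample", "gene", "bio_rep", "tech_rep", "cq")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Cq table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  cq_num <- suppressWarnings(as.numeric(raw$cq))
  nn <- which(is.na(cq_num))
  if (length(nn) > 0) {
    abort(paste0("non-numeric cq value at row ", nn[1], " (value: '", raw$cq[nn[1]], "')"))
  }
  check_cq_values(cq_num)
  for (col in c("bio_rep", "tech_rep")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    if (anyNA(v) || any(v < 1)) {
      abort(paste0("column '", col, "' must contain positive integers"))
    }
    raw[[col]] <- v
  }
  raw$cq <- cq_num

  design <- read_delim_auto(design_path)
  names(design) <- tolower(names(design))
  dmiss <- setdiff(c("sample", "tissue", "stage"), names(design))
  if (length(dmiss) > 0) {
    abort(paste0("design table is missing column(s): ", paste(dmiss, collapse = ", ")))
  }
  orphan <- setdiff(unique(raw$sample), design$sample)
  if (length(orphan) > 0) {
    abort(paste0(
      "sample(s) without a design entry: ",
      paste(head(orphan, 5), collapse = ", "),
      if (length(orphan) > 5) ", ..." else ""
    ))
  }
  out <- raw |>
    dplyr::select("sample", "gene", "bio_rep", "tech_rep", "cq") |>
    dplyr::left_join(
      dplyr::distinct(design, .data$sample, .data$tissue, .data$stage),
      by = "sample"
    )
  if (!is.null(species_label)) attr(out, "species_label") <- species_label
  out
}

#' Write a Cq table (and optionally its design) in canonical form
#'
#' Emits tab-separated files in the same layout [read_cq_long()] accepts,
#' with Cq formatted to 4 decimal places so that a write/read/write cycle is
#' byte-stable.
#'
#' @param data a Cq tibble as returned by [read_cq_long()].
#' @param path output path for the Cq table (TSV).
#' @param design_path optional output path for the design table.
#' @return `data`, invisibly.
#' @export
write_cq_long <- function(data, path, design_path = NULL) {
  data <- as_cq_df(data)
  tab <- data |>
    dplyr::mutate(cq = sprintf("%.4f", .data$cq)) |>
    dplyr::select(dplyr::any_of(c("sample", "gene", "bio_rep", "tech_rep", "cq")))
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(design_path)) {
    if (!all(c("tissue", "stage") %in% names(data))) {
      abort("data has no tissue/stage columns to write as a design table")
    }
    design <- dplyr::distinct(data, .data$sample, .data$tissue, .data$stage)
    readr::write_tsv(design, design_path, progress = FALSE)
  }
  invisible(data)
}

#' Collapse technical replicates to one Cq per gene and biological sample
#'
#' Technical (pipetting) replicates of the same reaction are averaged on the
#' Cq scale; since Cq is already logarithmic in template abundance, the
#' arithmetic mean of Cq is the community convention (a median policy is
#' available for outlier-heavy plates).
#'
#' @param data a long Cq tibble (see [read_cq_long()]).
#' @param policy `"mean"` (default) or `"median"`.
#' @return A tibble with one row per (sample, gene, bio_rep), `tech_rep`
#'   dropped, design columns preserved.
#' @export
collapse_technical_replicates <- function(data, policy = c("mean", "median")) {
  data <- as_cq_df(data)
  policy <- match.arg(policy)
  fun <- if (policy == "mean") mean else stats::median
  keys <- intersect(c("sample", "gene", "bio_rep", "tissue", "stage"), names(data))
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(cq = fun(.data$cq), .groups = "drop") |>
    dplyr::select(dplyr::all_of(c(setdiff(keys, c("tissue", "stage")), "cq",
                                  intersect(c("tissue", "stage"), keys))))
  dup <- out |>
    dplyr::count(.data$gene, .data$sample) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "sample id '", dup$sample[1], "' spans multiple biological replicates; ",
      "sample ids must identify one biological unit (e.g. root_April_b1)"
    ))
  }
  out
}

#' Per-gene descriptive statistics of Cq
#'
#' Summarises each gene's collapsed Cq values across samples: mean, sample
#' standard deviation (n-1 denominator), coefficient of variation
#' (100 * sd / mean), range, and sample count. Genes observed in fewer than
#' two samples are flagged (`sd_defined = FALSE`) with `NA` dispersion.
#'
#' @param data a collapsed Cq tibble.
#' @return A tibble with columns `gene`, `n`, `mean_cq`, `sd_cq`,
#'   `cv_percent`, `min_cq`, `max_cq`, `sd_defined`.
#' @export
cq_summary <- function(data) {
  data <- as_cq_df(data)
  data |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cq = mean(.data$cq),
      sd_cq = if (dplyr::n() >= 2) sd(.data$cq) else NA_real_,
      min_cq = min(.data$cq),
      max_cq = max(.data$cq),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cv_percent = 100 * .data$sd_cq / .data$mean_cq,
      sd_defined = !is.na(.data$sd_cq)
    ) |>
    dplyr::select(
      "gene", "n", "mean_cq", "sd_cq", "cv_percent",
      "min_cq", "max_cq", "sd_defined"
    )
}

#' Drop samples that are missing any gene
#'
#' Pairwise stability statistics require a complete gene-by-sample grid. The
#' default policy elsewhere in the package is a hard error on incomplete
#' data; this opt-in filter removes samples with any missing gene so the grid
#' stays balanced.
#'
#' @param data a collapsed Cq tibble.
#' @return The filtered tibble; a warning reports how many samples were lost.
#' @export
drop_incomplete_samples <- function(data) {
  data <- as_cq_df(data)
  genes <- unique(data$gene)
  keep <- data |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(complete = length(unique(.data$gene)) == length(genes)) |>
    dplyr::filter(.data$complete) |>
    dplyr::pull("sample")
  dropped <- setdiff(unique(data$sample), keep)
  if (length(dropped) > 0) {
    warn(paste0("dropped ", length(dropped), " incomplete sample(s)"))
  }
  dplyr::filter(data, .data$sample %in% keep)
}
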