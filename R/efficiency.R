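# Amplification-efficiency estimation from standard-curve dilution series.

#' Estimate PCR amplification efficiency from a dilution series
#'
#' Fits, per gene, an ordinary least-squares standard curve of Cq on
#' log10 relative template concentration and converts the slope to the
#' percent amplification efficiency
#' \deqn{E = (10^{-1/slope} - 1) \times 100,}
#' so a slope of \eqn{-1/\log_{10} 2 \approx -3.3219} (perfect doubling per
#' cycle) gives E = 100%.
#'
#' @param series a data frame with columns `gene`, `log10_dilution`
#'   (log10 relative concentration; e.g. 0, -1, -2 for a tenfold series) and
#'   `cq`. Each gene needs at least 3 distinct dilution levels.
#' @return A `gene_efficiency` tibble with columns `gene`, `slope`
#'   (cycles per log10 unit), `intercept`, `e_percent`, `r_squared`, `n`.
#' @examples
#' s <- tibble::tibble(gene = "G", log10_dilution = 0:-4,
#'                     cq = 20 - (0:-4) * 3.321928)
#' amplification_efficiency(s)
#' @export
amplification_efficiency <- function(series) {
  if (!is.data.frame(series)) abort("series must be a data frame")
  need <- c("gene", "log10_dilution", "cq")
  missing <- setdiff(need, names(series))
  if (length(missing) > 0) {
    abort(paste0("dilution series is missing column(s): ", paste(missing, collapse = ", ")))
  }
  fit_one <- function(df, gene) {
    if (length(unique(df$log10_dilution)) < 3) {
      abort(paste0("gene ", gene, ": fewer than 3 distinct dilution levels"))
    }
    fit <- lm(cq ~ log10_dilution, data = df)
    slope <- unname(coef(fit)[2])
    if (slope >= 0) {
      abort(paste0("gene ", gene, ": standard curve has non-negative slope"))
    }
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((df$cq - mean(df$cq))^2)
    tibble::tibble(
      gene = gene,
      slope = slope,
      intercept = unname(coef(fit)[1]),
      e_percent = (10^(-1 / slope) - 1) * 100,
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      n = nrow(df)
    )
  }
  out <- series |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_map(~ fit_one(.x, .y$gene)) |>
    dplyr::bind_rows()
  class(out) <- c("gene_efficiency", class(out))
  out
}

#' Gate amplification efficiencies against an acceptance window
#'
#' Primer pairs are conventionally accepted for RT-qPCR when their estimated
#' efficiency lies within 90--110% (boundaries inclusive).
#'
#' @param efficiency a `gene_efficiency` tibble (or any data frame with
#'   `gene` and `e_percent`).
#' @param low,high window bounds in percent.
#' @return The input with a logical `pass` column appended.
#' @export
check_efficiency_range <- function(efficiency, low = 90, high = 110) {
  if (!is.data.frame(efficiency) || !all(c("gene", "e_percent") %in% names(efficiency))) {
    abort("efficiency must be a data frame with columns 'gene' and 'e_percent'")
  }
  dplyr::mutate(efficiency, pass = .data$e_percent >= low & .data$e_percent <= high)
}
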