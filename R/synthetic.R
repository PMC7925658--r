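# Synthetic spatio-temporal RT-qPCR data with known ground truth.
#
# Generative model on the Cq (log2) scale:
#   Cq(gene, sample, tech) = baseline + tissue_effect + stage_effect
#     + interaction_effect + sample_effect(sample)
#     + N(0, residual_sd^2)   [biological noise, per gene x sample]
#     + N(0, tech_sd^2)       [technical noise, per well]
# Gaussian noise on Cq corresponds to multiplicative (log-normal) error in
# template abundance, the standard qPCR error model. Per-sample effects
# model loading/RT-yield differences shared by every gene in a sample; all
# stability statistics are expected to cancel them.

#' Specify a synthetic spatio-temporal Cq experiment
#'
#' @param genes a tibble with one row per gene: `gene`, `baseline_cq`,
#'   `residual_sd` (cycles), `e_true` (fold per cycle), `class` (free-text
#'   stability class, e.g. stable/moderate/unstable/target), plus
#'   per-condition effect columns handled via the `effects` argument.
#' @param effects a tibble of condition effects in cycles: columns `gene`,
#'   `tissue` (or `NA`), `stage` (or `NA`), `effect`. A row with only
#'   `tissue` set is a tissue main effect, only `stage` a stage main effect,
#'   both set an interaction effect. Unlisted combinations default to 0.
#' @param tissues,stages factor levels of the design.
#' @param n_bio,n_tech biological and technical replicates per cell.
#' @param sample_effect_sd,tech_sd global per-sample effect SD and technical
#'   noise SD, in cycles.
#' @param seed default RNG seed used by [generate_cq()].
#' @return A `synthetic_spec` object (list).
#' @export
synthetic_spec <- function(genes, effects = NULL,
                           tissues = c("root", "rhizome", "leaf"),
                           stages = c("April", "May", "July", "October"),
                           n_bio = 3, n_tech = 3,
                           sample_effect_sd = 0.5, tech_sd = 0.15,
                           seed = 1L) {
  genes <- tibble::as_tibble(genes)
  need <- c("gene", "baseline_cq", "residual_sd", "e_true")
  missing <- setdiff(need, names(genes))
  if (length(missing) > 0) {
    abort(paste0("genes table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"class" %in% names(genes)) genes$class <- "unspecified"
  if (any(genes$baseline_cq <= 0 | genes$baseline_cq >= CQ_MAX)) {
    abort("baseline Cq values must lie in (0, 45)")
  }
  if (any(genes$residual_sd < 0) || sample_effect_sd < 0 || tech_sd < 0) {
    abort("noise SDs must be non-negative")
  }
  if (is.null(effects)) {
    effects <- tibble::tibble(
      gene = character(), tissue = character(),
      stage = character(), effect = numeric()
    )
  }
  effects <- tibble::as_tibble(effects)
  bad_gene <- setdiff(effects$gene, genes$gene)
  if (length(bad_gene) > 0) {
    abort(paste0("effects reference unknown gene(s): ", paste(bad_gene, collapse = ", ")))
  }
  bad_t <- setdiff(stats::na.omit(effects$tissue), tissues)
  bad_s <- setdiff(stats::na.omit(effects$stage), stages)
  if (length(bad_t) > 0 || length(bad_s) > 0) {
    abort(paste0(
      "effects reference unknown design level(s): ",
      paste(c(bad_t, bad_s), collapse = ", ")
    ))
  }
  out <- list(
    genes = genes, effects = effects, tissues = tissues, stages = stages,
    n_bio = n_bio, n_tech = n_tech,
    sample_effect_sd = sample_effect_sd, tech_sd = tech_sd, seed = as.integer(seed)
  )
  class(out) <- "synthetic_spec"
  out
}

# total condition effect (cycles) for one gene in one (tissue, stage) cell
cell_effect <- function(effects, g, ti, st) {
  e <- effects[effects$gene == g, , drop = FALSE]
  sum(e$effect[(!is.na(e$tissue) & e$tissue == ti & is.na(e$stage)) |
    (is.na(e$tissue) & !is.na(e$stage) & e$stage == st) |
    (!is.na(e$tissue) & e$tissue == ti & !is.na(e$stage) & e$stage == st)])
}

#' Generate a synthetic Cq dataset with its ground truth
#'
#' Simulates the full factorial design of `spec` (tissues x stages x
#' biological x technical replicates) under the additive Cq model described
#' in the package vignette, deterministically for a given seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed; defaults to `spec$seed`. The global RNG state is
#'   left untouched.
#' @return A list with
#'   \describe{
#'     \item{data}{long Cq tibble (`sample`, `gene`, `bio_rep`, `tech_rep`,
#'       `cq`, `tissue`, `stage`); sample ids are `tissue_stage_b<i>`.}
#'     \item{truth}{list with `genes` (tibble `gene`, `class`,
#'       `condition_sd` — the SD of the total condition effect over design
#'       cells — and `residual_sd`) and `cell_means` (tibble `gene`,
#'       `tissue`, `stage`, `mean_cq` of the noiseless model).}
#'   }
#' @export
generate_cq <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- seed %||% spec$seed
  design <- tidyr::expand_grid(
    tissue = spec$tissues, stage = spec$stages,
    bio_rep = seq_len(spec$n_bio)
  ) |>
    dplyr::mutate(sample = paste0(.data$tissue, "_", .data$stage, "_b", .data$bio_rep))

  cells <- tidyr::expand_grid(
    gene = spec$genes$gene, tissue = spec$tissues, stage = spec$stages
  ) |>
    dplyr::rowwise() |>
    dplyr::mutate(cond_effect = cell_effect(spec$effects, .data$gene, .data$tissue, .data$stage)) |>
    dplyr::ungroup() |>
    dplyr::left_join(spec$genes[, c("gene", "baseline_cq")], by = "gene") |>
    dplyr::mutate(mean_cq = .data$baseline_cq + .data$cond_effect)

  grid <- tidyr::expand_grid(
    gene = spec$genes$gene,
    design
  ) |>
    dplyr::left_join(cells[, c("gene", "tissue", "stage", "mean_cq")],
      by = c("gene", "tissue", "stage")
    )

  withr::with_seed(seed, {
    sample_eff <- setNames(
      stats::rnorm(nrow(design), 0, spec$sample_effect_sd),
      design$sample
    )
    res_sd <- setNames(spec$genes$residual_sd, spec$genes$gene)
    grid$bio_noise <- stats::rnorm(nrow(grid), 0, res_sd[grid$gene])
    out <- tidyr::expand_grid(grid, tech_rep = seq_len(spec$n_tech))
    out$cq <- out$mean_cq + sample_eff[out$sample] + out$bio_noise +
      stats::rnorm(nrow(out), 0, spec$tech_sd)
  })

  truth_genes <- cells |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(condition_sd = sd(.data$cond_effect), .groups = "drop") |>
    dplyr::left_join(spec$genes[, c("gene", "class", "residual_sd")], by = "gene") |>
    dplyr::select("gene", "class", "condition_sd", "residual_sd")

  list(
    data = out |>
      dplyr::select("sample", "gene", "bio_rep", "tech_rep", "cq", "tissue", "stage") |>
      dplyr::arrange(.data$gene, .data$sample, .data$tech_rep),
    truth = list(
      genes = truth_genes,
      cell_means = cells[, c("gene", "tissue", "stage", "mean_cq")]
    )
  )
}

# deterministic centered pattern with max |value| = scale; `shift` rotates
# the pattern so different genes vary in different directions
shape_pattern <- function(n_levels, scale, shift = 0) {
  base <- c(1, -0.8, -0.3, 0.9, -1, 0.4)
  p <- base[((seq_len(n_levels) - 1 + shift) %% length(base)) + 1]
  p <- p - mean(p)
  if (max(abs(p)) == 0) {
    return(rep(0, n_levels))
  }
  p / max(abs(p)) * scale
}

#' Preset emulating a licorice spatio-temporal reference-gene study
#'
#' A 14-candidate panel plus one target gene across 3 tissues (root,
#' rhizome, leaf) and 4 developmental stages (April, May, July, October)
#' with 3 biological x 3 technical replicates. Baselines are spread over
#' 19--27 cycles. Three candidates are designed stable (condition effects
#' up to 0.1 cycles), eight moderate (0.4--0.9), and three unstable (up to
#' 1.5 cycles per factor, with low baselines so their CV of Cq reaches the
#' ~10% seen for the worst candidates in real panels; stable genes stay
#' under 5%). The extra target gene `bAS` is root/rhizome-specific: leaves
#' sit 4 cycles higher (~16-fold lower expression).
#'
#' Effects are fixed, structured patterns (no RNG): the preset defines the
#' study conditions, and only [generate_cq()] noise varies with the seed.
#'
#' @return A [synthetic_spec()].
#' @export
licorice_preset <- function() {
  candidates <- tibble::tibble(
    gene = c(
      "CAC", "COPS3", "R3HDM2", # designed stable
      "CYP", "DNAJ", "DREB", "RAN", "TUB", "UBC2", "ABCC2", "CS", # moderate
      "ACT", "TIF1", "EF1" # designed unstable
    ),
    class = rep(c("stable", "moderate", "unstable"), c(3, 8, 3)),
    baseline_cq = c(
      23.0, 24.5, 25.5,
      26.0, 23.5, 25.0, 22.5, 24.0, 26.5, 21.5, 27.0,
      19.5, 20.0, 20.0
    ),
    scale = c(
      0.1, 0.1, 0.1,
      0.4, 0.45, 0.5, 0.55, 0.6, 0.7, 0.8, 0.9,
      1.5, 1.5, 1.5
    ),
    # pattern phase: the three unstable genes share a same-sign root-leaf
    # contrast (a common systematic tissue trend, the realistic failure
    # mode of poor references); other genes vary in diverse directions
    shift = c(0:10, 5, 0, 2),
    residual_sd = 0.25,
    e_true = 2
  )
  target <- tibble::tibble(
    gene = "bAS", class = "target", baseline_cq = 22, scale = 0,
    shift = 0, residual_sd = 0.25, e_true = 2
  )
  genes <- dplyr::bind_rows(candidates, target)

  tissues <- c("root", "rhizome", "leaf")
  stages <- c("April", "May", "July", "October")
  effects <- purrr::imap_dfr(
    setNames(candidates$scale, candidates$gene),
    function(s, g) {
      shift <- candidates$shift[match(g, candidates$gene)]
      dplyr::bind_rows(
        tibble::tibble(
          gene = g, tissue = tissues, stage = NA_character_,
          effect = shape_pattern(3, s, shift)
        ),
        tibble::tibble(
          gene = g, tissue = NA_character_, stage = stages,
          effect = shape_pattern(4, s, shift + 1)
        ),
        {
          # pure interaction: outer product of centered patterns sums to
          # zero over each margin, so it cannot leak into the main effects
          pt <- shape_pattern(3, 1, shift + 2)
          ps <- shape_pattern(4, 1, shift + 3)
          inter <- outer(pt, ps)
          if (max(abs(inter)) > 0) inter <- inter / max(abs(inter)) * s
          tidyr::expand_grid(tissue = tissues, stage = stages) |>
            dplyr::mutate(
              gene = g,
              effect = as.vector(t(inter))
            ) |>
            dplyr::select("gene", "tissue", "stage", "effect")
        }
      )
    }
  )
  # root/rhizome-specific target: leaf ~16-fold lower (Cq + 4)
  effects <- dplyr::bind_rows(
    effects,
    tibble::tibble(gene = "bAS", tissue = "leaf", stage = NA_character_, effect = 4)
  )
  genes$scale <- NULL
  genes$shift <- NULL
  synthetic_spec(
    genes = genes, effects = effects, tissues = tissues, stages = stages,
    n_bio = 3, n_tech = 3, sample_effect_sd = 0.5, tech_sd = 0.15, seed = 1L
  )
}

#' Generate a standard-curve dilution series with known efficiency
#'
#' Tenfold dilution steps with
#' \eqn{Cq = c_0 + slope \cdot \log_{10}(dilution)}, where
#' \eqn{slope = -1/\log_{10}(E_{true})}, plus optional Gaussian noise.
#' Fitting the result with [amplification_efficiency()] recovers
#' `(e_true - 1) * 100` percent exactly in the noiseless case.
#'
#' @param gene gene name.
#' @param e_true true amplification efficiency, fold per cycle (> 1).
#' @param levels number of tenfold dilution levels (>= 3).
#' @param noise_sd Gaussian Cq noise SD in cycles.
#' @param c0 Cq of the undiluted sample.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return A dilution-series tibble: `gene`, `log10_dilution`, `cq`.
#' @export
generate_dilution <- function(gene, e_true, levels = 5, noise_sd = 0,
                              c0 = 18, seed = 1L) {
  if (e_true <= 1) abort("e_true must exceed 1 (fold amplification per cycle)")
  if (levels < 3) abort("need at least 3 dilution levels")
  slope <- -1 / log10(e_true)
  log10_dilution <- -(seq_len(levels) - 1)
  cq <- c0 + slope * log10_dilution
  if (noise_sd > 0) {
    cq <- withr::with_seed(seed, cq + stats::rnorm(levels, 0, noise_sd))
  }
  tibble::tibble(gene = gene, log10_dilution = log10_dilution, cq = cq)
}
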