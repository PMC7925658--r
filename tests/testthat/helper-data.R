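# Builders for small in-memory datasets used across the suite.

# collapsed Cq tibble from a genes x samples matrix
cq_from_matrix <- function(m, tissue = NULL, stage = NULL) {
  samples <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  genes <- rownames(m) %||% paste0("g", seq_len(nrow(m)))
  out <- tibble::tibble(
    sample = rep(samples, each = nrow(m)),
    gene = rep(genes, ncol(m)),
    bio_rep = 1L,
    cq = as.vector(m)
  )
  if (!is.null(tissue)) {
    if (length(tissue) == 1) tissue <- rep(tissue, ncol(m))
    out$tissue <- rep(tissue, each = nrow(m))
  }
  if (!is.null(stage)) {
    if (length(stage) == 1) stage <- rep(stage, ncol(m))
    out$stage <- rep(stage, each = nrow(m))
  }
  out
}

# random complete collapsed dataset, Cq in a realistic window
random_cq <- function(k, n, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(k * n, 18, 30), nrow = k)
  })
  rownames(m) <- paste0("g", seq_len(k))
  colnames(m) <- paste0("s", seq_len(n))
  m
}

`%||%` <- rlang::`%||%`
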