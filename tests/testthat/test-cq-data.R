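make_toy_files <- function(dir, cq_rows, design_rows) {
  cq_path <- file.path(dir, "cq.tsv")
  design_path <- file.path(dir, "design.tsv")
  writeLines(c("sample\tgene\tbio_rep\ttech_rep\tcq", cq_rows), cq_path)
  writeLines(c("sample\ttissue\tstage", design_rows), design_path)
  list(cq = cq_path, design = design_path)
}

test_that("read_cq_long round-trips a toy file and joins the design", {
  dir <- withr::local_tempdir()
  f <- make_toy_files(dir,
    cq_rows = c(
      "s1\tA\t1\t1\t20.5", "s1\tB\t1\t1\t22.0",
      "s2\tA\t1\t1\t21.0", "s2\tB\t1\t1\t23.5"
    ),
    design_rows = c("s1\troot\tApril", "s2\tleaf\tApril")
  )
  d <- read_cq_long(f$cq, f$design)
  expect_equal(nrow(d), 4)
  expect_equal(d$cq, c(20.5, 22.0, 21.0, 23.5))
  expect_equal(d$tissue[d$sample == "s1"], c("root", "root"))
  expect_named(d, c("sample", "gene", "bio_rep", "tech_rep", "cq", "tissue", "stage"))
})

test_that("malformed inputs are rejected with informative errors", {
  dir <- withr::local_tempdir()
  # non-numeric cq cites the row
  rows <- c(
    "s1\tA\t1\t1\t20.5", "s1\tB\t1\t1\t22.0", "s2\tA\t1\t1\t21.0",
    "s2\tB\t1\t1\t23.5", "s1\tC\t1\t1\t24.0", "s2\tC\t1\t1\t25.0",
    "s1\tD\t1\t1\tNA"
  )
  f <- make_toy_files(dir, rows, c("s1\troot\tApril", "s2\tleaf\tApril"))
  expect_error(read_cq_long(f$cq, f$design), "row 7")

  # missing column named in the error
  writeLines(c("sample\tgene\tbio_rep\tcq", "s1\tA\t1\t20"), file.path(dir, "bad.tsv"))
  expect_error(read_cq_long(file.path(dir, "bad.tsv"), f$design), "tech_rep")

  # out-of-range Cq (non-detect) rejected
  f2 <- make_toy_files(dir, "s1\tA\t1\t1\t46.0", "s1\troot\tApril")
  expect_error(read_cq_long(f2$cq, f2$design), "non-detect")

  # sample without a design entry
  f3 <- make_toy_files(dir, "s9\tA\t1\t1\t20.0", "s1\troot\tApril")
  expect_error(read_cq_long(f3$cq, f3$design), "s9")
})

test_that("write/read/write is byte-stable for canonical files", {
  dir <- withr::local_tempdir()
  withr::local_seed(42)
  d <- tidyr::expand_grid(
    sample = c("s1", "s2", "s3"), gene = c("A", "B"),
    bio_rep = 1L, tech_rep = 1:2
  ) |>
    dplyr::mutate(
      cq = round(stats::runif(dplyr::n(), 18, 30), 4),
      tissue = "root", stage = "April"
    )
  p1 <- file.path(dir, "a.tsv")
  p2 <- file.path(dir, "b.tsv")
  dp <- file.path(dir, "design.tsv")
  write_cq_long(d, p1, design_path = dp)
  roundtrip <- read_cq_long(p1, dp)
  write_cq_long(roundtrip, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
})

test_that("technical replicates collapse by mean or median", {
  d <- tibble::tibble(
    sample = "s1", gene = "A", bio_rep = 1L, tech_rep = 1:3,
    cq = c(20.0, 20.2, 20.4), tissue = "root", stage = "April"
  )
  expect_equal(collapse_technical_replicates(d, "mean")$cq, 20.2)
  d$cq <- c(20.0, 20.0, 25.0)
  expect_equal(collapse_technical_replicates(d, "median")$cq, 20.0)

  # brute-force group-by oracle on random triplets
  withr::local_seed(7)
  big <- tidyr::expand_grid(
    sample = paste0("s", 1:6), gene = c("A", "B", "C"), bio_rep = 1L, tech_rep = 1:3
  ) |>
    dplyr::mutate(cq = stats::runif(dplyr::n(), 18, 30))
  got <- collapse_technical_replicates(big, "mean")
  oracle <- stats::aggregate(cq ~ sample + gene, data = big, FUN = mean)
  merged <- merge(got, oracle, by = c("sample", "gene"))
  expect_equal(merged$cq.x, merged$cq.y)
  # singleton groups pass through
  single <- big[1, ]
  expect_equal(collapse_technical_replicates(single)$cq, single$cq)
})

test_that("cq_summary matches hand computations and flags tiny genes", {
  d <- cq_from_matrix(matrix(c(20, 21, 22, 23), nrow = 1, dimnames = list("A", NULL)))
  s <- cq_summary(d)
  expect_equal(s$mean_cq, 21.5)
  expect_equal(s$sd_cq, sd(c(20, 21, 22, 23)))
  expect_equal(round(s$sd_cq, 4), 1.2910)
  expect_equal(s$min_cq, 20)
  expect_equal(s$max_cq, 23)

  s2 <- cq_summary(cq_from_matrix(matrix(c(24, 24, 24), nrow = 1, dimnames = list("A", NULL))))
  expect_equal(s2$sd_cq, 0)
  expect_equal(s2$cv_percent, 0)

  s3 <- cq_summary(cq_from_matrix(matrix(c(19, 21), nrow = 1, dimnames = list("A", NULL))))
  expect_equal(round(s3$cv_percent, 2), 7.07)

  s4 <- cq_summary(tibble::tibble(sample = "s1", gene = "A", cq = 20))
  expect_false(s4$sd_defined)
  expect_true(is.na(s4$sd_cq))
})

test_that("per-gene Cq shifts move the mean and leave the SD alone; order is irrelevant", {
  m <- random_cq(4, 8, seed = 11)
  d <- cq_from_matrix(m)
  base <- cq_summary(d)
  shifted <- dplyr::mutate(d, cq = cq + ifelse(gene == "g2", 3.5, 0))
  s <- cq_summary(shifted)
  expect_equal(s$mean_cq[s$gene == "g2"], base$mean_cq[base$gene == "g2"] + 3.5)
  expect_equal(s$sd_cq, base$sd_cq)

  perm <- d[sample(nrow(d)), ]
  expect_equal(
    dplyr::arrange(cq_summary(perm), gene),
    dplyr::arrange(base, gene)
  )
})

test_that("incomplete gene-by-sample grids error by default and can drop samples", {
  m <- random_cq(3, 4, seed = 3)
  d <- cq_from_matrix(m)[-1, ] # remove g1 from s1
  expect_error(genorm_m(d), "incomplete")
  expect_warning(kept <- drop_incomplete_samples(d), "dropped 1")
  expect_setequal(unique(kept$sample), c("s2", "s3", "s4"))
})
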