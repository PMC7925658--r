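three_gene_example <- function() {
  cq_from_matrix(matrix(
    c(
      20, 21, 22, 23,
      20, 21, 22, 23,
      20, 22, 21, 23
    ),
    nrow = 3, byrow = TRUE, dimnames = list(c("A", "B", "C"), NULL)
  ))
}

test_that("relative quantities follow q = E^(Cqmin - Cq)", {
  d <- cq_from_matrix(matrix(c(20, 21, 23), nrow = 1, dimnames = list("A", NULL)))
  q <- relative_quantities(d)
  expect_equal(q$q, c(1, 0.5, 0.125))

  d2 <- cq_from_matrix(matrix(c(20, 21), nrow = 1, dimnames = list("A", NULL)))
  q2 <- relative_quantities(d2, efficiencies = c(A = 2.1544))
  expect_equal(q2$q, c(1, 1 / 2.1544), tolerance = 1e-9)

  d3 <- cq_from_matrix(matrix(c(22, 22, 22), nrow = 1, dimnames = list("A", NULL)))
  expect_equal(relative_quantities(d3)$q, c(1, 1, 1))

  expect_error(relative_quantities(d, efficiencies = 1), "exceed 1")
  # efficiency tables convert e_percent to fold change
  eff_tab <- tibble::tibble(gene = "A", e_percent = 115.44)
  q4 <- relative_quantities(d2, efficiencies = eff_tab)
  expect_equal(q4$q[2], 1 / 2.1544, tolerance = 1e-4)
})

test_that("M matches the hand-computed 3-gene example and a brute-force oracle", {
  m <- genorm_m(three_gene_example())
  expect_equal(m$m[m$gene == "A"], mean(c(0, sd(c(0, -1, 1, 0)))))
  expect_equal(round(m$m, 5), c(0.40825, 0.40825, 0.81650), ignore_attr = TRUE)

  # identical profiles (any common shape) have M = 0
  dup <- cq_from_matrix(matrix(
    c(20, 24, 21, 18, 20, 24, 21, 18),
    nrow = 2, byrow = TRUE, dimnames = list(c("A", "B"), NULL)
  ))
  expect_equal(genorm_m(dup)$m, c(0, 0))

  # brute-force double loop over all pairs on a random 5x8 matrix
  mat <- random_cq(5, 8, seed = 21)
  d <- cq_from_matrix(mat)
  got <- genorm_m(d)
  lq <- log2(2^(apply(mat, 1, min) - mat))
  brute <- vapply(1:5, function(j) {
    mean(vapply(setdiff(1:5, j), function(l) sd(lq[j, ] - lq[l, ]), numeric(1)))
  }, numeric(1))
  expect_equal(got$m[match(rownames(mat), got$gene)], brute, tolerance = 1e-12)

  expect_error(genorm_m(d, genes = "g1"), "fewer than 2")
})

test_that("iterative exclusion ranks the 3-gene example and breaks ties deterministically", {
  fit <- genorm_rank(three_gene_example())
  expect_equal(fit$exclusion_order, "C")
  expect_setequal(fit$final_pair, c("A", "B"))
  expect_equal(fit$stability$rank[match(c("A", "B", "C"), fit$stability$gene)], c(1L, 1L, 3L))
  # the final pair shares its mutual M
  expect_equal(
    fit$stability$m[fit$stability$gene == "A"],
    fit$stability$m[fit$stability$gene == "B"]
  )

  # k identical genes: all M = 0; later genes removed first
  k <- 5
  m <- matrix(rep(c(20, 22, 24, 21), each = k), nrow = k, dimnames = list(paste0("g", 1:k), NULL))
  fit2 <- genorm_rank(cq_from_matrix(m))
  expect_equal(fit2$exclusion_order, c("g5", "g4", "g3"))
  expect_equal(fit2$final_pair, c("g1", "g2"))
  expect_equal(max(fit2$stability$m), 0)
  expect_error(genorm_rank(cq_from_matrix(m[1:2, ])), "3 genes")
})

test_that("M is invariant to per-gene Cq shifts and to sample order", {
  mat <- random_cq(5, 10, seed = 5)
  d <- cq_from_matrix(mat)
  base <- genorm_m(d)
  shifted <- dplyr::mutate(d, cq = cq + ifelse(gene == "g3", 4, -1))
  expect_equal(genorm_m(shifted)$m, base$m, tolerance = 1e-12)
  perm <- d[sample(nrow(d)), ]
  got <- genorm_m(perm)
  expect_equal(got$m[match(base$gene, got$gene)], base$m, tolerance = 1e-12)
})

test_that("mean M of survivors never increases along the exclusion path", {
  for (seed in 1:5) {
    fit <- genorm_rank(cq_from_matrix(random_cq(7, 9, seed = seed)))
    expect_true(all(diff(fit$mean_m_path) <= 1e-12))
  }
})

test_that("pairwise variation matches a brute-force oracle and handles degeneracy", {
  # all genes identical: every V = 0, two references suffice
  k <- 4
  m <- matrix(rep(c(20, 22, 24, 21, 23), each = k),
    nrow = k,
    dimnames = list(paste0("g", 1:k), NULL)
  )
  v <- pairwise_variation(cq_from_matrix(m))
  expect_equal(v$v, rep(0, 2))
  expect_equal(recommended_n(v), 2L)

  mat <- random_cq(5, 8, seed = 13)
  d <- cq_from_matrix(mat)
  fit <- genorm_rank(d)
  ranking <- c(fit$final_pair, rev(fit$exclusion_order))
  got <- pairwise_variation(d, ranking = ranking)
  q <- 2^(apply(mat, 1, min) - mat)[ranking, ]
  for (n in 2:4) {
    nf_n <- apply(q[1:n, , drop = FALSE], 2, function(x) exp(mean(log(x))))
    nf_n1 <- apply(q[1:(n + 1), , drop = FALSE], 2, function(x) exp(mean(log(x))))
    expect_equal(got$v[got$n == n], sd(log2(nf_n / nf_n1)), tolerance = 1e-12)
  }
  expect_true(all(got$v >= 0))
})

test_that("two ultra-stable genes drive V2/3 below the 0.15 cutoff", {
  # synthetic panel built with two near-identical references plus noisier
  # genes: the first V below threshold is V2/3, so two references suffice
  withr::local_seed(99)
  n <- 24
  shared <- stats::rnorm(n, 0, 0.8)
  m <- rbind(
    r1 = 22 + shared + stats::rnorm(n, 0, 0.03),
    r2 = 24 + shared + stats::rnorm(n, 0, 0.03),
    g3 = 23 + shared + stats::rnorm(n, 0, 0.35),
    g4 = 25 + shared + stats::rnorm(n, 0, 0.5),
    g5 = 26 + shared + stats::rnorm(n, 0, 0.55)
  )
  colnames(m) <- paste0("s", 1:n)
  v <- pairwise_variation(cq_from_matrix(m))
  expect_equal(recommended_n(v), 2L)
  expect_lt(v$v[v$n == 2], 0.15)
})
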