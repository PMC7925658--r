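test_that("normalization factors are geometric means of reference quantities", {
  # single reference: NF equals its own q profile
  m <- random_cq(3, 6, seed = 41)
  d <- cq_from_matrix(m)
  nf1 <- normalization_factor(d, "g1")
  q <- relative_quantities(d)
  q1 <- q$q[q$gene == "g1"]
  expect_equal(nf1$nf, q1[match(nf1$sample, q$sample[q$gene == "g1"])])

  # two refs with q {1, 0.25} and {1, 1} -> NF {1, 0.5}
  d2 <- cq_from_matrix(matrix(c(20, 22, 21, 21),
    nrow = 2, byrow = TRUE, dimnames = list(c("r1", "r2"), NULL)
  ))
  nf2 <- normalization_factor(d2, c("r1", "r2"))
  expect_equal(sort(nf2$nf, decreasing = TRUE), c(1, 0.5))

  # duplicated reference list is deduplicated
  expect_equal(
    normalization_factor(d, c("g1", "g1", "g2"))$nf,
    normalization_factor(d, c("g1", "g2"))$nf
  )
  expect_error(normalization_factor(d, character(0)), "at least one")
  expect_error(normalization_factor(d, "nope"), "nope")
})

test_that("relative expression validates its inputs and cancels loading effects", {
  m <- random_cq(4, 12, seed = 55)
  tissue <- rep(c("root", "rhizome", "leaf"), each = 4)
  d <- cq_from_matrix(m, tissue = tissue, stage = "April")
  expect_error(relative_expression(d, "g1", c("g1", "g2")), "normalize itself")
  expect_error(relative_expression(d, "zz", "g2"), "not in data")

  base <- relative_expression(d, "g1", c("g2", "g3", "g4"))
  # add a per-sample constant to every gene: expression must not move (E = 2)
  shift <- stats::setNames(stats::rnorm(12), colnames(m))
  d2 <- dplyr::mutate(d, cq = cq + shift[sample])
  got <- relative_expression(d2, "g1", c("g2", "g3", "g4"))
  expect_equal(got$samples$expression, base$samples$expression, tolerance = 1e-10)

  # closed form: expr proportional to 2^-(Cq_target - mean ref Cq)
  closed <- 2^-(m[1, ] - colMeans(m[2:4, ]))
  ratio <- base$samples$expression_raw[match(colnames(m), base$samples$sample)] / closed
  expect_equal(diff(range(ratio)), 0, tolerance = 1e-10)

  # scaled so the peak group mean is 1
  expect_equal(max(base$groups$mean), 1)
})

test_that("one-way ANOVA matches the hand-computed F and flat data gives F = 0", {
  # groups {1,2} vs {3,4}: SSB 4, SSW 1 -> F = 8 on (1, 2) df
  d <- tibble::tibble(expression = c(1, 2, 3, 4), group = c("a", "a", "b", "b"))
  fit <- stats::aov(expression ~ factor(group), data = d)
  at <- stats::anova(fit)
  expect_equal(at$`F value`[1], 8)

  # through the package: build Cq so normalized values are {1,2,3,4}
  ref <- rep(20, 4)
  target <- 20 - log2(c(1, 2, 3, 4))
  m <- rbind(t = target, r = ref)
  colnames(m) <- paste0("s", 1:4)
  dd <- cq_from_matrix(m, tissue = c("a", "a", "b", "b"), stage = "x")
  res <- relative_expression(dd, "t", "r")
  expect_equal(res$anova_f, 8, tolerance = 1e-10)

  # constant ratio: target = ref + 2 everywhere -> no between-group signal
  m2 <- rbind(t = ref + 2, r = ref + c(0.1, -0.1, 0.2, -0.2))
  m2["t", ] <- m2["r", ] + 2
  colnames(m2) <- paste0("s", 1:4)
  flat <- relative_expression(
    cq_from_matrix(m2, tissue = c("a", "a", "b", "b"), stage = "x"), "t", "r"
  )
  expect_equal(flat$anova_f, 0)
  expect_equal(flat$anova_p, 1)

  # ANOVA F equals a brute-force sum-of-squares computation on random data
  withr::local_seed(60)
  for (i in 1:5) {
    x <- stats::rnorm(12)
    g <- rep(c("a", "b", "c"), each = 4)
    gm <- tapply(x, g, mean)
    ssb <- sum(4 * (gm - mean(x))^2)
    ssw <- sum((x - gm[g])^2)
    f_brute <- (ssb / 2) / (ssw / 9)
    at2 <- stats::anova(stats::aov(x ~ factor(g)))
    expect_equal(at2$`F value`[1], f_brute, tolerance = 1e-10)
  }
})

test_that("the scheme panel builds the seven canonical schemes from a ranking", {
  sim <- generate_cq(licorice_preset(), seed = 4)
  d <- collapse_technical_replicates(sim$data)
  cand <- dplyr::filter(d, gene != "bAS")
  an <- stability_workflow(cand, condition = "tissue:stage")
  panel <- scheme_panel(d, "bAS", an$ranking)
  expect_equal(
    panel$summary$scheme,
    c("top1", "top2", "top3", "worst1", "worst2", "worst3", "all")
  )
  expect_equal(panel$summary$n_refs, c(1, 2, 3, 1, 2, 3, 14))
  best <- an$ranking$gene[which.min(an$ranking$geomean)]
  expect_equal(panel$results$top1$refs, best)
  expect_error(scheme_panel(d, "CAC", an$ranking), "cannot appear")
})

test_that("stable references recover the designed expression profile; unstable ones distort it", {
  # target designed with root ~ rhizome >> leaf (16-fold): stable refs must
  # separate leaf but not root/rhizome; worst refs distort the root:leaf ratio
  sim <- generate_cq(licorice_preset(), seed = 10)
  d <- collapse_technical_replicates(sim$data)
  cand <- dplyr::filter(d, gene != "bAS")
  an <- stability_workflow(cand, condition = "tissue:stage")
  panel <- scheme_panel(d, "bAS", an$ranking)

  top3 <- panel$results$top3$groups
  expect_equal(top3$letter[top3$group == "leaf"], "b")
  expect_equal(sort(top3$letter[top3$group != "leaf"]), c("a", "a"))
  ratio_true <- 2^4
  est_ratio <- function(res) {
    g <- res$groups
    g$mean[g$group == "root"] / g$mean[g$group == "leaf"]
  }
  expect_lt(abs(log2(est_ratio(panel$results$top3)) - log2(ratio_true)), 1)
  expect_gt(abs(log2(est_ratio(panel$results$worst3)) - log2(ratio_true)), 1)
})
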