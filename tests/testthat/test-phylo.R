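test_that("column likelihoods match the zero-branch and missing-data limits", {
  m0 <- two_leaf_model(0, 0)
  expect_equal(column_log_likelihood(c(A = "A", B = "A"), m0, 1), log(0.3))
  expect_equal(column_log_likelihood(c(A = "A", B = "G"), m0, 1), -Inf)
  m <- two_leaf_model()
  expect_equal(column_log_likelihood(c(A = "-", B = "-"), m, 1), 0)
  expect_equal(column_log_likelihood(c(A = "N", B = "-"), m, 1), 0)
  expect_error(column_log_likelihood(c(A = "A", B = "A"), m, 0), "scale")
})

test_that("pruning equals the closed-form pairwise likelihood on 2-leaf trees", {
  set.seed(1)
  m <- two_leaf_model(0.07, 0.23, pi = c(0.35, 0.15, 0.2, 0.3))
  bases <- c("A", "C", "G", "T")
  for (i in 1:100) {
    a <- sample(bases, 1); b <- sample(bases, 1)
    s <- runif(1, 0.2, 3)
    P <- transition_matrix(m, 0.3 * s)
    expect_equal(column_log_likelihood(c(A = a, B = b), m, s),
                 log(m$pi[[a]] * P[a, b]))
  }
})

test_that("summing a leaf's observation over all bases equals marginalising it", {
  m <- default_neutral_model()
  set.seed(3)
  for (i in 1:20) {
    col <- setNames(sample(c("A", "C", "G", "T"), 9, replace = TRUE), m$tree$tip.label)
    drop <- sample(names(col), 1)
    parts <- vapply(c("A", "C", "G", "T"), function(b) {
      col2 <- col; col2[drop] <- b
      exp(column_log_likelihood(col2, m, 1))
    }, numeric(1))
    col[drop] <- "-"
    expect_equal(sum(parts), exp(column_log_likelihood(col, m, 1)), tolerance = 1e-10)
  }
})

test_that("invariant alignments drive the scale MLE to the lower bound", {
  m <- default_neutral_model()
  cols <- matrix("A", 9, 50, dimnames = list(m$tree$tip.label, NULL))
  fit <- fit_scale(cols, m)
  expect_equal(fit$scale, 1e-3)
})

test_that("doubling branch lengths and halving the scale leaves the likelihood unchanged", {
  m <- default_neutral_model()
  t2 <- m$tree; t2$edge.length <- 2 * t2$edge.length
  m2 <- neutral_model(t2, base_freqs = m$pi, rate_matrix = m$Q)
  set.seed(5)
  cols <- cisnat:::sim_tree_columns(m, 100, 1)
  expect_equal(locus_log_likelihood(cols, m, 1.4),
               locus_log_likelihood(cols, m2, 0.7), tolerance = 1e-9)
})

test_that("the LRT statistic maps to the chi-squared(1) tail", {
  expect_equal(lrt_pvalue(2 * (-995 - -1000)), 0.001565402, tolerance = 1e-6)
  expect_equal(lrt_pvalue(0), 1)
  m <- default_neutral_model()
  set.seed(8)
  cols <- cisnat:::sim_tree_columns(m, 200, 0.3)
  r <- scale_lrt(cols, m)
  expect_equal(r$D, 2 * (r$lnL_alt - r$lnL_null))
  expect_gte(r$D, 0)
  expect_equal(r$p_value, lrt_pvalue(r$D))
  expect_equal(r$direction, "conserved")
  expect_lt(r$scale, 1)
  td <- tidy(r)
  expect_equal(td$estimate, r$scale)
  expect_equal(glance(r)$lnL_null, r$lnL_null)
})

test_that("loci with too few usable columns are untestable, not scored", {
  m <- default_neutral_model()
  cols <- matrix("-", 9, 50, dimnames = list(m$tree$tip.label, NULL))
  cols[1, ] <- "A"  # every column has a single informative species
  r <- scale_lrt(cols, m)
  expect_true(r$untestable)
  expect_true(is.na(r$p_value))
})

test_that("Holm-Bonferroni matches the step-down maxima", {
  expect_equal(holm_bonferroni(0.02), 0.02)
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.03, 0.04)), c(0.04, 0.06, 0.06, 0.06))
  expect_equal(holm_bonferroni(rep(1, 5)), rep(1, 5))
  expect_error(holm_bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("per-NAT conservation calls combine p < alpha with scale < 1", {
  tbl <- tibble::tibble(
    locus = c("l1", "l2", "l3", "l4"),
    nat_id = c("n1", "n2", "n3", "n3"),
    type = c(1L, 1L, 4L, 4L),
    scale = c(0.5, 1.4, 0.4, 0.6),
    p_value = c(0.04, 0.04, 0.01, 0.03),
    p_adjusted = c(0.16, 0.16, 0.04, 0.12)
  )
  calls <- call_conserved(tbl, alpha = 0.05)
  expect_equal(calls$conserved_phylo[calls$nat_id == "n1"], TRUE)
  expect_equal(calls$conserved_phylo[calls$nat_id == "n2"], FALSE)  # accelerated
  expect_equal(calls$n_conserved_regions[calls$nat_id == "n3"], 2L)
  expect_equal(calls$conserved_phylo_hb[calls$nat_id == "n1"], FALSE)

  # type-3 records have no defined call
  t3 <- tibble::tibble(locus = "x", nat_id = "n4", type = 3L,
                       scale = 0.5, p_value = 0.01, p_adjusted = 0.01)
  c3 <- call_conserved(dplyr::bind_rows(tbl, t3))
  expect_true(is.na(c3$conserved_phylo[c3$nat_id == "n4"]))
})
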