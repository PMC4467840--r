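test_that("matched sampling preserves lengths and gene-relative placement", {
  genes <- dplyr::bind_rows(
    ann("g1.1", "c", 1000, 2000, "+", gene_id = "g1"),
    ann("g2.1", "c", 5000, 6000, "+", gene_id = "g2"),
    ann("g3.1", "c", 9000, 10000, "-", gene_id = "g3")
  )
  obs <- intervals("c", 700, 1000)  # length 300, abutting g1 upstream (delta 0)
  s <- sample_matched_set(obs, genes, c(c = 15000L), seed = 4)
  expect_equal(s$end - s$start, 300L)
  # delta 0 is preserved: the sample abuts its anchor gene
  gaps <- pmin(abs(s$start - c(2000L, 6000L, 10000L)), abs(c(1000L, 5000L, 9000L) - s$end))
  expect_true(any(gaps == 0))
  # never overlaps a gene transcript
  expect_equal(sum(overlap_bp(s[rep(1, 3), ], genes)), 0L)
})

test_that("matched sampling is deterministic in the seed and fails on dense genomes", {
  genes <- dplyr::bind_rows(
    ann("g1.1", "c", 1000, 2000, "+", gene_id = "g1"),
    ann("g2.1", "c", 5000, 6000, "+", gene_id = "g2"),
    ann("g3.1", "c", 9000, 10000, "-", gene_id = "g3")
  )
  obs <- intervals("c", c(700L, 2100L), c(1000L, 2500L))
  a <- sample_matched_set(obs, genes, c(c = 15000L), seed = 4)
  b <- sample_matched_set(obs, genes, c(c = 15000L), seed = 4)
  expect_identical(a, b)
  others <- lapply(5:12, function(s) sample_matched_set(obs, genes, c(c = 15000L), seed = s))
  expect_false(all(vapply(others, identical, logical(1), a)))

  # all flanks genic: placement is infeasible
  dense <- dplyr::bind_rows(
    ann("g1.1", "c", 0, 5000, "+", gene_id = "g1"),
    ann("g2.1", "c", 5000, 10000, "+", gene_id = "g2")
  )
  expect_error(sample_matched_set(intervals("c", 100, 400), dense, c(c = 10000L), seed = 1),
               "could not place")
})

test_that("null distributions and normal statistics behave as specified", {
  genes <- dplyr::bind_rows(lapply(1:8, function(i) {
    ann(sprintf("g%d.1", i), "c", i * 3000, i * 3000 + 800, "+", gene_id = sprintf("g%d", i))
  }))
  obs <- intervals("c", c(2000L, 7000L), c(2300L, 7400L))
  nd <- null_distribution(function(iv) sum(iv$end - iv$start), obs, genes,
                          c(c = 40000L), n_replicates = 20, seed = 2)
  expect_equal(nd$sd, 0)      # lengths are matched, total bp is constant
  expect_equal(nd$mean, 700)

  p <- normal_empirical_p(10, 20, 5, "lower")
  expect_equal(p$p, pnorm(-2), tolerance = 1e-12)
  expect_equal(p$p, 0.02275, tolerance = 1e-3)
  expect_equal(normal_empirical_p(20, 20, 5, "lower")$p, 0.5)
  expect_equal(normal_empirical_p(20, 20, 5, "upper")$p, 0.5)
  d <- normal_empirical_p(5, 20, 0, "lower")
  expect_equal(d$p, 0)
  expect_true(d$degenerate)
})

test_that("empirical p-values are roughly uniform for a random feature", {
  set.seed(31)
  genes <- dplyr::bind_rows(lapply(1:10, function(i) {
    ann(sprintf("g%d.1", i), "c", i * 4000, i * 4000 + 1000, "+", gene_id = sprintf("g%d", i))
  }))
  glen <- 48000L
  obs <- intervals("c", c(3000L, 11500L, 22000L), c(3400L, 11900L, 22500L))
  ps <- vapply(1:60, function(trial) {
    feat_start <- as.integer(sample.int(glen - 500L, 25L))
    feat <- intervals("c", feat_start, feat_start + 400L)
    stat <- function(iv) count_feature_overlap(iv, feat, "features")
    nd <- null_distribution(stat, obs, genes, c(c = glen), n_replicates = 40,
                            seed = trial)
    if (nd$sd == 0) return(NA_real_)
    normal_empirical_p(stat(obs), nd$mean, nd$sd, "upper")$p
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})
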