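test_that("hypergeometric tails are exact", {
  expect_equal(hypergeom_p(10, 5, 5, 5, "enrichment"), 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(hypergeom_p(10, 5, 5, 5, "enrichment"), 0.003968, tolerance = 1e-3)
  expect_error(hypergeom_p(10, 11, 5, 5), "K <= N")
  expect_error(hypergeom_p(10, 5, 5, 6), "min")
  # enrichment + depletion double-counts exactly P(X = k)
  set.seed(21)
  for (i in 1:50) {
    N <- sample(5:200, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    lo <- max(0, n - (N - K)); hi <- min(K, n)
    k <- sample(lo:hi, 1)
    expect_equal(hypergeom_p(N, K, n, k, "enrichment") + hypergeom_p(N, K, n, k, "depletion"),
                 1 + dhyper(k, K, N - K, n), tolerance = 1e-10)
  }
})

test_that("hypergeometric equals sequential-sampling enumeration on small populations", {
  set.seed(22)
  for (i in 1:40) {
    N <- sample(2:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    lo <- max(0, n - (N - K)); hi <- min(K, n)
    k <- sample(lo:hi, 1)
    expect_equal(hypergeom_p(N, K, n, k, "enrichment"), hyper_oracle(N, K, n, k, "enrichment"),
                 tolerance = 1e-10)
    expect_equal(hypergeom_p(N, K, n, k, "depletion"), hyper_oracle(N, K, n, k, "depletion"),
                 tolerance = 1e-10)
  }
})

test_that("association tests cross-tabulate flags and are symmetric", {
  d <- tibble::tibble(a = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                      b = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  r <- association_test(d, a, b)
  expect_equal(unlist(r[c("N", "K", "n", "k")]), c(N = 5L, K = 3L, n = 3L, k = 2L))
  r2 <- association_test(d, b, a)
  expect_equal(r$p_enrichment, r2$p_enrichment)
  expect_equal(c(r2$K, r2$n), c(r$n, r$K))
  # identical flags hit the single-term minimum
  d2 <- tibble::tibble(a = c(TRUE, TRUE, FALSE), b = c(TRUE, TRUE, FALSE))
  r3 <- association_test(d2, a, b)
  expect_equal(r3$p_enrichment, 1 / choose(3, 2))
  # NA rows drop out of the universe
  d3 <- tibble::tibble(a = c(TRUE, NA, FALSE), b = c(TRUE, TRUE, FALSE))
  expect_equal(association_test(d3, a, b)$N, 2L)
})

test_that("association p-values are near-uniform for independent flags", {
  set.seed(23)
  ps <- vapply(1:200, function(i) {
    d <- tibble::tibble(a = runif(2000) < 0.3, b = runif(2000) < 0.3)
    association_test(d, a, b)$p_enrichment
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("siRNA mapping flags unique forward matches and compartments", {
  set.seed(24)
  natseq <- random_dna_str(400)
  mrna <- random_dna_str(600)
  refs <- tibble::tibble(ref_id = c("nat1", "m1"), seq = c(natseq, mrna),
                         kind = c("nat", "mrna"), locus_id = c("L1", "L1"))
  regions <- tibble::tibble(ref_id = "nat1", start = 0L, end = 150L, part = "nolp")
  r_nolp <- substr(natseq, 50, 70)    # 21 nt inside the NOLP region
  r_olp <- substr(natseq, 300, 321)   # 22 nt in the OLP part
  r_multi <- substr(natseq, 10, 30)
  refs2 <- dplyr::bind_rows(refs, tibble::tibble(ref_id = "nat2",
                                                 seq = paste0(random_dna_str(50), r_multi, random_dna_str(50)),
                                                 kind = "nat", locus_id = "L2"))
  m <- map_sirnas(tibble::tibble(read_id = c("a", "b", "c"),
                                 seq = c(r_nolp, r_olp, r_multi)), refs2, regions)
  expect_equal(m$compartment[m$read_id == "a"], "nolp")
  expect_equal(m$compartment[m$read_id == "b"], "olp")
  expect_false(m$unique[m$read_id == "c"])   # two forward matches
  expect_error(map_sirnas(tibble::tibble(read_id = "x", seq = "ACGT"), refs),
               "18-30")
  expect_warning(map_sirnas(tibble::tibble(read_id = c("x", "a"),
                                           seq = c(strrep("X", 21), r_nolp)), refs2, regions),
                 "skipping")
})

test_that("siRNA mappings agree with brute-force offset scanning", {
  set.seed(25)
  refs <- tibble::tibble(ref_id = c("r1", "r2"),
                         seq = c(random_dna_str(3000), random_dna_str(2000)),
                         kind = c("nat", "mrna"), locus_id = c("L1", "L2"))
  ref_seqs <- setNames(refs$seq, refs$ref_id)
  reads <- tibble::tibble(read_id = sprintf("q%02d", 1:20),
                          seq = vapply(1:20, function(i) {
                            src <- sample(refs$seq, 1)
                            at <- sample.int(nchar(src) - 21, 1)
                            s <- substr(src, at, at + 20)
                            if (i %% 3 == 0) cisnat:::revcomp(s) else s
                          }, ""))
  m <- map_sirnas(reads, refs)
  for (i in seq_len(nrow(m))) {
    o <- scan_oracle(m$seq[i], ref_seqs)
    expect_equal(m$n_fwd[i], sum(o$ori == "fwd"))
    expect_equal(m$n_rev[i], sum(o$ori == "rev"))
    if (m$unique[i]) {
      expect_equal(m$pos[i], o$pos[o$ori == "fwd"])
      expect_equal(m$ref_id[i], o$ref[o$ori == "fwd"])
    }
  }
})

test_that("cis/trans labels follow the reverse-match rule with own-locus exclusion", {
  set.seed(26)
  natseq <- random_dna_str(300)
  core <- substr(natseq, 100, 120)
  distal <- paste0(random_dna_str(40), cisnat:::revcomp(core), random_dna_str(40))
  refs <- tibble::tibble(
    ref_id = c("nat1", "own_mrna", "distal_mrna"),
    seq = c(natseq, paste0(random_dna_str(30), cisnat:::revcomp(substr(natseq, 200, 230)), random_dna_str(30)), distal),
    kind = c("nat", "mrna", "mrna"),
    locus_id = c("L1", "L1", "L9"))
  m <- classify_sirna(map_sirnas(
    tibble::tibble(read_id = c("trans1", "cis1", "cisown"),
                   seq = c(core, substr(natseq, 150, 172), substr(natseq, 200, 222))),
    refs))
  expect_equal(m$acting[m$read_id == "trans1"], "trans")
  expect_equal(m$acting[m$read_id == "cis1"], "cis")
  expect_equal(m$acting[m$read_id == "cisown"], "cis")  # reverse hit only at own locus
})

test_that("feature overlap counts peaks once and sums covered bp", {
  nolps <- intervals("c", c(100L, 500L), c(300L, 700L))
  peak_spanning <- intervals("c", 250L, 550L)
  expect_equal(count_feature_overlap(nolps, peak_spanning, "features"), 1L)
  expect_equal(count_feature_overlap(nolps, intervals("c", 900L, 950L), "features"), 0L)
  expect_equal(count_feature_overlap(nolps, nolps, "bp"), 400L)
  expect_equal(count_feature_overlap(nolps, peak_spanning, "bp"), 100L)
})
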