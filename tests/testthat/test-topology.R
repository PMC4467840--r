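test_that("topology types follow the geometric definitions and precedence", {
  gene <- example_gene()
  # fully inside the antisense gene span
  expect_equal(classify_topology(nat1(1600, 2000), gene)$type, 3L)
  # gene span fully inside the NAT span
  expect_equal(classify_topology(nat1(1000, 3500), gene)$type, 4L)
  # partial overlap at the gene's 5' end (minus-strand gene: right end): divergent
  expect_equal(classify_topology(nat1(2500, 3500), gene)$type, 1L)
  # partial overlap at the 3' ends: convergent
  expect_equal(classify_topology(nat1(1000, 2000), gene)$type, 2L)
  # two antisense genes win over containment (precedence 5 first)
  genes2 <- dplyr::bind_rows(gene, ann("g2.1", "chr1", 3300, 4200, "-", gene_id = "g2"))
  r5 <- classify_topology(nat1(2500, 3500), genes2)
  expect_equal(r5$type, 5L)
  expect_equal(sort(r5$antisense_gene_ids[[1]]), c("g1", "g2"))
})

test_that("NATs without an opposite-strand partner are flagged, not typed", {
  gene_same <- ann("g1.1", "chr1", 1500, 3000, "+", gene_id = "g1")
  r <- classify_topology(nat1(1600, 2000, strand = "+"), gene_same)
  expect_equal(r$status, "no_antisense_partner")
  expect_true(is.na(r$type))
})

test_that("classification is invariant under relabeling which strand is plus", {
  # relabeling the strands reflects the coordinate axis and swaps labels
  gene <- example_gene()
  L <- 5000L
  mirror <- function(x) dplyr::mutate(x, s2 = L - end, end = L - start, start = s2,
                                      strand = ifelse(strand == "+", "-", "+"),
                                      s2 = NULL)
  for (iv in list(c(1600, 2000), c(1000, 3500), c(2500, 3500), c(1000, 2000))) {
    a <- classify_topology(nat1(iv[1], iv[2]), gene)$type
    b <- classify_topology(mirror(nat1(iv[1], iv[2])), mirror(gene))$type
    expect_equal(a, b)
  }
})

test_that("NOLP extraction subtracts exons (or spans) from the NAT footprint", {
  gene <- example_gene()
  parts <- extract_nolps(nat1(1000, 3500), gene)
  nolp <- parts[parts$part == "nolp", ]
  expect_equal(nolp[, c("start", "end")],
               tibble::tibble(start = c(1000L, 3000L), end = c(1500L, 3500L)))
  olp <- parts[parts$part == "olp", ]
  expect_equal(olp$start, 1500L)
  expect_equal(olp$end, 3000L)

  # type 3: no NOLP, footprint is all OLP
  p3 <- extract_nolps(nat1(1600, 2000), gene)
  expect_equal(sum(p3$part == "nolp"), 0)
  expect_equal(p3$start[p3$part == "olp"], 1600L)

  # intron handling differs between modes
  gi <- example_gene(exons = list(c(1500, 2000), c(2500, 3000)))
  pe <- extract_nolps(nat1(1600, 2900), gi, mode = "exon")
  expect_equal(pe[pe$part == "nolp", c("start", "end")],
               tibble::tibble(start = 2000L, end = 2500L))
  ps <- extract_nolps(nat1(1600, 2900), gi, mode = "transcript_span")
  expect_equal(sum(ps$part == "nolp"), 0)
})

test_that("NR-set construction is greedy by length with deterministic ties", {
  nolps <- tibble::tibble(
    nat_id = c("A", "B", "C"), chrom = "c",
    start = c(0L, 50L, 200L), end = c(100L, 130L, 260L), strand = "+"
  )
  expect_equal(build_nr_set(nolps)$nat_id, c("A", "C"))
  # disjoint inputs are all kept
  dis <- tibble::tibble(nat_id = c("A", "B"), chrom = "c",
                        start = c(0L, 500L), end = c(100L, 700L), strand = "+")
  expect_equal(nrow(build_nr_set(dis)), 2)
  # equal-length overlapping pair: lexicographically smaller id wins
  tie <- tibble::tibble(nat_id = c("b", "a"), chrom = "c",
                        start = c(0L, 50L), end = c(100L, 150L), strand = c("+", "-"))
  expect_equal(build_nr_set(tie)$nat_id, "a")
})

test_that("NR output is non-overlapping and idempotent", {
  set.seed(9)
  nolps <- tibble::tibble(
    nat_id = sprintf("n%02d", 1:40), chrom = "c",
    start = as.integer(sample.int(5000, 40)), strand = "+"
  )
  nolps$end <- nolps$start + as.integer(sample.int(400, 40)) + 10L
  kept <- build_nr_set(nolps)
  kept_iv <- nolps[nolps$nat_id %in% kept$nat_id, ]
  for (i in seq_len(nrow(kept_iv))) {
    others <- kept_iv[kept_iv$nat_id != kept_iv$nat_id[i], ]
    expect_true(all(overlap_bp(kept_iv[i, ], others) == 0))
  }
  again <- build_nr_set(kept_iv)
  expect_equal(again$nat_id, kept$nat_id)
})

test_that("cross-validation requires same-strand overlap", {
  tair <- nat1(1000, 1400, "+", id = "t1")
  same <- nat1(1000, 1400, "+", id = "m1")
  opp <- nat1(1000, 1400, "-", id = "m2")
  far <- nat1(9000, 9400, "+", id = "m3")
  expect_true(crossvalidate_nats(tair, same)$validated_by_other_sets)
  expect_false(crossvalidate_nats(tair, opp)$validated_by_other_sets)
  expect_false(crossvalidate_nats(tair, far)$validated_by_other_sets)
})
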