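test_that("local alignment matches direct expectations", {
  sc <- nt_scoring(match = 1, mismatch = -1, gap_open = 0.5, gap_extend = 0.5)
  r <- smith_waterman("ACGT", "ACGT", sc)
  expect_equal(r$score, 4)
  expect_equal(r$identity, 1)
  expect_equal(smith_waterman("AAAA", "TTTT", sc)$score, 0)
  expect_error(smith_waterman("", "ACGT", sc), "empty")
  # symmetry in score
  set.seed(11)
  for (i in 1:10) {
    a <- random_dna_str(sample(5:15, 1)); b <- random_dna_str(sample(5:15, 1))
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("alignment scores equal an independent full-matrix recurrence", {
  set.seed(12)
  for (i in 1:40) {
    a <- random_dna_str(sample(3:20, 1))
    b <- random_dna_str(sample(3:20, 1))
    expect_equal(smith_waterman(a, b)$score, sw_oracle_score(a, b))
  }
})

test_that("e-values follow the Karlin-Altschul formula", {
  sc <- nt_scoring(K = 0.1, lambda = 1.0)
  expect_equal(e_value(30, 100, 100, sc), 0.1 * 1e4 * exp(-30), tolerance = 1e-12)
  expect_equal(e_value(30, 100, 100, sc), 9.36e-11, tolerance = 1e-2)
  s <- seq(10, 60, by = 10)
  expect_true(all(diff(e_value(s, 100, 100, sc)) < 0))
  expect_equal(e_value(30, 100, 200, sc), 2 * e_value(30, 100, 100, sc))
})

test_that("ORF finding walks codons with N-aware matching", {
  o <- find_orfs("ATGAAATAA", strands = "+")
  expect_equal(nrow(o), 1)
  expect_equal(o$length_codons, 2L)
  expect_equal(nrow(find_orfs("CCCAAACCCTAA", strands = "+")), 0)
  long <- paste0("ATG", strrep("GCT", 100), "TAA")
  expect_equal(nchar(long), 306)
  expect_equal(find_orfs(long, strands = "+")$length_codons, 101L)
  # N breaks both start and stop codons
  expect_equal(nrow(find_orfs("ATNAAATAA", strands = "+")), 0)
  # reverse strand coordinates map back to the input sequence
  rc <- cisnat:::revcomp("ATGAAATAA")
  om <- find_orfs(rc, strands = "-")
  expect_equal(om$length_codons, 2L)
  expect_equal(c(om$start, om$end), c(0L, 9L))
})

test_that("seed-chain-extend recovers verbatim, reverse and mutated implants", {
  set.seed(13)
  genome <- c(chr1 = random_dna_str(20000))
  q <- substr(genome[[1]], 5001, 5400)
  h <- seed_chain_extend_map(q, genome)
  expect_equal(h$start[1], 5000L)
  expect_equal(h$end[1], 5400L)
  expect_equal(h$strand[1], "+")
  expect_equal(h$identity[1], 1)
  hr <- seed_chain_extend_map(cisnat:::revcomp(q), genome)
  expect_equal(hr$start[1], 5000L)
  expect_equal(hr$strand[1], "-")

  # 5% substitutions; the best locus must match a whole-genome alignment oracle
  qm <- strsplit(q, "")[[1]]
  idx <- sample(seq_along(qm), 20)
  qm[idx] <- vapply(qm[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  qm <- paste(qm, collapse = "")
  hm <- seed_chain_extend_map(qm, genome)
  oracle <- smith_waterman(qm, genome[[1]])
  expect_equal(hm$start[1], oracle$b_start)
  expect_equal(hm$end[1], oracle$b_end)
  expect_gte(hm$identity[1], 0.90)
})

test_that("bidirectional best hits: identity maps, ties excluded, symmetric", {
  prots <- tibble::tibble(id = c("p1", "p2", "p3"),
                          seq = c("MKLVINSGHW", "MTTYHHQQAD", "MGGCCWWLLV"))
  bd <- bdbh_orthologs(prots, prots)
  expect_equal(bd$id_a, bd$id_b)
  expect_equal(nrow(bd), 3)
  # duplicate sequence in B ties and removes the pair
  dup <- dplyr::bind_rows(prots, tibble::tibble(id = "p1b", seq = prots$seq[1]))
  bd2 <- bdbh_orthologs(prots, dup)
  expect_false("p1" %in% bd2$id_a)
  # symmetry under role swap
  set.seed(14)
  a <- tibble::tibble(id = paste0("a", 1:4),
                      seq = vapply(1:4, function(i) paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 30, TRUE), collapse = ""), ""))
  b <- dplyr::mutate(a, id = paste0("b", 1:4),
                     seq = vapply(seq, function(s) { x <- strsplit(s, "")[[1]]; x[5] <- "G"; paste(x, collapse = "") }, ""))
  ab <- bdbh_orthologs(a, b)
  ba <- bdbh_orthologs(b, a)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$id_a, ab$id_b), paste(ba$id_b, ba$id_a))
})

test_that("pairwise conservation calls use the e-value threshold", {
  set.seed(15)
  flank <- random_dna_str(5000)
  q <- substr(flank, 2001, 2080)  # 80 nt identical
  r <- pairwise_conservation_call(q, flank)
  expect_true(r$conserved)
  expect_lt(r$e_value, 1e-10)
  r2 <- pairwise_conservation_call(random_dna_str(200), random_dna_str(5000))
  expect_false(r2$conserved)
  r3 <- pairwise_conservation_call(q, "")
  expect_false(r3$conserved)
  expect_equal(r3$reason, "no_flank")
})

test_that("protein-homology coverage maps hits back to nucleotides", {
  set.seed(16)
  prot <- paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 60, TRUE), collapse = "")
  # encode the 60-residue segment in frame 0 of the query
  codon_of <- function(aa) names(Biostrings::GENETIC_CODE)[match(aa, Biostrings::GENETIC_CODE)]
  nt <- paste(vapply(strsplit(prot, "")[[1]], codon_of, ""), collapse = "")
  query <- paste0(random_dna_str(30), nt, random_dna_str(30))
  cov <- protein_homology_coverage(query, tibble::tibble(id = "p", seq = prot))
  expect_gte(cov, 180L)
  expect_equal(protein_homology_coverage(random_dna_str(200),
                                         tibble::tibble(id = "p", seq = prot)), 0L)
  expect_equal(protein_homology_coverage(query, character()), 0L)
})

test_that("expression-conservation calls apply the evidence and coding rules", {
  set.seed(17)
  world <- generate_world(small_world_config(q_expression = 1), seed = 21)
  id <- world$truth$nat_id[1]
  nat_seq <- cisnat:::transcript_seq(world$genome, world$nats, id)
  ok <- call_expression_conservation(nat_seq, world$sister$genome,
                                     world$sister$evidence, world$proteome)
  expect_true(ok$expression_conserved)
  # no evidence track at all
  none <- call_expression_conservation(nat_seq, world$sister$genome,
                                       world$sister$evidence[0, ], world$proteome)
  expect_false(none$expression_conserved)
  expect_equal(none$reason, "no_evidence")
  # a long ORF in the evidence region disqualifies it (rule ii)
  ev <- world$sister$evidence[world$sister$evidence$id == paste0(id, "_ev"), ]
  g <- world$sister$genome
  orf <- paste0("ATG", strrep("GCA", 120), "TAA")
  s <- g[[ev$chrom]]
  at <- if (ev$strand == "+") ev$start else ev$end - nchar(orf)
  body <- if (ev$strand == "+") orf else cisnat:::revcomp(orf)
  substr(s, at + 1, at + nchar(orf)) <- body
  g[[ev$chrom]] <- s
  bad <- call_expression_conservation(nat_seq, g, ev, world$proteome)
  expect_false(bad$expression_conserved)
})
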