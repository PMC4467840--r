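test_that("generators are pure functions of config and seed", {
  cfg <- small_world_config()
  w1 <- generate_world(cfg, seed = 42)
  w2 <- generate_world(cfg, seed = 42)
  expect_identical(w1$genome, w2$genome)
  expect_identical(w1$truth, w2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_world(w1, d1); write_world(w2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)), label = f)
  }
  w3 <- generate_world(cfg, seed = 43)
  expect_false(identical(w1$genome, w3$genome))
})

test_that("the classifier recovers every generated topology type", {
  w <- generate_world(small_world_config(), seed = 7)
  topo <- classify_topology(w$nats, w$genes)
  cmp <- dplyr::left_join(topo, dplyr::select(w$truth, nat_id, true = type), by = "nat_id")
  expect_equal(cmp$type, cmp$true)
  expect_setequal(unique(cmp$type), 1:5)
})

test_that("zero scale freezes every species at the root state", {
  cfg <- small_world_config()
  set.seed(1)
  cols <- cisnat:::sim_tree_columns(cfg$model, 200, 0)
  expect_true(all(apply(cols, 2, function(x) length(unique(x)) == 1)))
})

test_that("two-leaf simulation matches the analytic substitution probability", {
  m <- two_leaf_model(0.15, 0.15)
  set.seed(2)
  cols <- cisnat:::sim_tree_columns(m, 10000, 1)
  p_obs <- mean(cols["A", ] != cols["B", ])
  P <- transition_matrix(m, 0.3)
  p_true <- sum(m$pi * (1 - diag(P)))
  expect_lt(abs(p_obs - p_true), 3 * sqrt(p_true * (1 - p_true) / 10000))
})

test_that("long simulations preserve the equilibrium base composition", {
  m <- default_neutral_model()
  set.seed(3)
  cols <- cisnat:::sim_tree_columns(m, 8000, 1)
  freq <- table(factor(cols, levels = c("A", "C", "G", "T"))) / length(cols)
  expect_true(all(abs(as.numeric(freq) - as.numeric(m$pi)) < 0.01))
})

test_that("simulated alignment blocks agree with the patched focal genome", {
  w <- generate_world(small_world_config(), seed = 7)
  for (b in w$maf$blocks[1:3]) {
    ref_row <- b$rows[[w$config$focal_species]]
    expect_equal(ref_row, cisnat:::subseq0(w$genome[[b$ref$chrom]], b$ref$start, b$ref$end))
  }
})

test_that("zero expression retention gives no sister evidence", {
  w <- generate_world(small_world_config(q_expression = 0), seed = 9)
  expect_equal(nrow(w$sister$evidence), 0)
  expect_false(any(w$truth$expression_retained))
})

test_that("siRNA compartment draws reproduce the configured OLP:NOLP ratio", {
  w <- generate_world(small_world_config(n_sirna = 600L, sirna_background = 0), seed = 13)
  tab <- table(w$sirna$truth$compartment)
  n <- sum(tab)
  p_hat <- tab[["olp"]] / n
  ci <- 2.58 * sqrt(0.9 * 0.1 / n)
  expect_lt(abs(p_hat - 0.9), ci + 0.02)
})

test_that("transposons avoid conserved NOLPs", {
  w <- generate_world(small_world_config(n_nats = 15L, n_transposons = 60L,
                                         conserved_fraction = 0.5,
                                         te_conserved_weight = 0), seed = 15)
  cons <- w$nolp_truth[w$nolp_truth$nat_id %in% w$truth$nat_id[w$truth$conserved %in% TRUE], ]
  if (nrow(cons) && nrow(w$transposons)) {
    for (i in seq_len(nrow(w$transposons))) {
      expect_equal(sum(overlap_bp(w$transposons[rep(i, nrow(cons)), ], cons)), 0L)
    }
  }
})
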