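# Shared fixtures: tiny annotations, models, and small synthetic worlds.

ann <- function(transcript_id, chrom, start, end, strand,
                gene_id = transcript_id, biotype = "protein_coding") {
  tibble::tibble(transcript_id = transcript_id, gene_id = gene_id, biotype = biotype,
                 chrom = chrom, start = as.integer(start), end = as.integer(end),
                 strand = strand)
}

# The worked gene of the topology examples: protein-coding, minus strand,
# span [1500, 3000).
example_gene <- function(exons = list(c(1500, 3000))) {
  dplyr::bind_rows(lapply(exons, function(e) {
    ann("g1.1", "chr1", e[1], e[2], "-", gene_id = "g1")
  }))
}

nat1 <- function(start, end, strand = "+", id = "natA") {
  ann(id, "chr1", start, end, strand, biotype = "nat")
}

two_leaf_model <- function(t1 = 0.1, t2 = 0.2, pi = c(0.3, 0.2, 0.2, 0.3)) {
  neutral_model(sprintf("(A:%g,B:%g);", t1, t2), base_freqs = pi)
}

small_world_config <- function(...) {
  args <- utils::modifyList(
    list(n_nats = 10L, gene_cds_codons = c(100L, 160L),
         n_background_genes = 5L, n_sirna = 150L),
    list(...))
  do.call(synth_config, args)
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                    collapse = "")
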