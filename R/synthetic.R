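# Synthetic-data generator: builds a complete in-memory "world" (focal
# genome, gene/NAT annotation with known topologies, multi-species
# alignment blocks simulated under the neutral model with per-locus scales,
# siRNA reads, peak and transposon tracks, and an evolved sister genome
# with transcript evidence and proteome) so every pipeline stage can be
# exercised against known ground truth.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a compact Brassicaceae-like study: five topology types
#' in equal proportions, 30% of NOLP loci conserved at scale 0.3, siRNA
#' production favouring gene-overlapping NAT parts 9:1, promoter-enriched
#' peaks, transposons depleted in conserved NOLPs, a sister genome at 0.10
#' substitutions/site with antisense-expression retention probability 0.3.
#'
#' @param n_nats Number of cis-NATs.
#' @param topology_props Proportions of types 1-5 (sum to 1).
#' @param n_background_genes Extra NAT-free genes (anchors for the
#'   resampling null).
#' @param gene_cds_codons Range of gene CDS lengths in codons.
#' @param gene_two_exon_prob Probability a gene carries one intron.
#' @param intron_len,intergenic Length ranges (bp).
#' @param conserved_fraction Fraction of (non-type-3) NATs whose NOLPs are
#'   conserved.
#' @param conserved_scale Branch-length scale of conserved loci.
#' @param model Neutral model used for simulation.
#' @param focal_species Reference species name (a tree leaf).
#' @param n_sirna,sirna_olp_weight,sirna_nolp_weight,sirna_background
#'   siRNA read count, OLP:NOLP production weights, and background read
#'   fraction.
#' @param n_peaks,peak_width,peak_promoter_window,peak_enrichment Peak
#'   track parameters; enrichment 1 means uniform placement.
#' @param n_transposons,te_width,te_conserved_weight Transposon track
#'   parameters; placements overlapping conserved NOLPs are accepted with
#'   probability `te_conserved_weight`.
#' @param sister_divergence Sister-genome divergence (subst/site);
#'   gene exons evolve at 0.3x this rate.
#' @param q_expression Antisense-expression retention probability (used
#'   when `couple_expression = FALSE`).
#' @param couple_expression Couple expression retention to the conservation
#'   label, using `q_expression_conserved` / `q_expression_unconserved`.
#' @param q_expression_conserved,q_expression_unconserved Retention
#'   probabilities under coupling.
#' @param dataset Data set tag attached to the NATs.
#' @param chrom_name Chromosome name.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_nats = 25L,
                         topology_props = c(0.2, 0.2, 0.2, 0.2, 0.2),
                         n_background_genes = 10L,
                         gene_cds_codons = c(250L, 500L),
                         gene_two_exon_prob = 0.25,
                         intron_len = c(90L, 300L),
                         intergenic = c(800L, 2000L),
                         conserved_fraction = 0.3,
                         conserved_scale = 0.3,
                         model = default_neutral_model(),
                         focal_species = "Athaliana",
                         n_sirna = 300L,
                         sirna_olp_weight = 9,
                         sirna_nolp_weight = 1,
                         sirna_background = 0.1,
                         n_peaks = 60L,
                         peak_width = 150L,
                         peak_promoter_window = 500L,
                         peak_enrichment = 4,
                         n_transposons = 25L,
                         te_width = c(200L, 600L),
                         te_conserved_weight = 0.2,
                         sister_divergence = 0.10,
                         q_expression = 0.3,
                         couple_expression = FALSE,
                         q_expression_conserved = 0.7,
                         q_expression_unconserved = 0.13,
                         dataset = "SYNTH",
                         chrom_name = "chr1") {
  stopifnot(length(topology_props) == 5, abs(sum(topology_props) - 1) < 1e-8,
            all(topology_props >= 0), n_nats >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

rand_in <- function(r) if (length(r) == 2) sample(seq.int(r[1], r[2]), 1L) else as.integer(r)

SENSE_CODONS <- {
  all3 <- as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

gen_orf_seq <- function(n_codons) {
  paste0("ATG", paste(sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# Lay out one NAT module in local coordinates; returns exon tibbles for its
# gene(s) and NAT plus the module width. Margin 500 bp on each side.
layout_module <- function(type, cfg, idx) {
  M <- 500L
  gs <- sample(c("+", "-"), 1L)
  ns <- if (gs == "+") "-" else "+"
  mk_gene <- function(gid, at) {
    cds <- 3L * rand_in(cfg$gene_cds_codons)
    has_intron <- runif(1) < cfg$gene_two_exon_prob
    if (has_intron) {
      il <- rand_in(cfg$intron_len)
      e1 <- 3L * sample(seq.int(30L, cds %/% 3L - 30L), 1L)
      ex <- tibble(start = c(at, at + e1 + il), end = c(at + e1, at + cds + il))
    } else {
      ex <- tibble(start = at, end = at + cds)
    }
    list(exons = ex %>% mutate(gene_id = gid), cds = cds, span = c(at, max(ex$end)))
  }
  g <- mk_gene(sprintf("G%03d", idx), M)
  g0 <- g$span[1]; g1 <- g$span[2]; gl <- g1 - g0
  out <- rand_in(c(150L, 400L))
  inl <- rand_in(c(120L, min(500L, gl - 120L)))
  nat <- switch(as.character(type),
    "1" = if (gs == "+") c(g0 - out, g0 + inl) else c(g1 - inl, g1 + out),
    "2" = if (gs == "+") c(g1 - inl, g1 + out) else c(g0 - out, g0 + inl),
    "3" = {
      m <- 60L
      len <- min(rand_in(c(200L, 450L)), gl - 2L * m)
      at <- g0 + m + sample.int(gl - 2L * m - len + 1L, 1L) - 1L
      c(at, at + len)
    },
    "4" = c(g0 - rand_in(c(150L, 400L)), g1 + rand_in(c(150L, 400L))),
    "5" = NULL
  )
  genes <- list(g)
  if (type == 5L) {
    gap2 <- rand_in(c(140L, 260L))
    g2 <- mk_gene(sprintf("G%03db", idx), g1 + gap2)
    genes <- list(g, g2)
    in1 <- rand_in(c(100L, min(300L, gl - 60L)))
    in2 <- rand_in(c(100L, min(300L, (g2$span[2] - g2$span[1]) - 60L)))
    nat <- c(g1 - in1, g1 + gap2 + in2)
  }
  width <- max(vapply(genes, function(x) x$span[2], numeric(1)), nat[2]) + M
  list(genes = genes, gene_strand = gs, nat = nat, nat_strand = ns, width = as.integer(width))
}

#' Generate the synthetic genome and annotation
#'
#' Places one locus module per NAT (host gene(s) plus a NAT realising the
#' requested topology exactly) along a single chromosome, followed by
#' NAT-free background genes; gene exons are filled with valid ORFs
#' (ATG...stop, no internal stops).
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @return List with `genome` (named character), `annotation` (exon tibble
#'   of genes and NATs), `truth` (per-NAT tibble: `nat_id`, `dataset`,
#'   `type`, `gene_ids`, coordinates) and `nolp_truth` (interval tibble of
#'   true NOLPs per NAT).
#' @export
generate_annotation <- function(cfg, seed = 1L) {
  with_seed(seed, {
    types <- if (cfg$n_nats > 0) {
      base <- rep(1:5, times = floor(cfg$topology_props * cfg$n_nats))
      extra <- cfg$n_nats - length(base)
      if (extra > 0) base <- c(base, sample(1:5, extra, replace = TRUE, prob = cfg$topology_props))
      sample(base)
    } else integer()
    cursor <- 0L
    gene_rows <- list(); nat_rows <- list(); truth <- list()
    for (i in seq_along(types)) {
      mod <- layout_module(types[i], cfg, i)
      for (g in mod$genes) {
        gene_rows[[length(gene_rows) + 1]] <- g$exons %>%
          mutate(start = .data$start + cursor, end = .data$end + cursor,
                 strand = mod$gene_strand)
      }
      nat_id <- sprintf("NAT%03d", i)
      nat_rows[[length(nat_rows) + 1]] <- tibble(
        transcript_id = nat_id, gene_id = nat_id, biotype = "nat",
        chrom = cfg$chrom_name, start = mod$nat[1] + cursor, end = mod$nat[2] + cursor,
        strand = mod$nat_strand)
      truth[[length(truth) + 1]] <- tibble(
        nat_id = nat_id, dataset = cfg$dataset, type = types[i],
        gene_ids = list(vapply(mod$genes, function(g) g$exons$gene_id[1], "")),
        chrom = cfg$chrom_name, start = mod$nat[1] + cursor, end = mod$nat[2] + cursor,
        strand = mod$nat_strand)
      cursor <- cursor + mod$width + rand_in(cfg$intergenic)
    }
    for (b in seq_len(cfg$n_background_genes)) {
      cds <- 3L * rand_in(cfg$gene_cds_codons)
      gene_rows[[length(gene_rows) + 1]] <- tibble(
        start = cursor + 500L, end = cursor + 500L + cds,
        gene_id = sprintf("BG%03d", b), strand = sample(c("+", "-"), 1L))
      cursor <- cursor + 1000L + cds + rand_in(cfg$intergenic)
    }
    genes <- bind_rows(gene_rows) %>%
      mutate(transcript_id = paste0(.data$gene_id, ".1"), biotype = "protein_coding",
             chrom = cfg$chrom_name) %>%
      select("transcript_id", "gene_id", "biotype", "chrom", "start", "end", "strand")
    nats <- bind_rows(nat_rows)
    glen <- cursor + 1000L
    genome_chars <- sample(DNA_BASES, glen, replace = TRUE, prob = cfg$model$pi)
    # fill gene exons with clean ORFs (strand-aware)
    for (gid in unique(genes$gene_id)) {
      ex <- genes %>% filter(.data$gene_id == gid) %>% arrange(.data$start)
      cds_len <- sum(ex$end - ex$start)
      orf <- gen_orf_seq(cds_len %/% 3L)
      gseq <- if (ex$strand[1] == "+") orf else revcomp(orf)
      chars <- strsplit(gseq, "")[[1]]
      off <- 0L
      for (j in seq_len(nrow(ex))) {
        w <- ex$end[j] - ex$start[j]
        genome_chars[(ex$start[j] + 1L):ex$end[j]] <- chars[(off + 1L):(off + w)]
        off <- off + w
      }
    }
    genome <- setNames(paste(genome_chars, collapse = ""), cfg$chrom_name)
    truth <- bind_rows(truth)
    nolp_truth <- if (nrow(truth)) purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      blockers <- genes %>% filter(.data$start < tr$end + 5000L, .data$end > tr$start - 5000L)
      nn <- interval_subtract(intervals(tr$chrom, tr$start, tr$end, tr$strand),
                              blockers %>% select("chrom", "start", "end", "strand"))
      if (nrow(nn)) nn %>% mutate(nat_id = tr$nat_id) %>%
        select("nat_id", "chrom", "start", "end", "strand") else tibble()
    }) else tibble(nat_id = character(), chrom = character(), start = integer(),
                   end = integer(), strand = character())
    list(genome = genome, annotation = bind_rows(genes, nats), genes = genes,
         nats = nats, truth = truth, nolp_truth = nolp_truth)
  })
}

# Simulate aligned columns under the tree: root from the equilibrium
# frequencies, children sampled through P(branch * scale).
sim_tree_columns <- function(model, n, scale) {
  tree <- ape::reorder.phylo(model$tree, "cladewise")
  ntip <- length(tree$tip.label)
  states <- matrix(NA_integer_, ntip + tree$Nnode, n)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, n, replace = TRUE, prob = model$pi)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    P <- transition_matrix(model, tree$edge.length[e] * scale)
    for (s in 1:4) {
      idx <- which(states[p, ] == s)
      if (length(idx)) states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
  }
  out <- matrix(DNA_BASES[states[seq_len(ntip), , drop = FALSE]], ntip, n,
                dimnames = list(tree$tip.label, NULL))
  out
}

#' Simulate a multi-species alignment for scored loci
#'
#' One MAF block per locus; each block's reference row replaces the focal
#' genome at the locus so that alignment and genome agree.
#'
#' @param cfg A [synth_config()].
#' @param loci Interval tibble with a `scale` column (branch-length
#'   multiplier per locus).
#' @param genome Named character vector (the focal genome to patch).
#' @param seed Integer seed.
#' @return List with the patched `genome` and the `maf` object.
#' @export
simulate_alignment <- function(cfg, loci, genome, seed = 1L) {
  with_seed(seed, {
    blocks <- list()
    src <- setNames(rep(nchar(genome[[1]]), length(cfg$model$tree$tip.label)),
                    cfg$model$tree$tip.label)
    for (i in seq_len(nrow(loci))) {
      n <- loci$end[i] - loci$start[i]
      cols <- sim_tree_columns(cfg$model, n, loci$scale[i])
      ord <- c(cfg$focal_species, setdiff(rownames(cols), cfg$focal_species))
      rows <- setNames(apply(cols[ord, , drop = FALSE], 1, paste, collapse = ""), ord)
      blocks[[length(blocks) + 1]] <- maf_block(loci$chrom[i], loci$start[i], loci$end[i],
                                                rows, src_sizes = src[ord])
      g <- genome[[loci$chrom[i]]]
      substr(g, loci$start[i] + 1L, loci$end[i]) <- rows[[cfg$focal_species]]
      genome[[loci$chrom[i]]] <- g
    }
    list(genome = genome, maf = new_maf(blocks))
  })
}

#' Generate siRNA reads from NAT compartments
#'
#' Reads of 21-24 nt are drawn from OLP vs NOLP NAT parts at the configured
#' weight ratio (intervals within a compartment chosen proportionally to
#' length), plus a background fraction from random genomic positions.
#'
#' @param cfg A [synth_config()].
#' @param world Output of [generate_annotation()] (with the patched
#'   genome).
#' @param seed Integer seed.
#' @return List with `reads` (tibble `read_id`, `seq`) and `truth` (tibble
#'   with the source compartment per read).
#' @export
generate_sirnas <- function(cfg, world, seed = 1L) {
  with_seed(seed, {
    nolps <- world$nolp_truth
    olps <- purrr::map_dfr(seq_len(nrow(world$truth)), function(i) {
      tr <- world$truth[i, ]
      nn <- nolps %>% filter(.data$nat_id == tr$nat_id)
      olp <- interval_subtract(intervals(tr$chrom, tr$start, tr$end, tr$strand),
                               nn %>% select("chrom", "start", "end", "strand"))
      if (nrow(olp)) olp %>% mutate(nat_id = tr$nat_id) %>%
        select("nat_id", "chrom", "start", "end", "strand") else tibble()
    })
    pools <- list(olp = olps, nolp = nolps)
    n_bg <- round(cfg$n_sirna * cfg$sirna_background)
    n_nat <- cfg$n_sirna - n_bg
    w <- c(olp = cfg$sirna_olp_weight, nolp = cfg$sirna_nolp_weight)
    reads <- list(); src <- list()
    draw_from <- function(iv_tbl, len) {
      ok <- iv_tbl %>% filter(.data$end - .data$start >= len)
      if (!nrow(ok)) return(NULL)
      r <- ok[sample.int(nrow(ok), 1L, prob = ok$end - ok$start), ]
      at <- r$start + sample.int(r$end - r$start - len + 1L, 1L) - 1L
      s <- subseq0(world$genome[[r$chrom]], at, at + len)
      if (r$strand == "-") s <- revcomp(s)
      list(seq = s, nat_id = if ("nat_id" %in% names(r)) r$nat_id else NA_character_)
    }
    for (i in seq_len(n_nat)) {
      comp <- sample(c("olp", "nolp"), 1L, prob = w)
      len <- sample(21:24, 1L)
      d <- draw_from(pools[[comp]], len)
      if (is.null(d)) next
      reads[[length(reads) + 1]] <- tibble(read_id = sprintf("r%04d", length(reads) + 1L), seq = d$seq)
      src[[length(src) + 1]] <- tibble(read_id = sprintf("r%04d", length(src) + 1L),
                                       compartment = comp, nat_id = d$nat_id)
    }
    glen <- nchar(world$genome[[1]])
    for (i in seq_len(n_bg)) {
      len <- sample(21:24, 1L)
      at <- sample.int(glen - len, 1L) - 1L
      reads[[length(reads) + 1]] <- tibble(read_id = sprintf("r%04d", length(reads) + 1L),
                                           seq = subseq0(world$genome[[1]], at, at + len))
      src[[length(src) + 1]] <- tibble(read_id = sprintf("r%04d", length(src) + 1L),
                                       compartment = "background", nat_id = NA_character_)
    }
    list(reads = bind_rows(reads), truth = bind_rows(src))
  })
}

#' Generate a promoter-enriched peak track
#'
#' @inheritParams generate_sirnas
#' @return Interval tibble of peaks.
#' @export
generate_peaks <- function(cfg, world, seed = 1L) {
  with_seed(seed, {
    genes <- gene_span_tbl(world$annotation)
    glen <- nchar(world$genome[[1]])
    prom <- genes %>% mutate(
      ps = ifelse(.data$strand == "+", pmax(0L, .data$start - cfg$peak_promoter_window), .data$end),
      pe = ifelse(.data$strand == "+", .data$start, pmin(glen, .data$end + cfg$peak_promoter_window))
    ) %>% filter(.data$pe > .data$ps)
    a_prom <- sum(prom$pe - prom$ps)
    p_prom <- cfg$peak_enrichment * a_prom / (cfg$peak_enrichment * a_prom + (glen - a_prom))
    rows <- purrr::map_dfr(seq_len(cfg$n_peaks), function(i) {
      wdt <- cfg$peak_width
      if (runif(1) < p_prom) {
        r <- prom[sample.int(nrow(prom), 1L, prob = prom$pe - prom$ps), ]
        at <- r$ps + sample.int(max(1L, r$pe - r$ps), 1L) - 1L
      } else {
        at <- sample.int(glen - wdt, 1L) - 1L
      }
      at <- min(at, glen - wdt)
      tibble(chrom = names(world$genome)[1],
             start = as.integer(at), end = as.integer(at + wdt), strand = "*",
             id = sprintf("peak%03d", i))
    })
    validate_intervals(rows)
  })
}

#' Generate a transposon track depleted in conserved NOLPs
#'
#' @inheritParams generate_sirnas
#' @param conserved_nolps Interval tibble of NOLPs labelled conserved.
#' @return Interval tibble of transposon insertions.
#' @export
generate_transposons <- function(cfg, world, conserved_nolps, seed = 1L) {
  with_seed(seed, {
    glen <- nchar(world$genome[[1]])
    chrom <- names(world$genome)[1]
    starts <- integer(); widths <- integer()
    attempts <- 0L
    while (length(starts) < cfg$n_transposons && attempts < cfg$n_transposons * 200L) {
      attempts <- attempts + 1L
      wdt <- rand_in(cfg$te_width)
      at <- sample.int(glen - wdt, 1L) - 1L
      hit_cons <- nrow(conserved_nolps) > 0 &&
        any(conserved_nolps$chrom == chrom & conserved_nolps$start < at + wdt &
            conserved_nolps$end > at)
      if (hit_cons && runif(1) > cfg$te_conserved_weight) next
      starts <- c(starts, at); widths <- c(widths, wdt)
    }
    if (!length(starts)) {
      tibble(chrom = character(), start = integer(), end = integer(),
             strand = character(), id = character())
    } else {
      tibble(chrom = chrom, start = starts, end = starts + widths, strand = "*",
             id = sprintf("TE%03d", seq_along(starts)))
    }
  })
}

# Evolve a sequence by per-position divergence classes.
evolve_seq <- function(seq, model, d_vec) {
  chars <- strsplit(seq, "")[[1]]
  code <- match(chars, DNA_BASES)
  out <- chars
  for (d in unique(d_vec)) {
    P <- transition_matrix(model, d)
    for (b in 1:4) {
      idx <- which(d_vec == d & code == b)
      if (length(idx)) out[idx] <- DNA_BASES[sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])]
    }
  }
  paste(out, collapse = "")
}

translate_cds <- function(seq) {
  n3 <- nchar(seq) %/% 3L
  if (n3 == 0) return("")
  starts <- 3L * (seq_len(n3) - 1L) + 1L
  aa <- Biostrings::GENETIC_CODE[substring(seq, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  sub("\\*.*$", "", paste(aa, collapse = ""))
}

proteome_from <- function(genome, genes) {
  purrr::map_dfr(unique(genes$gene_id), function(gid) {
    ex <- genes %>% filter(.data$gene_id == gid) %>% arrange(.data$start)
    s <- paste(vapply(seq_len(nrow(ex)), function(j)
      subseq0(genome[[ex$chrom[j]]], ex$start[j], ex$end[j]), ""), collapse = "")
    if (ex$strand[1] == "-") s <- revcomp(s)
    tibble(id = gid, seq = translate_cds(s))
  }) %>% filter(nchar(.data$seq) >= 10)
}

#' Generate the sister genome, transcript evidence and proteome
#'
#' The sister genome evolves from the focal genome at the configured
#' divergence (gene exons at 0.3x, reflecting purifying selection); each
#' NAT retains antisense transcript evidence with the configured
#' probability (optionally coupled to its conservation label).
#'
#' @inheritParams generate_sirnas
#' @param truth Truth tibble carrying per-NAT `conserved` labels.
#' @return List with `genome`, `evidence` (interval tibble), `proteome`
#'   (tibble `id`, `seq`) and `expression_truth` (per-NAT retention flag).
#' @export
generate_sister <- function(cfg, world, truth, seed = 1L) {
  with_seed(seed, {
    glen <- nchar(world$genome[[1]])
    d_vec <- rep(cfg$sister_divergence, glen)
    genes <- world$genes
    for (j in seq_len(nrow(genes))) {
      d_vec[(genes$start[j] + 1L):genes$end[j]] <- 0.3 * cfg$sister_divergence
    }
    sister <- setNames(evolve_seq(world$genome[[1]], cfg$model, d_vec),
                       names(world$genome))
    q <- if (cfg$couple_expression) {
      ifelse(truth$conserved %in% TRUE, cfg$q_expression_conserved, cfg$q_expression_unconserved)
    } else {
      rep(cfg$q_expression, nrow(truth))
    }
    retained <- runif(nrow(truth)) < q
    evidence <- truth %>% filter(retained) %>%
      transmute(chrom = .data$chrom, start = .data$start, end = .data$end,
                strand = .data$strand, id = paste0(.data$nat_id, "_ev"))
    if (!nrow(evidence)) {
      evidence <- tibble(chrom = character(), start = integer(), end = integer(),
                         strand = character(), id = character())
    }
    list(genome = sister, evidence = evidence,
         proteome = proteome_from(sister, genes),
         expression_truth = tibble(nat_id = truth$nat_id, expression_retained = retained))
  })
}

#' Generate a complete synthetic world
#'
#' Runs every generator with sub-seeds derived from the master seed. The
#' same `(cfg, seed)` pair always produces identical output.
#'
#' @param cfg A [synth_config()].
#' @param seed Master seed.
#' @param tracks Generate the siRNA, peak and transposon tracks (set
#'   `FALSE` for runs that only need annotation, alignment and the sister
#'   genome).
#' @return A list: `config`, `seed`, `genome`, `annotation`, `genes`,
#'   `nats`, `truth` (with `conserved`, `scale`, `expression_retained`),
#'   `nolp_truth`, `maf`, `model`, `sirna` (reads + truth), `peaks`,
#'   `transposons`, `sister` (genome, evidence, proteome), `proteome`.
#' @export
generate_world <- function(cfg = synth_config(), seed = 1L, tracks = TRUE) {
  world <- generate_annotation(cfg, derive_seed(seed, 1))
  truth <- world$truth
  with_seed(derive_seed(seed, 2), {
    eligible <- truth$type != 3L
    truth$conserved <- NA
    truth$conserved[eligible] <- runif(sum(eligible)) < cfg$conserved_fraction
    truth$scale <- ifelse(truth$conserved %in% TRUE, cfg$conserved_scale, 1)
  })
  loci <- world$nolp_truth %>%
    left_join(truth %>% select("nat_id", "type", "scale"), by = "nat_id") %>%
    filter(.data$type != 3L)
  sim <- simulate_alignment(cfg, loci, world$genome, derive_seed(seed, 3))
  world$genome <- sim$genome
  sirna <- NULL; peaks <- NULL; te <- NULL
  if (tracks) {
    sirna <- generate_sirnas(cfg, world, derive_seed(seed, 4))
    peaks <- generate_peaks(cfg, world, derive_seed(seed, 5))
    cons_nolps <- world$nolp_truth %>% filter(.data$nat_id %in% truth$nat_id[truth$conserved %in% TRUE])
    te <- generate_transposons(cfg, world, cons_nolps, derive_seed(seed, 6))
  }
  sister <- generate_sister(cfg, world, truth, derive_seed(seed, 7))
  truth <- truth %>% left_join(sister$expression_truth, by = "nat_id")
  list(config = cfg, seed = seed, genome = world$genome,
       annotation = world$annotation, genes = world$genes, nats = world$nats,
       truth = truth, nolp_truth = world$nolp_truth, maf = sim$maf,
       model = cfg$model, sirna = sirna, peaks = peaks, transposons = te,
       sister = sister, proteome = proteome_from(world$genome, world$genes))
}

#' Write a synthetic world to disk in standard formats
#'
#' @param world Output of [generate_world()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(x) file.path(dir, x)
  write_fasta(world$genome, p("genome.fa"))
  write_gff3(world$genes, p("genes.gff3"))
  write_gff3(world$nats, p("nats.gff3"))
  write_maf(world$maf, p("alignment.maf"))
  write_neutral_model(world$model, p("neutral.mod"))
  write_bed(world$peaks, p("peaks.bed"))
  write_bed(world$transposons, p("transposons.bed"))
  write_fasta(setNames(world$sirna$reads$seq, world$sirna$reads$read_id), p("sirnas.fa"))
  write_fasta(world$sister$genome, p("sister_genome.fa"))
  write_bed(world$sister$evidence, p("sister_evidence.bed"))
  write_fasta(setNames(world$sister$proteome$seq, world$sister$proteome$id),
              p("sister_proteome.fa"))
  write_fasta(setNames(world$proteome$seq, world$proteome$id), p("proteome.fa"))
  truth_flat <- world$truth %>%
    mutate(gene_ids = vapply(.data$gene_ids, paste, "", collapse = ","))
  utils::write.table(truth_flat, p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$nolp_truth, p("nolp_truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
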