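# End-to-end orchestration: topology -> NOLPs -> NR set -> conservation ->
# sister-genome expression/sequence conservation -> siRNA / feature
# cross-referencing -> matched resampling null -> report tables.

#' Pipeline configuration
#'
#' Collects the inputs and thresholds of a full run. Inputs are either a
#' `world` list (from [generate_world()]) or a `world_dir` containing the
#' files written by [write_world()].
#'
#' @param world In-memory world, or `NULL`.
#' @param world_dir Directory of input files, or `NULL`.
#' @param alpha Significance threshold for conservation calls.
#' @param nolp_mode NOLP subtraction mode (see [extract_nolps()]).
#' @param evalue_pairwise Pairwise sequence-conservation cutoff.
#' @param evalue_protein Protein-homology cutoff.
#' @param orf_max_codons ORF length rule for antisense evidence.
#' @param flank_bp Sister-genome flank around orthologous genes.
#' @param min_identity,min_coverage Transcript-mapping acceptance.
#' @param replicates Matched resampling replicates (0 disables the stage).
#' @param seed Master seed.
#' @param stages Stages to run.
#' @param out_dir Output directory for TSVs, or `NULL` to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(world = NULL, world_dir = NULL, alpha = 0.05,
                            nolp_mode = "exon", evalue_pairwise = 1e-10,
                            evalue_protein = 1e-4, orf_max_codons = 100L,
                            flank_bp = 5000L, min_identity = 0.90,
                            min_coverage = 0.50, replicates = 500L, seed = 1L,
                            stages = c("topology", "conservation", "expression",
                                       "pairwise", "sirna", "null", "tables"),
                            out_dir = NULL) {
  if (is.null(world) && is.null(world_dir)) abort("need world or world_dir")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

read_world_dir <- function(dir) {
  p <- function(x) file.path(dir, x)
  need <- function(x) {
    if (!file.exists(p(x))) abort(paste0("missing input file: ", p(x)))
    p(x)
  }
  genes <- read_annotation(need("genes.gff3"), "gff3")
  nats <- read_annotation(need("nats.gff3"), "gff3")
  list(
    genome = read_fasta(need("genome.fa")),
    genes = genes, nats = nats, annotation = bind_rows(genes, nats),
    maf = read_maf(need("alignment.maf")),
    model = read_neutral_model(need("neutral.mod")),
    peaks = read_track(need("peaks.bed")),
    transposons = read_track(need("transposons.bed")),
    sirna = list(reads = read_reads(need("sirnas.fa"))),
    sister = list(genome = read_fasta(need("sister_genome.fa")),
                  evidence = read_track(need("sister_evidence.bed")),
                  proteome = {
                    x <- read_fasta(need("sister_proteome.fa"))
                    tibble(id = names(x), seq = unname(x))
                  }),
    proteome = {
      x <- read_fasta(need("proteome.fa"))
      tibble(id = names(x), seq = unname(x))
    }
  )
}

# Exonic transcript sequence (sense orientation) from the genome.
transcript_seq <- function(genome, annotation, id) {
  ex <- annotation %>% filter(.data$transcript_id == id) %>% arrange(.data$start)
  if (!nrow(ex)) abort(paste0("unknown transcript: ", id))
  s <- paste(vapply(seq_len(nrow(ex)), function(j)
    subseq0(genome[[ex$chrom[j]]], ex$start[j], ex$end[j]), ""), collapse = "")
  if (ex$strand[1] == "-") revcomp(s) else s
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full cis-NAT analysis pipeline
#'
#' Stages run in dependency order; any stage failure aborts with the stage
#' name. Reruns with the same configuration produce identical results.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of result tables: `records` (per-NAT master table),
#'   `topology`, `nolps`, `nr`, `conservation` (per-NOLP-interval LRT),
#'   `conservation_calls`, `expression`, `sirna`, `null`, `tables`,
#'   plus `config_hash`.
#' @export
run_pipeline <- function(cfg) {
  w <- if (!is.null(cfg$world)) cfg$world else run_stage("read_inputs", read_world_dir(cfg$world_dir))
  genes <- w$genes
  nats <- w$nats

  topo <- run_stage("topology", classify_topology(nats, genes))
  parts <- run_stage("topology", extract_nolps(nats, genes, mode = cfg$nolp_mode))
  nolps <- parts %>% filter(.data$part == "nolp") %>%
    left_join(topo %>% select("nat_id", "type"), by = "nat_id")
  nr <- run_stage("topology", build_nr_set(nolps))
  records <- topo %>% select("nat_id", "type", "n_antisense", "status",
                             "antisense_gene_ids")

  lrt <- NULL; calls <- NULL
  if ("conservation" %in% cfg$stages) {
    lrt <- run_stage("conservation", {
      if (is.null(w$maf)) abort("no alignment available")
      scored <- nolps %>% filter(.data$type != 3L | is.na(.data$type))
      species <- w$model$tree$tip.label
      absent <- setdiff(species, maf_species(w$maf))
      if (length(absent)) {
        warn(paste0("tree species absent from the alignment (treated as missing data): ",
                    paste(absent, collapse = ", ")))
      }
      loci <- lapply(seq_len(nrow(scored)), function(i)
        maf_columns(w$maf, scored[i, c("chrom", "start", "end", "strand")], species))
      names(loci) <- sprintf("%s:%d-%d", scored$nat_id, scored$start, scored$end)
      tb <- scale_lrt_table(loci, w$model)
      tb$nat_id <- scored$nat_id
      tb$type <- scored$type
      tb
    })
    calls <- run_stage("conservation", call_conserved(lrt, alpha = cfg$alpha))
    records <- records %>% left_join(calls, by = "nat_id")
  }

  expression <- NULL
  if ("expression" %in% cfg$stages) {
    expression <- run_stage("expression", {
      purrr::map_dfr(records$nat_id, function(id) {
        res <- call_expression_conservation(
          transcript_seq(w$genome, nats, id), w$sister$genome, w$sister$evidence,
          proteome = w$proteome, orf_max_codons = cfg$orf_max_codons,
          protein_evalue = cfg$evalue_protein,
          min_identity = cfg$min_identity, min_coverage = cfg$min_coverage)
        res$nat_id <- id
        res
      })
    })
    records <- records %>%
      left_join(expression %>% select("nat_id", "expression_conserved"), by = "nat_id")
  }

  if ("pairwise" %in% cfg$stages) {
    pairwise <- run_stage("pairwise", {
      orth <- bdbh_orthologs(w$proteome, w$sister$proteome)
      gene_spans <- gene_span_tbl(genes)
      purrr::map_dfr(records$nat_id, function(id) {
        anti <- records$antisense_gene_ids[[match(id, records$nat_id)]]
        nn <- nolps %>% filter(.data$nat_id == id)
        if (!length(anti) || !nrow(nn)) {
          return(tibble(nat_id = id, conserved_pairwise = FALSE, reason = "no_partner_or_nolp"))
        }
        orth_id <- orth$id_b[match(anti, orth$id_a)]
        orth_id <- orth_id[!is.na(orth_id)]
        if (!length(orth_id)) {
          return(tibble(nat_id = id, conserved_pairwise = FALSE, reason = "no_ortholog"))
        }
        # synteny assumption: ortholog locus looked up at the focal gene
        # coordinates on the sister assembly
        g <- gene_spans %>% filter(.data$gene_id == anti[1])
        chrom <- g$chrom[1]
        fs <- max(0L, g$start[1] - cfg$flank_bp)
        fe <- min(nchar(w$sister$genome[[chrom]]), g$end[1] + cfg$flank_bp)
        flank <- subseq0(w$sister$genome[[chrom]], fs, fe)
        cons <- FALSE
        for (i in seq_len(nrow(nn))) {
          q <- subseq0(w$genome[[nn$chrom[i]]], nn$start[i], nn$end[i])
          pc <- pairwise_conservation_call(q, flank, evalue_threshold = cfg$evalue_pairwise)
          if (pc$conserved) { cons <- TRUE; break }
        }
        tibble(nat_id = id, conserved_pairwise = cons,
               reason = if (cons) "hit" else "below_threshold")
      })
    })
    records <- records %>%
      left_join(pairwise %>% select("nat_id", "conserved_pairwise"), by = "nat_id")
  }

  sirna_tbl <- NULL
  if ("sirna" %in% cfg$stages && !is.null(w$sirna)) {
    sirna_tbl <- run_stage("sirna", {
      refs <- bind_rows(
        purrr::map_dfr(records$nat_id, function(id) {
          anti <- records$antisense_gene_ids[[match(id, records$nat_id)]]
          tibble(ref_id = id, seq = transcript_seq(w$genome, nats, id), kind = "nat",
                 locus_id = if (length(anti)) anti[1] else id)
        }),
        purrr::map_dfr(unique(genes$transcript_id), function(tid) {
          gid <- genes$gene_id[match(tid, genes$transcript_id)]
          tibble(ref_id = tid, seq = transcript_seq(w$genome, genes, tid), kind = "mrna",
                 locus_id = gid)
        })
      )
      regions <- purrr::map_dfr(records$nat_id, function(id) {
        nn <- nolps %>% filter(.data$nat_id == id)
        if (!nrow(nn)) return(tibble())
        span <- transcript_spans(nats %>% filter(.data$transcript_id == id))
        loc <- if (span$strand == "+") {
          tibble(start = nn$start - span$start, end = nn$end - span$start)
        } else {
          tibble(start = span$end - nn$end, end = span$end - nn$start)
        }
        loc %>% mutate(ref_id = id, part = "nolp") %>% select("ref_id", "start", "end", "part")
      })
      m <- map_sirnas(w$sirna$reads, refs, regions)
      classify_sirna(m) %>% mutate(nat_id = ifelse(.data$kind %in% "nat", .data$ref_id, NA))
    })
  }

  null_res <- NULL
  if ("null" %in% cfg$stages && cfg$replicates > 0 && nrow(nolps)) {
    null_res <- run_stage("null", {
      chrom_lengths <- setNames(nchar(w$genome), names(w$genome))
      stat <- function(iv) count_feature_overlap(iv, w$peaks, "features")
      nd <- null_distribution(stat, nolps, w$genes, chrom_lengths,
                              n_replicates = cfg$replicates, seed = cfg$seed)
      obs <- stat(nolps)
      list(observed = obs, mean = nd$mean, sd = nd$sd, values = nd$values,
           p_upper = normal_empirical_p(obs, nd$mean, nd$sd, "upper"),
           p_lower = normal_empirical_p(obs, nd$mean, nd$sd, "lower"))
    })
  }

  tables <- NULL
  if ("tables" %in% cfg$stages) {
    tables <- run_stage("tables", {
      rec <- records %>% mutate(dataset = "SYNTH")
      build_report_tables(rec, nolps %>% mutate(dataset = "SYNTH"),
                          sirna = sirna_tbl, peaks = w$peaks,
                          transposons = w$transposons, proteome = w$proteome)
    })
  }

  out <- list(records = records, topology = topo, nolps = nolps, nr = nr,
              conservation = lrt, conservation_calls = calls,
              expression = expression, sirna = sirna_tbl, null = null_res,
              tables = tables,
              config_hash = rlang::hash(cfg[setdiff(names(cfg), c("world", "out_dir"))]))
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg)
  out
}

write_pipeline_outputs <- function(out, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(sprintf("# cisnat %s", as.character(utils::packageVersion("cisnat"))),
            sprintf("# config_hash=%s", out$config_hash),
            sprintf("# seed=%d", cfg$seed))
  wr <- function(df, name) {
    if (is.null(df)) return(invisible())
    path <- file.path(cfg$out_dir, name)
    df <- df %>% dplyr::mutate(dplyr::across(dplyr::where(is.list),
                                             ~ vapply(.x, function(v) paste(unlist(v), collapse = ","), "")))
    con <- file(path, "w")
    writeLines(meta, con)
    close(con)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    invisible()
  }
  wr(out$topology, "topology.tsv")
  wr(out$nolps, "nolps.tsv")
  wr(out$nr, "nr_set.tsv")
  wr(out$conservation, "conservation.tsv")
  wr(out$expression, "expression.tsv")
  wr(out$records, "records.tsv")
  if (!is.null(out$null)) {
    wr(tibble(observed = out$null$observed, mean = out$null$mean, sd = out$null$sd,
              p_upper = out$null$p_upper$p, p_lower = out$null$p_lower$p), "null.tsv")
  }
  if (!is.null(out$tables)) {
    dir.create(file.path(cfg$out_dir, "tables"), showWarnings = FALSE)
    for (nm in names(out$tables)) {
      if (!is.null(out$tables[[nm]])) wr(out$tables[[nm]], file.path("tables", paste0(nm, ".tsv")))
    }
  }
  invisible()
}
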