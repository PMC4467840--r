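# Simplified local-alignment homology toolkit: affine-gap Smith-Waterman
# with Karlin-Altschul e-values, seed-and-extend transcript mapping,
# bidirectional best-hit orthologs, ORF finding, and the sister-genome
# sequence/expression conservation calls built from them.

#' Scoring schemes for local alignment
#'
#' `nt_scoring()` builds a nucleotide match/mismatch scheme (BLASTN-like
#' defaults +2/-3, gap open 5, extend 2, Karlin-Altschul `K = 0.41`,
#' `lambda = 0.625`); `aa_scoring()` uses the BLOSUM62 matrix with the
#' published gapped-search constants (`K = 0.041`, `lambda = 0.267`). The
#' Karlin-Altschul constants are calibration defaults, configurable and
#' recorded with results.
#'
#' @param match,mismatch Nucleotide match/mismatch scores.
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L
#'   costs `gap_open + gap_extend * L`.
#' @param K,lambda Karlin-Altschul parameters for [e_value()].
#' @return A `scoring_scheme` object.
#' @export
nt_scoring <- function(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2,
                       K = 0.41, lambda = 0.625) {
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be > 0")
  if (K <= 0 || lambda <= 0) abort("K and lambda must be > 0")
  alpha <- c(DNA_BASES, "N")
  smat <- matrix(mismatch, 5, 5, dimnames = list(alpha, alpha))
  diag(smat) <- match
  smat["N", ] <- 0
  smat[, "N"] <- 0
  structure(list(type = "nucleotide", alphabet = alpha, smat = smat,
                 gap_open = gap_open, gap_extend = gap_extend, K = K, lambda = lambda),
            class = "scoring_scheme")
}

#' @rdname nt_scoring
#' @export
aa_scoring <- function(gap_open = 11, gap_extend = 1, K = 0.041, lambda = 0.267) {
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be > 0")
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  smat <- e$BLOSUM62
  structure(list(type = "protein", alphabet = rownames(smat), smat = smat,
                 gap_open = gap_open, gap_extend = gap_extend, K = K, lambda = lambda),
            class = "scoring_scheme")
}

encode_seq <- function(x, scoring) {
  chars <- strsplit(toupper(x), "")[[1]]
  code <- match(chars, scoring$alphabet)
  if (anyNA(code)) {
    # unknown residues score like the wildcard (last alphabet entry: N or *)
    wild <- if (scoring$type == "nucleotide") match("N", scoring$alphabet) else match("X", scoring$alphabet)
    code[is.na(code)] <- wild
  }
  code
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Deterministic traceback (ties prefer diagonal, then up, then left).
#'
#' @param a,b Sequences (character strings) over the scheme's alphabet.
#' @param scoring A `scoring_scheme`.
#' @return One-row tibble: `score`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open), `matches`, `aln_len`, `identity`.
#' @export
smith_waterman <- function(a, b, scoring = nt_scoring()) {
  if (!nzchar(a) || !nzchar(b)) abort("smith_waterman: empty sequence")
  hit <- sw_align(encode_seq(a, scoring), encode_seq(b, scoring),
                  scoring$smat, scoring$gap_open, scoring$gap_extend)
  tibble(score = hit$score,
         a_start = hit$a_start, a_end = hit$a_end,
         b_start = hit$b_start, b_end = hit$b_end,
         matches = hit$matches, aln_len = hit$aln_len,
         identity = if (hit$aln_len > 0) hit$matches / hit$aln_len else NA_real_)
}

#' Karlin-Altschul expected hit count
#'
#' `E = K * m * n * exp(-lambda * score)`.
#'
#' @param score Raw alignment score.
#' @param m,n Query and target lengths.
#' @param scoring A `scoring_scheme` carrying `K` and `lambda`.
#' @return Expected number of chance hits at or above `score`.
#' @export
e_value <- function(score, m, n, scoring = nt_scoring()) {
  scoring$K * m * n * exp(-scoring$lambda * score)
}

#' Find open reading frames
#'
#' An ORF runs from an ATG to the next in-frame stop codon; its length in
#' codons excludes the stop. Codons containing `N` never match ATG or a
#' stop. Coordinates are 0-based half-open on the input sequence (the
#' reported interval includes the stop codon).
#'
#' @param seq DNA sequence over `A,C,G,T,N`.
#' @param strands Strands to scan (`"+"` scans `seq` as given, `"-"` its
#'   reverse complement, with coordinates mapped back).
#' @return Tibble with `strand`, `frame` (0-2), `start`, `end`,
#'   `length_codons`.
#' @export
find_orfs <- function(seq, strands = c("+", "-")) {
  seq <- toupper(seq)
  scan <- function(s, strand_label) {
    n <- nchar(s)
    out <- list()
    for (frame in 0:2) {
      if (n - frame < 6) next
      starts <- seq.int(frame + 1L, n - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      is_atg <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      open <- NA_integer_
      for (i in seq_along(codons)) {
        if (is_stop[i]) {
          if (!is.na(open)) {
            out[[length(out) + 1]] <- c(frame, starts[open] - 1L, starts[i] + 2L, i - open)
          }
          open <- NA_integer_
        } else if (is.na(open) && is_atg[i]) {
          open <- i
        }
      }
    }
    if (!length(out)) {
      return(tibble(strand = character(), frame = integer(), start = integer(),
                    end = integer(), length_codons = integer()))
    }
    m <- do.call(rbind, out)
    res <- tibble(strand = strand_label, frame = m[, 1], start = m[, 2],
                  end = m[, 3], length_codons = m[, 4])
    if (strand_label == "-") {
      res <- res %>% mutate(start2 = nchar(seq) - .data$end,
                            end = nchar(seq) - .data$start, start = .data$start2) %>%
        select(-"start2")
    }
    res
  }
  out <- bind_rows(
    if ("+" %in% strands) scan(seq, "+") else NULL,
    if ("-" %in% strands) scan(revcomp(seq), "-") else NULL
  )
  if (!nrow(out)) {
    out <- tibble(strand = character(), frame = integer(), start = integer(),
                  end = integer(), length_codons = integer())
  }
  out
}

# k-mer seed positions of query q in one subject sequence (exact matches).
seed_hits <- function(q, subject, k, step) {
  qlen <- nchar(q)
  qpos <- seq.int(1L, qlen - k + 1L, by = step)
  out <- list()
  for (p in qpos) {
    kmer <- substr(q, p, p + k - 1L)
    if (grepl("N", kmer, fixed = TRUE)) next
    tpos <- find_all_fixed(kmer, subject) + 1L
    if (length(tpos)) {
      out[[length(out) + 1]] <- tibble(qpos = p, tpos = tpos)
    }
  }
  if (!length(out)) tibble(qpos = integer(), tpos = integer()) else bind_rows(out)
}

# Highest-scoring collinear chain of seeds (O(n^2) DP on seed count).
best_chain <- function(seeds, max_band = 200L) {
  n <- nrow(seeds)
  if (!n) return(NULL)
  seeds <- seeds %>% arrange(.data$qpos, .data$tpos)
  score <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (seeds$qpos[j] < seeds$qpos[i] && seeds$tpos[j] < seeds$tpos[i] &&
          abs((seeds$tpos[i] - seeds$qpos[i]) - (seeds$tpos[j] - seeds$qpos[j])) <= max_band &&
          score[j] + 1L > score[i]) {
        score[i] <- score[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(score)
  idx <- integer()
  while (!is.na(i)) {
    idx <- c(i, idx)
    i <- prev[i]
  }
  list(seeds = seeds[idx, , drop = FALSE], n = max(score))
}

#' Map a transcript onto a genome by seed, chain and extend
#'
#' Exact k-mer seeds on both strands, collinear chaining, then gapped
#' Smith-Waterman extension of the best chain per chromosome and strand.
#' A mapping is accepted when identity and query coverage reach the
#' thresholds.
#'
#' @param query Transcript sequence.
#' @param genome Named character vector of chromosome sequences.
#' @param k Seed length.
#' @param min_identity,min_coverage Acceptance thresholds.
#' @param scoring Nucleotide `scoring_scheme` for the extension.
#' @param seed_step Distance between query seed starts.
#' @param pad Window padding around the chain for the extension.
#' @return Tibble of accepted loci (possibly empty): `chrom`, `start`,
#'   `end`, `strand`, `score`, `identity`, `coverage`, `e_value`,
#'   `query_start`, `query_end`; sorted by decreasing score.
#' @export
seed_chain_extend_map <- function(query, genome, k = 11L, min_identity = 0.90,
                                  min_coverage = 0.50, scoring = nt_scoring(),
                                  seed_step = k, pad = 50L) {
  qlen <- nchar(query)
  if (qlen < k) abort("query shorter than seed length")
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    for (chrom in names(genome)) {
      seeds <- seed_hits(q, genome[[chrom]], k, seed_step)
      ch <- best_chain(seeds)
      if (is.null(ch)) next
      s <- ch$seeds
      wstart <- max(1L, min(s$tpos) - min(s$qpos) - pad)
      wend <- min(nchar(genome[[chrom]]), max(s$tpos) + k - 1L + (qlen - max(s$qpos)) + pad)
      window <- substr(genome[[chrom]], wstart, wend)
      aln <- smith_waterman(q, window, scoring)
      cov <- (aln$a_end - aln$a_start) / qlen
      if (is.na(aln$identity) || aln$identity < min_identity || cov < min_coverage) next
      qs <- aln$a_start; qe <- aln$a_end
      if (strand == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
      hits[[length(hits) + 1]] <- tibble(
        chrom = chrom,
        start = wstart - 1L + aln$b_start,
        end = wstart - 1L + aln$b_end,
        strand = strand,
        score = aln$score, identity = aln$identity, coverage = cov,
        e_value = e_value(aln$score, qlen, nchar(genome[[chrom]]), scoring),
        query_start = qs, query_end = qe
      )
    }
  }
  if (!length(hits)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric(), identity = numeric(),
                  coverage = numeric(), e_value = numeric(),
                  query_start = integer(), query_end = integer()))
  }
  bind_rows(hits) %>% arrange(desc(.data$score))
}

as_seq_tbl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    as_tibble(x[, c("id", "seq")])
  } else {
    tibble(id = names(x), seq = unname(as.character(x)))
  }
}

#' Bidirectional best-hit orthologs
#'
#' A pair (a, b) is reported when b is a's unique best-scoring hit in B and
#' a is b's unique best in A under Smith-Waterman scores; ties yield no
#' pair.
#'
#' @param proteome_a,proteome_b Named character vectors or tibbles with
#'   `id`, `seq`.
#' @param scoring A `scoring_scheme` (protein by default).
#' @return Tibble with `id_a`, `id_b`, `score`.
#' @export
bdbh_orthologs <- function(proteome_a, proteome_b, scoring = aa_scoring()) {
  a <- as_seq_tbl(proteome_a)
  b <- as_seq_tbl(proteome_b)
  if (!nrow(a) || !nrow(b)) abort("both proteomes must be non-empty")
  S <- matrix(0, nrow(a), nrow(b), dimnames = list(a$id, b$id))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      S[i, j] <- smith_waterman(a$seq[i], b$seq[j], scoring)$score
    }
  }
  unique_argmax <- function(v) {
    m <- max(v)
    w <- which(v == m)
    if (length(w) == 1 && m > 0) w else NA_integer_
  }
  best_in_b <- apply(S, 1, unique_argmax)
  best_in_a <- apply(S, 2, unique_argmax)
  pairs <- purrr::map_dfr(seq_len(nrow(a)), function(i) {
    j <- best_in_b[i]
    if (!is.na(j) && !is.na(best_in_a[j]) && best_in_a[j] == i) {
      tibble(id_a = a$id[i], id_b = b$id[j], score = S[i, j])
    } else {
      tibble()
    }
  })
  if (!nrow(pairs)) pairs <- tibble(id_a = character(), id_b = character(), score = numeric())
  pairs
}

#' Pairwise sequence-conservation call against a sister-genome flank
#'
#' The query (typically a NOLP sequence) is locally aligned against the
#' sister-genome flank around the orthologous gene, on both strands; the
#' locus is conserved when the best hit's e-value falls below the
#' threshold.
#'
#' @param query Query sequence.
#' @param flank Sister-genome flank sequence (may be empty/`NA`).
#' @param scoring Nucleotide `scoring_scheme`.
#' @param evalue_threshold Conservation threshold (default `1e-10`).
#' @return One-row tibble: `conserved`, `e_value`, `score`, `reason`.
#' @export
pairwise_conservation_call <- function(query, flank, scoring = nt_scoring(),
                                       evalue_threshold = 1e-10) {
  if (is.na(flank) || !nzchar(flank)) {
    return(tibble(conserved = FALSE, e_value = NA_real_, score = NA_real_,
                  reason = "no_flank"))
  }
  best <- -Inf
  for (q in c(query, revcomp(query))) {
    best <- max(best, smith_waterman(q, flank, scoring)$score)
  }
  ev <- e_value(best, nchar(query), nchar(flank), scoring)
  tibble(conserved = ev < evalue_threshold, e_value = ev, score = best,
         reason = if (ev < evalue_threshold) "hit" else "below_threshold")
}

# Fast necessary condition for a significant protein hit: the two
# sequences share an exact k-mer (BLAST-like word seeding).
shares_aa_word <- function(a, b, k = 4L) {
  na <- nchar(a)
  if (na < k || nchar(b) < k) return(FALSE)
  words <- substring(a, 1:(na - k + 1L), k:na)
  any(vapply(unique(words), function(w) grepl(w, b, fixed = TRUE), logical(1)))
}

# Translate a DNA string in one frame, keeping stops as '*'.
translate_dna <- function(seq) {
  n3 <- nchar(seq) %/% 3L
  if (n3 == 0) return("")
  starts <- 3L * (seq_len(n3) - 1L) + 1L
  aa <- Biostrings::GENETIC_CODE[substring(seq, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Translate the three sense-strand frames (and optionally the reverse
# strand) of a DNA sequence; returns a tibble of frame, strand, aa.
translate_frames <- function(seq, strands = c("+", "-")) {
  out <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      sub <- substr(s, frame + 1L, nchar(s))
      if (nchar(sub) < 3) next
      out[[length(out) + 1]] <- tibble(strand = strand, frame = frame,
                                       aa = translate_dna(sub))
    }
  }
  bind_rows(out)
}

#' Protein-homology coverage of a sequence
#'
#' Translates the query in six frames, finds local protein hits against a
#' proteome at or below the e-value threshold, and reports the union of hit
#' footprints mapped back to nucleotide coordinates.
#'
#' @param query DNA sequence (typically a NOLP).
#' @param proteome Named character vector or tibble (`id`, `seq`) of
#'   protein sequences.
#' @param scoring Protein `scoring_scheme`.
#' @param evalue_threshold Hit threshold (default `1e-4`).
#' @return Number of query bp covered by protein homology.
#' @export
protein_homology_coverage <- function(query, proteome, scoring = aa_scoring(),
                                      evalue_threshold = 1e-4) {
  prot <- if (is.data.frame(proteome) || length(proteome)) as_seq_tbl(proteome) else tibble(id = character(), seq = character())
  if (!nrow(prot) || !nzchar(query)) return(0L)
  L <- nchar(query)
  frames <- translate_frames(query)
  cov <- IRanges::IRanges()
  for (i in seq_len(nrow(frames))) {
    aa <- frames$aa[i]
    if (nchar(aa) < 5) next
    for (j in seq_len(nrow(prot))) {
      if (!shares_aa_word(aa, prot$seq[j])) next
      aln <- smith_waterman(aa, prot$seq[j], scoring)
      ev <- e_value(aln$score, nchar(aa), nchar(prot$seq[j]), scoring)
      if (ev <= evalue_threshold && aln$aln_len > 0) {
        f <- frames$frame[i]
        if (frames$strand[i] == "+") {
          ns <- f + 3L * aln$a_start
          ne <- f + 3L * aln$a_end
        } else {
          ns <- L - (f + 3L * aln$a_end)
          ne <- L - (f + 3L * aln$a_start)
        }
        cov <- c(cov, IRanges::IRanges(ns + 1L, ne))
      }
    }
  }
  if (!length(cov)) return(0L)
  sum(IRanges::width(IRanges::reduce(cov)))
}

#' Call conservation of antisense expression in a sister genome
#'
#' A NAT's expression is conserved when (i) its mapped sister locus is
#' overlapped by transcript evidence on the mapped (antisense) strand,
#' (ii) that evidence sequence has no sense-strand ORF longer than
#' `orf_max_codons` codons, and (iii) its sense-direction translation has
#' no protein hit at or below `protein_evalue` against the proteome.
#'
#' @param nat_seq NAT transcript sequence (focal genome, sense orientation).
#' @param sister_genome Named character vector of sister chromosome
#'   sequences.
#' @param sister_evidence Interval tibble of transcript evidence on the
#'   sister genome (with strand).
#' @param proteome Protein set for rule (iii).
#' @param orf_max_codons ORF length cutoff (default 100 codons).
#' @param protein_evalue Protein-homology cutoff (default `1e-4`).
#' @param ... Passed to [seed_chain_extend_map()].
#' @return One-row tibble: `expression_conserved`, `reason`, and the mapped
#'   locus (`chrom`, `start`, `end`, `strand`; `NA` when unmapped).
#' @export
call_expression_conservation <- function(nat_seq, sister_genome, sister_evidence,
                                         proteome, orf_max_codons = 100L,
                                         protein_evalue = 1e-4, ...) {
  empty_locus <- function(conserved, reason) {
    tibble(expression_conserved = conserved, reason = reason,
           chrom = NA_character_, start = NA_integer_, end = NA_integer_,
           strand = NA_character_)
  }
  hits <- seed_chain_extend_map(nat_seq, sister_genome, ...)
  if (!nrow(hits)) return(empty_locus(FALSE, "unmapped"))
  locus <- hits[1, ]
  ev <- validate_intervals(sister_evidence)
  ov <- ev %>% filter(.data$chrom == locus$chrom, .data$strand == locus$strand,
                      .data$start < locus$end, .data$end > locus$start)
  if (!nrow(ov)) {
    return(tibble(expression_conserved = FALSE, reason = "no_evidence",
                  chrom = locus$chrom, start = locus$start, end = locus$end,
                  strand = locus$strand))
  }
  ok <- FALSE
  reason <- "evidence_fails_noncoding_rules"
  for (i in seq_len(nrow(ov))) {
    seq <- subseq0(sister_genome[[ov$chrom[i]]], ov$start[i], ov$end[i])
    if (ov$strand[i] == "-") seq <- revcomp(seq)
    orfs <- find_orfs(seq, strands = "+")
    if (nrow(orfs) && any(orfs$length_codons > orf_max_codons)) next
    sense_aa <- translate_frames(seq, strands = "+")
    coding <- FALSE
    prot <- as_seq_tbl(proteome)
    for (k in seq_len(nrow(sense_aa))) {
      if (coding) break
      for (j in seq_len(nrow(prot))) {
        if (!shares_aa_word(sense_aa$aa[k], prot$seq[j])) next
        aln <- smith_waterman(sense_aa$aa[k], prot$seq[j], aa_scoring())
        if (e_value(aln$score, nchar(sense_aa$aa[k]), nchar(prot$seq[j]), aa_scoring()) <= protein_evalue) {
          coding <- TRUE
          break
        }
      }
    }
    if (!coding) { ok <- TRUE; reason <- "conserved"; break }
  }
  tibble(expression_conserved = ok, reason = reason,
         chrom = locus$chrom, start = locus$start, end = locus$end,
         strand = locus$strand)
}
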