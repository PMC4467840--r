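# Matched resampling null: random samples of near-gene, NOLP-like genomic
# DNA with the same length and gene-relative positioning as the observed
# NOLPs, and the normal-statistics empirical comparison.

# Gene spans used both for anchoring and as forbidden territory.
gene_span_tbl <- function(annotation) {
  transcript_spans(annotation) %>%
    filter(.data$biotype == "protein_coding") %>%
    select("gene_id", "chrom", "start", "end", "strand") %>%
    distinct()
}

# Nearest-gene descriptor of one interval: anchor gene, side (up/downstream
# in the gene's orientation) and edge distance (0 when abutting/overlapping).
describe_position <- function(iv, genes) {
  g <- genes %>% filter(.data$chrom == iv$chrom)
  if (!nrow(g)) abort("no gene on the interval's chromosome")
  gap <- ifelse(iv$end <= g$start, g$start - iv$end,
                ifelse(iv$start >= g$end, iv$start - g$end, 0L))
  i <- which.min(gap)
  left_of_gene <- (iv$start + iv$end) / 2 < (g$start[i] + g$end[i]) / 2
  side <- if (g$strand[i] == "+") {
    if (left_of_gene) "upstream" else "downstream"
  } else {
    if (left_of_gene) "downstream" else "upstream"
  }
  list(gene_id = g$gene_id[i], side = side, delta = as.integer(gap[i]))
}

#' Sample one matched set of near-gene intervals
#'
#' For each observed NOLP, records its length, its side (upstream or
#' downstream) relative to its nearest protein-coding gene, and the edge
#' distance to that gene; then places an interval of the same length at the
#' same side and distance next to a uniformly chosen different gene,
#' redrawing (up to `max_attempts` times) when the placement overlaps any
#' gene transcript or leaves the chromosome.
#'
#' @param observed_nolps Interval tibble of observed NOLPs (a `nat_id` or
#'   `id` column, when present, names errors).
#' @param annotation Exon-level annotation (protein-coding rows are the
#'   genes).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @param max_attempts Redraw budget per NOLP.
#' @return Interval tibble with one row per observed NOLP (`nolp` column
#'   gives the match), in observed order.
#' @export
sample_matched_set <- function(observed_nolps, annotation, chrom_lengths, seed,
                               max_attempts = 1000L) {
  obs <- validate_intervals(observed_nolps)
  genes <- gene_span_tbl(annotation)
  if (!nrow(genes)) abort("annotation contains no protein-coding genes")
  labels <- if ("nat_id" %in% names(obs)) obs$nat_id else if ("id" %in% names(obs)) obs$id else paste0("nolp", seq_len(nrow(obs)))
  descr <- lapply(seq_len(nrow(obs)), function(i) describe_position(obs[i, ], genes))
  n <- nrow(obs)
  out_chrom <- character(n); out_start <- integer(n); out_end <- integer(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      d <- descr[[i]]
      len <- obs$end[i] - obs$start[i]
      pool <- which(genes$gene_id != d$gene_id)
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        if (!length(pool)) break
        j <- pool[sample.int(length(pool), 1L)]
        left <- (d$side == "upstream") == (genes$strand[j] == "+")
        if (left) {
          ce <- genes$start[j] - d$delta
          cs <- ce - len
        } else {
          cs <- genes$end[j] + d$delta
          ce <- cs + len
        }
        chrom <- genes$chrom[j]
        if (cs < 0 || ce > chrom_lengths[[chrom]]) next
        if (any(genes$chrom == chrom & genes$start < ce & genes$end > cs)) next
        out_chrom[i] <- chrom; out_start[i] <- cs; out_end[i] <- ce
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf("could not place a matched interval for NOLP '%s' after %d attempts",
                      labels[i], max_attempts))
      }
    }
  })
  tibble(chrom = out_chrom, start = out_start, end = out_end, strand = "*", nolp = labels)
}

#' Null distribution of a statistic over matched resampled sets
#'
#' Evaluates `statistic` on `n_replicates` matched near-gene sample sets;
#' per-replicate seeds are derived deterministically from the master seed.
#'
#' @param statistic Function of an interval tibble returning one number.
#' @inheritParams sample_matched_set
#' @param n_replicates Number of replicate sets (the study uses 500).
#' @return List with `mean`, `sd` and the replicate `values`.
#' @export
null_distribution <- function(statistic, observed_nolps, annotation, chrom_lengths,
                              n_replicates = 500L, seed = 1L) {
  values <- vapply(seq_len(n_replicates), function(r) {
    s <- sample_matched_set(observed_nolps, annotation, chrom_lengths,
                            seed = derive_seed(seed, r))
    as.numeric(statistic(s))
  }, numeric(1))
  list(mean = mean(values), sd = stats::sd(values), values = values)
}

#' Empirical p-value under normal statistics
#'
#' `z = (observed - null_mean) / null_sd`, referred to the standard normal
#' tail in the requested direction. A degenerate null (`sd = 0`) gives 0 or
#' 1 by direct comparison and is flagged.
#'
#' @param observed Observed statistic.
#' @param null_mean,null_sd Null-distribution moments.
#' @param tail `"upper"` (enrichment) or `"lower"` (depletion).
#' @return One-row tibble: `p`, `z`, `degenerate`.
#' @export
normal_empirical_p <- function(observed, null_mean, null_sd,
                               tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (null_sd < 0) abort("null_sd must be >= 0")
  if (null_sd == 0) {
    p <- if (tail == "lower") as.numeric(observed >= null_mean) else as.numeric(observed <= null_mean)
    return(tibble(p = p, z = NA_real_, degenerate = TRUE))
  }
  z <- (observed - null_mean) / null_sd
  p <- if (tail == "lower") pnorm(z) else pnorm(z, lower.tail = FALSE)
  tibble(p = p, z = z, degenerate = FALSE)
}
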