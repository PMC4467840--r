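# Topology classification of cis-NATs against antisense protein-coding
# genes, NOLP/OLP extraction, the non-redundant NOLP set, and
# cross-validation between NAT data sets.
#
# The five topology types, assigned with precedence 5, 3, 4, 1, 2:
#   1  divergent partial overlap (head-to-head: each transcript's 5' end
#      lies inside the other)
#   2  convergent partial overlap (tail-to-tail)
#   3  NAT span fully inside one antisense gene span
#   4  antisense gene span fully inside the NAT span
#   5  NAT antisense to two or more distinct genes
# Spans decide typing; exon chains decide NOLP extraction.

five_prime <- function(start, end, strand) ifelse(strand == "+", start, end - 1L)
three_prime <- function(start, end, strand) ifelse(strand == "+", end - 1L, start)

#' Classify cis-NAT topologies
#'
#' Each NAT is compared against all protein-coding genes that overlap its
#' span on the opposite strand (unstranded features never count as antisense
#' partners). Exactly one type is assigned using the precedence order
#' 5, 3, 4, 1, 2; NATs with no antisense partner get status
#' `"no_antisense_partner"` and an `NA` type.
#'
#' @param nats Exon-level annotation tibble of NAT transcripts.
#' @param genes Exon-level annotation tibble of genes (only
#'   `protein_coding` rows are used).
#' @return One row per NAT: `nat_id`, `type` (integer or `NA`),
#'   `antisense_gene_ids` (list-column), `n_antisense`, `status`.
#' @export
classify_topology <- function(nats, genes) {
  nat_spans <- transcript_spans(nats)
  gene_spans <- transcript_spans(genes) %>%
    filter(.data$biotype == "protein_coding") %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  purrr::map_dfr(seq_len(nrow(nat_spans)), function(i) {
    nat <- nat_spans[i, ]
    partners <- gene_spans %>%
      filter(.data$chrom == nat$chrom,
             .data$strand != nat$strand, .data$strand != "*",
             nat$strand != "*",
             .data$start < nat$end, .data$end > nat$start)
    if (!nrow(partners)) {
      return(tibble(nat_id = nat$transcript_id, type = NA_integer_,
                    antisense_gene_ids = list(character()), n_antisense = 0L,
                    status = "no_antisense_partner"))
    }
    type <- if (nrow(partners) >= 2) {
      5L
    } else {
      g <- partners[1, ]
      if (nat$start >= g$start && nat$end <= g$end) {
        3L
      } else if (g$start >= nat$start && g$end <= nat$end) {
        4L
      } else {
        nat5 <- five_prime(nat$start, nat$end, nat$strand)
        gene5 <- five_prime(g$start, g$end, g$strand)
        div <- nat5 >= g$start && nat5 < g$end && gene5 >= nat$start && gene5 < nat$end
        if (div) 1L else 2L
      }
    }
    tibble(nat_id = nat$transcript_id, type = type,
           antisense_gene_ids = list(sort(partners$gene_id)),
           n_antisense = nrow(partners), status = "classified")
  })
}

#' Extract OLP and NOLP intervals of cis-NATs
#'
#' The NOLPs of a NAT are the parts of its exonic footprint that do not
#' overlap protein-coding exons (`mode = "exon"`, default) or
#' protein-coding transcript spans (`mode = "transcript_span"`); the OLP is
#' the complement within the footprint.
#'
#' @inheritParams classify_topology
#' @param mode Subtraction mode.
#' @return Tibble with `nat_id`, `part` (`"olp"`/`"nolp"`), `chrom`,
#'   `start`, `end`, `strand` (the NAT's strand).
#' @export
extract_nolps <- function(nats, genes, mode = c("exon", "transcript_span")) {
  mode <- match.arg(mode)
  nats <- validate_annotation(nats)
  pc <- validate_annotation(genes) %>% filter(.data$biotype == "protein_coding")
  sub_tbl <- if (mode == "exon") pc else transcript_spans(pc)
  purrr::map_dfr(unique(nats$transcript_id), function(id) {
    foot <- interval_reduce(nats %>% filter(.data$transcript_id == id))
    strand <- nats$strand[nats$transcript_id == id][1]
    foot$strand <- strand
    blockers <- sub_tbl %>% filter(.data$chrom == foot$chrom[1])
    nolp <- interval_subtract(foot, blockers %>% select("chrom", "start", "end", "strand"))
    olp <- if (nrow(nolp)) {
      interval_subtract(foot, nolp %>% select("chrom", "start", "end", "strand"))
    } else {
      foot %>% mutate(.row = dplyr::row_number())
    }
    bind_rows(
      if (nrow(olp)) olp %>% mutate(part = "olp") else NULL,
      if (nrow(nolp)) nolp %>% mutate(part = "nolp") else NULL
    ) %>%
      mutate(nat_id = id, strand = strand) %>%
      select("nat_id", "part", "chrom", "start", "end", "strand") %>%
      arrange(.data$part, .data$start)
  })
}

#' Build the non-redundant NOLP set
#'
#' Greedy construction: records are visited in decreasing order of total
#' NOLP length (ties broken by record id); a record is kept when none of its
#' NOLP intervals overlaps (by at least 1 bp, either strand) any NOLP of an
#' already-kept record. Records with no NOLP interval are excluded first.
#'
#' @param nolps Tibble of NOLP intervals with a `nat_id` column (e.g. the
#'   `part == "nolp"` rows of [extract_nolps()], possibly pooled across data
#'   sets).
#' @return Tibble of kept records in kept order: `nat_id`,
#'   `total_nolp_bp`.
#' @export
build_nr_set <- function(nolps) {
  nolps <- validate_intervals(nolps)
  if (!"nat_id" %in% names(nolps)) abort("nolps must carry a nat_id column")
  if (!nrow(nolps)) return(tibble(nat_id = character(), total_nolp_bp = integer()))
  lens <- nolps %>%
    group_by(.data$nat_id) %>%
    summarise(total_nolp_bp = sum(.data$end - .data$start), .groups = "drop") %>%
    arrange(desc(.data$total_nolp_bp), .data$nat_id)
  kept <- character()
  kept_gr <- GenomicRanges::GRanges()
  for (id in lens$nat_id) {
    cand <- as_granges(nolps %>% filter(.data$nat_id == id), ignore_strand = TRUE)
    if (!length(kept_gr) ||
        !any(IRanges::overlapsAny(cand, kept_gr, ignore.strand = TRUE))) {
      kept <- c(kept, id)
      kept_gr <- c(kept_gr, cand)
    }
  }
  lens %>% filter(.data$nat_id %in% kept) %>%
    arrange(match(.data$nat_id, kept)) %>%
    select("nat_id", "total_nolp_bp")
}

#' Cross-validate one NAT set against others
#'
#' A NAT is validated when its exonic footprint overlaps, on the same
#' strand and by at least 1 bp, the footprint of any NAT from another data
#' set.
#'
#' @param nats Exon-level annotation of the set to validate.
#' @param others Exon-level annotation pooling the other data sets.
#' @return Tibble with `nat_id` and logical `validated_by_other_sets`.
#' @export
crossvalidate_nats <- function(nats, others) {
  nats <- validate_annotation(nats)
  others <- validate_annotation(others)
  ids <- unique(nats$transcript_id)
  if (!nrow(others)) {
    return(tibble(nat_id = ids, validated_by_other_sets = FALSE))
  }
  other_gr <- as_granges(others %>% filter(.data$strand != "*"))
  validated <- vapply(ids, function(id) {
    x <- nats %>% filter(.data$transcript_id == id, .data$strand != "*")
    if (!nrow(x)) return(FALSE)
    any(IRanges::overlapsAny(as_granges(x), other_gr, ignore.strand = FALSE))
  }, logical(1))
  tibble(nat_id = ids, validated_by_other_sets = unname(validated))
}
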