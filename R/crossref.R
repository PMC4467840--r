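# Hypergeometric association/depletion tests, siRNA mapping and cis/trans
# classification, feature-overlap counting, and report-table assembly.

#' Exact hypergeometric tail probability
#'
#' Enrichment: `P(X >= k)`; depletion: `P(X <= k)`, for X hypergeometric
#' with population `N`, `K` population successes and sample size `n`.
#' Computed exactly (log-space internally via `phyper`).
#'
#' @param N Population size.
#' @param K Population successes.
#' @param n Sample size.
#' @param k Sample successes.
#' @param tail `"enrichment"` or `"depletion"`.
#' @return The tail probability.
#' @export
#' @examples
#' hypergeom_p(3172, 1014, 1023, 350, "enrichment")
hypergeom_p <- function(N, K, n, k, tail = c("enrichment", "depletion")) {
  tail <- match.arg(tail)
  for (v in list(N, K, n, k)) if (!is_count(v)) abort("counts must be non-negative integers")
  if (K > N || n > N) abort("need K <= N and n <= N")
  if (k > min(K, n)) abort("need k <= min(K, n)")
  if (tail == "enrichment") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n, lower.tail = TRUE)
  }
}

#' Association test between two per-NAT flags
#'
#' Cross-tabulates two boolean flags over the same NAT universe and reports
#' both hypergeometric tails. Rows with `NA` in either flag are dropped
#' from the universe.
#'
#' @param data Data frame holding the flags.
#' @param a,b Column names (tidyselect) of the two logical flags.
#' @return One-row tibble: `N`, `K`, `n`, `k`, `p_enrichment`,
#'   `p_depletion`.
#' @export
association_test <- function(data, a, b) {
  fa <- dplyr::pull(data, {{ a }})
  fb <- dplyr::pull(data, {{ b }})
  if (length(fa) != length(fb)) abort("flag vectors must cover the same universe")
  keep <- !is.na(fa) & !is.na(fb)
  fa <- as.logical(fa[keep]); fb <- as.logical(fb[keep])
  N <- length(fa); K <- sum(fa); n <- sum(fb); k <- sum(fa & fb)
  tibble(N = N, K = K, n = n, k = k,
         p_enrichment = hypergeom_p(N, K, n, k, "enrichment"),
         p_depletion = hypergeom_p(N, K, n, k, "depletion"))
}

#' Map short siRNA reads against a reference set
#'
#' Reads are collapsed to non-redundant sequences, then matched exactly
#' (or with up to `max_mismatches` mismatches) in both orientations against
#' every reference. A read is *unique* when it has exactly one
#' forward-orientation match across the combined reference set. Unique
#' forward mappings onto NAT references are assigned a compartment (NOLP or
#' OLP) by the midpoint of the match against the reference's region table.
#'
#' @param reads Tibble with `read_id` and `seq` (lengths 18-30 nt; reads
#'   with other characters than ACGT are skipped with a warning).
#' @param references Tibble with `ref_id`, `seq`, `kind` (`"nat"`,
#'   `"mrna"`, `"other"`) and `locus_id`.
#' @param regions Optional tibble with `ref_id`, `start`, `end`, `part`
#'   (`"nolp"`/`"olp"`) in reference-local 0-based coordinates, for NAT
#'   references.
#' @param max_mismatches Allowed mismatches (default 0, exact).
#' @return Tibble with one row per non-redundant read sequence: `read_id`
#'   (representative), `seq`, `n_fwd`, `n_rev`, `unique`, `ref_id`, `pos`,
#'   `kind`, `locus_id`, `compartment`, and a list-column `rev_hits`.
#' @export
map_sirnas <- function(reads, references, regions = NULL, max_mismatches = 0L) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  stopifnot(all(c("ref_id", "seq") %in% names(references)))
  if (!"kind" %in% names(references)) references$kind <- "other"
  if (!"locus_id" %in% names(references)) references$locus_id <- references$ref_id
  reads <- reads %>% mutate(seq = toupper(.data$seq))
  lens <- nchar(reads$seq)
  if (any(lens < 18 | lens > 30)) abort("read lengths must be 18-30 nt")
  bad <- grepl("[^ACGT]", reads$seq)
  if (any(bad)) {
    warn(sprintf("skipping %d read(s) with non-ACGT characters", sum(bad)))
    reads <- reads[!bad, , drop = FALSE]
  }
  nr <- reads %>% arrange(.data$read_id) %>% distinct(.data$seq, .keep_all = TRUE)
  subjects <- if (max_mismatches > 0) lapply(references$seq, Biostrings::DNAString)
  scan_one <- function(pattern) {
    out <- list()
    for (i in seq_len(nrow(references))) {
      pos <- if (max_mismatches == 0L) {
        find_all_fixed(pattern, references$seq[i])
      } else {
        m <- Biostrings::matchPattern(pattern, subjects[[i]], max.mismatch = max_mismatches)
        Biostrings::start(m) - 1L
      }
      if (length(pos)) {
        out[[length(out) + 1]] <- tibble(ref_id = references$ref_id[i], pos = pos,
                                         kind = references$kind[i],
                                         locus_id = references$locus_id[i])
      }
    }
    if (!length(out)) {
      tibble(ref_id = character(), pos = integer(), kind = character(), locus_id = character())
    } else bind_rows(out)
  }
  purrr::map_dfr(seq_len(nrow(nr)), function(r) {
    seq <- nr$seq[r]
    fwd <- scan_one(seq)
    rev <- scan_one(revcomp(seq))
    uni <- nrow(fwd) == 1L
    comp <- NA_character_
    ref_id <- NA_character_; pos <- NA_integer_; kind <- NA_character_; locus <- NA_character_
    if (uni) {
      ref_id <- fwd$ref_id[1]; pos <- fwd$pos[1]; kind <- fwd$kind[1]; locus <- fwd$locus_id[1]
      if (kind == "nat") {
        comp <- "olp"
        if (!is.null(regions)) {
          mid <- pos + nchar(seq) %/% 2L
          rr <- regions %>% filter(.data$ref_id == !!ref_id, .data$start <= mid, mid < .data$end)
          if (nrow(rr) && rr$part[1] == "nolp") comp <- "nolp"
        }
      } else {
        comp <- "other"
      }
    }
    tibble(read_id = nr$read_id[r], seq = seq,
           n_fwd = nrow(fwd), n_rev = nrow(rev), unique = uni,
           ref_id = ref_id, pos = pos, kind = kind, locus_id = locus,
           compartment = comp, rev_hits = list(rev))
  })
}

#' Classify unique NAT-mapped siRNAs as cis- or trans-acting
#'
#' A read is trans-acting when, besides its unique forward match on a NAT,
#' it also matches in reverse orientation on a transcribed region at a
#' different locus; reverse matches within the NAT's own locus (its
#' antisense gene) are the definition of cis and do not trigger the trans
#' label.
#'
#' @param mappings Output of [map_sirnas()].
#' @return `mappings` with an `acting` column (`"cis"`, `"trans"`, or
#'   `"unassigned"` for non-unique or non-NAT reads).
#' @export
classify_sirna <- function(mappings) {
  mappings %>% mutate(acting = purrr::map_chr(seq_len(dplyr::n()), function(i) {
    if (!mappings$unique[i] || is.na(mappings$kind[i]) || mappings$kind[i] != "nat") {
      return("unassigned")
    }
    rev <- mappings$rev_hits[[i]]
    if (nrow(rev) && any(rev$locus_id != mappings$locus_id[i])) "trans" else "cis"
  }))
}

#' Count feature overlap with NOLPs
#'
#' @param nolps Interval tibble of NOLPs.
#' @param track Interval tibble of features (e.g. ChIP-seq peaks,
#'   transposons).
#' @param unit `"features"` counts distinct track intervals overlapping at
#'   least 1 bp of any NOLP (a peak spanning two NOLPs counts once);
#'   `"bp"` reports total NOLP bp covered by the track's union.
#' @return Integer count.
#' @export
count_feature_overlap <- function(nolps, track, unit = c("features", "bp")) {
  unit <- match.arg(unit)
  nolps <- validate_intervals(nolps)
  track <- validate_intervals(track)
  if (!nrow(nolps) || !nrow(track)) return(0L)
  if (unit == "features") {
    hit <- vapply(seq_len(nrow(track)), function(i) {
      any(nolps$chrom == track$chrom[i] & nolps$start < track$end[i] &
            nolps$end > track$start[i])
    }, logical(1))
    sum(hit)
  } else {
    covered_bp(nolps, track)
  }
}

sig_marker <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p <= 1e-25 ~ "††", p < 0.05 ~ "†", TRUE ~ "")
}

#' Assemble summary report tables
#'
#' Builds tidy analogues of the study's report tables from a per-NAT record
#' table and optional cross-referencing results: topology tallies with
#' conservation counts, cross-validation rates, the conservation x
#' expression cross-tab with hypergeometric markers, ChIP-peak counts,
#' siRNA compartment counts, and transposon/protein-homology coverage.
#' Missing inputs yield `NA` cells.
#'
#' @param records Per-NAT tibble with `nat_id`, `dataset`, `type` and any
#'   of the logical flag columns `conserved_phylo`, `conserved_phylo_hb`,
#'   `conserved_pairwise`, `expression_conserved`,
#'   `validated_by_other_sets`.
#' @param nolps Interval tibble of NOLPs with `nat_id` (and `dataset`).
#' @param sirna Classified mappings from [classify_sirna()], with a
#'   `nat_id` column mapping `ref_id`/`locus_id` onto records, or `NULL`.
#' @param peaks,transposons Feature tracks or `NULL`.
#' @param proteome Protein set for homology coverage or `NULL`.
#' @return Named list of tibbles: `topology`, `validation`,
#'   `conservation_expression`, `chip`, `sirna`, `te_protein`.
#' @export
build_report_tables <- function(records, nolps, sirna = NULL, peaks = NULL,
                                transposons = NULL, proteome = NULL) {
  flag <- function(col) if (col %in% names(records)) records[[col]] else rep(NA, nrow(records))
  records <- records %>% mutate(
    conserved_phylo = flag("conserved_phylo"),
    conserved_pairwise = flag("conserved_pairwise"),
    expression_conserved = flag("expression_conserved"),
    validated_by_other_sets = flag("validated_by_other_sets")
  )
  if (!"dataset" %in% names(records)) records$dataset <- "all"
  if (!"dataset" %in% names(nolps) && nrow(nolps)) {
    nolps <- nolps %>% left_join(records %>% select("nat_id", "dataset"), by = "nat_id")
  }

  topology <- records %>%
    group_by(.data$dataset, .data$type) %>%
    summarise(n = dplyr::n(),
              n_conserved = sum(.data$conserved_phylo %in% TRUE), .groups = "drop")

  validation <- records %>%
    group_by(.data$dataset) %>%
    summarise(n = dplyr::n(),
              n_validated = sum(.data$validated_by_other_sets %in% TRUE), .groups = "drop")

  conservation_expression <- records %>%
    group_by(.data$dataset) %>%
    dplyr::group_modify(function(d, key) {
      res <- tibble(n = nrow(d),
                    n_pairwise = sum(d$conserved_pairwise %in% TRUE),
                    n_phylo = sum(d$conserved_phylo %in% TRUE),
                    n_expression = sum(d$expression_conserved %in% TRUE))
      at <- function(a) {
        if (all(is.na(d[[a]])) || all(is.na(d$expression_conserved))) {
          tibble(k = NA_integer_, p = NA_real_)
        } else {
          t <- association_test(d, !!rlang::sym(a), "expression_conserved")
          tibble(k = t$k, p = t$p_enrichment)
        }
      }
      pw <- at("conserved_pairwise"); ph <- at("conserved_phylo")
      res %>% mutate(k_pairwise_expression = pw$k, p_pairwise_expression = pw$p,
                     marker_pairwise = sig_marker(pw$p),
                     k_phylo_expression = ph$k, p_phylo_expression = ph$p,
                     marker_phylo = sig_marker(ph$p))
    }) %>% ungroup()

  chip <- NULL
  if (!is.null(peaks) && nrow(nolps)) {
    chip <- records %>%
      group_by(.data$dataset) %>%
      dplyr::group_modify(function(d, key) {
        nn <- nolps %>% filter(.data$nat_id %in% d$nat_id)
        has_peak <- vapply(d$nat_id, function(id) {
          count_feature_overlap(nn %>% filter(.data$nat_id == id), peaks, "features") > 0
        }, logical(1))
        cons_ids <- d$nat_id[d$conserved_phylo %in% TRUE]
        expr_ids <- d$nat_id[d$expression_conserved %in% TRUE]
        p <- if (any(!is.na(d$conserved_phylo))) {
          hypergeom_p(nrow(d), sum(has_peak), length(cons_ids),
                      sum(has_peak[d$nat_id %in% cons_ids]), "enrichment")
        } else NA_real_
        tibble(
          n_peaks = count_feature_overlap(nn, peaks, "features"),
          n_peaks_conserved = count_feature_overlap(
            nn %>% filter(.data$nat_id %in% cons_ids), peaks, "features"),
          n_peaks_expression = count_feature_overlap(
            nn %>% filter(.data$nat_id %in% expr_ids), peaks, "features"),
          p_conserved_enrichment = p, marker = sig_marker(p)
        )
      }) %>% ungroup()
  }

  sirna_tbl <- NULL
  if (!is.null(sirna)) {
    nat_ds <- records %>% select("nat_id", "dataset")
    s <- sirna %>% filter(.data$unique, .data$kind == "nat")
    if (!"nat_id" %in% names(s)) s <- s %>% mutate(nat_id = .data$ref_id)
    s <- s %>% left_join(nat_ds, by = "nat_id")
    cons_ids <- records$nat_id[records$conserved_phylo %in% TRUE]
    expr_ids <- records$nat_id[records$expression_conserved %in% TRUE]
    sirna_tbl <- s %>%
      group_by(.data$dataset) %>%
      summarise(n_unique_nolp = sum(.data$compartment == "nolp"),
                n_unique_olp = sum(.data$compartment == "olp"),
                n_trans_nolp = sum(.data$compartment == "nolp" & .data$acting == "trans"),
                n_nolp_conserved = sum(.data$compartment == "nolp" & .data$nat_id %in% cons_ids),
                n_nolp_expression = sum(.data$compartment == "nolp" & .data$nat_id %in% expr_ids),
                .groups = "drop")
  }

  te_protein <- NULL
  if (!is.null(transposons) && nrow(nolps)) {
    cons_ids <- records$nat_id[records$conserved_phylo %in% TRUE]
    te_protein <- nolps %>%
      group_by(.data$dataset) %>%
      dplyr::group_modify(function(nn, key) {
        cons_nn <- nn %>% filter(.data$nat_id %in% cons_ids)
        tibble(
          nolp_bp = sum(nn$end - nn$start),
          nolp_bp_conserved = sum(cons_nn$end - cons_nn$start),
          te_bp_total = count_feature_overlap(nn, transposons, "bp"),
          te_bp_conserved = if (nrow(cons_nn)) count_feature_overlap(cons_nn, transposons, "bp") else 0L
        )
      }) %>% ungroup()
  }

  list(topology = topology, validation = validation,
       conservation_expression = conservation_expression,
       chip = chip, sirna = sirna_tbl, te_protein = te_protein)
}
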