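#' Read a transcript annotation (GFF3 or BED)
#'
#' Returns a tidy exon-level annotation: one row per exon with columns
#' `transcript_id`, `gene_id`, `biotype`, `chrom`, `start`, `end`, `strand`.
#' GFF3 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention; BED is already 0-based half-open. GFF3 transcript
#' features without exon children (e.g. tiling-array regions) become
#' single-exon transcripts.
#'
#' @param path File path.
#' @param format `"gff3"` or `"bed"`.
#' @param default_biotype Biotype assigned when the file carries none
#'   (BED input, or GFF3 types with no mapping). One of
#'   `"protein_coding"`, `"nat"`, `"transposon"`, `"pseudogene"`, `"other"`.
#' @return Exon-level annotation tibble.
#' @export
read_annotation <- function(path, format = c("gff3", "bed"), default_biotype = "nat") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "gff3") read_annotation_gff3(path) else read_annotation_bed(path, default_biotype)
}

BIOTYPES <- c("protein_coding", "nat", "transposon", "pseudogene", "other")

type_to_biotype <- function(type) {
  dplyr::case_when(
    type %in% c("mRNA") ~ "protein_coding",
    type %in% c("antisense_RNA", "antisense_lncRNA") ~ "nat",
    grepl("transposable|transposon", type) ~ "transposon",
    grepl("pseudogen", type) ~ "pseudogene",
    TRUE ~ "other"
  )
}

read_annotation_gff3 <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1]]
    abort(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields", bad, path))
  }
  flds <- strsplit(lines[body], "\t", fixed = TRUE)
  s <- as.integer(vapply(flds, `[[`, "", 4))
  e <- as.integer(vapply(flds, `[[`, "", 5))
  if (any(e < s)) {
    bad <- which(body)[which(e < s)[1]]
    abort(sprintf("GFF3 line %d in %s: end < start", bad, path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  tb <- granges_to_tibble(gr)
  tb$type <- as.character(mc$type)
  tb$id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
  tb$parent <- if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else NA_character_
  tb$biotype_attr <- if ("biotype" %in% names(mc)) as.character(mc$biotype) else NA_character_

  exons <- tb %>% filter(.data$type == "exon", !is.na(.data$parent))
  tx <- tb %>% filter(.data$type != "exon", .data$type != "gene", !is.na(.data$id))
  tx <- tx %>% mutate(biotype = dplyr::coalesce(.data$biotype_attr, type_to_biotype(.data$type)))

  out <- if (nrow(exons)) {
    tx_info <- tx %>% select(transcript_id = "id", gene_id = "parent", "biotype")
    exons %>%
      select(transcript_id = "parent", "chrom", "start", "end", "strand") %>%
      left_join(tx_info, by = "transcript_id") %>%
      mutate(gene_id = dplyr::coalesce(.data$gene_id, .data$transcript_id),
             biotype = dplyr::coalesce(.data$biotype, "other"))
  } else {
    tibble(transcript_id = character(), gene_id = character(), biotype = character(),
           chrom = character(), start = integer(), end = integer(), strand = character())
  }
  # transcripts with no exon children become single-exon models
  lone <- tx %>% filter(!.data$id %in% out$transcript_id)
  if (nrow(lone)) {
    out <- bind_rows(out, lone %>%
      mutate(gene_id = dplyr::coalesce(.data$parent, .data$id)) %>%
      select(transcript_id = "id", "gene_id", "biotype", "chrom", "start", "end", "strand"))
  }
  validate_annotation(out %>% select("transcript_id", "gene_id", "biotype",
                                     "chrom", "start", "end", "strand"))
}

read_annotation_bed <- function(path, default_biotype) {
  tr <- read_track(path)
  if (!nrow(tr)) {
    return(tibble(transcript_id = character(), gene_id = character(), biotype = character(),
                  chrom = character(), start = integer(), end = integer(), strand = character()))
  }
  validate_annotation(tibble(
    transcript_id = tr$id, gene_id = tr$id, biotype = default_biotype,
    chrom = tr$chrom, start = tr$start, end = tr$end, strand = tr$strand
  ))
}

#' Read a BED feature track
#'
#' @param path BED file (3-6 columns).
#' @return Interval tibble with an `id` column (auto-generated when the file
#'   has no name field).
#' @export
read_track <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(trimws(lines)))
  if (!length(body)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), id = character()))
  }
  flds <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(flds)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d in %s: fewer than 3 fields", body[which(nf < 3)[1]], path))
  }
  get <- function(i, default) vapply(flds, function(f) if (length(f) >= i) f[[i]] else default, "")
  out <- tibble(
    chrom = get(1, NA_character_),
    start = as.integer(get(2, NA_character_)),
    end = as.integer(get(3, NA_character_)),
    strand = dplyr::if_else(get(6, "*") %in% c("+", "-"), get(6, "*"), "*"),
    id = get(4, "")
  )
  out$id[!nzchar(out$id) | out$id == "."] <- paste0("feat", which(!nzchar(out$id) | out$id == "."))
  if (any(duplicated(out$id))) out$id <- make.unique(out$id, sep = "_")
  validate_intervals(out)
}

#' Validate an exon-level annotation tibble
#'
#' Checks the per-transcript invariants: exons on one chromosome and strand,
#' sorted and pairwise disjoint.
#'
#' @param x Annotation tibble.
#' @return `x`, with exons sorted within each transcript.
#' @export
validate_annotation <- function(x) {
  x <- validate_intervals(x)
  need <- c("transcript_id", "gene_id", "biotype")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("missing annotation columns: ", paste(miss, collapse = ", ")))
  if (any(!x$biotype %in% BIOTYPES)) {
    abort(paste0("unknown biotype: ", paste(setdiff(unique(x$biotype), BIOTYPES), collapse = ", ")))
  }
  x <- x %>% arrange(.data$transcript_id, .data$start)
  by_tx <- split(seq_len(nrow(x)), x$transcript_id)
  for (idx in by_tx) {
    if (length(unique(x$chrom[idx])) > 1 || length(unique(x$strand[idx])) > 1) {
      abort(paste0("transcript ", x$transcript_id[idx[1]], ": exons on multiple chroms/strands"))
    }
    if (length(idx) > 1 && any(x$start[idx][-1] < x$end[idx][-length(idx)])) {
      abort(paste0("transcript ", x$transcript_id[idx[1]], ": overlapping exons"))
    }
  }
  x
}

#' Per-transcript spans of an annotation
#'
#' @param x Exon-level annotation tibble.
#' @return One row per transcript: `transcript_id`, `gene_id`, `biotype`,
#'   `chrom`, `start`, `end`, `strand`, `exon_bp`.
#' @export
transcript_spans <- function(x) {
  validate_annotation(x) %>%
    group_by(.data$transcript_id, .data$gene_id, .data$biotype, .data$chrom, .data$strand) %>%
    summarise(exon_bp = sum(.data$end - .data$start),
              start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    select("transcript_id", "gene_id", "biotype", "chrom", "start", "end", "strand", "exon_bp")
}

#' Write an annotation to GFF3
#'
#' Emits gene, transcript and exon features in the same dialect
#' [read_annotation()] parses; internal 0-based half-open coordinates are
#' converted back to GFF3's 1-based inclusive convention.
#'
#' @param x Exon-level annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path) {
  x <- validate_annotation(x)
  tx_type <- c(protein_coding = "mRNA", nat = "ncRNA", transposon = "transposable_element",
               pseudogene = "pseudogenic_transcript", other = "transcript")
  spans <- transcript_spans(x)
  genes <- spans %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  lines <- c("##gff-version 3")
  fmt <- function(chrom, type, s, e, strand, attrs) {
    sprintf("%s\tcisnat\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, s + 1L, e, strand, attrs)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand, paste0("ID=", g$gene_id)))
    gtx <- spans %>% filter(.data$gene_id == g$gene_id)
    for (j in seq_len(nrow(gtx))) {
      t <- gtx[j, ]
      lines <- c(lines, fmt(t$chrom, tx_type[[t$biotype]], t$start, t$end, t$strand,
                            sprintf("ID=%s;Parent=%s;biotype=%s", t$transcript_id, t$gene_id, t$biotype)))
      ex <- x %>% filter(.data$transcript_id == t$transcript_id)
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines, fmt(ex$chrom[k], "exon", ex$start[k], ex$end[k], ex$strand[k],
                              paste0("Parent=", t$transcript_id)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals to BED6
#'
#' @param x Interval tibble, optionally with an `id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  id <- if ("id" %in% names(x)) x$id else paste0("feat", seq_len(nrow(x)))
  strand <- ifelse(x$strand == "*", ".", x$strand)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, x$start, x$end, id, strand), path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read short reads (FASTA or FASTQ)
#'
#' @param path Reads file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return Tibble with `read_id` and `seq`.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  tibble(read_id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}
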