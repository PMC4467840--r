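# MAF alignment blocks referenced to a focal genome.
#
# A maf object is a list of blocks; each block has
#   $ref     one-row interval tibble on the focal genome ('+' strand)
#   $rows    named character vector of gapped sequences (reference first)
#   $src_sizes named integer vector of source sequence sizes
# No installed package reads MAF, so the (simple, line-oriented) format is
# parsed here directly.

new_maf <- function(blocks) structure(list(blocks = blocks), class = "cisnat_maf")

#' Construct a MAF block
#'
#' @param ref_chrom,ref_start,ref_end Reference interval (0-based half-open)
#'   on the focal genome.
#' @param rows Named character vector of equal-length gapped sequences over
#'   `A,C,G,T,N,-`; the first row is the reference species.
#' @param src_sizes Named integer vector of source sequence lengths
#'   (defaults to each row's ungapped length).
#' @return A block (plain list) suitable for [maf()].
#' @export
maf_block <- function(ref_chrom, ref_start, ref_end, rows, src_sizes = NULL) {
  if (length(unique(nchar(rows))) != 1) abort("MAF block rows must have equal length")
  ungapped <- nchar(gsub("-", "", rows[[1]], fixed = TRUE))
  if (ungapped != ref_end - ref_start) {
    abort(sprintf("MAF block: ungapped reference length %d != interval length %d",
                  ungapped, ref_end - ref_start))
  }
  if (is.null(src_sizes)) {
    src_sizes <- setNames(nchar(gsub("-", "", rows, fixed = TRUE)), names(rows))
  }
  list(ref = intervals(ref_chrom, ref_start, ref_end, "+"),
       rows = rows, src_sizes = src_sizes)
}

#' Bundle blocks into a MAF object
#' @param blocks List of blocks from [maf_block()].
#' @return A `cisnat_maf` object.
#' @export
maf <- function(blocks) new_maf(blocks)

#' @export
print.cisnat_maf <- function(x, ...) {
  cat(sprintf("<cisnat_maf> %d block(s), species: %s\n", length(x$blocks),
              paste(maf_species(x), collapse = ", ")))
  invisible(x)
}

#' Species present in a MAF
#' @param x A `cisnat_maf`.
#' @return Character vector of species names across all blocks.
#' @export
maf_species <- function(x) unique(unlist(lapply(x$blocks, function(b) names(b$rows))))

#' Read a MAF file
#'
#' Sequence names must be of the form `species.chrom`. Blocks on the `-`
#' strand of the reference are not supported (the focal genome is the
#' reference). Blocks are indexed by their reference interval.
#'
#' @param path MAF file.
#' @return A `cisnat_maf` object.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || !length(cur$rows)) return(NULL)
    maf_block(cur$chrom, cur$start, cur$end, cur$rows, cur$src_sizes)
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
      cur <- list(rows = character(), src_sizes = integer())
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 7) abort(paste0("malformed MAF 's' line: ", ln))
      name <- f[2]
      sp <- sub("\\..*$", "", name)
      chrom <- sub("^[^.]*\\.", "", name)
      start <- as.integer(f[3]); size <- as.integer(f[4])
      strand <- f[5]; src_size <- as.integer(f[6]); text <- f[7]
      if (!length(cur$rows)) {
        if (strand != "+") abort("MAF reference row must be on the + strand")
        cur$chrom <- chrom; cur$start <- start; cur$end <- start + size
      }
      cur$rows[sp] <- text
      cur$src_sizes[sp] <- src_size
    }
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
  new_maf(blocks)
}

#' Write a MAF file
#'
#' @param x A `cisnat_maf` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in x$blocks) {
    writeLines("a score=0.0", con)
    for (sp in names(b$rows)) {
      txt <- b$rows[[sp]]
      size <- nchar(gsub("-", "", txt, fixed = TRUE))
      chrom <- if (sp == names(b$rows)[1]) b$ref$chrom else "chrUn"
      start <- if (sp == names(b$rows)[1]) b$ref$start else 0L
      writeLines(sprintf("s %s.%s %d %d + %d %s", sp, chrom, start, size,
                         b$src_sizes[[sp]], txt), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Extract aligned columns for a focal-genome interval
#'
#' Stitches all blocks overlapping the query interval by reference
#' coordinate. Species absent from a block (or the whole alignment) and
#' reference positions covered by no block contribute missing data.
#'
#' @param x A `cisnat_maf` object.
#' @param interval One-row interval tibble on the focal genome.
#' @param species Character vector fixing the row order (e.g. the tree's
#'   leaves); defaults to all species seen in the MAF.
#' @return Character matrix, rows = species, columns = reference positions
#'   within the interval that are covered by at least one block. Missing
#'   data is `NA`; alignment gaps are `"-"`. Columns from insertion columns
#'   (gap in the reference) are not returned.
#' @export
maf_columns <- function(x, interval, species = NULL) {
  interval <- validate_intervals(interval)
  stopifnot(nrow(interval) == 1)
  if (is.null(species)) species <- maf_species(x)
  cols <- list()
  pos_seen <- integer()
  for (b in x$blocks) {
    if (b$ref$chrom != interval$chrom) next
    ov_s <- max(b$ref$start, interval$start)
    ov_e <- min(b$ref$end, interval$end)
    if (ov_s >= ov_e) next
    chars <- do.call(rbind, strsplit(unname(b$rows), ""))
    rownames(chars) <- names(b$rows)
    ref_chars <- chars[1, ]
    not_gap <- ref_chars != "-"
    ref_pos <- b$ref$start + cumsum(not_gap) - 1L  # genomic pos of each non-gap ref column
    keep <- which(not_gap & ref_pos >= ov_s & ref_pos < ov_e)
    if (!length(keep)) next
    m <- matrix(NA_character_, length(species), length(keep),
                dimnames = list(species, NULL))
    shared <- intersect(species, rownames(chars))
    m[shared, ] <- chars[shared, keep, drop = FALSE]
    cols[[length(cols) + 1]] <- list(pos = ref_pos[keep], m = m)
  }
  if (!length(cols)) {
    return(matrix(NA_character_, length(species), 0, dimnames = list(species, NULL)))
  }
  pos <- unlist(lapply(cols, `[[`, "pos"))
  m <- do.call(cbind, lapply(cols, `[[`, "m"))
  # keep first block's columns where blocks overlap
  ord <- order(pos)
  pos <- pos[ord]; m <- m[, ord, drop = FALSE]
  dup <- duplicated(pos)
  m[, !dup, drop = FALSE]
}
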