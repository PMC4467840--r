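#' Genomic interval tables
#'
#' Intervals are plain tibbles with columns `chrom` (character), `start` and
#' `end` (0-based half-open integers, `0 <= start < end`) and `strand`
#' (`"+"`, `"-"` or `"*"` for unstranded). All internal coordinates use this
#' convention; conversion to/from 1-based inclusive (GFF3) happens only at
#' I/O boundaries.
#'
#' @param chrom,start,end,strand Vectors, recycled to a common length.
#' @return A validated interval tibble.
#' @export
#' @examples
#' intervals("chr1", 0, 100)
intervals <- function(chrom, start, end, strand = "*") {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand)
  )
  validate_intervals(x)
}

#' Validate an interval tibble
#'
#' @param x A data frame with `chrom`, `start`, `end` and optionally `strand`.
#' @return `x` as a tibble, with `strand` filled in as `"*"` when absent.
#' @export
validate_intervals <- function(x) {
  if (!is.data.frame(x)) abort("intervals must be a data frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("missing interval columns: ", paste(miss, collapse = ", ")))
  x <- as_tibble(x)
  if (!"strand" %in% names(x)) x$strand <- "*"
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) abort("chrom must be non-empty")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort(sprintf("invalid interval at row %d: need 0 <= start < end, got [%s, %s)",
                  bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  if (any(!x$strand %in% c("+", "-", "*"))) abort("strand must be one of '+', '-', '*'")
  x
}

#' Interval length in bp
#' @param x Interval tibble.
#' @return Integer vector of widths.
#' @export
interval_width <- function(x) {
  x <- validate_intervals(x)
  x$end - x$start
}

# Convert an interval tibble to a GRanges (coordinates become 1-based).
as_granges <- function(x, ignore_strand = FALSE) {
  x <- validate_intervals(x)
  strand <- if (ignore_strand) "*" else x$strand
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end), strand = strand)
}

# Back-conversion from GRanges to the tidy representation.
granges_to_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Subtract a set of intervals from intervals
#'
#' For each row of `x`, returns the maximal sub-intervals not covered by any
#' interval in `y`. Strand is ignored for the subtraction itself; the result
#' inherits each `x` row's strand. All intervals must be on a single
#' chromosome.
#'
#' @param x Interval tibble (minuend); one or more rows.
#' @param y Interval tibble (subtrahend); may be empty.
#' @return Interval tibble, sorted by `start` within each input row, with a
#'   `.row` column identifying the originating row of `x`.
#' @export
#' @examples
#' interval_subtract(intervals("c", 0, 1000), intervals("c", 400, 600))
interval_subtract <- function(x, y) {
  x <- validate_intervals(x)
  y <- validate_intervals(y)
  chroms <- unique(c(x$chrom, y$chrom))
  if (length(chroms) > 1) {
    abort(paste0("interval_subtract requires a single chromosome, got: ",
                 paste(chroms, collapse = ", ")))
  }
  m <- merge_blocks(y$start, y$end)
  out <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    ks <- x$start[i]; ke <- x$end[i]
    starts <- integer(); ends <- integer()
    cur <- ks
    for (j in seq_along(m$start)) {
      if (m$end[j] <= cur || m$start[j] >= ke) next
      if (m$start[j] > cur) { starts <- c(starts, cur); ends <- c(ends, m$start[j]) }
      cur <- max(cur, m$end[j])
      if (cur >= ke) break
    }
    if (cur < ke) { starts <- c(starts, cur); ends <- c(ends, ke) }
    if (!length(starts)) return(tibble())
    tibble(chrom = x$chrom[i], start = starts, end = ends, strand = x$strand[i], .row = i)
  })
  if (!nrow(out)) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), .row = integer())
  }
  out
}

# Merge possibly-overlapping blocks into disjoint sorted blocks.
merge_blocks <- function(start, end) {
  if (!length(start)) return(list(start = integer(), end = integer()))
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]
  ms <- start[1]; me <- end[1]
  outs <- integer(); oute <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(outs, ms), end = c(oute, me))
}

#' Pairwise overlap in bp between two intervals
#'
#' Vectorised over rows; length-1 inputs recycle. Different chromosomes or
#' disjoint intervals give 0. Strand is ignored.
#'
#' @param a,b Interval tibbles.
#' @return Integer vector of overlap widths.
#' @export
#' @examples
#' overlap_bp(intervals("c", 0, 100), intervals("c", 50, 150))
overlap_bp <- function(a, b) {
  a <- validate_intervals(a)
  b <- validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[idx_a], b$end[idx_b]) - pmax(a$start[idx_a], b$start[idx_b])
  ov[a$chrom[idx_a] != b$chrom[idx_b]] <- 0L
  as.integer(pmax(ov, 0L))
}

# Union (reduce) of an interval tibble, optionally per strand.
interval_reduce <- function(x, ignore_strand = TRUE) {
  x <- validate_intervals(x)
  if (!nrow(x)) return(x)
  gr <- GenomicRanges::reduce(as_granges(x, ignore_strand = ignore_strand))
  granges_to_tibble(gr)
}

# Total bp of x covered by the union of track intervals (strand-blind).
covered_bp <- function(x, track) {
  x <- validate_intervals(x)
  track <- validate_intervals(track)
  if (!nrow(x) || !nrow(track)) return(0L)
  total <- 0L
  for (chr in unique(x$chrom)) {
    xs <- merge_blocks(x$start[x$chrom == chr], x$end[x$chrom == chr])
    sel <- track$chrom == chr
    if (!any(sel)) next
    ts <- merge_blocks(track$start[sel], track$end[sel])
    for (i in seq_along(xs$start)) {
      ov <- pmin(xs$end[i], ts$end) - pmax(xs$start[i], ts$start)
      total <- total + sum(pmax(ov, 0L))
    }
  }
  as.integer(total)
}
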