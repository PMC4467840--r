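# Internal helpers shared across the package.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code with a temporary, restorable RNG seed
#'
#' All stochastic operations in the package funnel their randomness through
#' this helper so that a master seed makes every result reproducible without
#' clobbering the caller's RNG state.
#'
#' @param seed Integer seed (must be < 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a replicate seed from a master seed; stays within 32-bit range.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 1009 + i * 9973) %% 2147483629)
}

# Random DNA of length n with base frequencies pi (named or in ACGT order).
random_dna <- function(n, pi = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = pi), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s)))),
         "", USE.NAMES = FALSE)
}

# Substring with 0-based half-open coordinates.
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# All (possibly overlapping) 0-based start positions of a fixed pattern.
find_all_fixed <- function(pattern, subject) {
  out <- integer()
  from <- 1L
  n <- nchar(subject)
  repeat {
    hit <- regexpr(pattern, substr(subject, from, n), fixed = TRUE)
    if (hit == -1L) break
    at <- from + as.integer(hit) - 1L
    out <- c(out, at)
    from <- at + 1L
  }
  out - 1L
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}
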