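# Independent oracles used to cross-check the implementations.

# Plain-R affine-gap local alignment, written as a direct three-matrix
# recurrence over full matrices (no traceback, no optimisation).
sw_oracle_score <- function(a, b, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  max(H)
}

# Exact hypergeometric pmf by sequential sampling without replacement:
# builds P(X = i) by drawing the n sample members one at a time.
hyper_oracle_pmf <- function(N, K, n) {
  f <- 1  # index i+1 = P(i successes so far)
  for (j in seq_len(n)) {
    drawn <- j - 1
    nf <- numeric(j + 1)
    for (idx in seq_along(f)) {
      i <- idx - 1
      p_succ <- (K - i) / (N - drawn)
      nf[idx] <- nf[idx] + f[idx] * (1 - p_succ)
      nf[idx + 1] <- nf[idx + 1] + f[idx] * p_succ
    }
    f <- nf
  }
  f  # P(X = 0..n)
}

hyper_oracle <- function(N, K, n, k, tail) {
  probs <- hyper_oracle_pmf(N, K, n)
  if (tail == "enrichment") sum(probs[(k + 1):length(probs)]) else sum(probs[1:(k + 1)])
}

# Greedy non-redundant selection, written independently over flat vectors.
nr_oracle <- function(nolps) {
  agg <- aggregate(nolps$end - nolps$start, by = list(nat_id = nolps$nat_id), FUN = sum)
  agg <- agg[order(-agg$x, agg$nat_id), ]
  kept <- character()
  kept_iv <- data.frame(chrom = character(), start = integer(), end = integer())
  for (id in agg$nat_id) {
    iv <- nolps[nolps$nat_id == id, ]
    clash <- FALSE
    for (r in seq_len(nrow(iv))) {
      if (any(kept_iv$chrom == iv$chrom[r] & kept_iv$start < iv$end[r] &
              kept_iv$end > iv$start[r])) {
        clash <- TRUE
        break
      }
    }
    if (!clash) {
      kept <- c(kept, id)
      kept_iv <- rbind(kept_iv, iv[, c("chrom", "start", "end")])
    }
  }
  kept
}

# Brute-force exact read mapping: compare the read (and its reverse
# complement) against every offset of every reference.
scan_oracle <- function(read, refs) {
  rc <- cisnat:::revcomp(read)
  k <- nchar(read)
  out <- list()
  for (nm in names(refs)) {
    s <- refs[[nm]]
    n <- nchar(s)
    if (n < k) next
    windows <- substring(s, 1:(n - k + 1), k:n)
    for (at in which(windows == read)) {
      out[[length(out) + 1]] <- data.frame(ref = nm, pos = at - 1, ori = "fwd")
    }
    for (at in which(windows == rc)) {
      out[[length(out) + 1]] <- data.frame(ref = nm, pos = at - 1, ori = "rev")
    }
  }
  if (!length(out)) data.frame(ref = character(), pos = integer(), ori = character())
  else do.call(rbind, out)
}
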