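# Branch-length-scale likelihood-ratio conservation test.
#
# The alternative model multiplies every neutral branch length by a free
# scale; scale < 1 indicates conservation, > 1 accelerated evolution. The
# null fixes scale = 1. D = 2(lnL_alt - lnL_null) ~ chi-squared(1) under
# the null.

# Encode a character matrix (rows = species) into 1..4 codes; gaps, N and
# anything outside ACGT become NA (missing data).
encode_columns <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1, dimnames = list(names(mat), NULL))
  code <- match(toupper(mat), DNA_BASES)
  dim(code) <- dim(mat)
  rownames(code) <- rownames(mat)
  code
}

# Compress encoded columns into unique patterns with multiplicities.
compress_patterns <- function(code) {
  if (ncol(code) == 0) return(list(code = code, w = numeric()))
  key <- apply(code, 2, paste, collapse = ",")
  u <- !duplicated(key)
  list(code = code[, u, drop = FALSE], w = as.numeric(table(key)[key[u]]))
}

# Felsenstein pruning over the (postorder) tree; vectorised across patterns.
peel_loglik <- function(model, code, w, scale) {
  tree <- model$tree_post
  ntip <- length(tree$tip.label)
  npat <- ncol(code)
  if (npat == 0) return(0)
  L <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    M <- matrix(1, 4, npat)
    sp <- tree$tip.label[i]
    if (sp %in% rownames(code)) {
      obs <- code[sp, ]
      known <- which(!is.na(obs))
      if (length(known)) {
        M[, known] <- 0
        M[cbind(obs[known], known)] <- 1
      }
    }
    L[[i]] <- M
  }
  edge <- tree$edge
  el <- tree$edge.length
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    contrib <- transition_matrix(model, el[e] * scale) %*% L[[ch]]
    L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
  }
  root <- edge[nrow(edge), 1]
  sum(w * log(colSums(model$pi * L[[root]])))
}

#' Log-likelihood of one alignment column
#'
#' @param column Named character vector of bases (one per species; gaps/`N`
#'   or missing species are marginalised out).
#' @param model A `neutral_model`.
#' @param scale Positive branch-length multiplier.
#' @return The column log-likelihood (may be `-Inf` for impossible data).
#' @export
column_log_likelihood <- function(column, model, scale = 1) {
  if (scale <= 0) abort("scale must be > 0")
  code <- encode_columns(column)
  peel_loglik(model, code, 1, scale)
}

#' Log-likelihood of a locus alignment
#'
#' @param columns Character matrix, rows = species, columns = sites.
#' @inheritParams column_log_likelihood
#' @return Summed log-likelihood over columns.
#' @export
locus_log_likelihood <- function(columns, model, scale = 1) {
  if (scale <= 0) abort("scale must be > 0")
  cp <- compress_patterns(encode_columns(columns))
  peel_loglik(model, cp$code, cp$w, scale)
}

# Columns with at least two non-missing species are informative.
usable_columns <- function(code) {
  if (ncol(code) == 0) return(code[, 0, drop = FALSE])
  code[, colSums(!is.na(code)) >= 2, drop = FALSE]
}

#' Maximum-likelihood branch-length scale for a locus
#'
#' Bounded one-dimensional optimisation of the locus log-likelihood over the
#' scale. Columns with fewer than two non-missing species are skipped; loci
#' with fewer than `min_columns` usable columns are flagged untestable.
#'
#' @param columns Character matrix, rows = species, columns = sites.
#' @param model A `neutral_model`.
#' @param lower,upper Scale bounds.
#' @param tol Optimisation tolerance in scale units.
#' @param min_columns Minimum usable columns for a testable locus.
#' @return List with `scale`, `lnL_alt`, `n_columns`, `untestable`, and the
#'   profile log-likelihood function `lnL_fn`.
#' @export
fit_scale <- function(columns, model, lower = 1e-3, upper = 10, tol = 1e-6,
                      min_columns = 10) {
  code <- usable_columns(encode_columns(columns))
  n_col <- ncol(code)
  if (n_col < min_columns) {
    return(list(scale = NA_real_, lnL_alt = NA_real_, n_columns = n_col,
                untestable = TRUE, lnL_fn = NULL))
  }
  cp <- compress_patterns(code)
  f <- function(s) peel_loglik(model, cp$code, cp$w, s)
  opt <- optimize(f, c(lower, upper), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, lower, upper)
  vals <- c(opt$objective, f(lower), f(upper))
  best <- which.max(vals)
  list(scale = cand[best], lnL_alt = vals[best], n_columns = n_col,
       untestable = FALSE, lnL_fn = f)
}

#' Chi-squared(1) upper-tail p-value of the LRT statistic
#' @param D Non-negative LRT statistic.
#' @return Upper tail probability.
#' @export
lrt_pvalue <- function(D) pchisq(D, df = 1, lower.tail = FALSE)

#' Scale likelihood-ratio test for one locus
#'
#' Compares the free-scale alternative to the neutral null (scale = 1);
#' `D = 2(lnL_alt - lnL_null)` is referred to a chi-squared distribution
#' with one degree of freedom. Direction is read off the scale MLE.
#'
#' @inheritParams fit_scale
#' @return A `cisnat_lrt` object with `scale`, `lnL_null`, `lnL_alt`, `D`,
#'   `p_value`, `direction`, `n_columns`, `untestable`.
#' @export
scale_lrt <- function(columns, model, lower = 1e-3, upper = 10, tol = 1e-6,
                      min_columns = 10) {
  fit <- fit_scale(columns, model, lower, upper, tol, min_columns)
  if (fit$untestable) {
    res <- list(scale = NA_real_, lnL_null = NA_real_, lnL_alt = NA_real_,
                D = NA_real_, p_value = NA_real_, direction = NA_character_,
                n_columns = fit$n_columns, untestable = TRUE)
    return(structure(res, class = "cisnat_lrt"))
  }
  lnL_null <- fit$lnL_fn(1)
  scale <- fit$scale
  lnL_alt <- fit$lnL_alt
  if (lnL_alt < lnL_null) {  # optimiser noise: null is the better fit
    scale <- 1
    lnL_alt <- lnL_null
  }
  D <- max(0, 2 * (lnL_alt - lnL_null))
  direction <- if (D == 0 || abs(scale - 1) <= 1e-6) "neutral"
               else if (scale < 1) "conserved" else "accelerated"
  structure(list(scale = scale, lnL_null = lnL_null, lnL_alt = lnL_alt,
                 D = D, p_value = lrt_pvalue(D), direction = direction,
                 n_columns = fit$n_columns, untestable = FALSE),
            class = "cisnat_lrt")
}

#' @export
print.cisnat_lrt <- function(x, ...) {
  if (x$untestable) {
    cat("<scale LRT> untestable (", x$n_columns, "usable columns )\n")
  } else {
    cat(sprintf("<scale LRT> scale=%.4g D=%.3f p=%.3g (%s), %d columns\n",
                x$scale, x$D, x$p_value, x$direction, x$n_columns))
  }
  invisible(x)
}

#' @rdname scale_lrt
#' @param x A `cisnat_lrt` object.
#' @param ... Unused.
#' @method tidy cisnat_lrt
#' @export
tidy.cisnat_lrt <- function(x, ...) {
  tibble(term = "scale", estimate = x$scale, statistic = x$D, p.value = x$p_value)
}

#' @rdname scale_lrt
#' @method glance cisnat_lrt
#' @export
glance.cisnat_lrt <- function(x, ...) {
  tibble(scale = x$scale, lnL_null = x$lnL_null, lnL_alt = x$lnL_alt, D = x$D,
         p_value = x$p_value, direction = x$direction %||% NA_character_,
         n_columns = x$n_columns, untestable = x$untestable)
}

#' Scale LRT over a set of loci, with Holm-Bonferroni correction
#'
#' @param loci Named list of alignment matrices (rows = species), or a
#'   tibble with columns `locus` and a list-column `columns`.
#' @inheritParams fit_scale
#' @return Tibble with one row per locus: `locus`, `n_columns`, `scale`,
#'   `lnL_null`, `lnL_alt`, `D`, `p_value`, `direction`, `untestable`,
#'   `p_adjusted` (Holm-Bonferroni over the testable loci).
#' @export
scale_lrt_table <- function(loci, model, lower = 1e-3, upper = 10, tol = 1e-6,
                            min_columns = 10) {
  if (is.data.frame(loci)) {
    nm <- loci$locus
    loci <- setNames(loci$columns, nm)
  }
  if (is.null(names(loci))) names(loci) <- paste0("locus", seq_along(loci))
  rows <- purrr::map_dfr(names(loci), function(id) {
    g <- glance(scale_lrt(loci[[id]], model, lower, upper, tol, min_columns))
    g$locus <- id
    g
  })
  rows$p_adjusted <- holm_bonferroni(rows$p_value)
  rows %>% select("locus", "n_columns", "scale", "lnL_null", "lnL_alt",
                  "D", "p_value", "direction", "untestable", "p_adjusted")
}

#' Holm-Bonferroni step-down adjusted p-values
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed for
#'   untestable entries, which are ignored by the correction).
#' @return Adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Per-NAT conservation calls from per-interval LRT results
#'
#' A cis-NAT is called conserved when any of its NOLP intervals is
#' significant (p below `alpha`) with scale below 1. NATs of topology type 3
#' have no NOLPs and are excluded (flag `NA`).
#'
#' @param lrt_tbl Tibble from [scale_lrt_table()] carrying an extra `nat_id`
#'   column (and optionally `type`).
#' @param alpha Significance threshold.
#' @return Tibble with `nat_id`, `conserved_phylo` (raw p),
#'   `conserved_phylo_hb` (Holm-Bonferroni-adjusted p), and
#'   `n_conserved_regions`.
#' @export
call_conserved <- function(lrt_tbl, alpha = 0.05) {
  if (!"nat_id" %in% names(lrt_tbl)) abort("lrt_tbl must carry a nat_id column")
  out <- lrt_tbl %>%
    group_by(.data$nat_id) %>%
    summarise(
      conserved_phylo = any(!is.na(.data$p_value) & .data$p_value < alpha & .data$scale < 1),
      conserved_phylo_hb = any(!is.na(.data$p_adjusted) & .data$p_adjusted < alpha & .data$scale < 1),
      n_conserved_regions = sum(!is.na(.data$p_value) & .data$p_value < alpha & .data$scale < 1),
      .groups = "drop"
    )
  if ("type" %in% names(lrt_tbl)) {
    t3 <- lrt_tbl %>% distinct(.data$nat_id, .data$type) %>% filter(.data$type == 3L)
    out <- out %>% mutate(
      conserved_phylo = replace(.data$conserved_phylo, .data$nat_id %in% t3$nat_id, NA),
      conserved_phylo_hb = replace(.data$conserved_phylo_hb, .data$nat_id %in% t3$nat_id, NA)
    )
  }
  out
}
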