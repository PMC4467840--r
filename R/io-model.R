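# Neutral substitution model: tree with branch lengths plus a general
# reversible rate matrix and equilibrium base frequencies.

#' Construct a neutral model
#'
#' Builds a general reversible (GTR-style) substitution model from symmetric
#' exchangeabilities and equilibrium frequencies, attached to a tree with
#' branch lengths in expected substitutions per site. The rate matrix is
#' normalised so the expected substitution rate at equilibrium is 1 per unit
#' branch length.
#'
#' @param tree An `ape::phylo` tree with branch lengths, or a newick string.
#' @param exchangeabilities Numeric vector of the six symmetric rates in the
#'   order AC, AG, AT, CG, CT, GT.
#' @param base_freqs Equilibrium frequencies over A, C, G, T (must sum to 1).
#' @param rate_matrix Alternatively, a full 4x4 reversible rate matrix
#'   (rows sum to 0, detailed balance with `base_freqs`); overrides
#'   `exchangeabilities`.
#' @return A `neutral_model` object.
#' @export
neutral_model <- function(tree, exchangeabilities = c(1, 2, 1, 1, 2, 1),
                          base_freqs = rep(0.25, 4), rate_matrix = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) abort("tree must be an ape phylo or newick string")
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  pi <- as.numeric(base_freqs)
  if (length(pi) != 4 || any(pi <= 0)) abort("base_freqs must be 4 positive values")
  pi <- pi / sum(pi)
  if (is.null(rate_matrix)) {
    s <- as.numeric(exchangeabilities)
    if (length(s) != 6 || any(s < 0)) abort("need 6 non-negative exchangeabilities")
    Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (r in seq_len(6)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      Q[i, j] <- s[r] * pi[j]
      Q[j, i] <- s[r] * pi[i]
    }
  } else {
    Q <- rate_matrix
    dimnames(Q) <- list(DNA_BASES, DNA_BASES)
    diag(Q) <- 0
  }
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(pi * diag(Q))
  if (mean_rate <= 0) abort("rate matrix has no substitution flux")
  Q <- Q / mean_rate
  db <- pi * Q  # detailed balance check: pi_i q_ij symmetric
  if (max(abs(db - t(db))) > 1e-8) abort("rate matrix violates detailed balance")
  m <- structure(list(tree = tree, Q = Q, pi = setNames(pi, DNA_BASES)),
                 class = "neutral_model")
  m$eig <- model_eigen(m)
  m$tree_post <- ape::reorder.phylo(tree, "postorder")
  m
}

#' @export
print.neutral_model <- function(x, ...) {
  cat(sprintf("<neutral_model> %d leaves, total branch length %.4g\n",
              length(x$tree$tip.label), sum(x$tree$edge.length)))
  cat("base freqs:", paste(sprintf("%s=%.3f", DNA_BASES, x$pi), collapse = " "), "\n")
  invisible(x)
}

# Eigendecomposition of the reversible Q via its symmetrised form, cached
# for fast transition-probability evaluation.
model_eigen <- function(m) {
  d <- sqrt(m$pi)
  S <- diag(d) %*% m$Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       left = diag(1 / d) %*% e$vectors,
       right = t(e$vectors) %*% diag(d))
}

#' Transition probability matrix P(t)
#'
#' @param model A `neutral_model`.
#' @param t Branch length (expected substitutions/site), `t >= 0`.
#' @return 4x4 matrix with rows = ancestral base, columns = descendant base.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) abort("branch length must be >= 0")
  if (t == 0) return(diag(4) + 0 * model$Q)  # exact identity, keeps dimnames
  P <- model$eig$left %*% (exp(model$eig$values * t) * model$eig$right)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}

#' Read a phyloFit-style neutral model file
#'
#' Parses the text format with `ALPHABET`, `BACKGROUND`, `RATE_MAT` and
#' `TREE` stanzas. The rate matrix is re-normalised to a mean equilibrium
#' rate of 1 per unit branch length.
#'
#' @param path Model file.
#' @return A `neutral_model`.
#' @export
read_neutral_model <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  grab <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(ln)) abort(paste0("malformed model file: missing ", key))
    trimws(sub(paste0("^", key, ":"), "", ln[1]))
  }
  bg <- as.numeric(strsplit(grab("BACKGROUND"), "\\s+")[[1]])
  if (length(bg) != 4 || any(is.na(bg))) abort("malformed BACKGROUND line")
  mat_at <- grep("^RATE_MAT:", lines)
  if (!length(mat_at) || mat_at[1] + 4 > length(lines)) abort("malformed RATE_MAT stanza")
  Q <- t(vapply(lines[(mat_at[1] + 1):(mat_at[1] + 4)], function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(v) != 4 || any(is.na(v))) abort("malformed RATE_MAT row")
    v
  }, numeric(4)))
  tree <- ape::read.tree(text = grab("TREE"))
  if (is.null(tree)) abort("malformed TREE line")
  neutral_model(tree, base_freqs = bg, rate_matrix = Q)
}

#' Write a neutral model in the phyloFit-style text format
#'
#' @param model A `neutral_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_neutral_model <- function(model, path) {
  lines <- c(
    "ALPHABET: A C G T",
    "ORDER: 0",
    "SUBST_MOD: REV",
    paste("BACKGROUND:", paste(sprintf("%.6f", model$pi), collapse = " ")),
    "RATE_MAT:",
    apply(model$Q, 1, function(r) paste0("  ", paste(sprintf("%.6f", r), collapse = " "))),
    paste("TREE:", ape::write.tree(model$tree))
  )
  writeLines(lines, path)
  invisible(path)
}

#' A default 9-taxon Brassicaceae-like neutral model
#'
#' Nine leaves with an HKY-style rate matrix (transition/transversion ratio
#' 2) and mildly AT-rich base composition; used to seed tests and the
#' synthetic-data generator.
#'
#' @return A `neutral_model`.
#' @export
default_neutral_model <- function() {
  tre <- paste0(
    "(((((Athaliana:0.06,Alyrata:0.06):0.04,Crubella:0.10):0.05,",
    "Lalabamica:0.15):0.03,(Sirio:0.12,(Brapa:0.10,Esalsugineum:0.10):0.04):0.05):0.02,",
    "(Sparvula:0.18,Aarabicum:0.20):0.02);"
  )
  neutral_model(tre, exchangeabilities = c(1, 2, 1, 1, 2, 1),
                base_freqs = c(0.32, 0.18, 0.18, 0.32))
}
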