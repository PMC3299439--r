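NUC <- c("A", "C", "G", "T")

#' Jukes-Cantor single-edge transition matrix
#'
#' Under the Jukes-Cantor model a site changes state on an edge with
#' probability p, and when it changes it moves to each of the other three
#' nucleotides with equal probability. The transition matrix therefore has
#' `1 - p` on the diagonal and `p/3` off it. At the saturation boundary
#' p = 3/4 every entry equals 1/4 and the edge carries no information.
#'
#' @param p substitution probability on the edge, in \[0, 3/4\].
#' @return a 4x4 row-stochastic matrix with rows/columns A, C, G, T.
#' @examples
#' jc_edge_transition(0.3)
#' @export
jc_edge_transition <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 0.75)
    stop("substitution probability must be a single value in [0, 3/4]")
  m <- matrix(p / 3, 4, 4, dimnames = list(NUC, NUC))
  diag(m) <- 1 - p
  m
}

# Leaf partial-likelihood vectors: a base is a unit vector, a gap is all
# ones (missing data: the leaf is marginalized over A,C,G,T).
leaf_partials <- function(chars) {
  npat <- length(chars)
  out <- matrix(0, 4, npat)
  gap <- chars == GAP
  out[, gap] <- 1
  j <- which(!gap)
  out[cbind(match(chars[j], NUC), j)] <- 1
  out
}

# Pruning (dynamic-programming) likelihood over site patterns.
# pattern_mat: character matrix, rows in tree tip-label order, one column
# per distinct site pattern. Returns per-pattern log-likelihoods.
# Partial vectors are kept in linear space and rescaled per pattern when
# they underflow; the rescaling constants are re-applied in log space.
jc_pattern_logliks <- function(tree, pattern_mat, tip_part = NULL) {
  r <- jc_pattern_root(tree, pattern_mat, tip_part)
  log(r$lik) + r$logscale
}

# tip_part: optional precomputed list of per-tip 4 x npat leaf partial
# matrices (indexed by tip number), so repeated evaluations on the same
# topology/alignment skip rebuilding them.
jc_pattern_root <- function(tree, pattern_mat, tip_part = NULL) {
  check_edge_probs(tree)
  if (is.null(tree$edge.length))
    stop("tree has no edge substitution probabilities; use set_edge_params()")
  n_tip <- length(tree$tip.label)
  npat <- if (is.null(pattern_mat)) ncol(tip_part[[1]]) else ncol(pattern_mat)
  tr <- stats::reorder(tree, "postorder")
  n_node <- n_tip + tr$Nnode
  part <- vector("list", n_node)
  logscale <- numeric(npat)
  for (k in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[k, 1]
    child <- tr$edge[k, 2]
    cp <- if (child > n_tip) part[[child]]
          else if (!is.null(tip_part)) tip_part[[child]]
          else leaf_partials(pattern_mat[child, ])
    p_e <- tr$edge.length[k]
    P <- matrix(p_e / 3, 4, 4)
    diag(P) <- 1 - p_e
    m <- P %*% cp
    part[[parent]] <- if (is.null(part[[parent]])) m else part[[parent]] * m
    if (min(part[[parent]]) < 1e-280 && max(part[[parent]]) > 0) {
      mx <- apply(part[[parent]], 2, max)
      low <- which(mx < 1e-280 & mx > 0)
      if (length(low)) {
        part[[parent]][, low] <- part[[parent]][, low, drop = FALSE] /
          rep(mx[low], each = 4)
        logscale[low] <- logscale[low] + log(mx[low])
      }
    }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  list(lik = 0.25 * colSums(part[[root]]), logscale = logscale)
}

#' Likelihood of a single alignment column
#'
#' Computes the probability of one site under the Jukes-Cantor model on a
#' tree with fixed edge substitution probabilities, with gaps treated as
#' missing data: a gapped leaf contributes an all-ones partial vector,
#' which is equivalent to summing the gap-free column likelihood over the
#' four possible nucleotides at that leaf. The root state is uniform over
#' A, C, G, T.
#'
#' @param tree a `phylo` object with edge parameters (see
#'   [set_edge_params()]).
#' @param column a named character vector over `{A,C,G,T,-}`, names matching
#'   the tree's leaf labels.
#' @param treatment must be `"missing_data"`; stripping gapped sites is an
#'   alignment-level transform (see [strip_gapped_sites()]).
#' @return the column probability, in \[0, 1\].
#' @examples
#' tr <- set_edge_params(parse_newick("(a,b);"), 0)
#' column_likelihood(tr, c(a = "A", b = "-"))  # 1/4
#' @export
column_likelihood <- function(tree, column, treatment = "missing_data") {
  treatment <- match.arg(treatment, "missing_data")
  if (is.null(names(column)) || !setequal(names(column), tree$tip.label))
    stop("column must be named by exactly the tree's leaf labels")
  bad <- setdiff(unique(column), ALPHABET)
  if (length(bad)) stop("invalid characters in column: ",
                        paste(bad, collapse = ", "))
  mat <- matrix(toupper(column[tree$tip.label]), ncol = 1)
  r <- jc_pattern_root(tree, mat)
  unname(r$lik * exp(r$logscale))
}

#' Log-likelihood of an alignment on a tree
#'
#' Sites are independent and identically distributed, so the alignment
#' log-likelihood is the sum of per-column log-likelihoods. Identical site
#' patterns are collapsed and weighted before the pruning pass, so long
#' alignments with few distinct patterns are cheap.
#'
#' If `treatment = "strip_gapped_sites"` every column containing a gap is
#' removed first; should this empty the alignment, the log-likelihood of the
#' empty product is 0 (probability 1) and the result carries the attribute
#' `degenerate = TRUE`.
#'
#' @param tree a `phylo` object with edge parameters.
#' @param aln a `gapml_alignment` whose taxa equal the tree's leaf set.
#' @param treatment `"missing_data"` (gapped leaves marginalized over the
#'   four nucleotides) or `"strip_gapped_sites"`.
#' @return the log-likelihood (a single number); attribute `degenerate` is
#'   TRUE when the treated alignment has zero sites.
#' @export
alignment_log_likelihood <- function(tree, aln,
                                     treatment = c("missing_data",
                                                   "strip_gapped_sites")) {
  treatment <- match.arg(treatment)
  if (!setequal(rownames(aln), tree$tip.label))
    stop("alignment taxa must equal the tree's leaf set")
  if (treatment == "strip_gapped_sites") aln <- strip_gapped_sites(aln)
  if (ncol(aln) == 0L)
    return(structure(0, degenerate = TRUE))
  mat <- unclass(aln)[tree$tip.label, , drop = FALSE]
  key <- apply(mat, 2, paste, collapse = "")
  uniq <- !duplicated(key)
  w <- as.vector(table(key)[key[uniq]])
  ll <- jc_pattern_logliks(tree, mat[, uniq, drop = FALSE])
  sum(w * ll)
}
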