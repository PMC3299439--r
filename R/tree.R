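#' Parse a Newick string into a phylogenetic tree
#'
#' Trees are stored as [ape::phylo] objects. Branch "lengths", if present in
#' the Newick text, are interpreted as per-edge Jukes-Cantor substitution
#' probabilities p(e) and must lie in the closed interval \[0, 3/4\]; they are
#' probabilities, not expected numbers of substitutions.
#'
#' @param text a single Newick string (with terminating semicolon).
#' @return an object of class `phylo`. `edge.length`, when present, carries
#'   the substitution probabilities.
#' @examples
#' tr <- parse_newick("(a,b,(c,d));")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced parentheses in Newick string at position ", i)
  }
  if (depth != 0L)
    stop("unbalanced parentheses in Newick string: ", depth,
         " unclosed '(' at end of input")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  check_edge_probs(tree)
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object; `edge.length`, if present, is written as the
#'   branch annotation (substitution probabilities).
#' @param digits significant digits for edge parameters.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 17) {
  ape::write.tree(tree, digits = digits)
}

#' Check that edge parameters are valid substitution probabilities
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly; errors if any p(e) lies outside \[0, 3/4\].
#' @keywords internal
check_edge_probs <- function(tree) {
  p <- tree$edge.length
  if (!is.null(p)) {
    bad <- which(!is.finite(p) | p < 0 | p > 0.75)
    if (length(bad))
      stop("edge substitution probabilities must lie in [0, 3/4]; ",
           "offending edge index ", bad[1], " has p = ", p[bad[1]])
  }
  invisible(tree)
}

#' Set all edge substitution probabilities of a tree
#'
#' @param tree a `phylo` object.
#' @param p a scalar or vector (one value per row of `tree$edge`) in
#'   \[0, 3/4\].
#' @return the tree with `edge.length` set to `p`.
#' @export
set_edge_params <- function(tree, p) {
  n_edge <- nrow(tree$edge)
  p <- rep_len(as.numeric(p), n_edge)
  tree$edge.length <- p
  check_edge_probs(tree)
  tree
}

#' Enumerate all unrooted binary topologies on a taxon set
#'
#' Generates every distinct unrooted binary tree shape on the given taxa,
#' exactly once. The number of such topologies on n taxa is the double
#' factorial (2n-5)!!, so exhaustive enumeration is only feasible for small
#' n; the function refuses n > 8 (10395 topologies) by default.
#'
#' @param taxa character vector of unique taxon labels (n >= 3), or a single
#'   integer n (labels `t1..tn` are generated).
#' @param max_taxa enumeration guard; raise deliberately if you accept the
#'   combinatorial cost.
#' @return a list of `phylo` objects in a deterministic canonical order
#'   (sorted by canonical Newick string), without edge parameters.
#' @examples
#' length(enumerate_unrooted_topologies(c("a", "b", "c", "d")))  # 3
#' @export
enumerate_unrooted_topologies <- function(taxa, max_taxa = 8) {
  if (is.numeric(taxa) && length(taxa) == 1L)
    taxa <- paste0("t", seq_len(taxa))
  taxa <- as.character(taxa)
  n <- length(taxa)
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  if (n < 3L) stop("need at least 3 taxa to enumerate unrooted topologies")
  if (n > max_taxa)
    stop("refusing to enumerate ", n, " taxa (", num_unrooted_topologies(n),
         " topologies); heuristic search is out of scope")
  all_t <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  trees <- lapply(seq_along(all_t), function(i) all_t[[i]])
  ord <- order(vapply(trees, canonical_newick, character(1)))
  trees[ord]
}

#' Number of unrooted binary topologies on n taxa
#'
#' The double factorial (2n-5)!! for n >= 3.
#'
#' @param n number of taxa.
#' @return an integer-valued count.
#' @export
num_unrooted_topologies <- function(n) {
  stopifnot(n >= 3)
  k <- seq(from = 1, to = 2 * n - 5, by = 2)
  prod(k)
}

#' Canonical Newick string of a topology
#'
#' Rotation-invariant representation: the unrooted tree is re-rooted on the
#' lexicographically smallest leaf, and at every internal node the subtrees
#' are ordered by the smallest leaf label they contain. Two trees have the
#' same canonical string iff they share the same unrooted topology (and leaf
#' set). Edge parameters are ignored.
#'
#' @param tree a `phylo` object.
#' @return a single string.
#' @export
canonical_newick <- function(tree) {
  n_tip <- length(tree$tip.label)
  if (n_tip == 2L) {
    return(paste0("(", paste(sort(tree$tip.label), collapse = ","), ");"))
  }
  tree <- ape::unroot(tree)
  n_node <- n_tip + tree$Nnode
  adj <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  rec <- function(node, parent) {
    if (node <= n_tip) {
      lab <- tree$tip.label[node]
      return(list(str = lab, min = lab))
    }
    kids <- setdiff(adj[[node]], parent)
    parts <- lapply(kids, rec, parent = node)
    ord <- order(vapply(parts, `[[`, character(1), "min"))
    parts <- parts[ord]
    list(str = paste0("(", paste(vapply(parts, `[[`, character(1), "str"),
                                 collapse = ","), ")"),
         min = parts[[1]]$min)
  }
  s <- which(tree$tip.label == min(tree$tip.label))[1]
  rest <- rec(adj[[s]][1], parent = s)
  paste0("(", tree$tip.label[s], ",", rest$str, ");")
}

#' Robinson-Foulds distance between two topologies
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' trees. Zero iff the unrooted topologies are identical; at most 2(n-3)
#' for binary trees.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return a non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Test whether two trees share the same unrooted topology
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return logical.
#' @export
same_topology <- function(t1, t2) {
  rf_distance(t1, t2) == 0L
}
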