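# Independent oracles and generators used across the suite. These
# deliberately avoid the package's pruning/Fitch code paths: likelihoods are
# brute-force sums over internal-node state assignments, parsimony scores
# brute-force minima over internal labelings.

NUC4 <- c("A", "C", "G", "T")

# P(column | tree) by explicit enumeration of all 4^(internal nodes) state
# assignments. Gapped leaves contribute factor 1 (missing data).
brute_force_column_likelihood <- function(tree, column) {
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  internal <- (n_tip + 1):n_node
  trans <- function(from, to, p) if (from == to) 1 - p else p / 3
  grid <- expand.grid(rep(list(NUC4), length(internal)),
                      stringsAsFactors = FALSE)
  root <- tr$edge[nrow(tr$edge), 1]
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- character(n_node)
    st[internal] <- unlist(grid[g, ])
    prob <- 0.25  # uniform root prior on the assigned root state
    for (k in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[k, 1]; child <- tr$edge[k, 2]
      p <- tr$edge.length[k]
      if (child <= n_tip) {
        obs <- column[[tr$tip.label[child]]]
        if (obs == "-") next
        prob <- prob * trans(st[parent], obs, p)
      } else {
        prob <- prob * trans(st[parent], st[child], p)
      }
    }
    total <- total + prob
  }
  total
}

# Minimum state changes of one binary character by enumeration of all
# 2^(internal nodes) internal labelings.
brute_force_binary_parsimony <- function(tree, char) {
  tr <- stats::reorder(ape::unroot(tree), "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  internal <- (n_tip + 1):n_node
  grid <- expand.grid(rep(list(c(0L, 1L)), length(internal)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- integer(n_node)
    st[internal] <- unlist(grid[g, ])
    st[seq_len(n_tip)] <- char[tr$tip.label]
    changes <- sum(st[tr$edge[, 1]] != st[tr$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Random unrooted binary topology with uniform-ish edge substitution
# probabilities.
random_tree <- function(n, p_range = c(0.02, 0.6)) {
  tr <- ape::unroot(ape::rtree(n, tip.label = paste0("t", seq_len(n))))
  tr$edge.length <- stats::runif(nrow(tr$edge), p_range[1], p_range[2])
  tr
}

# Random monotypic alignment: each column one nucleotide type carried by a
# random non-empty taxon subset.
random_monotypic_alignment <- function(n, R) {
  taxa <- paste0("t", seq_len(n))
  mat <- matrix("-", n, R, dimnames = list(taxa, NULL))
  for (j in seq_len(R)) {
    carriers <- sample(n, sample(n, 1))
    mat[carriers, j] <- sample(NUC4, 1)
  }
  alignment(mat)
}

# Random gapped (not necessarily monotypic) column on given taxa.
random_column <- function(taxa, n_gaps = 1) {
  col <- sample(NUC4, length(taxa), replace = TRUE)
  if (n_gaps > 0) col[sample(length(taxa), n_gaps)] <- "-"
  names(col) <- taxa
  col
}
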