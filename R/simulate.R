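# Deterministic 31-bit string hash (polynomial rolling hash). Used to give
# every edge of the simulation tree its own reproducible RNG substream, so
# results cannot depend on traversal or iteration order.
hash31 <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Configure a substitution + indel simulation
#'
#' Describes sequence evolution down a fixed tree: Jukes-Cantor
#' substitutions with per-edge probability `p`, single-residue deletions
#' with per-site, per-edge probability `d`, and (optionally) single-residue
#' insertions with per-slot, per-edge probability `i`. Setting `p = 0`
#' with `d > 0` is the indel-only regime, which always produces monotypic
#' alignments.
#'
#' @param tree a `phylo` object (the true tree); edge parameters on the
#'   tree itself are ignored in favor of `p`.
#' @param p substitution probability per edge (scalar or one value per edge
#'   row), in \[0, 3/4\].
#' @param d deletion probability per site per edge, in \[0, 1\].
#' @param i insertion probability per slot per edge, in \[0, 1).
#' @param root_length number of sites in the root sequence (L >= 1).
#' @param seed integer RNG seed.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(tree, p = 0, d = 0, i = 0, root_length,
                              seed = 1L) {
  n_edge <- nrow(tree$edge)
  p <- rep_len(as.numeric(p), n_edge)
  d <- rep_len(as.numeric(d), n_edge)
  i <- rep_len(as.numeric(i), n_edge)
  if (any(!is.finite(p)) || any(p < 0 | p > 0.75))
    stop("substitution probabilities must lie in [0, 3/4]")
  if (any(!is.finite(d)) || any(d < 0 | d > 1))
    stop("deletion probabilities must lie in [0, 1]")
  if (any(!is.finite(i)) || any(i < 0 | i >= 1))
    stop("insertion probabilities must lie in [0, 1)")
  if (root_length < 1) stop("root sequence length must be >= 1")
  structure(list(tree = tree, p = p, d = d, i = i,
                 root_length = as.integer(root_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate sequence evolution with substitutions and indels
#'
#' Evolves a uniform-random root sequence of length L down the configured
#' tree. On each edge, each inherited site is first deleted with probability
#' `d(e)`; surviving sites then substitute with probability `p(e)`, moving
#' to one of the other three nucleotides uniformly. Optionally, each of the
#' m+1 junctions of the m surviving sites gains a newly inserted site with
#' probability `i(e)`. Deletion is irreversible within a lineage and an
#' insertion founds a fresh homology column, so positional homology is known
#' exactly: the returned alignment is the true alignment, with one column
#' per homology class (ordered by ancestral position) and a gap wherever a
#' lineage lacks the residue. Columns surviving in no leaf are dropped.
#'
#' Each edge draws from its own RNG substream seeded by a hash of the global
#' seed and the edge's descendant clade, so the output is reproducible and
#' independent of traversal order.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return an object of class `sim_result`: list with `alignment` (the true
#'   alignment, a `gapml_alignment`), `tree` (the true tree), `events`
#'   (per-edge counts of substitutions, deletions, insertions) and `config`.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  tree <- stats::reorder(config$tree, "cladewise")
  # reorder permutes edge rows; carry the per-edge parameters along
  key_new <- paste(tree$edge[, 1], tree$edge[, 2])
  key_old <- paste(config$tree$edge[, 1], config$tree$edge[, 2])
  idx <- match(key_new, key_old)
  p <- config$p[idx]; d <- config$d[idx]; i <- config$i[idx]
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # descendant-clade label per node, for stable edge substreams
  clade <- character(n_node)
  clade[seq_len(n_tip)] <- tree$tip.label
  for (k in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    clade[parent] <- paste(sort(c(strsplit(clade[parent], "|",
                                           fixed = TRUE)[[1]],
                                  strsplit(clade[child], "|",
                                           fixed = TRUE)[[1]])),
                           collapse = "|")
  }
  set.seed(config$seed)
  L <- config$root_length
  root_seq <- data.frame(id = seq_len(L), pos = as.numeric(seq_len(L)),
                         state = sample(NUC, L, replace = TRUE))
  next_id <- L + 1L
  seqs <- vector("list", n_node)
  root <- tree$edge[1, 1]
  seqs[[root]] <- root_seq
  events <- data.frame(edge = character(0), substitutions = integer(0),
                       deletions = integer(0), insertions = integer(0))
  for (k in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    set.seed(hash31(paste(config$seed, clade[child], sep = "@")))
    s <- seqs[[parent]]
    n0 <- nrow(s)
    keep <- stats::runif(n0) >= d[k]
    n_del <- sum(!keep)
    s <- s[keep, , drop = FALSE]
    m <- nrow(s)
    sub <- stats::runif(m) < p[k]
    n_sub <- sum(sub)
    if (n_sub) {
      s$state[sub] <- vapply(s$state[sub], function(x)
        sample(setdiff(NUC, x), 1L), character(1))
    }
    n_ins <- 0L
    if (i[k] > 0) {
      bounds <- c(if (m) min(s$pos) - 1 else 0,
                  s$pos,
                  if (m) max(s$pos) + 1 else 1)
      slots <- which(stats::runif(m + 1L) < i[k])
      for (sl in slots) {
        new_pos <- (bounds[sl] + bounds[sl + 1L]) / 2
        s <- rbind(s, data.frame(id = next_id, pos = new_pos,
                                 state = sample(NUC, 1L)))
        next_id <- next_id + 1L
        n_ins <- n_ins + 1L
      }
      s <- s[order(s$pos, s$id), , drop = FALSE]
    }
    seqs[[child]] <- s
    events <- rbind(events,
                    data.frame(edge = clade[child], substitutions = n_sub,
                               deletions = n_del, insertions = n_ins))
  }
  # assemble the true alignment: columns = homology classes seen in >=1 leaf
  leaf_seqs <- seqs[seq_len(n_tip)]
  all_cols <- unique(do.call(rbind, lapply(leaf_seqs,
                                           function(s) s[, c("id", "pos")])))
  all_cols <- all_cols[order(all_cols$pos, all_cols$id), , drop = FALSE]
  mat <- matrix(GAP, nrow = n_tip, ncol = nrow(all_cols),
                dimnames = list(tree$tip.label, NULL))
  for (t in seq_len(n_tip)) {
    hit <- match(leaf_seqs[[t]]$id, all_cols$id)
    mat[t, hit] <- leaf_seqs[[t]]$state
  }
  structure(list(alignment = alignment(mat), tree = config$tree,
                 events = events, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("simulated alignment:", nrow(x$alignment), "taxa x",
      ncol(x$alignment), "sites (seed ", x$config$seed, ")\n")
  cat("events:", sum(x$events$substitutions), "substitutions,",
      sum(x$events$deletions), "deletions,",
      sum(x$events$insertions), "insertions\n")
  invisible(x)
}

#' The worked 7-taxon monotypic example alignment
#'
#' A 7-sequence, 3-site alignment in which every column shows a single
#' nucleotide type among its non-gap entries, two rows are entirely gapped,
#' and every column contains at least one gap — so stripping gapped sites
#' leaves nothing. Despite being monotypic it still carries gap-pattern
#' signal (sites 0 groups s1, s3, s7).
#'
#' @return a `gapml_alignment` with rows s1..s7.
#' @examples
#' printed_alignment_fixture()
#' @export
printed_alignment_fixture <- function() {
  alignment(c(s1 = "A--", s2 = "-C-", s3 = "A--", s4 = "---",
              s5 = "---", s6 = "--T", s7 = "A--"))
}
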