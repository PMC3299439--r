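# Build a fast log-likelihood evaluator for a fixed topology/alignment.
# Site patterns are collapsed once; the returned function maps an edge
# parameter vector (ordered like the postorder tree's edge rows) to the
# alignment log-likelihood.
make_loglik_fun <- function(topology, aln, treatment) {
  if (!setequal(rownames(aln), topology$tip.label))
    stop("alignment taxa must equal the topology's leaf set")
  if (treatment == "strip_gapped_sites") aln <- strip_gapped_sites(aln)
  tr <- stats::reorder(topology, "postorder")
  if (ncol(aln) == 0L)
    return(list(tree = tr, fn = NULL, degenerate = TRUE))
  mat <- unclass(aln)[tr$tip.label, , drop = FALSE]
  key <- apply(mat, 2, paste, collapse = "")
  uniq <- !duplicated(key)
  w <- as.vector(table(key)[key[uniq]])
  mat <- mat[, uniq, drop = FALSE]
  tip_part <- lapply(seq_len(nrow(mat)), function(i) leaf_partials(mat[i, ]))
  pat_fn <- function(pvec) {
    tr$edge.length <- pvec
    jc_pattern_logliks(tr, mat, tip_part)
  }
  fn <- function(pvec) sum(w * pat_fn(pvec))
  list(tree = tr, fn = fn, pat_fn = pat_fn, w = w, degenerate = FALSE)
}

# Deterministic multistart grid: three constant starts plus one fixed
# quasi-random vector (no RNG involved, so results cannot depend on call
# order).
default_starts <- function(n_edge) {
  list(rep(0.01, n_edge),
       rep(0.1, n_edge),
       rep(0.3, n_edge),
       0.02 + (seq_len(n_edge) * 0.2843) %% 0.7)
}

#' Maximize the Jukes-Cantor likelihood over edge parameters
#'
#' For a fixed topology, finds the edge substitution probabilities in the
#' closed box \[0, 3/4\]^E that maximize the alignment log-likelihood. The
#' open-interval supremum of the model equals this maximum by continuity;
#' optima sitting on the box boundary (p = 0 or p = 3/4), where the open
#' model only approaches its supremum, are reported through boundary flags.
#'
#' The optimizer is per-edge coordinate ascent with bounded scalar
#' optimization, restarted from a fixed multistart grid; after each scalar
#' optimization the two boundary values are probed explicitly so boundary
#' optima are found exactly, not as numerical limits.
#'
#' @param topology a `phylo` object (edge parameters, if any, are ignored).
#' @param aln a `gapml_alignment` on the same taxa.
#' @param treatment gap treatment, `"missing_data"` or
#'   `"strip_gapped_sites"`.
#' @param starts list of starting edge-parameter vectors; default a fixed
#'   4-point grid.
#' @param tol convergence tolerance on the log-likelihood between sweeps.
#' @param max_sweeps cap on coordinate-ascent sweeps per start.
#' @return an object of class `jc_ml_fit`: list with `tree` (postorder, with
#'   optimized `edge.length`), `log_likelihood`, `edge_params`,
#'   `at_lower`/`at_upper` boundary flags per edge, `degenerate`, and
#'   `treatment`. If stripping gaps empties the alignment the fit is
#'   degenerate with log-likelihood 0 and a warning is issued.
#' @export
optimize_edge_params <- function(topology, aln,
                                 treatment = c("missing_data",
                                               "strip_gapped_sites"),
                                 starts = NULL, tol = 1e-10,
                                 max_sweeps = 50L) {
  treatment <- match.arg(treatment)
  obj <- make_loglik_fun(topology, aln, treatment)
  tr <- obj$tree
  n_edge <- nrow(tr$edge)
  if (obj$degenerate) {
    warning("alignment has no sites after gap treatment; ",
            "likelihood is the empty product (log-likelihood 0)")
    tr$edge.length <- rep(0, n_edge)
    return(structure(list(tree = tr, log_likelihood = 0,
                          edge_params = rep(NA_real_, n_edge),
                          at_lower = rep(NA, n_edge),
                          at_upper = rep(NA, n_edge),
                          degenerate = TRUE, treatment = treatment),
                     class = "jc_ml_fit"))
  }
  f <- obj$fn
  pat_f <- obj$pat_fn
  w <- obj$w
  if (is.null(starts)) starts <- default_starts(n_edge)
  best_p <- NULL
  best_ll <- -Inf
  for (p0 in starts) {
    p <- rep_len(p0, n_edge)
    ll <- f(p)
    for (sweep in seq_len(max_sweeps)) {
      ll_before <- ll
      for (e in seq_len(n_edge)) {
        # each pattern's likelihood is affine in this edge's p (the pruning
        # recursion is multilinear in transition-matrix entries), so two
        # pruning passes determine the whole 1-D profile exactly
        la <- exp(pat_f(replace(p, e, 0)))
        lb <- exp(pat_f(replace(p, e, 0.75)))
        slope <- (lb - la) / 0.75
        g <- function(x) sum(w * log(la + slope * x))
        opt <- stats::optimize(g, c(0, 0.75), maximum = TRUE, tol = 1e-9)
        cand_x <- c(opt$maximum, 0, 0.75)
        cand_ll <- c(opt$objective, sum(w * log(la)), sum(w * log(lb)))
        k <- which.max(cand_ll)
        if (cand_ll[k] > ll) {
          p[e] <- cand_x[k]
          ll <- cand_ll[k]
        }
      }
      if (ll - ll_before <= tol) break
    }
    if (ll > best_ll) {
      best_ll <- ll
      best_p <- p
    }
  }
  tr$edge.length <- best_p
  # final score from a direct pruning evaluation at the optimum, so the
  # reported value does not inherit round-off from the profile shortcut
  best_ll <- f(best_p)
  structure(list(tree = tr, log_likelihood = best_ll, edge_params = best_p,
                 at_lower = best_p == 0, at_upper = best_p == 0.75,
                 degenerate = FALSE, treatment = treatment),
            class = "jc_ml_fit")
}

#' @export
print.jc_ml_fit <- function(x, ...) {
  cat("JC maximum-likelihood fit (gaps:", x$treatment, ")\n")
  cat("log-likelihood:", format(x$log_likelihood, digits = 12), "\n")
  cat("edge params:", paste(signif(x$edge_params, 4), collapse = " "), "\n")
  if (any(x$at_lower %in% TRUE) || any(x$at_upper %in% TRUE))
    cat("boundary optima:", sum(x$at_lower %in% TRUE), "edge(s) at p=0,",
        sum(x$at_upper %in% TRUE), "at p=3/4\n")
  invisible(x)
}

#' Exhaustive maximum-likelihood tree search
#'
#' Evaluates the supremum Jukes-Cantor likelihood on every unrooted binary
#' topology for the alignment's taxa and returns all topologies whose score
#' ties the best within a relative tolerance. Because exhaustive enumeration
#' grows as (2n-5)!!, the search is limited to at most `max_taxa` taxa.
#'
#' @param aln a `gapml_alignment` (3 to `max_taxa` taxa).
#' @param treatment gap treatment passed to [optimize_edge_params()].
#' @param tie_tol relative log-likelihood tolerance for membership in the
#'   optimal set: a topology is optimal when
#'   `best - ll <= tie_tol * max(1, |best|)`.
#' @param max_taxa enumeration guard (default 8).
#' @param ... further arguments to [optimize_edge_params()].
#' @return an object of class `ml_search_result`: list with `fits` (one
#'   `jc_ml_fit` per topology, canonical order), `log_likelihoods`,
#'   `best_log_likelihood`, `optimal_idx`, `optimal` (the tied topologies),
#'   `tie_tol` and `treatment`.
#' @export
exhaustive_ml <- function(aln, treatment = c("missing_data",
                                             "strip_gapped_sites"),
                          tie_tol = 1e-9, max_taxa = 8, ...) {
  treatment <- match.arg(treatment)
  n <- nrow(aln)
  if (n < 3) stop("need at least 3 taxa")
  topologies <- enumerate_unrooted_topologies(rownames(aln),
                                              max_taxa = max_taxa)
  fits <- lapply(topologies, optimize_edge_params, aln = aln,
                 treatment = treatment, ...)
  ll <- vapply(fits, `[[`, numeric(1), "log_likelihood")
  best <- max(ll)
  opt <- which(best - ll <= tie_tol * max(1, abs(best)))
  structure(list(fits = fits, log_likelihoods = ll,
                 best_log_likelihood = best, optimal_idx = opt,
                 optimal = topologies[opt], tie_tol = tie_tol,
                 treatment = treatment),
            class = "ml_search_result")
}

#' @export
print.ml_search_result <- function(x, ...) {
  cat("exhaustive JC ML search over", length(x$fits), "topologies\n")
  cat("best log-likelihood:", format(x$best_log_likelihood, digits = 12),
      "\n")
  cat("optimal set:", length(x$optimal_idx), "of", length(x$fits),
      "topologies (relative tie tolerance ", x$tie_tol, ")\n")
  invisible(x)
}
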