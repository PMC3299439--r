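#' Verify the flat-likelihood property on a monotypic alignment
#'
#' For a monotypic alignment (every column a single nucleotide type among
#' its non-gap entries), the supremum Jukes-Cantor likelihood with gaps as
#' missing data is (1/4)^R on every topology, attained in the limit of all
#' edge substitution probabilities going to 0: with no substitutions, each
#' column's probability is just the chance of drawing its one nucleotide at
#' the root, 1/4. This function checks that claim exhaustively: it evaluates
#' every unrooted topology at p(e) = 0 and requires bit-exact equality of
#' the log-likelihood with R*log(1/4); optionally, the numerical optimizer
#' is run on a subset of topologies to confirm no interior parameter point
#' does better.
#'
#' @param aln a monotypic `gapml_alignment`.
#' @param optimizer_check number of topologies (evenly spaced through the
#'   canonical ordering) on which to also run [optimize_edge_params()]; 0
#'   disables the check.
#' @param opt_tol tolerance (log units) for the optimizer confirmation.
#' @param max_taxa enumeration guard.
#' @return a list with `records` (per-topology data frame: canonical Newick,
#'   log-likelihood at p = 0, exactness flag, optional optimizer score and
#'   flag), `R`, `expected_log_likelihood`, `n_topologies`, `all_exact`,
#'   and `all_optimizer_ok`.
#' @export
verify_lemma1 <- function(aln, optimizer_check = 0L, opt_tol = 1e-9,
                          max_taxa = 8) {
  if (!is_monotypic(aln))
    stop("alignment is not monotypic; the flat-likelihood property only ",
         "applies to monotypic alignments")
  R <- ncol(aln)
  expected <- R * log(0.25)
  topologies <- enumerate_unrooted_topologies(rownames(aln),
                                              max_taxa = max_taxa)
  ll0 <- vapply(topologies, function(t)
    alignment_log_likelihood(set_edge_params(t, 0), aln, "missing_data"),
    numeric(1))
  records <- data.frame(
    topology = vapply(topologies, canonical_newick, character(1)),
    loglik_p0 = ll0,
    exact = ll0 == expected,
    opt_loglik = NA_real_,
    opt_ok = NA)
  if (optimizer_check > 0L) {
    idx <- unique(round(seq(1, length(topologies),
                            length.out = min(optimizer_check,
                                             length(topologies)))))
    for (j in idx) {
      fit <- optimize_edge_params(topologies[[j]], aln, "missing_data")
      records$opt_loglik[j] <- fit$log_likelihood
      records$opt_ok[j] <- abs(fit$log_likelihood - expected) <= opt_tol
    }
  }
  list(records = records, R = R, expected_log_likelihood = expected,
       n_topologies = length(topologies),
       all_exact = all(records$exact),
       all_optimizer_ok = all(records$opt_ok[!is.na(records$opt_ok)]))
}

rep_seed <- function(seed, ...) {
  hash31(paste(seed, ..., sep = "/"))
}

#' Indel-only inconsistency experiment
#'
#' Simulates evolution on a true tree with zero substitution probability and
#' a per-edge deletion probability, so every replicate alignment is
#' monotypic, then contrasts the two analyses of the same true alignment:
#' exhaustive maximum likelihood treating gaps as missing data (whose
#' likelihood surface over topologies is flat, so the optimal set is all
#' topologies and the true tree cannot be identified no matter how long the
#' sequences), and Fitch parsimony on the binary gap coding of the gapped
#' columns (which favors topologies compatible with the deletion history).
#'
#' @param tree the true tree (`phylo`).
#' @param d per-edge, per-site deletion probability.
#' @param L root sequence length.
#' @param replicates number of seeded replicates.
#' @param seed master seed; each replicate uses a derived substream.
#' @param p per-edge substitution probability (default 0, the indel-only
#'   regime; small values > 0 are allowed for exploration but void the
#'   flat-surface expectation).
#' @param tie_tol tie tolerance for the ML optimal set.
#' @return a list with `per_replicate` (data frame: seed, sites, monotypic
#'   flag, best log-likelihood, ML optimal-set size, topology count,
#'   flat-surface log-likelihood range, gap-signal optimal-set size,
#'   minimum RF distance from the gap-signal optimal set to the true tree,
#'   number of parsimony-informative gap characters, runtime) and `summary`.
#' @export
run_inconsistency_experiment <- function(tree, d = 0.15, L = 200,
                                         replicates = 20, seed = 1,
                                         p = 0, tie_tol = 1e-9) {
  if (replicates < 1) stop("need at least one replicate")
  n <- length(tree$tip.label)
  if (n > 7) stop("exhaustive search limited to 7 taxa in experiments")
  n_topo <- num_unrooted_topologies(n)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    t0 <- proc.time()[["elapsed"]]
    cfg <- simulation_config(tree, p = p, d = d, root_length = L,
                             seed = rep_seed(seed, "indel", r))
    sim <- simulate_alignment(cfg)
    aln <- sim$alignment
    mono <- is_monotypic(aln)
    res <- exhaustive_ml(aln, "missing_data", tie_tol = tie_tol)
    gc <- gap_code(aln)
    informative <- sum(apply(gc$matrix, 2, function(x)
      min(sum(x == 0), sum(x == 1)) >= 2))
    gt <- estimate_tree_from_gaps(gc)
    rf_min <- min(vapply(gt$optimal, rf_distance, integer(1), t2 = tree))
    rows[[r]] <- data.frame(
      replicate = r, seed = cfg$seed, sites = ncol(aln), monotypic = mono,
      best_loglik = res$best_log_likelihood,
      ml_optimal_size = length(res$optimal_idx),
      n_topologies = n_topo,
      loglik_range = max(res$log_likelihoods) - min(res$log_likelihoods),
      gap_optimal_size = length(gt$optimal_idx),
      gap_rf_min = rf_min,
      informative_gap_chars = informative,
      runtime_s = proc.time()[["elapsed"]] - t0)
  }
  per_replicate <- do.call(rbind, rows)
  summary <- list(
    replicates = replicates, taxa = n, d = d, L = L, p = p, seed = seed,
    all_monotypic = all(per_replicate$monotypic),
    ml_always_all_topologies =
      all(per_replicate$ml_optimal_size == n_topo),
    max_loglik_range = max(per_replicate$loglik_range),
    gap_subset_when_informative =
      all(per_replicate$gap_optimal_size[
        per_replicate$informative_gap_chars > 0] < n_topo),
    mean_gap_optimal_size = mean(per_replicate$gap_optimal_size),
    frac_gap_set_contains_truth = mean(per_replicate$gap_rf_min == 0))
  list(per_replicate = per_replicate, summary = summary)
}

#' Substitution-only consistency experiment
#'
#' The sanity-check counterpart of the indel-only experiment: sequences
#' evolve with substitutions but no indels, and exhaustive missing-data
#' maximum likelihood is expected to recover the true topology increasingly
#' often as sequences grow. Each replicate simulates once at the largest
#' length and truncates to the shorter lengths, so the length series is
#' nested within a replicate.
#'
#' @param tree the true tree (`phylo`).
#' @param p per-edge substitution probability.
#' @param L_grid increasing vector of alignment lengths.
#' @param replicates number of seeded replicates.
#' @param seed master seed.
#' @param tie_tol tie tolerance for the ML optimal set.
#' @return a list with `per_replicate` (data frame: replicate, L, recovered
#'   flag, optimal-set size, minimum RF distance of the optimal set to the
#'   truth) and `summary` (per-L recovery fraction and mean minimum RF).
#' @export
run_consistency_experiment <- function(tree, p = 0.05,
                                       L_grid = c(100, 500, 2000),
                                       replicates = 20, seed = 1,
                                       tie_tol = 1e-9) {
  L_grid <- sort(unique(as.integer(L_grid)))
  L_max <- max(L_grid)
  rows <- vector("list", 0L)
  for (r in seq_len(replicates)) {
    cfg <- simulation_config(tree, p = p, d = 0, root_length = L_max,
                             seed = rep_seed(seed, "subst", r))
    sim <- simulate_alignment(cfg)
    for (L in L_grid) {
      aln <- structure(unclass(sim$alignment)[, seq_len(L), drop = FALSE],
                       class = c("gapml_alignment", "matrix", "array"))
      res <- exhaustive_ml(aln, "missing_data", tie_tol = tie_tol)
      rf <- vapply(res$optimal, rf_distance, integer(1), t2 = tree)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, L = L,
        recovered = length(res$optimal_idx) == 1L && rf[1] == 0L,
        optimal_size = length(res$optimal_idx),
        rf_min = min(rf))
    }
  }
  per_replicate <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(L_grid, function(L) {
    sub <- per_replicate[per_replicate$L == L, ]
    data.frame(L = L, recovery = mean(sub$recovered),
               mean_rf_min = mean(sub$rf_min))
  }))
  list(per_replicate = per_replicate, summary = summary)
}
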