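#!/usr/bin/env Rscript
# The inconsistency regime: sequences evolve with deletions but zero
# substitution probability, so the true alignments are monotypic. No matter
# how long the sequences, missing-data ML scores every topology identically
# -- the estimator cannot converge to the true tree. The deletion pattern in
# the very same alignments, scored by Fitch parsimony on the binary gap
# coding, does separate topologies and usually pins down the truth.

suppressPackageStartupMessages(library(gapml))

dir.create("results", showWarnings = FALSE)
true_tree <- parse_newick("(((a,b),c),(d,e));")
cat("true tree:", write_newick(true_tree), "\n")
cat("condition: p = 0, d = 0.15, L = 200, 20 replicates, seed 2026\n\n")

ex <- run_inconsistency_experiment(true_tree, d = 0.15, L = 200,
                                   replicates = 20, seed = 2026)
s <- ex$summary
cat(sprintf("all replicates monotypic:            %s\n", s$all_monotypic))
cat(sprintf("ML optimal set always all 15 trees:  %s\n",
            s$ml_always_all_topologies))
cat(sprintf("max likelihood range over trees:     %g log units\n",
            s$max_loglik_range))
cat(sprintf("gap-signal set a strict subset when informative: %s\n",
            s$gap_subset_when_informative))
cat(sprintf("mean gap-signal optimal-set size:    %.2f of 15\n",
            s$mean_gap_optimal_size))
cat(sprintf("gap-signal set contains true tree:   %.0f%% of replicates\n",
            100 * s$frac_gap_set_contains_truth))

write.table(ex$per_replicate, "results/indel_only_per_replicate.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
jsonlite::write_json(s, "results/indel_only_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nper-replicate table -> results/indel_only_per_replicate.tsv\n")
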