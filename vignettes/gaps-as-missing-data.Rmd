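---
title: "Gaps as missing data: a flat likelihood surface and where the signal went"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaps as missing data: a flat likelihood surface and where the signal went}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapml)
```

## The question

Almost every likelihood-based phylogenetics program treats an alignment gap
as missing data: at a gapped leaf the site likelihood is summed over all
four nucleotides. This vignette walks through the model and the
computational machinery `gapml` uses to study a sharp consequence of that
convention: on *monotypic* alignments — alignments in which every column
shows a single nucleotide type among its non-gap entries and no column is
entirely gapped — the supremum Jukes-Cantor likelihood is $(1/4)^R$ for
*every* topology on the taxa, where $R$ is the number of sites. The
likelihood surface over tree space is perfectly flat, so maximum likelihood
cannot distinguish any tree from any other no matter how long the sequences
are. Since evolution with deletions but without substitutions generates
exactly such alignments, missing-data ML is not a statistically consistent
estimator under indel-only evolution, even when given the true alignment.
The same alignments are not phylogenetically uninformative, though: the gap
pattern itself separates topologies, which the package demonstrates with a
parsimony analysis of binary gap characters.

## Model and likelihood machinery

Under the Jukes-Cantor model a tree topology $T$ carries one substitution
probability $p(e)$ per edge; a site changes state on edge $e$ with
probability $p(e)$ and, conditional on changing, picks each of the other
three nucleotides with probability $1/3$. The root state is uniform on
$\{A,C,G,T\}$ and sites are i.i.d. The transition matrix on an edge is
therefore $1-p$ on the diagonal and $p/3$ off it; at $p = 3/4$ it is
uniform (saturation) and the edge carries no information.

The model as usually stated keeps $p(e)$ in the *open* interval
$(0, 3/4)$, so the supremum likelihood
$\sup_\theta P(A \mid T, \theta)$ need not be attained — for monotypic
alignments it is approached as all $p(e) \to 0$. `gapml` stores edge
parameters on the **closed** interval $[0, 3/4]$: the likelihood is
continuous in $\theta$, so the supremum over the open box equals the
maximum over its closure, and that maximum is representable and exactly
computable. Fits record per-edge boundary flags (`at_lower`, `at_upper`) so
the distinction between an attained interior maximum and a boundary
supremum is never lost.

Site likelihoods are computed by the pruning (dynamic-programming)
recursion, with three numerical commitments:

* a gapped leaf contributes the all-ones partial vector — algebraically
  identical to summing the gap-free likelihood over the four nucleotides at
  that leaf (this identity is property-tested at tolerance $10^{-12}$);
* $p(e) = 0$ uses the exact identity transition matrix, so the monotypic
  optimum $R \log(1/4)$ is reproduced *bit-exactly* in log space, not as a
  numerical limit;
* per-column partial vectors live in linear space and are rescaled only if
  an entry drops below $10^{-280}$, with the rescaling constants re-applied
  in log space; alignment log-likelihoods are sums of per-column logs.
  Identical site patterns are collapsed and weighted first, which is what
  makes 2000-site alignments cheap.

Only `-` is a gap. `N` and `?` are rejected outright: the analyses concern
indel gaps, and silently conflating ambiguity codes with indels would
change the question being asked. Entirely gapped rows are legal input
(the built-in 7-taxon example contains two) — under missing data such a row
contributes a factor 1 to every column.

## Optimization over edge parameters

For a fixed topology, `optimize_edge_params()` maximizes the
log-likelihood over the closed box by per-edge coordinate ascent. The key
structural fact is that the pruning likelihood is *multilinear* in the
transition-matrix entries, hence affine in any single edge's $p(e)$; two
pruning passes (at $p_e = 0$ and $p_e = 3/4$) therefore determine the whole
one-dimensional profile exactly, and the scalar maximization runs on that
closed form. Both interval endpoints are probed explicitly after each
scalar search, so boundary optima are found exactly rather than approached.
Sweeps stop when a full pass improves the log-likelihood by less than
$10^{-10}$.

The ascent restarts from a fixed four-point grid: all edges at 0.01, at
0.1, at 0.3, and one fixed quasi-random vector. The fourth start is
deterministic by design (a fixed low-discrepancy sequence rather than an
RNG draw) so that fits never depend on call order or global RNG state. On
4-taxon test problems the ascent matches an independent box-constrained
quasi-Newton optimizer to within $10^{-6}$ log units and is never beaten by
random probes of the box.

`exhaustive_ml()` runs this fit on every unrooted binary topology — there
are $(2n-5)!!$ of them, so enumeration is guarded at $n \le 8$ — and
returns every topology within a relative log-likelihood tie tolerance of
the best. The tolerance defaults to $10^{-9}$. No tolerance is inherent to
the "all trees optimal" statement itself: on monotypic alignments the
analytic scores are bit-identical, so the tolerance only absorbs optimizer
round-off; it is exposed as an argument, not buried.

## The worked example

```{r example, eval = FALSE}
aln <- printed_alignment_fixture()   # 7 taxa, 3 sites, every column gapped
verify_lemma1(aln)                   # all 945 topologies at 3*log(1/4), exact
exhaustive_ml(aln)                   # optimal set = all 945 topologies
estimate_tree_from_gaps(gap_code(aln))  # 45 of 945 topologies
```

Stripping gapped sites from this alignment leaves zero columns — the other
standard gap treatment degenerates to the empty product (log-likelihood 0,
flagged `degenerate`), which is why the package treats that outcome as a
warning-level result rather than an error.

## Gap coding and the contrast estimator

`gap_code()` turns every column containing at least one gap into one binary
presence/absence character (1 = nucleotide, 0 = gap), recording the 0-based
source column. The coded characters are kept strictly separate from the
nucleotide matrix — the two are never concatenated into a mixed analysis,
because no principled joint weighting of the two character types is on
offer here and the demonstration only needs the gap characters alone.

`gap_parsimony_scores()` scores a topology by two-state Fitch small
parsimony summed over characters (verified against brute-force enumeration
of internal labelings and against an independent parsimony implementation),
and `estimate_tree_from_gaps()` exhaustively returns all minimum-score
topologies, never an arbitrary tie-break. Parsimony was chosen as the
contrast method because it is the simplest estimator that exposes the
signal; this demonstrates that the gap pattern separates topologies — it
is *not* a claim that gap-coding parsimony is statistically consistent.

## What the simulator does and does not emulate

`simulate_alignment()` evolves a uniform-random root sequence of length
$L$ down a tree. Per edge, each inherited site is deleted with probability
$d(e)$; survivors substitute with probability $p(e)$; optionally each
junction between surviving sites gains an inserted site with probability
$i(e)$ (default 0). Deletion precedes substitution on an edge — one order
had to be fixed for reproducibility, and either order is a valid process.
Deletions are irreversible within a lineage and insertions found fresh
homology columns, so the emitted alignment is the *true* alignment with
positional homology known exactly; this matches the analyses, which always
condition on the true alignment. Every edge draws from its own RNG
substream keyed by a hash of the seed and the edge's descendant clade, so
results are reproducible and independent of iteration order.

This is deliberately the simplest indel process that can produce monotypic
alignments: single-residue events, no indel-length distribution, no
birth-death (TKF-style) machinery, no rate heterogeneity across sites, no
context dependence. Real indels come in multi-residue bursts with strongly
non-uniform length distributions, so passing tests here say nothing about
fit to real data — they say that *within* a model whose zero-substitution
regime provably yields flat likelihood surfaces, the package's estimators
behave exactly as the theory predicts. Conclusions tied to the specific
indel mechanism are properties of this simulator, not general claims.

In the zero-substitution regime every simulated alignment is monotypic by
construction (property-tested across random trees and configurations), which
is precisely the regime in which the flat-surface result applies to data of
unbounded length — the root of the inconsistency.

## Experiment design and scale

The bundled experiments run at a scale chosen for a single CPU while still
exercising the claims at full strength:

* *Indel-only* (`run_inconsistency_experiment()`): 5 taxa, $d = 0.15$,
  $L = 200$, 20 replicates. Each replicate checks monotypy, runs exhaustive
  missing-data ML (expecting the full 15-topology optimal set and a
  likelihood range of 0), and runs the gap-signal estimator (expecting a
  strict subset whenever an informative character exists).
* *Substitution-only* (`run_consistency_experiment()`): 5 taxa,
  $p = 0.05$, $L \in \{100, 500, 2000\}$, 20 replicates. Each replicate
  simulates once at $L = 2000$ and truncates to the shorter lengths, so the
  length series is nested and the recovery trend is not confounded by
  fresh randomness at each length.

Replicate seeds are derived from the master seed by the same stable hash
used for edge substreams, so reports are byte-reproducible and aggregation
is invariant to processing order.

## Limitations

* Exhaustive enumeration caps the taxon count at 8 (945 topologies at 7,
  10395 at 8); no heuristic tree search is provided.
* Only the Jukes-Cantor substitution model is implemented. The flat-surface
  argument extends to richer reversible models with a uniform stationary
  distribution at the analogous boundary, but nothing here verifies that.
* The gap-signal estimator demonstrates separation of topologies; its
  statistical properties (consistency, rates) are out of scope.
* The fifth-state ("gap as extra character") treatment is deliberately
  absent: with multi-residue indels it violates site independence, and its
  proper formulation is a modeling problem this package does not take on.
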