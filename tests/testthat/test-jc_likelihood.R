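test_that("JC edge transition matrix follows the equal-rates rule", {
  expect_equal(jc_edge_transition(0), diag(4), ignore_attr = TRUE)
  expect_true(all(jc_edge_transition(0.75) == 0.25))
  m <- jc_edge_transition(0.3)
  expect_equal(unname(diag(m)), rep(0.7, 4))
  expect_equal(unname(m[row(m) != col(m)]), rep(0.1, 12), tolerance = 1e-15)
  for (p in seq(0, 0.75, by = 0.05))
    expect_equal(rowSums(jc_edge_transition(p)), rep(1, 4),
                 ignore_attr = TRUE, tolerance = 1e-15)
  expect_error(jc_edge_transition(-0.01), "\\[0, 3/4\\]")
  expect_error(jc_edge_transition(0.76), "\\[0, 3/4\\]")
})

test_that("column likelihood handles identical, gapped, and monotypic sites", {
  two <- set_edge_params(parse_newick("(a,b);"), 0)
  expect_equal(column_likelihood(two, c(a = "A", b = "A")), 0.25)
  for (p in c(0, 0.2, 0.75)) {
    twp <- set_edge_params(two, p)
    expect_equal(column_likelihood(twp, c(a = "A", b = "-")), 0.25)
  }
  # a monotypic column on a 7-taxon tree at p = 0 is worth exactly 1/4
  aln <- printed_alignment_fixture()
  tr <- set_edge_params(enumerate_unrooted_topologies(rownames(aln))[[1]], 0)
  col1 <- setNames(unclass(aln)[, 1], rownames(aln))
  expect_identical(column_likelihood(tr, col1), 0.25)
  expect_error(column_likelihood(two, c(a = "A", x = "C")), "leaf labels")
})

test_that("a gapped leaf marginalizes to the sum over four nucleotides", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    tr <- random_tree(n)
    col <- random_column(tr$tip.label, n_gaps = 1)
    gap_leaf <- names(col)[col == "-"]
    total <- 0
    for (x in NUC4) {
      col2 <- col
      col2[gap_leaf] <- x
      total <- total + column_likelihood(tr, col2)
    }
    expect_equal(column_likelihood(tr, col), total, tolerance = 1e-12)
  }
})

test_that("pruning equals the brute-force sum over internal states", {
  set.seed(31)
  for (n in c(4, 5)) {
    for (rep in 1:6) {
      tr <- random_tree(n)
      col <- random_column(tr$tip.label, n_gaps = sample(0:2, 1))
      expect_equal(column_likelihood(tr, col),
                   brute_force_column_likelihood(tr, col),
                   tolerance = 1e-12)
    }
  }
})

test_that("gap-free column likelihoods are a probability distribution", {
  set.seed(41)
  for (n in 4:5) {
    tr <- random_tree(n)
    cols <- expand.grid(rep(list(NUC4), n), stringsAsFactors = FALSE)
    total <- sum(apply(cols, 1, function(cc)
      column_likelihood(tr, setNames(unlist(cc), tr$tip.label))))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("the likelihood does not depend on where the tree is rooted", {
  # same unrooted model written down with different rootings/rotations
  reps <- c("(a:0.1,b:0.2,(c:0.3,d:0.4):0.15);",
            "(c:0.3,d:0.4,(a:0.1,b:0.2):0.15);",
            "((a:0.1,b:0.2):0.15,(c:0.3,d:0.4):0);",
            "((a:0.1,b:0.2):0,(c:0.3,d:0.4):0.15);")
  aln <- alignment(c(a = "ACG-T", b = "AC-AT", c = "GCGAT", d = "AAG-T"))
  ll <- vapply(reps, function(s)
    alignment_log_likelihood(parse_newick(s), aln), numeric(1))
  expect_true(all(abs(ll - ll[1]) <= 1e-12))
  # and re-rooting a random tree at any internal node changes nothing
  set.seed(51)
  tr <- random_tree(6)
  m <- replicate(4, random_column(tr$tip.label, n_gaps = 1))
  rownames(m) <- tr$tip.label
  aln2 <- alignment(m)
  base <- alignment_log_likelihood(tr, aln2)
  n_tip <- length(tr$tip.label)
  for (node in (n_tip + 2):(n_tip + tr$Nnode)) {
    rerooted <- ape::root(tr, node = node, resolve.root = FALSE)
    expect_equal(alignment_log_likelihood(rerooted, aln2), base,
                 tolerance = 1e-12)
  }
})

test_that("alignment log-likelihood is the weighted sum over sites", {
  set.seed(61)
  tr <- random_tree(5)
  m <- replicate(6, random_column(tr$tip.label, n_gaps = sample(0:2, 1)))
  rownames(m) <- tr$tip.label
  aln <- alignment(m)
  per_col <- sum(log(apply(unclass(aln), 2, function(cc)
    column_likelihood(tr, setNames(cc, rownames(aln))))))
  expect_equal(alignment_log_likelihood(tr, aln), per_col,
               tolerance = 1e-12)
  # duplicated columns exercise the pattern-compression weights
  aln2 <- alignment(cbind(unclass(aln), unclass(aln)))
  expect_equal(alignment_log_likelihood(tr, aln2), 2 * per_col,
               tolerance = 1e-12)
})

test_that("an empty alignment has log-likelihood 0 and is flagged", {
  tr <- set_edge_params(parse_newick("(a,b,(c,d));"), 0.1)
  aln <- alignment(matrix("A", 4, 0,
                          dimnames = list(c("a", "b", "c", "d"), NULL)))
  ll <- alignment_log_likelihood(tr, aln)
  expect_equal(as.numeric(ll), 0)
  expect_true(attr(ll, "degenerate"))
})

test_that("stripping gapped sites keeps exactly the gap-free columns", {
  expect_equal(ncol(strip_gapped_sites(printed_alignment_fixture())), 0)
  clean <- alignment(c(a = "ACG", b = "ACT"))
  expect_identical(unclass(strip_gapped_sites(clean)), unclass(clean))
  one_gap <- alignment(c(a = "A-G", b = "ACT"))
  expect_equal(ncol(strip_gapped_sites(one_gap)), 2)
  expect_identical(unclass(strip_gapped_sites(one_gap))[1, ], c("A", "G"))
})

test_that("monotypic predicate requires one nucleotide type per column", {
  expect_true(is_monotypic(printed_alignment_fixture()))
  expect_false(is_monotypic(alignment(c(a = "AC", b = "AA"))))   # A and C
  expect_false(is_monotypic(alignment(c(a = "A-", b = "A-"))))   # all-gap col
  expect_true(is_monotypic(alignment(c(a = "A-", b = "AT"))))
})

test_that("gap coding produces one presence/absence character per gapped column", {
  gc <- gap_code(printed_alignment_fixture())
  expect_equal(ncol(gc$matrix), 3)
  expect_equal(gc$sites, c(0L, 1L, 2L))
  expect_equal(unname(gc$matrix[, 1]), c(1L, 0L, 1L, 0L, 0L, 0L, 1L))
  expect_equal(unname(gc$matrix[, 2]), c(0L, 1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(unname(gc$matrix[, 3]), c(0L, 0L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(ncol(gap_code(alignment(c(a = "ACG", b = "ACT")))$matrix), 0)
  all_gap <- alignment(rbind(a = c("A", "-"), b = c("C", "-")))
  gc2 <- gap_code(all_gap)
  expect_equal(unname(gc2$matrix[, 1]), c(0L, 0L))
})

test_that("ambiguity codes are rejected rather than treated as gaps", {
  expect_error(alignment(c(a = "AN", b = "AC")), "N")
  expect_error(alignment(c(a = "A?", b = "AC")), "outside")
})

test_that("aligned FASTA round-trips through disk", {
  aln <- printed_alignment_fixture()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  expect_identical(unclass(read_alignment(f)), unclass(aln))
  shipped <- read_alignment(system.file("extdata", "monotypic7.fasta",
                                        package = "gapml"))
  expect_identical(unclass(shipped), unclass(aln))
})
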