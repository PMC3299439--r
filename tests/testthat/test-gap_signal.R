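make_gc <- function(mat) {
  structure(list(taxa = rownames(mat), matrix = mat,
                 sites = seq_len(ncol(mat)) - 1L),
            class = "gap_characters")
}

test_that("binary Fitch score matches brute force over internal labelings", {
  set.seed(121)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    tr <- ape::unroot(ape::rtree(n, tip.label = paste0("t", 1:n)))
    char <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    mat <- matrix(char, ncol = 1, dimnames = list(names(char), NULL))
    expect_equal(gap_parsimony_scores(make_gc(mat), tr),
                 brute_force_binary_parsimony(tr, char))
  }
})

test_that("Fitch score agrees with phangorn's parsimony on multi-character matrices", {
  set.seed(131)
  for (rep in 1:5) {
    n <- sample(5:7, 1)
    tr <- ape::unroot(ape::rtree(n, tip.label = paste0("t", 1:n)))
    mat <- matrix(sample(0:1, n * 8, replace = TRUE), n,
                  dimnames = list(tr$tip.label, NULL))
    pd <- phangorn::phyDat(mat, type = "USER", levels = c(0, 1))
    expect_equal(gap_parsimony_scores(make_gc(mat), tr),
                 as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("character scores reflect bipartition compatibility", {
  # a character whose presence set is a clade costs 1; constant costs 0
  tr <- parse_newick("(((s1,s3),s7),(s2,(s4,(s5,s6))));")
  char <- setNames(c(1, 0, 1, 0, 0, 0, 1), paste0("s", 1:7))
  mat <- matrix(char, ncol = 1, dimnames = list(names(char), NULL))
  expect_equal(gap_parsimony_scores(make_gc(mat), tr), 1L)
  ones <- matrix(1L, 7, 1, dimnames = list(paste0("s", 1:7), NULL))
  expect_equal(gap_parsimony_scores(make_gc(ones), tr), 0L)
  # non-clade presence set needs >= 2 changes
  char2 <- setNames(c(1, 1, 0, 0, 1, 0, 0), paste0("s", 1:7))
  mat2 <- matrix(char2, ncol = 1, dimnames = list(names(char2), NULL))
  expect_gte(gap_parsimony_scores(make_gc(mat2), tr), 2L)
})

test_that("the worked example's gap characters score 3 on a compatible tree", {
  gc <- gap_code(printed_alignment_fixture())
  tr <- parse_newick("(((s1,s3),s7),(s2,(s4,(s5,s6))));")
  expect_equal(gap_parsimony_scores(gc, tr), 3L)
  expect_equal(gap_parsimony_scores(gc, tr, per_character = TRUE),
               c(1L, 1L, 1L))
})

test_that("gap-pattern estimation returns the compatible strict subset", {
  gc <- gap_code(printed_alignment_fixture())
  gt <- estimate_tree_from_gaps(gc)
  expect_lt(length(gt$optimal_idx), length(gt$topologies))
  expect_equal(gt$min_score, 3L)
  # the optimal set is exactly the topologies containing the {s1,s3,s7}
  # bipartition: 3 shapes for that triple times 15 for the other four taxa
  expect_length(gt$optimal_idx, 45)
  trio <- c("s1", "s3", "s7")
  for (t in gt$optimal) {
    sides <- ape::prop.part(t)
    has <- any(vapply(sides, function(x)
      setequal(t$tip.label[x], trio) ||
        setequal(setdiff(t$tip.label, t$tip.label[x]), trio), logical(1)))
    expect_true(has)
  }
})

test_that("a characterless matrix leaves all topologies tied", {
  gc <- gap_code(alignment(c(a = "ACG", b = "ACG", c = "ACG", d = "ACG")))
  gt <- estimate_tree_from_gaps(gc)
  expect_length(gt$optimal_idx, 3)
  expect_equal(gt$min_score, 0L)
})

test_that("nested deletion histories let gap parsimony find the true tree", {
  caterpillar <- parse_newick("((((a,b),c),d),e);")
  hits <- 0
  for (r in 1:20) {
    sim <- simulate_alignment(simulation_config(caterpillar, p = 0, d = 0.2,
                                                root_length = 500,
                                                seed = 1000 + r))
    gt <- estimate_tree_from_gaps(gap_code(sim$alignment))
    rf <- min(vapply(gt$optimal, rf_distance, integer(1),
                     t2 = caterpillar))
    if (rf == 0) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("gap characters write to a readable PHYLIP-style file", {
  gc <- gap_code(printed_alignment_fixture())
  f <- withr::local_tempfile(fileext = ".txt")
  write_gap_characters(gc, f)
  lines <- readLines(f)
  expect_match(lines[1], "0,1,2")
  expect_match(lines[2], "7 3")
  expect_length(lines, 9)
})
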