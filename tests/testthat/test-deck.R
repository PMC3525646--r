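# deck-based classification of 6-node subgraphs

test_that("the complete 6-digraph has six identical complete cards", {
  d <- compute_deck(complete_digraph(6))
  complete5 <- graph_id(complete_digraph(5))
  expect_equal(as.numeric(d), rep(complete5, 6))
})

test_that("decks are invariant under relabeling of the parent graph", {
  set.seed(31)
  for (trial in seq_len(200)) {
    g <- random_digraph(6, stats::runif(1, 0.2, 0.8), seed = 7000 + trial)
    h <- relabel(g, sample(6))
    expect_identical(unclass(compute_deck(g)), unclass(compute_deck(h)))
    expect_identical(deck_hash(compute_deck(g)), deck_hash(compute_deck(h)))
  }
})

test_that("the directed 6-path deck matches directly constructed cards", {
  p6 <- path_digraph(6)
  d <- compute_deck(p6)
  # oracle: canonicalize each vertex-deleted card by brute force
  expected <- sort(vapply(1:6, function(v) {
    keep <- setdiff(1:6, v)
    canonical_id(graph_id(p6, vertices = keep), 5)
  }, numeric(1)))
  expect_equal(as.numeric(d), expected)
  # endpoint deletions give the 5-path, exactly twice
  path5 <- canonical_id(graph_id(path_digraph(5)), 5)
  expect_equal(sum(as.numeric(d) == path5), 2)
})

test_that("deck hashes are deterministic and collision-scarce", {
  d1 <- compute_deck(path_digraph(6))
  d2 <- compute_deck(relabel(path_digraph(6), c(3, 1, 4, 2, 6, 5)))
  expect_identical(deck_hash(d1), deck_hash(d2))
  expect_identical(deck_hash(d1), deck_hash(compute_deck(path_digraph(6))))
  # distinct random graphs: hash collisions far below 1%
  set.seed(32)
  hashes <- character(0)
  decks <- character(0)
  for (trial in seq_len(500)) {
    g <- random_digraph(6, stats::runif(1, 0.2, 0.8), seed = 8000 + trial)
    d <- compute_deck(g)
    hashes <- c(hashes, deck_hash(d))
    decks <- c(decks, paste(as.numeric(d), collapse = ","))
  }
  distinct_decks <- !duplicated(decks)
  expect_lt(sum(duplicated(hashes[distinct_decks])) / sum(distinct_decks), 0.01)
})

test_that("stage 1 merges isomorphic subgraphs into one entry", {
  # all seven 6-subsets of the complete 7-digraph induce the complete 6-digraph
  cen <- census(complete_digraph(7), 6)
  expect_length(cen$ids, 1)
  expect_equal(cen$counts, 7)
  expect_equal(cen$total, 7)
})

test_that("stage 2 ignores classes absent from the input network", {
  # input: a 6-path embedded in 8 nodes; comparison: complete digraph,
  # whose 6-subgraphs are all complete and never occur in the input
  input <- digraph(cbind(1:5, 2:6), n_nodes = 8)
  cen <- census(input, 6)
  counts <- netmotif:::census_against(complete_digraph(8), 6L, cen)
  expect_equal(counts, rep(0, length(cen$ids)))
  # and a comparison equal to the input reproduces the input counts
  expect_equal(netmotif:::census_against(input, 6L, cen), cen$counts)
})

test_that("deck collisions exist and the isomorphism fallback separates them", {
  col <- find_deck_collision(seed = 1, max_tries = 20000)
  expect_false(is.null(col))
  expect_identical(unclass(compute_deck(col$g1)), unclass(compute_deck(col$g2)))
  expect_false(is_isomorphic(col$g1, col$g2))
  # a network holding both graphs as components classifies them as two
  # distinct entries even though their decks (and deck hashes) coincide
  both <- digraph(rbind(col$g1$arcs, col$g2$arcs + 6L), n_nodes = 12)
  cen <- census(both, 6)
  expect_length(cen$ids, 2)
  expect_equal(cen$counts, c(1, 1))
})
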