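# subgraph enumeration and census

test_that("enumeration yields each connected subset exactly once", {
  s <- enumerate_connected_subgraphs(complete_digraph(4), 3)
  expect_equal(nrow(s), 4)  # C(4,3), all connected
  expect_false(any(duplicated(s)))
  s <- enumerate_connected_subgraphs(cycle_digraph(4), 3)
  expect_equal(nrow(s), 4)  # every 3-subset of a 4-cycle induces a path
  expect_false(any(duplicated(s)))
  # an isolated vertex disconnects the full-size subset
  g <- digraph(rbind(c(1, 2)), n_nodes = 3)
  expect_equal(nrow(enumerate_connected_subgraphs(g, 3)), 0)
  # k > n: empty stream, not an error
  expect_equal(nrow(enumerate_connected_subgraphs(path_digraph(3), 4)), 0)
  # uniqueness on a denser case
  g <- random_digraph(10, 0.35, seed = 99)
  for (k in 3:5) {
    s <- enumerate_connected_subgraphs(g, k)
    expect_false(any(duplicated(s)))
  }
})

test_that("census counts known small cases", {
  cen <- census(complete_digraph(4), 3)
  expect_equal(cen$ids, 238)
  expect_equal(cen$counts, 4)
  cen <- census(feed_forward_loop(), 3)
  expect_equal(cen$ids, 38)
  expect_equal(cen$counts, 1)
  cen <- census(cycle_digraph(4), 3)
  expect_equal(cen$ids, 12)  # the directed 3-path
  expect_equal(cen$counts, 4)
  # empty graph: empty census
  cen <- census(digraph(rbind(c(1, 2)), n_nodes = 8), 4)
  expect_length(cen$ids, 0)
  expect_equal(cen$total, 0)
})

test_that("census equals the brute-force oracle on random graphs", {
  set.seed(41)
  for (trial in seq_len(20)) {
    g <- random_digraph(sample(8:12, 1), stats::runif(1, 0.15, 0.5),
                        seed = 9000 + trial)
    for (k in 3:6) {
      fast <- census(g, k)
      slow <- census_bruteforce(g, k)
      if (k == 6) {
        can <- canonicalize_census6(fast)
        expect_equal(can$ids, slow$ids)
        expect_equal(can$counts, slow$counts)
      } else {
        expect_equal(fast$ids, slow$ids)
        expect_equal(fast$counts, slow$counts)
      }
      expect_equal(fast$total, slow$total)
      expect_equal(sum(fast$counts), fast$total)
    }
  }
})

test_that("complete-graph censuses have a single class with C(n, k) copies", {
  for (k in 3:5) {
    cen <- census(complete_digraph(7), k)
    expect_length(cen$ids, 1)
    expect_equal(cen$counts, choose(7, k))
  }
})

test_that("the census is invariant under vertex relabeling", {
  set.seed(42)
  g <- random_digraph(11, 0.3, seed = 77)
  for (k in 3:5) {
    cen <- census(g, k)
    cen2 <- census(relabel(g, sample(11)), k)
    expect_equal(cen$ids, cen2$ids)
    expect_equal(cen$counts, cen2$counts)
  }
  c6a <- canonicalize_census6(census(g, 6))
  c6b <- canonicalize_census6(census(relabel(g, sample(11)), 6))
  expect_equal(c6a, c6b)
})

test_that("brute-force census refuses oversized graphs", {
  expect_error(census_bruteforce(complete_digraph(16), 3), "15 nodes")
})

test_that("3-node census agrees with igraph's triad classification", {
  skip_if_not_installed("igraph")
  g <- random_digraph(12, 0.3, seed = 123)
  cen <- census(g, 3)
  ig <- igraph::graph_from_edgelist(g$arcs)
  m <- igraph::motifs(ig, 3)
  for (i in seq_along(cen$ids)) {
    rep3 <- decode_graph_id(cen$ids[i], 3)
    ig_rep <- igraph::graph_from_edgelist(rep3$arcs)
    cls <- igraph::isomorphism_class(ig_rep)
    expect_equal(cen$counts[i], m[cls + 1])
  }
  expect_equal(cen$total, sum(m, na.rm = TRUE))
})
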