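# graph-ID codec, canonical labeling, isomorphism, connectivity

test_that("graph_id encodes the adjacency matrix row-major, MSB first", {
  expect_equal(graph_id(feed_forward_loop()), 38)
  expect_equal(graph_id(digraph(NULL, n_nodes = 3)), 0)
  expect_equal(graph_id(complete_digraph(3)), 238)
  # vertex order matters: the same arcs read in a different order
  expect_equal(graph_id(feed_forward_loop(), vertices = c(3, 2, 1)), 200)
  expect_error(graph_id(feed_forward_loop(), vertices = 1), "2..6")
})

test_that("decode_graph_id inverts graph_id", {
  g <- decode_graph_id(38, 3)
  expect_equal(sort(paste(g$arcs[, 1], g$arcs[, 2])), c("2 1", "3 1", "3 2"))
  expect_equal(n_arcs(decode_graph_id(0, 4)), 0L)
  expect_error(decode_graph_id(2^8, 3), "diagonal")  # bit (1,1) set
  set.seed(4)
  for (trial in seq_len(1000)) {
    k <- sample(3:6, 1)
    g <- random_digraph(k, stats::runif(1, 0.2, 0.8), seed = trial)
    id <- graph_id(g)
    g2 <- decode_graph_id(id, k)
    expect_identical(g2$arcs[order(g2$arcs[, 1], g2$arcs[, 2]), , drop = FALSE],
                     g$arcs[order(g$arcs[, 1], g$arcs[, 2]), , drop = FALSE])
    expect_equal(graph_id(g2), id)
  }
})

test_that("canonical_id is the minimum over all relabelings", {
  # every labeling of the feed-forward loop canonicalizes to 38
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  ffl <- feed_forward_loop()
  for (r in seq_len(nrow(perms)))
    expect_equal(canonical_id(graph_id(relabel(ffl, perms[r, ])), 3), 38)
  # a single arc lands on the lowest legal off-diagonal bit, entry (3,2)
  expect_equal(canonical_id(graph_id(digraph(rbind(c(1, 2)), n_nodes = 3)), 3), 2)
  expect_equal(canonical_id(0, 4), 0)
  expect_equal(canonical_id(238, 3), 238)
})

test_that("canonical_id is idempotent, minimal, and relabeling-invariant", {
  set.seed(11)
  for (trial in seq_len(200)) {
    k <- sample(3:6, 1)
    g <- random_digraph(k, stats::runif(1, 0.2, 0.8), seed = 1000 + trial)
    id <- graph_id(g)
    can <- canonical_id(id, k)
    expect_lte(can, id)
    expect_equal(canonical_id(can, k), can)
    expect_equal(canonical_id(graph_id(relabel(g, sample(k))), k), can)
  }
})

test_that("is_isomorphic agrees with canonical-ID equality on all 3-node pairs", {
  ids <- 0:63
  # unpack: valid 3-node ids have the 6 off-diagonal bits in positions
  # {1,2,3,5,6,7}; build them through decode of packed values
  valid <- Filter(function(v) {
    !is.null(tryCatch(decode_graph_id(v, 3), error = function(e) NULL))
  }, 0:511)
  cans <- vapply(valid, canonical_id, numeric(1), k = 3)
  gs <- lapply(valid, decode_graph_id, k = 3)
  expect_length(valid, 64)
  expect_length(unique(cans), 16)  # 13 connected + 3 disconnected classes
  for (i in seq_along(valid))
    for (j in seq_along(valid))
      expect_identical(is_isomorphic(gs[[i]], gs[[j]]), cans[i] == cans[j])
})

test_that("is_isomorphic separates graphs by degree structure", {
  expect_true(is_isomorphic(feed_forward_loop(),
                            digraph(rbind(c(1, 2), c(1, 3), c(2, 3)))))
  path3 <- path_digraph(3)
  fan3 <- digraph(rbind(c(1, 2), c(1, 3)), n_nodes = 3)
  expect_false(is_isomorphic(path3, fan3))
  expect_false(is_isomorphic(path3, path_digraph(4)))  # size mismatch: FALSE
})

test_that("weak connectivity ignores arc direction", {
  expect_true(is_weakly_connected(feed_forward_loop()))
  expect_true(is_weakly_connected(path_digraph(5)))
  expect_false(is_weakly_connected(digraph(rbind(c(1, 2)), n_nodes = 4)))
  expect_true(is_weakly_connected(digraph(NULL, n_nodes = 1)))
})

test_that("digraph() strips loops and duplicates with a warning", {
  expect_warning(g <- digraph(rbind(c(1, 1), c(1, 2))), "loop")
  expect_equal(n_arcs(g), 1L)
  expect_warning(g2 <- digraph(rbind(c(1, 2), c(1, 2))), "parallel")
  expect_equal(n_arcs(g2), 1L)
})
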