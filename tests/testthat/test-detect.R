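# the full detection pipeline

test_that("detection is deterministic across thread counts", {
  g <- random_digraph(15, 0.25, seed = 17)
  reports <- lapply(c(1, 2, 4), function(t)
    run_detection(g, k = 3, n_comparison = 10, method = "lc", seed = 99,
                  threads = t))
  strip_threads <- function(r) { a <- attr(r, "config"); a$threads <- NULL
    attr(r, "config") <- a; r }
  for (t in 2:3) {
    expect_identical(strip_threads(reports[[1]]), strip_threads(reports[[t]]))
    # byte-identical written output
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    write_report(reports[[1]], f1)
    write_report(reports[[t]], f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("detection works through the deck-based k = 6 path", {
  g <- random_digraph(12, 0.3, seed = 23)
  rep <- run_detection(g, k = 6, n_comparison = 5, seed = 31)
  expect_gt(nrow(rep), 0)
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  expect_equal(sum(rep$concentration), 1)
  # representative ids decode to 6-node graphs with the reported adjacency
  for (r in seq_len(min(nrow(rep), 5)))
    expect_equal(adjacency_string(rep$id[r], 6), rep$adj[r])
})

test_that("rows are ordered by descending frequency with ID tie-break", {
  g <- random_digraph(14, 0.3, seed = 29)
  rep <- run_detection(g, k = 4, n_comparison = 5, seed = 7)
  expect_true(all(diff(rep$frequency) <= 0))
  ties <- which(diff(rep$frequency) == 0)
  if (length(ties)) expect_true(all(rep$id[ties + 1] > rep$id[ties]))
})

test_that("a zero-switch ensemble gives p = 1 for every input class", {
  g <- random_digraph(13, 0.3, seed = 37)
  rep <- run_detection(g, k = 4, n_comparison = 6, switches_per_arc = 0, seed = 3)
  expect_true(all(rep$p_value == 1))
  expect_true(all(rep$null_mean == rep$frequency))
})

test_that("size bounds and empty inputs are rejected", {
  g <- random_digraph(10, 0.3, seed = 41)
  expect_error(run_detection(g, k = 7), "3 <= k <= 6")
  expect_error(run_detection(g, k = 2), "3 <= k <= 6")
  sparse <- digraph(rbind(c(1, 2)), n_nodes = 6)
  expect_error(run_detection(sparse, k = 4), "no connected")
})

test_that("the add-one p-value convention is exposed", {
  g <- complete_digraph(4)
  rep <- run_detection(g, k = 3, n_comparison = 4, switches_per_arc = 0,
                       seed = 1, p_add_one = TRUE)
  expect_equal(rep$p_value, 1)  # (4 + 1) / (4 + 1)
})
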