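# degree-preserving randomization and the uniform sampler

expect_simple <- function(g) {
  expect_false(any(g$arcs[, 1] == g$arcs[, 2]))      # loop-free
  expect_false(any(duplicated(g$arcs)))              # no parallel arcs
}

test_that("all methods preserve per-vertex in/out degrees and simplicity", {
  for (method in c("f", "nr", "gc", "lc", "ulc")) {
    for (trial in seq_len(25)) {
      # uniform sampling by whole-sample rejection is only practical on
      # sparse profiles; switching methods take denser ones
      g <- if (method == "ulc") random_digraph(10, 0.2, seed = 100 * trial + 1)
           else random_digraph(12, 0.3, seed = 100 * trial + 1)
      cfg <- null_model_config(method, n_comparison = 3, seed = trial)
      gi <- generate_comparison(g, cfg, index = 1 + trial %% 3)
      expect_simple(gi)
      p0 <- degree_profile(g)
      p1 <- degree_profile(gi)
      expect_equal(p1[, "out"], p0[, "out"])
      expect_equal(p1[, "in"], p0[, "in"])
    }
  }
})

test_that("each method conserves its reciprocal-edge law", {
  for (trial in seq_len(25)) {
    # denser graphs so reciprocal pairs actually occur
    g <- random_digraph(10, 0.45, seed = 300 + trial)
    p0 <- degree_profile(g)
    for (method in c("f", "gc", "lc")) {
      cfg <- null_model_config(method, n_comparison = 2, seed = trial)
      gi <- generate_comparison(g, cfg, index = 1)
      p1 <- degree_profile(gi)
      if (method == "f") expect_identical(recip_pairs(gi), recip_pairs(g))
      if (method == "gc") expect_equal(sum(p1[, "recip"]), sum(p0[, "recip"]))
      if (method == "lc") expect_equal(p1[, "recip"], p0[, "recip"])
    }
    # the uniform sampler needs a sparser profile to accept, but must
    # reproduce the reciprocal degrees exactly
    gs <- random_digraph(10, 0.25, seed = 300 + trial)
    gu <- generate_comparison(gs, null_model_config("ulc", n_comparison = 2,
                                                    seed = trial), index = 1)
    expect_equal(degree_profile(gu)[, "recip"], degree_profile(gs)[, "recip"])
  }
})

test_that("the directed 3-cycle admits no valid switch", {
  g <- cycle_digraph(3)
  # exhaustive check: every ordered arc pair proposes a loop or parallel arc
  m <- g$arcs
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    u <- m[i, 1]; v <- m[i, 2]; x <- m[j, 1]; y <- m[j, 2]
    makes_loop <- (u == y) || (x == v)
    noop <- (v == y) || (u == x)
    parallel <- paste(u, y) %in% paste(m[, 1], m[, 2]) ||
                paste(x, v) %in% paste(m[, 1], m[, 2])
    expect_true(makes_loop || noop || parallel)
  }
  # so the chain never moves
  cfg <- null_model_config("nr", n_comparison = 1, switches_per_arc = 100, seed = 5)
  gi <- generate_comparison(g, cfg, index = 1)
  expect_identical(gi$arcs[order(gi$arcs[, 1]), ], g$arcs[order(g$arcs[, 1]), ])
})

test_that("zero switches reproduce the input and burnin shifts the chain", {
  g <- random_digraph(10, 0.3, seed = 9)
  cfg0 <- null_model_config("lc", n_comparison = 2, switches_per_arc = 0, seed = 3)
  gi <- generate_comparison(g, cfg0, index = 2)
  expect_identical(sort(paste(gi$arcs[, 1], gi$arcs[, 2])),
                   sort(paste(g$arcs[, 1], g$arcs[, 2])))
  # with burnin b, ensemble graph i is chain state b + i: the first b
  # chain outputs never appear in the ensemble
  cfg_b <- null_model_config("lc", n_comparison = 2, burnin = 2, seed = 3)
  cfg_nb <- null_model_config("lc", n_comparison = 4, burnin = 0, seed = 3)
  expect_identical(generate_comparison(g, cfg_b, 1)$arcs,
                   generate_comparison(g, cfg_nb, 3)$arcs)
})

test_that("comparison graphs are reproducible from (seed, index) alone", {
  for (method in c("lc", "ulc")) {
    g <- if (method == "ulc") random_digraph(10, 0.2, seed = 10)
         else random_digraph(12, 0.3, seed = 10)
    cfg <- null_model_config(method, n_comparison = 5, seed = 11)
    expect_identical(generate_comparison(g, cfg, 4)$arcs,
                     generate_comparison(g, cfg, 4)$arcs)
    expect_false(identical(generate_comparison(g, cfg, 1)$arcs,
                           generate_comparison(g, cfg, 2)$arcs))
  }
})

test_that("uniform sampling hits the two 3-cycle realizations equally", {
  g <- cycle_digraph(3)
  realizations <- enumerate_profile_realizations(degree_profile(g))
  expect_length(realizations, 2)  # the two orientations of the triangle
  draws <- vapply(seq_len(10000), function(i)
    graph_id(sample_uniform_lc(g, seed = 202, index = i)), numeric(1))
  expect_setequal(unique(draws), realizations)
  freq <- mean(draws == realizations[1])
  expect_gt(freq, 0.48)
  expect_lt(freq, 0.52)
})

test_that("a single reciprocal pair has a unique realization", {
  g <- digraph(rbind(c(1, 2), c(2, 1)))
  for (i in 1:20)
    expect_identical(sort(paste(sample_uniform_lc(g, seed = 7, index = i)$arcs[, 1],
                                sample_uniform_lc(g, seed = 7, index = i)$arcs[, 2])),
                     c("1 2", "2 1"))
})

test_that("uniform sampling is chi-square uniform over a 5-node realization set", {
  g <- random_digraph(5, 0.4, seed = 58)  # profile with 8 labeled realizations
  realizations <- enumerate_profile_realizations(degree_profile(g))
  expect_gt(length(realizations), 1)
  draws <- vapply(seq_len(10000), function(i)
    graph_id(sample_uniform_lc(g, seed = 404, index = i)), numeric(1))
  expect_setequal(unique(draws), realizations)
  observed <- table(factor(draws, levels = realizations))
  p <- stats::chisq.test(observed)$p.value
  expect_gt(p, 0.01)
})
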