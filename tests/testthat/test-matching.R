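make_index <- function(na, nb) {
  ga <- add_null_vertex(hypergraph(paste0("a", seq_len(na))))
  gb <- add_null_vertex(hypergraph(paste0("b", seq_len(nb))))
  build_association_index(ga, gb)
}

test_that("a permutation indicator is returned unchanged", {
  idx <- make_index(3, 3)
  x <- numeric(idx$n)
  perm <- c(a1 = "b2", a2 = "b3", a3 = "b1")
  x[pair_to_flat(idx, names(perm), perm)] <- 1
  m <- discretize(x, idx)
  expect_equal(stats::setNames(m$b, m$a), perm)
})

test_that("discretization matches the exhaustive assignment oracle", {
  for (seed in 1:10) {
    idx <- make_index(3, 3)
    x <- withr::with_seed(seed, runif(idx$n))
    m <- discretize(x, idx)
    expect_equal(matching_weight(m, x, idx),
                 brute_best_matching_weight(x, idx), tolerance = 1e-12)
    # one-to-one constraints
    expect_false(anyDuplicated(m$a) > 0)
    expect_false(anyDuplicated(m$b) > 0)
  }
  # rectangular case
  for (seed in 1:5) {
    idx <- make_index(4, 2)
    x <- withr::with_seed(seed + 100, runif(idx$n))
    m <- discretize(x, idx)
    expect_equal(matching_weight(m, x, idx),
                 brute_best_matching_weight(x, idx), tolerance = 1e-12)
  }
})

test_that("mass on null pairs only gives an empty matching", {
  idx <- make_index(2, 2)
  x <- numeric(idx$n)
  x[pair_to_flat(idx, c("a1", "a2"), rep(idx$null_b, 2))] <- 0.5
  x[pair_to_flat(idx, rep(idx$null_a, 2), c("b1", "b2"))] <- 0.5
  x[pair_to_flat(idx, idx$null_a, idx$null_b)] <- 0.2
  expect_equal(nrow(discretize(x, idx)), 0)
})

test_that("weights separated by many orders of magnitude are still resolved", {
  # a single double-precision assignment is blind below ~1e-16 of the top
  # weight; the scale-peeled solve must recover the per-row ordering
  idx <- make_index(3, 3)
  x <- numeric(idx$n)
  x[pair_to_flat(idx, "a1", "b1")] <- 1
  x[pair_to_flat(idx, "a2", "b2")] <- 1e-25
  x[pair_to_flat(idx, "a2", "b3")] <- 1e-28
  x[pair_to_flat(idx, "a3", "b3")] <- 1e-40
  m <- discretize(x, idx)
  expect_equal(stats::setNames(m$b, m$a),
               c(a1 = "b1", a2 = "b2", a3 = "b3"))
})

test_that("the discrete score equals a hand-summed contraction", {
  ga <- add_null_vertex(hypergraph(c("V1", "V2"), list(E1 = c("V1", "V2")),
                                   annotations = c(E1 = "1.1.1.1")))
  gb <- add_null_vertex(hypergraph(c("W1", "W2"), list(F1 = c("W1", "W2")),
                                   annotations = c(F1 = "1.1.1.1")))
  sims <- compound_similarity_table(data.frame(
    a = c("V1", "V2", "V1", "V2"), b = c("W1", "W2", "W2", "W1"),
    score = c(0.8, 0.6, 0.1, 0.1)))
  bt <- build_tensor(ga, gb, sims, lambda = 0.9)
  # identical EC appears twice in the union census: enzyme sim = 1/2
  # K = 2; matching {V1-W1, V2-W2}:
  #   diagonal: 0.9*0.8 + 0.9*0.6; edge element {V1W1, V2W2}: 2! * 0.1*0.5
  m <- data.frame(a = c("V1", "V2"), b = c("W1", "W2"))
  expect_equal(discrete_score(bt$tensor, m, bt$index),
               0.9 * 0.8 + 0.9 * 0.6 + 2 * 0.1 * 0.5, tolerance = 1e-12)
  expect_equal(discrete_score(bt$tensor,
                              data.frame(a = character(0), b = character(0)),
                              bt$index), 0)
})

test_that("the true matching is locally optimal on a self-alignment fixture", {
  gen <- random_hypergraph(6, 5, 2, seed = 21)
  pair <- knockout(gen$hypergraph, 0, seed = 21)
  ga <- add_null_vertex(pair$g_big); gb <- add_null_vertex(pair$g_small)
  bt <- suppressWarnings(build_tensor(ga, gb, gen$sim_table))
  truth <- pair$truth
  s_true <- discrete_score(bt$tensor, truth, bt$index)
  # swapping any two assignments can never improve the score
  for (i in seq_len(nrow(truth) - 1)) {
    for (j in (i + 1):nrow(truth)) {
      sw <- truth
      sw$b[c(i, j)] <- sw$b[c(j, i)]
      expect_lte(discrete_score(bt$tensor, sw, bt$index), s_true + 1e-12)
    }
  }
})

test_that("vertex and edge correctness count matched truth", {
  g <- hypergraph(c("u1", "u2", "u3", "u4"),
                  list(e1 = c("u1", "u2"), e2 = c("u3", "u4")))
  truth <- data.frame(a = c("u1", "u2", "u3", "u4"),
                      b = c("u1", "u2", "u3", "u4"))
  expect_equal(vertex_correctness(truth, truth, g), 1)
  expect_equal(edge_correctness(truth, truth, g), 1)

  empty <- data.frame(a = character(0), b = character(0))
  expect_equal(vertex_correctness(empty, truth, g), 0)
  expect_equal(edge_correctness(empty, truth, g), 0)

  # half the vertices correct; one of the two edges fully correct
  half <- data.frame(a = c("u1", "u2", "u3", "u4"),
                     b = c("u1", "u2", "u4", "u3"))
  expect_equal(vertex_correctness(half, truth, g), 0.5)
  expect_equal(edge_correctness(half, truth, g), 0.5)

  bad_truth <- data.frame(a = c("u1", "zz"), b = c("u1", "zz"))
  expect_error(vertex_correctness(truth, bad_truth, g), "outside")
})

test_that("edge correctness never exceeds the vertex-induced bound", {
  for (seed in 1:5) {
    gen <- random_hypergraph(8, 6, 3, seed = seed)
    pair <- knockout(gen$hypergraph, 2, seed = seed)
    out <- suppressWarnings(
      align_benchmark(pair, gen$sim_table, seed = seed, max_iter = 40))
    expect_lte(out$report$ec, out$report$vc + 1e-12)
  }
})

test_that("greedy refinement adds strictly improving pairs only", {
  ga <- add_null_vertex(hypergraph(c("V1", "V2"), list(E1 = c("V1", "V2")),
                                   annotations = c(E1 = "1.1.1.1")))
  gb <- add_null_vertex(hypergraph(c("W1", "W2"), list(F1 = c("W1", "W2")),
                                   annotations = c(F1 = "1.1.1.1")))
  sims <- compound_similarity_table(data.frame(
    a = c("V1", "V2", "V1", "V2"), b = c("W1", "W2", "W2", "W1"),
    score = c(0.8, 0.6, 0.1, 0.1)))
  bt <- build_tensor(ga, gb, sims, lambda = 0.9)
  partial <- data.frame(a = "V1", b = "W1")
  refined <- refine_matching(partial, bt$tensor, bt$index)
  expect_equal(stats::setNames(refined$b, refined$a),
               c(V1 = "W1", V2 = "W2"))
  expect_gt(discrete_score(bt$tensor, refined, bt$index),
            discrete_score(bt$tensor, partial, bt$index))
  # a complete matching is left untouched
  expect_equal(refine_matching(refined, bt$tensor, bt$index), refined)
})
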