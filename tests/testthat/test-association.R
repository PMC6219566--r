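test_that("association order is the larger of the two hypergraph orders", {
  pair <- toy_pair()
  expect_equal(association_order(pair$ga, pair$gb), 3L)
  expect_equal(association_order(pair$gb, pair$gb), 2L)

  g4 <- hypergraph(paste0("v", 1:4), list(e = paste0("v", 1:4)))
  g1 <- hypergraph("w", list(e = "w"))
  expect_equal(association_order(g4, g1), 4L)

  e1 <- hypergraph("a"); e2 <- hypergraph("b")
  expect_error(association_order(e1, e2), "edgeless")
})

test_that("the association index is the Cartesian product of padded vertex sets", {
  pair <- toy_pair()
  idx <- build_association_index(add_null_vertex(pair$ga),
                                 add_null_vertex(pair$gb))
  expect_equal(idx$n, 12L)  # (3+1) x (2+1)

  expect_error(build_association_index(pair$ga, add_null_vertex(pair$gb)),
               "null")

  # degenerate: two empty vertex sets still give the (N, N) vertex
  idx0 <- build_association_index(add_null_vertex(hypergraph(character(0))),
                                  add_null_vertex(hypergraph(character(0))))
  expect_equal(idx0$n, 1L)
  expect_equal(flat_to_pair(idx0, 1)$a, idx0$null_a)

  # flat index <-> pair is a bijection
  pp <- association_pairs(idx)
  expect_equal(nrow(unique(pp)), idx$n)
  expect_equal(pair_to_flat(idx, pp$a, pp$b), seq_len(idx$n))
})

test_that("equal-size reactions at K=3 produce exactly the two hyperedges", {
  pair <- toy_pair()
  idx <- build_association_index(add_null_vertex(pair$ga),
                                 add_null_vertex(pair$gb))
  al <- enumerate_edge_alignments(c("V1", "V2"), c("V1p", "V2p"), 3, idx)
  expect_length(al, 2)
  labelled <- lapply(al, function(tp) {
    p <- flat_to_pair(idx, tp)
    sort(paste(p$a, p$b, sep = "~"))
  })
  nn <- paste(idx$null_a, idx$null_b, sep = "~")
  has <- function(expected) any(vapply(labelled, identical, logical(1),
                                       sort(expected)))
  expect_true(has(c("V1~V1p", "V2~V2p", nn)))
  expect_true(has(c("V1~V2p", "V2~V1p", nn)))
})

test_that("unequal reactions pair surplus metabolites with the null vertex", {
  pair <- toy_pair()
  idx <- build_association_index(add_null_vertex(pair$ga),
                                 add_null_vertex(pair$gb))
  al <- enumerate_edge_alignments(c("V1", "V2", "V3"), c("V1p", "V2p"), 3, idx)
  expect_length(al, 6)  # 3!/1!
  for (tp in al) {
    p <- flat_to_pair(idx, tp)
    expect_equal(sum(p$b == idx$null_b & p$a != idx$null_a), 1)
  }

  al1 <- enumerate_edge_alignments("V1", "V1p", 2, idx)
  expect_length(al1, 1)
  p <- flat_to_pair(idx, al1[[1]])
  expect_setequal(paste(p$a, p$b), c("V1 V1p", "N N"))

  expect_error(enumerate_edge_alignments(c("V1", "V2", "V3"), "V1p", 2, idx),
               "larger than tensor order")
})

test_that("hyperedge counts follow max!/(max-min)! for random size pairs", {
  verts_a <- paste0("a", 1:6)
  verts_b <- paste0("b", 1:6)
  ga <- add_null_vertex(hypergraph(verts_a, list(e = verts_a)))
  gb <- add_null_vertex(hypergraph(verts_b, list(e = verts_b)))
  idx <- build_association_index(ga, gb)
  for (p in 1:4) {
    for (q in 1:4) {
      K <- max(p, q) + 1L
      al <- enumerate_edge_alignments(verts_a[seq_len(p)], verts_b[seq_len(q)],
                                      K, idx)
      expect_length(al, factorial(max(p, q)) / factorial(max(p, q) - min(p, q)))
      expect_true(all(lengths(al) == K))
    }
  }
})

test_that("lambda = 1 stores only diagonal elements with balanced values", {
  pair <- toy_pair()
  ga <- add_null_vertex(pair$ga); gb <- add_null_vertex(pair$gb)
  bt <- build_tensor(ga, gb, toy_sim_table(), lambda = 1)
  expect_true(all(apply(bt$tensor$subs, 1, function(r) all(r == r[1]))))
  i <- pair_to_flat(bt$index, "V1", "V1p")
  row <- which(apply(bt$tensor$subs, 1, function(r) all(r == i)))
  expect_equal(bt$tensor$values[row], 1 * 0.9)  # lambda * sim
})

test_that("stored element count matches the combinatorial prediction", {
  pair <- toy_pair()
  ga <- add_null_vertex(pair$ga); gb <- add_null_vertex(pair$gb)
  lam <- 0.9
  bt <- build_tensor(ga, gb, toy_sim_table(), lambda = lam)
  # diagonal: every real pair has positive similarity here (imputation)
  n_diag <- length(real_vertices(ga)) * length(real_vertices(gb))
  # off-diagonal: per reaction pair, max!/(max-min)! multisets; E1 and E2
  # share EC class 1.1.1.- with the b-reaction, E3 (2.7.1.1) shares none
  # and stores nothing
  sizes <- c(E1 = 1, E2 = 2)
  n_off <- sum(vapply(sizes, function(p) {
    q <- 2
    factorial(max(p, q)) / factorial(max(p, q) - min(p, q))
  }, numeric(1)))
  expect_equal(nrow(bt$tensor$subs), n_diag + n_off)
  expect_equal(bt$tensor$K, 3L)
  expect_equal(bt$tensor$n, 12L)
})

test_that("all hyperedges of one reaction pair carry the same value", {
  pair <- toy_pair()
  ga <- add_null_vertex(pair$ga); gb <- add_null_vertex(pair$gb)
  bt <- build_tensor(ga, gb, toy_sim_table(), lambda = 0.5)
  idx <- bt$index
  al <- enumerate_edge_alignments(ga$edges$E2, gb$edges$E1b, 3, idx)
  keys <- vapply(al, paste, character(1), collapse = ",")
  tkeys <- apply(bt$tensor$subs, 1, paste, collapse = ",")
  vals <- bt$tensor$values[match(keys, tkeys)]
  expect_length(unique(vals), 1)
})

test_that("swapping the two networks permutes but preserves the tensor", {
  pair <- toy_pair()
  ga <- add_null_vertex(pair$ga); gb <- add_null_vertex(pair$gb)
  sims <- toy_sim_table()
  ab <- build_tensor(ga, gb, sims, lambda = 0.5)
  ba <- build_tensor(gb, ga, sims, lambda = 0.5)
  expect_equal(nrow(ab$tensor$subs), nrow(ba$tensor$subs))
  # map each ab element through the pair swap and look it up in ba
  for (r in seq_len(nrow(ab$tensor$subs))) {
    p <- flat_to_pair(ab$index, ab$tensor$subs[r, ])
    swapped <- sort(pair_to_flat(ba$index, p$b, p$a))
    hit <- which(apply(ba$tensor$subs, 1, function(q) all(q == swapped)))
    expect_length(hit, 1)
    expect_equal(ba$tensor$values[hit], ab$tensor$values[r])
  }
})

test_that("tensor construction validates its inputs", {
  pair <- toy_pair()
  ga <- add_null_vertex(pair$ga); gb <- add_null_vertex(pair$gb)
  expect_error(build_tensor(ga, gb, toy_sim_table(), lambda = 1.5), "lambda")
  ga_bare <- add_null_vertex(hypergraph(c("V1", "V2"),
                                        list(E1 = c("V1", "V2"))))
  expect_error(build_tensor(ga_bare, gb, toy_sim_table(), lambda = 0.5),
               "annotation")
})
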