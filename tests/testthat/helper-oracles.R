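# Independent oracles and fixture builders.  Everything here is deliberately
# brute force and shares no code with the package internals it checks.

# all permutations of a vector (list of vectors)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# materialize a sparse canonical tensor as a dense K-way array by
# proliferating every stored element over all subscript permutations
dense_from_sparse <- function(t) {
  arr <- array(0, dim = rep(t$n, t$K))
  for (i in seq_len(nrow(t$subs))) {
    for (p in unique(all_perms(t$subs[i, ])))
      arr[matrix(p, 1)] <- t$values[i]
  }
  arr
}

# brute-force (K-1)-mode product of a dense array with x
dense_ttv <- function(arr, x) {
  d <- dim(arr)
  K <- length(d); n <- d[1]
  y <- numeric(n)
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), K)))
  for (r in seq_len(nrow(idx))) {
    v <- arr[matrix(idx[r, ], 1)]
    if (v != 0)
      y[idx[r, 1]] <- y[idx[r, 1]] + v * prod(x[idx[r, -1]])
  }
  y
}

# random canonical sparse tensor for oracle comparisons
random_sparse_tensor <- function(K, n, m, seed) {
  withr::with_seed(seed, {
    subs <- t(replicate(m, sort(sample.int(n, K, replace = TRUE))))
    if (K == 1L) subs <- matrix(subs, ncol = 1)
    key <- apply(subs, 1, paste, collapse = ",")
    keep <- !duplicated(key)
    sparse_tensor(K, n, subs[keep, , drop = FALSE], runif(sum(keep)))
  })
}

# exhaustive maximum-weight partial matching: every a-vertex is either
# unmatched (collecting its (a, N) mass) or matched to a distinct b-vertex;
# unmatched b-vertices collect their (N, b) mass
brute_best_matching_weight <- function(x, index) {
  ra <- setdiff(index$a_ids, index$null_a)
  rb <- setdiff(index$b_ids, index$null_b)
  null_a_mass <- vapply(ra, function(a)
    x[pair_to_flat(index, a, index$null_b)], numeric(1))
  null_b_mass <- vapply(rb, function(b)
    x[pair_to_flat(index, index$null_a, b)], numeric(1))
  best <- -Inf
  rec <- function(i, used, acc) {
    if (i > length(ra)) {
      tot <- unname(acc + sum(null_b_mass[!used]))
      if (tot > best) best <<- tot
      return(invisible())
    }
    rec(i + 1L, used, acc + null_a_mass[i])
    for (j in seq_along(rb)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used,
            acc + x[pair_to_flat(index, ra[i], rb[j])])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(length(rb)), 0)
  best
}

# total weight of a concrete matching under the same convention
matching_weight <- function(matching, x, index) {
  ra <- setdiff(index$a_ids, index$null_a)
  rb <- setdiff(index$b_ids, index$null_b)
  w <- 0
  if (nrow(matching))
    w <- sum(x[pair_to_flat(index, matching$a, matching$b)])
  for (a in setdiff(ra, matching$a))
    w <- w + x[pair_to_flat(index, a, index$null_b)]
  for (b in setdiff(rb, matching$b))
    w <- w + x[pair_to_flat(index, index$null_a, b)]
  w
}

# the worked toy pair: network a with three reactions of sizes 1, 2, 3 over
# three metabolites; network b with one reaction over two metabolites
toy_pair <- function() {
  ga <- hypergraph(c("V1", "V2", "V3"),
                   list(E1 = "V1",
                        E2 = c("V1", "V2"),
                        E3 = c("V1", "V2", "V3")),
                   annotations = c(E1 = "1.1.1.1", E2 = "1.1.1.2",
                                   E3 = "2.7.1.1"))
  gb <- hypergraph(c("V1p", "V2p"),
                   list(E1b = c("V1p", "V2p")),
                   annotations = c(E1b = "1.1.1.3"))
  list(ga = ga, gb = gb)
}

toy_sim_table <- function() {
  compound_similarity_table(data.frame(
    a = c("V1", "V2", "V3", "V1", "V2"),
    b = c("V1p", "V2p", "V1p", "V2p", "V1p"),
    score = c(0.9, 0.8, 0.2, 0.1, 0.1)))
}
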