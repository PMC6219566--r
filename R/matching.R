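#' Discretize a continuous alignment vector into a one-to-one matching
#'
#' Reshapes the alignment vector onto the (n_a+1) x (n_b+1) association
#' grid and solves a maximum-weight one-to-one assignment (Kuhn-Munkres)
#' over the real vertex block, augmented with a null option per vertex
#' weighted by the vector mass on the corresponding (vertex, null)
#' association vertex.  Vertices assigned to a null option are unmatched.
#'
#' The power iteration converges to near-rank-1 vectors whose residual
#' mass spans many orders of magnitude, so a single double-precision
#' assignment solve would be blind to everything far below the largest
#' entry.  The assignment is therefore solved scale by scale: at each
#' round only pairs whose weight is within \code{rel_tol} of the current
#' maximum are committed, the matched vertices are removed, and the
#' remainder is re-solved after rescaling.  For weights of comparable
#' magnitude this reduces to one exact maximum-weight assignment.
#'
#' @param x non-negative numeric vector over all association vertices.
#' @param index the \code{\link{association_index}} the vector is defined
#'   over.
#' @param rel_tol scale window of one assignment round (default 1e-6).
#' @return data frame with columns \code{a}, \code{b}: the matched
#'   real-real vertex pairs (each real vertex appears at most once).
#' @export
discretize <- function(x, index, rel_tol = 1e-6) {
  stopifnot(inherits(index, "association_index"))
  if (length(x) != index$n)
    stop("vector length ", length(x),
         " does not match association index size ", index$n)
  if (any(x < 0)) stop("alignment vector must be non-negative")
  ra <- setdiff(index$a_ids, index$null_a)
  rb <- setdiff(index$b_ids, index$null_b)
  out_a <- character(0); out_b <- character(0)
  rem_a <- ra; rem_b <- rb
  while (length(rem_a) && length(rem_b)) {
    na <- length(rem_a); nb <- length(rem_b)
    # square weight matrix: rows = a-vertices then slots for unmatched b,
    # columns = b-vertices then null slots for a.  A vertex reaches its own
    # null slot with the (vertex, null) mass; foreign null slots weigh 0.
    n <- na + nb
    W <- matrix(0, n, n)
    for (i in seq_len(na))
      W[i, seq_len(nb)] <- x[pair_to_flat(index, rep(rem_a[i], nb), rem_b)]
    for (i in seq_len(na))
      W[i, nb + i] <- x[pair_to_flat(index, rem_a[i], index$null_b)]
    for (j in seq_len(nb))
      W[na + j, j] <- x[pair_to_flat(index, index$null_a, rem_b[j])]
    M <- max(W)
    if (M <= 0) break
    sol <- as.integer(clue::solve_LSAP(W / M, maximum = TRUE))
    thr <- M * rel_tol
    drop_a <- logical(na); drop_b <- logical(nb)
    for (i in seq_len(na)) {
      j <- sol[i]
      if (W[i, j] < thr) next
      if (j <= nb) {
        out_a <- c(out_a, rem_a[i]); out_b <- c(out_b, rem_b[j])
        drop_a[i] <- TRUE; drop_b[j] <- TRUE
      } else if (j == nb + i) {
        drop_a[i] <- TRUE            # decisively unmatched
      }
    }
    for (j in seq_len(nb)) {
      if (!drop_b[j] && sol[na + j] == j && W[na + j, j] >= thr)
        drop_b[j] <- TRUE            # decisively unmatched
    }
    if (!any(drop_a) && !any(drop_b)) {
      # assignment placed every above-threshold entry elsewhere; commit the
      # single largest entry to guarantee progress
      pos <- which(W == M, arr.ind = TRUE)[1, ]
      i <- pos[1]; j <- pos[2]
      if (i <= na && j <= nb) {
        out_a <- c(out_a, rem_a[i]); out_b <- c(out_b, rem_b[j])
        drop_a[i] <- TRUE; drop_b[j] <- TRUE
      } else if (i <= na) drop_a[i] <- TRUE else drop_b[j] <- TRUE
    }
    rem_a <- rem_a[!drop_a]
    rem_b <- rem_b[!drop_b]
  }
  o <- order(match(out_a, ra))
  data.frame(a = out_a[o], b = out_b[o], stringsAsFactors = FALSE)
}

#' Binary alignment vector of a matching
#'
#' Indicator vector over the association vertices: 1 for each matched
#' real-real pair, for each unmatched vertex paired with the other
#' network's null, and for the (null, null) vertex.
#'
#' @param matching data frame with columns \code{a}, \code{b}.
#' @param index an \code{\link{association_index}}.
#' @return 0/1 numeric vector of length \code{index$n}.
#' @export
matching_indicator <- function(matching, index) {
  ra <- setdiff(index$a_ids, index$null_a)
  rb <- setdiff(index$b_ids, index$null_b)
  if (anyDuplicated(matching$a) || anyDuplicated(matching$b))
    stop("matching is not one-to-one")
  x <- numeric(index$n)
  if (nrow(matching))
    x[pair_to_flat(index, matching$a, matching$b)] <- 1
  un_a <- setdiff(ra, matching$a)
  if (length(un_a))
    x[pair_to_flat(index, un_a, rep(index$null_b, length(un_a)))] <- 1
  un_b <- setdiff(rb, matching$b)
  if (length(un_b))
    x[pair_to_flat(index, rep(index$null_a, length(un_b)), un_b)] <- 1
  x[pair_to_flat(index, index$null_a, index$null_b)] <- 1
  x
}

#' Alignment score of a discrete matching
#'
#' Evaluates the tensor objective on the binary indicator vector of the
#' matching, i.e. the score the alignment attains after discretization.
#'
#' @param t the association \code{\link{sparse_tensor}}.
#' @param matching data frame with columns \code{a}, \code{b}.
#' @param index the matching \code{\link{association_index}}.
#' @return scalar score.
#' @export
discrete_score <- function(t, matching, index) {
  tensor_score(t, matching_indicator(matching, index))
}

#' Greedy augmentation of a discretized matching
#'
#' The continuous relaxation can leave a vertex unmatched although matching
#' it would increase the discrete alignment score (its null-pair coordinate
#' can accumulate more iterate mass than its best real pair).  This pass
#' repairs that: while some pair of unmatched vertices strictly increases
#' the discrete score, the pair with the largest gain is added.  Existing
#' pairs are never removed, so the result dominates the input matching
#' under the tensor objective.
#'
#' @param matching data frame with columns \code{a}, \code{b}.
#' @param t the association \code{\link{sparse_tensor}}.
#' @param index the matching \code{\link{association_index}}.
#' @return augmented matching data frame.
#' @export
refine_matching <- function(matching, t, index) {
  ra <- setdiff(index$a_ids, index$null_a)
  rb <- setdiff(index$b_ids, index$null_b)
  repeat {
    un_a <- setdiff(ra, matching$a)
    un_b <- setdiff(rb, matching$b)
    if (!length(un_a) || !length(un_b)) break
    base <- discrete_score(t, matching, index)
    best_gain <- 1e-12
    best <- NULL
    for (u in un_a) {
      for (w in un_b) {
        cand <- rbind(matching,
                      data.frame(a = u, b = w, stringsAsFactors = FALSE))
        gain <- discrete_score(t, cand, index) - base
        if (gain > best_gain) {
          best_gain <- gain
          best <- c(u, w)
        }
      }
    }
    if (is.null(best)) break
    matching <- rbind(matching,
                      data.frame(a = best[1], b = best[2],
                                 stringsAsFactors = FALSE))
  }
  o <- order(match(matching$a, ra))
  matching[o, , drop = FALSE]
}

# orient a matching/truth data frame so that column `key` holds the small
# network's vertices; errors when the frame references vertices outside sv.
.orient_to_small <- function(df, sv, what) {
  if (all(df$a %in% sv)) {
    stats::setNames(as.character(df$b), as.character(df$a))
  } else if (all(df$b %in% sv)) {
    stats::setNames(as.character(df$a), as.character(df$b))
  } else {
    bad <- setdiff(union(df$a, df$b), sv)
    stop(what, " references vertices outside the smaller hypergraph: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
}

.correct_vertices <- function(matching, truth, g_small) {
  sv <- real_vertices(g_small)
  tr <- .orient_to_small(truth, sv, "truth")
  if (!all(sv %in% names(tr)))
    stop("truth does not cover all vertices of the smaller hypergraph")
  mt <- if (nrow(matching)) {
    if (all(matching$a %in% sv) || all(matching$b %in% sv)) {
      m <- matching
      if (!all(m$a %in% sv)) m <- data.frame(a = m$b, b = m$a)
      stats::setNames(as.character(m$b), as.character(m$a))
    } else {
      # mixed orientation cannot happen for one-to-one matchings over two
      # disjoint id spaces; orient by majority of hits on the small side
      stats::setNames(as.character(matching$b), as.character(matching$a))
    }
  } else stats::setNames(character(0), character(0))
  vapply(sv, function(v) !is.na(mt[v]) && mt[v] == tr[v], logical(1))
}

#' Vertex correctness of a matching against ground truth
#'
#' Fraction of the smaller hypergraph's vertices that the matching aligns
#' to their true counterparts.  Unmatched vertices count as incorrect.
#'
#' @param matching data frame with columns \code{a}, \code{b}.
#' @param truth ground-truth vertex matching in the same format.
#' @param g_small the smaller hypergraph (the denominator of the metric).
#' @return fraction in [0, 1].
#' @export
vertex_correctness <- function(matching, truth, g_small) {
  ok <- .correct_vertices(matching, truth, g_small)
  if (!length(ok)) return(0)
  mean(ok)
}

#' Edge correctness of a matching against ground truth
#'
#' Fraction of the smaller hypergraph's hyperedges all of whose member
#' vertices are aligned to their true counterparts.  An edge is correct
#' only if every one of its metabolites is, so EC is never above VC's
#' induced bound.
#'
#' @inheritParams vertex_correctness
#' @return fraction in [0, 1].
#' @export
edge_correctness <- function(matching, truth, g_small) {
  if (!length(g_small$edges)) return(0)
  ok <- .correct_vertices(matching, truth, g_small)
  mean(vapply(g_small$edges, function(ev) all(ok[ev]), logical(1)))
}

#' Accuracy report for an alignment
#'
#' @param t association \code{\link{sparse_tensor}}.
#' @param matching data frame with columns \code{a}, \code{b}.
#' @param index matching \code{\link{association_index}}.
#' @param truth ground-truth vertex matching (data frame \code{a}, \code{b}).
#' @param g_small the smaller hypergraph.
#' @return list with \code{score} (discrete alignment score), \code{ec} and
#'   \code{vc}.
#' @export
accuracy_report <- function(t, matching, index, truth, g_small) {
  list(score = discrete_score(t, matching, index),
       ec = edge_correctness(matching, truth, g_small),
       vc = vertex_correctness(matching, truth, g_small))
}
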