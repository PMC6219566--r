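#' Order of the association hypergraph
#'
#' The association hypergraph of two networks inherits the larger of the two
#' hypergraph orders: an aligned reaction pair occupies as many association
#' vertices as the bigger reaction has metabolites, with null fillers making
#' up the difference.
#'
#' @param ga,gb hypergraphs.
#' @return integer, \code{max} of the two orders.
#' @export
association_order <- function(ga, gb) {
  ka <- hypergraph_order(ga)
  kb <- hypergraph_order(gb)
  if (ka == 0L && kb == 0L)
    stop("both hypergraphs are edgeless: no alignable structure")
  max(ka, kb)
}

#' Association vertex index
#'
#' Enumerates the vertices of the association hypergraph: every pair of one
#' (possibly null) vertex from network a and one from network b, in a-major
#' order, with a bijection onto flat tensor subscripts 1..(n_a+1)(n_b+1).
#'
#' @param ga,gb hypergraphs with the null vertex appended
#'   (\code{\link{add_null_vertex}}).
#' @return an object of class \code{"association_index"}.
#' @export
build_association_index <- function(ga, gb) {
  if (!isTRUE(ga$has_null) || !isTRUE(gb$has_null))
    stop("both hypergraphs must have a null vertex appended; ",
         "call add_null_vertex() first")
  structure(list(a_ids = ga$vertices, b_ids = gb$vertices,
                 null_a = ga$null_id, null_b = gb$null_id,
                 n = length(ga$vertices) * length(gb$vertices)),
            class = "association_index")
}

#' @export
print.association_index <- function(x, ...) {
  cat("Association index:", x$n, "association vertices (",
      length(x$a_ids), "x", length(x$b_ids), "padded )\n")
  invisible(x)
}

#' Map vertex pairs to flat association indices
#'
#' @param index an \code{\link{association_index}}.
#' @param a,b vectors of vertex ids (may include the null ids).
#' @return integer vector of flat indices.
#' @export
pair_to_flat <- function(index, a, b) {
  ia <- match(a, index$a_ids)
  ib <- match(b, index$b_ids)
  if (anyNA(ia)) stop("unknown a-vertex: ", paste(a[is.na(ia)], collapse = ", "))
  if (anyNA(ib)) stop("unknown b-vertex: ", paste(b[is.na(ib)], collapse = ", "))
  (ia - 1L) * length(index$b_ids) + ib
}

#' Map flat association indices back to vertex pairs
#'
#' @param index an \code{\link{association_index}}.
#' @param i integer vector of flat indices.
#' @return data frame with columns \code{a} and \code{b}.
#' @export
flat_to_pair <- function(index, i) {
  i <- as.integer(i)
  if (any(i < 1L) || any(i > index$n)) stop("flat index out of range")
  nb <- length(index$b_ids)
  data.frame(a = index$a_ids[(i - 1L) %/% nb + 1L],
             b = index$b_ids[(i - 1L) %% nb + 1L])
}

#' All association vertex pairs in index order
#'
#' @param index an \code{\link{association_index}}.
#' @return data frame with columns \code{a} and \code{b}, one row per
#'   association vertex, in flat-index order.
#' @export
association_pairs <- function(index) {
  flat_to_pair(index, seq_len(index$n))
}

# all ordered k-permutations of v (list of vectors)
.perm_k <- function(v, k) {
  if (k == 0L) return(list(v[0]))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perm_k(v[-i], k - 1L))
      out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Enumerate the association hyperedges of one reaction pair
#'
#' A pair of reactions (one per network) yields one association hyperedge
#' per maximal injective matching of their metabolite sets: every metabolite
#' of the smaller reaction is paired with a distinct metabolite of the
#' larger one, surplus metabolites of the larger reaction are paired with
#' the other network's null vertex, and remaining slots up to the tensor
#' order K are filled with the (null, null) vertex.  For reactions of sizes
#' p and q this gives max(p,q)! / (max(p,q) - min(p,q))! hyperedges, each a
#' multiset of exactly K association vertices.
#'
#' @param ea,eb character vectors: the metabolite sets of the two reactions.
#' @param K association tensor order; both edges must have at most K
#'   vertices.
#' @param index an \code{\link{association_index}} covering both networks.
#' @return list of sorted integer vectors of length K (canonical flat-index
#'   multisets), duplicates removed.
#' @export
enumerate_edge_alignments <- function(ea, eb, K, index) {
  p <- length(ea); q <- length(eb)
  if (p > K || q > K)
    stop("edge larger than tensor order K = ", K)
  if (p == 0L || q == 0L) stop("empty hyperedge")
  nn <- pair_to_flat(index, index$null_a, index$null_b)
  if (p >= q) {
    maps <- .perm_k(ea, q)
    tuples <- lapply(maps, function(sel) {
      real <- pair_to_flat(index, sel, eb)
      surplus <- setdiff(ea, sel)
      gaps <- if (length(surplus))
        pair_to_flat(index, surplus, rep(index$null_b, length(surplus)))
      else integer(0)
      sort(c(real, gaps, rep(nn, K - p)))
    })
  } else {
    maps <- .perm_k(eb, p)
    tuples <- lapply(maps, function(sel) {
      real <- pair_to_flat(index, ea, sel)
      surplus <- setdiff(eb, sel)
      gaps <- if (length(surplus))
        pair_to_flat(index, rep(index$null_a, length(surplus)), surplus)
      else integer(0)
      sort(c(real, gaps, rep(nn, K - q)))
    })
  }
  unique(tuples)
}

#' Build the association score tensor of two annotated hypergraphs
#'
#' Materialises the association hypergraph of the two networks as a sparse
#' super-symmetric tensor of order K = max of the two hypergraph orders and
#' dimension (n_a+1)(n_b+1).  Diagonal elements (i,...,i) for a real vertex
#' pair carry lambda times the compound similarity; each enumerated
#' hyperedge of a reaction pair carries (1 - lambda) times the enzyme
#' similarity of the two EC numbers.  Zero-valued elements are not stored.
#' If two distinct reaction pairs generate the same canonical multiset with
#' different values, the larger value is kept (best supporting evidence)
#' and a warning is emitted.
#'
#' @param ga,gb hypergraphs with null vertices appended; EC annotations are
#'   required on every edge whenever \code{lambda < 1} and both networks
#'   have edges.
#' @param sim_table a \code{\link{compound_similarity_table}}.
#' @param census an \code{\link{enzyme_census}}; default is the union of the
#'   two networks' EC annotations.
#' @param lambda vertex/edge balance in [0, 1] (default 0.9: metabolite
#'   similarity dominates).
#' @param gap_score score for null-involving diagonal entries (alignment to
#'   a null vertex); default 0, in which case they are not stored.
#' @return list with components \code{tensor}
#'   (\code{\link{sparse_tensor}}) and \code{index}
#'   (\code{\link{association_index}}).
#' @export
build_tensor <- function(ga, gb, sim_table, census = NULL, lambda = 0.9,
                         gap_score = 0) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (gap_score < 0) stop("gap_score must be non-negative")
  K <- association_order(ga, gb)
  index <- build_association_index(ga, gb)
  ra <- real_vertices(ga)
  rb <- real_vertices(gb)
  need_enzymes <- lambda < 1 && length(ga$edges) && length(gb$edges)
  if (need_enzymes) {
    for (g in list(ga, gb)) {
      miss <- setdiff(names(g$edges), names(g$annotations))
      if (length(miss))
        stop("missing EC annotation for edge(s): ",
             paste(miss, collapse = ", "))
    }
    if (is.null(census))
      census <- enzyme_census(c(unname(ga$annotations), unname(gb$annotations)))
  }

  store <- new.env(parent = emptyenv())
  n_collisions <- 0L
  put <- function(tuple, value, warn_collision = FALSE) {
    key <- paste(tuple, collapse = ",")
    prev <- store[[key]]
    if (is.null(prev)) {
      store[[key]] <- c(value, tuple)
    } else if (prev[1] != value) {
      if (warn_collision)
        n_collisions <<- n_collisions + 1L
      store[[key]] <- c(max(prev[1], value), tuple)
    }
  }

  # diagonal: vertex (metabolite) similarities
  if (lambda > 0) {
    for (va in ra) {
      for (vb in rb) {
        s <- lambda * compound_similarity(sim_table, va, vb)
        if (s > 0) put(rep(pair_to_flat(index, va, vb), K), s)
      }
    }
  }
  if (gap_score > 0) {
    null_pairs <- c(pair_to_flat(index, ra, rep(index$null_b, length(ra))),
                    pair_to_flat(index, rep(index$null_a, length(rb)), rb),
                    pair_to_flat(index, index$null_a, index$null_b))
    for (i in null_pairs) put(rep(i, K), gap_score)
  }

  # off-diagonal: hyperedge (enzyme) similarities
  if (need_enzymes) {
    for (ia in names(ga$edges)) {
      for (ib in names(gb$edges)) {
        val <- (1 - lambda) *
          enzyme_similarity(ga$annotations[[ia]], gb$annotations[[ib]], census)
        if (val > 0) {
          tuples <- enumerate_edge_alignments(ga$edges[[ia]], gb$edges[[ib]],
                                              K, index)
          for (tp in tuples) put(tp, val, warn_collision = TRUE)
        }
      }
    }
  }

  if (n_collisions > 0L)
    warning(n_collisions, " association hyperedge(s) generated by more ",
            "than one reaction pair with differing scores; ",
            "kept the maximum for each")
  keys <- ls(store)
  m <- length(keys)
  subs <- matrix(integer(0), 0, K)
  values <- numeric(0)
  if (m) {
    recs <- lapply(keys, function(k) store[[k]])
    values <- vapply(recs, `[`, numeric(1), 1L)
    subs <- do.call(rbind, lapply(recs, function(r) as.integer(r[-1L])))
  }
  list(tensor = sparse_tensor(K, index$n, subs, values), index = index)
}
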