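#' Random hypergraph with synthetic annotations and similarities
#'
#' Generates a benchmark network: hyperedges are random vertex subsets with
#' sizes uniform on 1..max_edge_size, every reaction gets an EC number drawn
#' from a synthetic four-level hierarchy, and a compound similarity table is
#' built with self-similarity 1 and cross-similarities drawn uniformly from
#' [0, 0.3].  The clear self-versus-cross contrast emulates the situation
#' where every metabolite has a distinctive structure, the regime in which
#' self-alignment recovery is well-posed.
#'
#' @param n_vertices number of metabolites; must be at least
#'   \code{max_edge_size}.
#' @param n_edges number of reactions.
#' @param max_edge_size largest allowed reaction size (the hypergraph order
#'   never exceeds it).
#' @param seed RNG seed.
#' @return list with components \code{hypergraph} (annotated),
#'   \code{sim_table} (\code{\link{compound_similarity_table}} over all
#'   vertex pairs) and \code{census} (\code{\link{enzyme_census}} of the
#'   drawn annotations).
#' @export
random_hypergraph <- function(n_vertices, n_edges, max_edge_size = 3L,
                              seed = 1L) {
  n_vertices <- as.integer(n_vertices)
  n_edges <- as.integer(n_edges)
  max_edge_size <- as.integer(max_edge_size)
  if (max_edge_size < 1L) stop("max_edge_size must be >= 1")
  if (n_vertices < max_edge_size)
    stop("need at least max_edge_size vertices")
  if (n_edges < 0L) stop("n_edges must be >= 0")
  verts <- sprintf("C%02d", seq_len(n_vertices))
  withr::with_seed(seed, {
    sizes <- sample.int(max_edge_size, n_edges, replace = TRUE)
    edges <- lapply(sizes, function(s) sample(verts, s))
    names(edges) <- sprintf("R%02d", seq_len(n_edges))
    ecs <- sprintf("%d.%d.%d.%d",
                   sample.int(3L, n_edges, replace = TRUE),
                   sample.int(3L, n_edges, replace = TRUE),
                   sample.int(2L, n_edges, replace = TRUE),
                   sample.int(30L, n_edges, replace = TRUE))
    names(ecs) <- names(edges)
    pairs <- expand.grid(a = verts, b = verts, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a <= pairs$b, ]
    pairs$score <- ifelse(pairs$a == pairs$b, 1,
                          stats::runif(nrow(pairs), 0, 0.3))
  })
  g <- hypergraph(verts, edges,
                  annotations = if (n_edges) ecs else NULL)
  list(hypergraph = g,
       sim_table = compound_similarity_table(pairs),
       census = if (n_edges) enzyme_census(ecs) else NULL)
}

#' Knockout benchmark pair with known ground truth
#'
#' Deletes \code{n_remove} reactions uniformly at random from a network and
#' returns the original together with the knockout sub-network.  Metabolites
#' whose reactions were all removed are dropped from the sub-network.
#' Aligning the pair is a self-alignment with known truth: the identity on
#' the retained vertices.
#'
#' @param g a \code{hypergraph} (without null vertex).
#' @param n_remove number of reactions to delete, between 0 and the number
#'   of edges.
#' @param seed RNG seed.
#' @return list of class \code{"benchmark_pair"} with components
#'   \code{g_big}, \code{g_small}, \code{truth} (data frame \code{a} = big,
#'   \code{b} = small vertex ids), \code{retained_edges},
#'   \code{removed_edges}.
#' @export
knockout <- function(g, n_remove, seed = 1L) {
  if (isTRUE(g$has_null)) stop("knockout expects a hypergraph without null vertex")
  n_remove <- as.integer(n_remove)
  if (n_remove < 0L) stop("n_remove must be non-negative")
  m <- length(g$edges)
  if (n_remove > m) stop("n_remove exceeds the number of edges (", m, ")")
  removed <- withr::with_seed(seed, sample(names(g$edges), n_remove))
  retained <- setdiff(names(g$edges), removed)
  sub_edges <- g$edges[retained]
  deg_before <- table(factor(unlist(g$edges), levels = g$vertices))
  deg_after <- table(factor(unlist(sub_edges), levels = g$vertices))
  # drop vertices orphaned by the knockout; originally isolated ones stay
  keep <- g$vertices[deg_after > 0 | deg_before == 0]
  ann <- g$annotations
  if (!is.null(ann)) ann <- ann[intersect(names(ann), retained)]
  g_small <- hypergraph(keep, sub_edges,
                        annotations = if (length(ann)) ann else NULL)
  structure(list(g_big = g, g_small = g_small,
                 truth = data.frame(a = keep, b = keep,
                                    stringsAsFactors = FALSE),
                 retained_edges = retained, removed_edges = removed),
            class = "benchmark_pair")
}

#' @export
print.benchmark_pair <- function(x, ...) {
  cat("Benchmark pair:", length(x$g_big$edges), "->",
      length(x$g_small$edges), "reactions (",
      length(x$removed_edges), "knocked out ),",
      length(x$g_small$vertices), "retained metabolites\n")
  invisible(x)
}

#' Perturb a score tensor with additive noise
#'
#' Adds an independent draw from Uniform(-delta, +delta) to every stored
#' element, with delta = \code{fraction} times the mean stored element
#' value, and clips at zero to preserve non-negativity.  This emulates
#' measurement noise on the similarity scores of the association
#' hypergraph's components.
#'
#' @param t a \code{\link{sparse_tensor}} with at least one stored element.
#' @param fraction noise intensity as a fraction of the mean element value
#'   (e.g. 0.05 for 5 percent).
#' @param seed RNG seed.
#' @return a new \code{\link{sparse_tensor}} with perturbed values.
#' @export
add_noise <- function(t, fraction, seed = 1L) {
  stopifnot(inherits(t, "sparse_symmetric_tensor"))
  if (fraction < 0) stop("fraction must be non-negative")
  m <- nrow(t$subs)
  if (m == 0L) stop("cannot perturb an empty tensor")
  if (fraction == 0) return(t)
  delta <- fraction * mean(t$values)
  noise <- withr::with_seed(seed, stats::runif(m, -delta, delta))
  sparse_tensor(t$K, t$n, t$subs, pmax(t$values + noise, 0))
}
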