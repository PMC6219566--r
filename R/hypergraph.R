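#' Construct a metabolic hypergraph
#'
#' A metabolic network is represented as a hypergraph: vertices are
#' metabolites and each hyperedge is the full set of metabolites taking part
#' in one enzymatic reaction.  Reaction direction is not represented;
#' hyperedges are plain vertex sets.
#'
#' @param vertices character vector of unique metabolite identifiers.
#' @param edges named list of character vectors; each element is the vertex
#'   set of one reaction, names are the reaction identifiers.  May be empty.
#' @param annotations optional named character vector mapping reaction ids to
#'   EC numbers (e.g. \code{"1.1.1.1"}; partial classes such as
#'   \code{"1.1.-.-"} are allowed).
#'
#' @return An object of class \code{"hypergraph"} with fields
#'   \code{vertices}, \code{edges}, \code{annotations} and \code{has_null}.
#' @examples
#' g <- hypergraph(c("V1", "V2", "V3"),
#'                 list(E1 = "V1", E2 = c("V1", "V2"), E3 = c("V1", "V2", "V3")))
#' hypergraph_order(g)
#' @export
hypergraph <- function(vertices, edges = list(), annotations = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices))
    stop("duplicate vertex ids: ",
         paste(unique(vertices[duplicated(vertices)]), collapse = ", "))
  if (length(edges)) {
    if (is.null(names(edges)) || any(!nzchar(names(edges))))
      stop("all edges must be named with reaction ids")
    if (anyDuplicated(names(edges)))
      stop("duplicate edge ids")
    edges <- lapply(edges, as.character)
    for (id in names(edges)) {
      ev <- edges[[id]]
      if (length(ev) == 0L)
        stop("empty hyperedge: ", id)
      if (anyDuplicated(ev))
        stop("duplicate vertex in hyperedge ", id)
      missing <- setdiff(ev, vertices)
      if (length(missing))
        stop("hyperedge ", id, " refers to unknown vertices: ",
             paste(missing, collapse = ", "))
    }
  } else {
    edges <- stats::setNames(list(), character())
  }
  if (!is.null(annotations)) {
    annotations <- vapply(annotations, as.character, character(1))
    unknown <- setdiff(names(annotations), names(edges))
    if (length(unknown))
      stop("annotation for unknown edge id: ", paste(unknown, collapse = ", "))
  }
  structure(list(vertices = vertices, edges = edges,
                 annotations = annotations, has_null = FALSE,
                 null_id = NA_character_),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("Hypergraph:", length(x$vertices), "vertices,",
      length(x$edges), "hyperedges, order", hypergraph_order(x), "\n")
  if (isTRUE(x$has_null))
    cat("  null vertex appended:", x$null_id, "\n")
  if (!is.null(x$annotations))
    cat("  EC annotations:", length(x$annotations), "\n")
  invisible(x)
}

#' Number of real (non-null) vertices
#' @param g a \code{hypergraph}.
#' @return integer count of vertices, excluding the null vertex if present.
#' @export
n_real_vertices <- function(g) {
  length(g$vertices) - as.integer(isTRUE(g$has_null))
}

#' Real (non-null) vertex ids
#' @param g a \code{hypergraph}.
#' @return character vector of vertex ids excluding the null vertex.
#' @export
real_vertices <- function(g) {
  if (isTRUE(g$has_null)) setdiff(g$vertices, g$null_id) else g$vertices
}

#' Order of a hypergraph
#'
#' The order is the cardinality of the largest hyperedge, i.e. the number of
#' metabolites in the reaction with the most participants.  It equals the
#' order of the score tensor built for an alignment involving this network.
#'
#' @param g a \code{hypergraph}.
#' @return integer; 0 for an edgeless hypergraph.
#' @export
hypergraph_order <- function(g) {
  if (!length(g$edges)) return(0L)
  max(lengths(g$edges))
}

#' Binarize a stoichiometric matrix into an incidence matrix
#'
#' A stoichiometric matrix (rows = metabolites, columns = reactions, entries
#' = signed stoichiometric coefficients) is turned into the binary hypergraph
#' incidence matrix: an entry is 1 iff the coefficient is non-zero.  Sign and
#' magnitude (and hence reaction direction) are discarded.
#'
#' @param S numeric matrix with row names (metabolites) and column names
#'   (reactions).
#' @return integer 0/1 matrix with the same dimnames.
#' @export
binarize_stoichiometry <- function(S) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("stoichiometric matrix needs row (metabolite) and column (reaction) names")
  inc <- (S != 0) * 1L
  empty <- colSums(inc) == 0
  if (any(empty))
    stop("empty hyperedge: reaction column(s) with all-zero coefficients: ",
         paste(colnames(S)[empty], collapse = ", "))
  storage.mode(inc) <- "integer"
  inc
}

#' Build a hypergraph from an incidence matrix
#'
#' @param inc binary incidence matrix, rows = metabolites, columns =
#'   reactions; every column must contain at least one 1.
#' @param annotations optional named character vector of EC numbers keyed by
#'   reaction (column) id.
#' @return a \code{hypergraph} with one hyperedge per column.
#' @export
build_hypergraph <- function(inc, annotations = NULL) {
  inc <- as.matrix(inc)
  if (is.null(rownames(inc)) || (ncol(inc) > 0 && is.null(colnames(inc))))
    stop("incidence matrix needs row names (and column names if any columns)")
  if (!all(inc %in% c(0, 1)))
    stop("incidence matrix entries must be 0 or 1")
  edges <- lapply(seq_len(ncol(inc)), function(j) rownames(inc)[inc[, j] == 1])
  names(edges) <- colnames(inc)
  hypergraph(rownames(inc), edges, annotations)
}

#' Incidence matrix of a hypergraph
#'
#' Inverse of \code{\link{build_hypergraph}}; the null vertex, which belongs
#' to no edge, appears as an all-zero row when present.
#'
#' @param g a \code{hypergraph}.
#' @return integer 0/1 matrix, rows = vertices, columns = edges.
#' @export
as_incidence <- function(g) {
  inc <- matrix(0L, nrow = length(g$vertices), ncol = length(g$edges),
                dimnames = list(g$vertices, names(g$edges)))
  for (j in seq_along(g$edges))
    inc[g$edges[[j]], j] <- 1L
  inc
}

#' Append the null vertex
#'
#' Adds the placeholder vertex N used to align hyperedges of unequal size
#' and to represent insertions/deletions: an unmatched metabolite is aligned
#' to the other network's null vertex.  N belongs to no hyperedge, so the
#' hypergraph order is unchanged.
#'
#' @param g a \code{hypergraph} without a null vertex.
#' @return a copy of \code{g} with one extra vertex and \code{has_null = TRUE}.
#' @export
add_null_vertex <- function(g) {
  if (isTRUE(g$has_null))
    stop("hypergraph already has a null vertex")
  null_id <- "N"
  while (null_id %in% g$vertices)
    null_id <- paste0(null_id, "*")
  g$vertices <- c(g$vertices, null_id)
  g$has_null <- TRUE
  g$null_id <- null_id
  g
}
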