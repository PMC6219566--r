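#' Align two metabolic hypergraphs
#'
#' End-to-end pipeline: appends null vertices, builds the association score
#' tensor, maximises the alignment score with the shifted symmetric
#' higher-order power method, and discretizes the continuous solution into
#' a one-to-one vertex matching with the Hungarian algorithm.
#'
#' @param ga,gb annotated hypergraphs (without null vertices).
#' @param sim_table a \code{\link{compound_similarity_table}}.
#' @param census optional \code{\link{enzyme_census}}; defaults to the
#'   union of the two networks' EC annotations.
#' @param lambda vertex/edge balance in [0, 1]; default 0.9.
#' @param alpha power-method shift in [0, 1); default 0.01.
#' @param beta uniform fraction of the start vector; default 1.
#' @param gap_score score of null-involving diagonal entries; default 0.
#' @param tol,max_iter,seed iteration controls, see \code{\link{sshopm}}.
#' @param noise_fraction optional noise intensity applied to the tensor
#'   before optimisation (see \code{\link{add_noise}}); default 0.
#' @return object of class \code{"hypergraph_alignment"}: list with
#'   \code{matching} (data frame \code{a}, \code{b}), \code{result}
#'   (\code{\link{sshopm}} output), \code{tensor}, \code{index},
#'   \code{discrete_score}, and the parameters used.
#' @examples
#' ga <- hypergraph(c("V1", "V2"), list(E1 = c("V1", "V2")),
#'                  annotations = c(E1 = "1.1.1.1"))
#' gb <- hypergraph(c("W1", "W2"), list(F1 = c("W1", "W2")),
#'                  annotations = c(F1 = "1.1.1.2"))
#' sims <- compound_similarity_table(data.frame(
#'   a = c("V1", "V2"), b = c("W1", "W2"), score = c(0.9, 0.8)))
#' aln <- align_hypergraphs(ga, gb, sims)
#' aln$matching
#' @export
align_hypergraphs <- function(ga, gb, sim_table, census = NULL,
                              lambda = 0.9, alpha = 0.01, beta = 1,
                              gap_score = 0, tol = 1e-8, max_iter = 1000L,
                              seed = 1L, noise_fraction = 0) {
  if (!isTRUE(ga$has_null)) ga <- add_null_vertex(ga)
  if (!isTRUE(gb$has_null)) gb <- add_null_vertex(gb)
  built <- build_tensor(ga, gb, sim_table, census = census,
                        lambda = lambda, gap_score = gap_score)
  tensor <- built$tensor
  if (noise_fraction > 0)
    tensor <- add_noise(tensor, noise_fraction, seed = seed)
  res <- sshopm(tensor, alpha = alpha, beta = beta, tol = tol,
                max_iter = max_iter, seed = seed)
  matching <- discretize(res$x, built$index)
  matching <- refine_matching(matching, tensor, built$index)
  structure(list(matching = matching, result = res, tensor = tensor,
                 index = built$index,
                 discrete_score = discrete_score(tensor, matching,
                                                 built$index),
                 params = list(lambda = lambda, alpha = alpha, beta = beta,
                               gap_score = gap_score, tol = tol,
                               max_iter = max_iter, seed = seed,
                               noise_fraction = noise_fraction)),
            class = "hypergraph_alignment")
}

#' @export
print.hypergraph_alignment <- function(x, ...) {
  cat("Hypergraph alignment\n")
  cat("  association vertices:", x$index$n,
      " stored tensor elements:", nrow(x$tensor$subs),
      " order K:", x$tensor$K, "\n")
  cat("  SS-HOPM:", if (x$result$converged) "converged" else "not converged",
      "in", x$result$iterations, "iterations, gamma =",
      format(x$result$gamma, digits = 8), "\n")
  cat("  matched vertex pairs:", nrow(x$matching),
      " discrete score:", format(x$discrete_score, digits = 8), "\n")
  invisible(x)
}

#' Evaluate an alignment of a knockout benchmark pair
#'
#' Runs the full pipeline on a \code{\link{knockout}} pair (big network vs
#' retained sub-network) and scores it against the known identity truth.
#'
#' @param pair a \code{"benchmark_pair"}.
#' @param sim_table compound similarity table covering the big network.
#' @param census optional enzyme census.
#' @param ... further arguments passed to \code{\link{align_hypergraphs}}.
#' @return list with the \code{alignment} and the accuracy \code{report}
#'   (\code{score}, \code{ec}, \code{vc}).
#' @export
align_benchmark <- function(pair, sim_table, census = NULL, ...) {
  stopifnot(inherits(pair, "benchmark_pair"))
  aln <- align_hypergraphs(pair$g_big, pair$g_small, sim_table,
                           census = census, ...)
  rep <- accuracy_report(aln$tensor, aln$matching, aln$index,
                         pair$truth, pair$g_small)
  list(alignment = aln, report = rep)
}
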