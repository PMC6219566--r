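#' Initial alignment vector
#'
#' Builds the starting point for the power iteration as a convex blend of a
#' non-negative random vector and the uniform vector: x0 = (1 - beta) x_r +
#' beta x_u, rescaled to unit 2-norm.  beta = 1 gives the uniform start,
#' which in practice converges to the best-scoring stationary points.
#'
#' @param n vector length (number of association vertices).
#' @param beta uniform-component fraction in [0, 1].
#' @param seed RNG seed for the random component.
#' @return non-negative unit 2-norm vector of length \code{n}.
#' @export
initial_vector <- function(n, beta = 1, seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  xu <- rep(1 / sqrt(n), n)
  if (beta == 1) return(xu)
  xr <- withr::with_seed(seed, stats::runif(n))
  xr <- xr / sqrt(sum(xr^2))
  x0 <- (1 - beta) * xr + beta * xu
  x0 / sqrt(sum(x0^2))
}

#' Shifted symmetric higher-order power method
#'
#' Iterates x' = H (x)^(K-1) (the rotational tensor-vector product) and
#' x <- alpha x + (1 - alpha) x'/||x'||, renormalised to the unit sphere,
#' until the Rayleigh-type score gamma = S(x) = H x^K stabilises.  For a
#' non-negative tensor and non-negative start every iterate stays
#' non-negative, and the converged (gamma, x) approximates the dominant
#' Z-eigenpair, i.e. the relaxed optimum of the alignment problem.
#'
#' The shift alpha damps the update: alpha near 0 gives fast, accurate
#' convergence on alignment tensors, while alpha near 1 barely moves the
#' iterate.
#'
#' @param t a \code{\link{sparse_tensor}} with non-negative values.
#' @param alpha shift parameter in [0, 1); default 0.01.
#' @param beta uniform fraction of the start vector; default 1 (uniform).
#' @param x0 optional explicit start vector (overrides \code{beta}); must be
#'   non-negative, it is renormalised internally.
#' @param tol convergence tolerance; the run stops once both the score
#'   change |gamma_{n+1} - gamma_n| and the iterate change ||x_{n+1} -
#'   x_n|| fall below it (the score alone flattens before the iterate
#'   settles, which would leave the eigen-equation residual inflated);
#'   default 1e-8.
#' @param max_iter iteration cap; default 1000.
#' @param seed RNG seed used when \code{beta < 1}.
#' @return list of class \code{"sshopm_result"} with components \code{x}
#'   (unit non-negative vector), \code{gamma} (final score), \code{history}
#'   (per-iteration gamma), \code{converged}, \code{iterations}.
#' @export
sshopm <- function(t, alpha = 0.01, beta = 1, x0 = NULL, tol = 1e-8,
                   max_iter = 1000L, seed = 1L) {
  stopifnot(inherits(t, "sparse_symmetric_tensor"))
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  if (tol <= 0) stop("tol must be positive")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (is.null(x0)) {
    x <- initial_vector(t$n, beta, seed)
  } else {
    if (length(x0) != t$n) stop("x0 length does not match tensor dimension")
    if (any(x0 < 0)) stop("x0 must be non-negative")
    nrm <- sqrt(sum(x0^2))
    if (nrm == 0) stop("x0 must be non-zero")
    x <- x0 / nrm
  }
  history <- numeric(0)
  gamma_prev <- NA_real_
  x_prev <- NULL
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    xp <- as.numeric(rotational_ttv(t, x))
    gamma <- sum(x * xp)
    history <- c(history, gamma)
    iterations <- it
    if (!is.na(gamma_prev) && abs(gamma - gamma_prev) < tol &&
        sqrt(sum((x - x_prev)^2)) < tol) {
      converged <- TRUE
      break
    }
    gamma_prev <- gamma
    x_prev <- x
    nrm <- sqrt(sum(xp^2))
    if (nrm == 0)
      stop("iterate annihilated by the tensor (H x^(K-1) = 0); ",
           "the tensor has no support on the current vector")
    x <- alpha * x + (1 - alpha) * xp / nrm
    x <- x / sqrt(sum(x^2))
  }
  structure(list(x = x, gamma = history[iterations], history = history,
                 converged = converged, iterations = iterations),
            class = "sshopm_result")
}

#' @export
print.sshopm_result <- function(x, ...) {
  cat("SS-HOPM:", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iterations, gamma =",
      format(x$gamma, digits = 8), "\n")
  invisible(x)
}

#' Z-eigenpair residual
#'
#' Convergence diagnostic for a candidate Z-eigenpair: the 2-norm of
#' H x^(K-1) - gamma x.  Zero for an exact eigenpair.
#'
#' @param t a \code{\link{sparse_tensor}}.
#' @param x unit 2-norm vector.
#' @param gamma candidate Z-eigenvalue.
#' @return non-negative scalar.
#' @export
zeig_residual <- function(t, x, gamma) {
  xp <- as.numeric(rotational_ttv(t, x))
  sqrt(sum((xp - gamma * x)^2))
}
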