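#' Sparse super-symmetric tensor
#'
#' Canonical storage for a symmetric tensor of order \code{K} and dimension
#' \code{n}: each stored element is a sorted (non-decreasing) subscript tuple
#' with a non-negative value, and stands for all permutations of that tuple.
#' Only one representative per subscript multiset is kept, which is what
#' makes the rotational tensor-vector product cheap.
#'
#' On construction the \emph{contribution table} used by
#' \code{\link{rotational_ttv}} is precomputed: one row per (element,
#' distinct subscript value) combination, carrying the output slot, the
#' permutation multiplicity of the remaining K-1 subscripts, and those
#' remaining subscripts themselves.
#'
#' @param K tensor order (number of subscripts per element).
#' @param n dimension (subscripts range over 1..n).
#' @param subs integer matrix with \code{K} columns; each row a sorted
#'   subscript tuple.  Zero rows give the empty (all-zero) tensor.
#' @param values numeric vector of non-negative element values, one per row.
#' @return an object of class \code{"sparse_symmetric_tensor"}.
#' @export
sparse_tensor <- function(K, n, subs, values) {
  K <- as.integer(K); n <- as.integer(n)
  if (K < 1L) stop("tensor order K must be >= 1")
  if (n < 1L) stop("tensor dimension n must be >= 1")
  if (is.null(dim(subs))) subs <- matrix(as.integer(subs), ncol = K)
  subs <- matrix(as.integer(subs), ncol = K)
  values <- as.numeric(values)
  if (nrow(subs) != length(values))
    stop("subs and values lengths differ")
  if (nrow(subs)) {
    if (any(subs < 1L) || any(subs > n))
      stop("subscripts out of range 1..n")
    if (K > 1L && any(subs[, -1L, drop = FALSE] < subs[, -K, drop = FALSE]))
      stop("subscript tuples must be sorted non-decreasing (canonical form)")
    if (any(values < 0)) stop("tensor values must be non-negative")
    key <- do.call(paste, c(asplit(subs, 2), sep = ","))
    if (anyDuplicated(key)) stop("duplicate canonical subscript tuples")
    o <- order(key, method = "radix")
    subs <- subs[o, , drop = FALSE]
    values <- values[o]
  }
  obj <- list(K = K, n = n, subs = subs, values = values)
  obj$contrib <- .build_contrib(obj)
  class(obj) <- "sparse_symmetric_tensor"
  obj
}

#' @export
print.sparse_symmetric_tensor <- function(x, ...) {
  cat("Sparse super-symmetric tensor: order", x$K, ", dimension", x$n,
      ",", nrow(x$subs), "stored elements\n")
  invisible(x)
}

#' Number of distinct permutations of the K-1 remaining subscripts
#'
#' For a stored canonical element, the contribution it makes to one output
#' slot of the tensor-vector product must be weighted by the number of
#' distinct permutations of the subscripts that remain after removing one
#' copy of the output subscript, i.e. (K-1)! divided by the product of the
#' factorials of the remaining multiplicities.
#'
#' @param subscripts integer vector, the element's length-K subscript tuple.
#' @param removed one subscript value to delete one copy of.
#' @return integer permutation count.
#' @examples
#' remaining_multiplicity(c(1, 2, 3), 1)  # permutations of {2,3} -> 2
#' remaining_multiplicity(c(1, 1, 2), 1)  # permutations of {1,2} -> 2
#' @export
remaining_multiplicity <- function(subscripts, removed) {
  pos <- match(removed, subscripts)
  if (is.na(pos)) stop("removed subscript ", removed, " not present in tuple")
  rest <- subscripts[-pos]
  if (!length(rest)) return(1L)
  counts <- table(rest)
  as.integer(round(factorial(length(rest)) / prod(factorial(counts))))
}

# Precompute the contribution table: one row per stored element x distinct
# subscript value.  Rows are sorted by (output slot, element) so that the
# floating-point accumulation order is reproducible run to run.
.build_contrib <- function(t) {
  m <- nrow(t$subs); K <- t$K
  if (m == 0L) {
    return(list(elem = integer(0), out = integer(0), mult = numeric(0),
                rem = matrix(integer(0), 0, max(K - 1L, 0L))))
  }
  elem <- integer(0); out <- integer(0); mult <- numeric(0)
  rem <- vector("list", 0)
  for (i in seq_len(m)) {
    row <- t$subs[i, ]
    for (d in unique(row)) {
      elem <- c(elem, i)
      out <- c(out, d)
      mult <- c(mult, remaining_multiplicity(row, d))
      rem[[length(rem) + 1L]] <- row[-match(d, row)]
    }
  }
  rem <- if (K > 1L) do.call(rbind, rem) else matrix(integer(0), length(elem), 0L)
  o <- order(out, elem)
  list(elem = elem[o], out = out[o], mult = mult[o],
       rem = rem[o, , drop = FALSE])
}

#' Rotational tensor-vector product
#'
#' Computes y with \eqn{y_i = \sum H(i, j_2, \ldots, j_K) x_{j_2} \cdots
#' x_{j_K}}, where the sum runs over the full symmetric tensor, directly
#' from canonical storage: each stored element is "rotated" to every
#' distinct subscript value it contains, contributing its value times the
#' permutation count of the remaining subscripts times the product of the
#' vector entries at those subscripts.  The cost is at most (stored
#' elements) x K contributions, versus the K!-fold proliferation a dense
#' symmetric expansion would need.
#'
#' The returned vector carries an attribute \code{"counters"} with
#' \code{element_visits} (contribution rows processed) and
#' \code{multiplications} (scalar multiplies performed).
#'
#' @param t a \code{\link{sparse_tensor}}.
#' @param x numeric vector of length \code{t$n}.
#' @return numeric vector of length \code{t$n}.
#' @export
rotational_ttv <- function(t, x) {
  stopifnot(inherits(t, "sparse_symmetric_tensor"))
  if (length(x) != t$n)
    stop("vector length ", length(x), " does not match tensor dimension ", t$n)
  if (any(!is.finite(x))) stop("x must be finite")
  y <- numeric(t$n)
  ct <- t$contrib
  nvisit <- length(ct$elem)
  if (nvisit) {
    prods <- rep(1, nvisit)
    for (j in seq_len(ncol(ct$rem)))
      prods <- prods * x[ct$rem[, j]]
    contrib <- t$values[ct$elem] * ct$mult * prods
    # ct rows are sorted by output slot; rowsum preserves that order
    acc <- rowsum(contrib, group = ct$out)
    y[as.integer(rownames(acc))] <- acc[, 1]
  }
  attr(y, "counters") <- list(
    element_visits = nvisit,
    multiplications = nvisit * (t$K + 1L))
  y
}

#' Alignment score of a vector under the tensor
#'
#' The full K-mode contraction \eqn{S(x) = H \otimes_1 x \cdots \otimes_K x},
#' computed as the dot product of x with the rotational (K-1)-mode product.
#'
#' @param t a \code{\link{sparse_tensor}}.
#' @param x numeric vector of length \code{t$n}.
#' @return scalar score.
#' @export
tensor_score <- function(t, x) {
  y <- rotational_ttv(t, x)
  sum(x * as.numeric(y))
}

#' Sparse canonical storage of a dense symmetric array
#'
#' Convenience constructor for small tensors: collapses a dense K-way array
#' to canonical sorted-subscript storage, checking that entries related by
#' subscript permutation agree.
#'
#' @param arr a K-dimensional array with equal extents.
#' @param tol tolerance for the symmetry check.
#' @return a \code{\link{sparse_tensor}}.
#' @export
as_sparse_tensor <- function(arr, tol = 1e-12) {
  d <- dim(arr)
  if (is.null(d)) stop("arr must be an array")
  if (length(unique(d)) != 1L) stop("array extents must be equal")
  K <- length(d); n <- d[1]
  nz <- which(arr != 0)
  subs_all <- arrayInd(nz, d)
  canon <- t(apply(subs_all, 1, sort))
  if (length(nz) == 0L)
    return(sparse_tensor(K, n, matrix(integer(0), 0, K), numeric(0)))
  if (K == 1L) canon <- matrix(subs_all, ncol = 1)
  key <- do.call(paste, c(asplit(canon, 2), sep = ","))
  vals <- as.numeric(arr[nz])
  first <- !duplicated(key)
  ref <- stats::setNames(vals[first], key[first])
  if (any(abs(vals - ref[key]) > tol))
    stop("array is not symmetric under subscript permutation")
  # every permutation of a non-zero tuple must itself be non-zero
  orbit <- vapply(which(first), function(i) {
    counts <- table(canon[i, ])
    round(factorial(K) / prod(factorial(counts)))
  }, numeric(1))
  if (any(tabulate(match(key, key[first]), sum(first)) != orbit))
    stop("array is not symmetric under subscript permutation: ",
         "missing permuted entries")
  sparse_tensor(K, n, canon[first, , drop = FALSE], vals[first])
}
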