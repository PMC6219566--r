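#' Compound similarity table
#'
#' Holds pairwise structural similarity scores between metabolites (e.g.
#' Tanimoto scores from a chemoinformatics tool), in long format.  Lookups
#' for pairs absent from the table are imputed with the mean of all stored
#' off-diagonal pairs; absent self-pairs default to 1.
#'
#' @param pairs data frame with columns \code{a}, \code{b}, \code{score}
#'   (scores in [0, 1]).  Symmetric duplicates are tolerated when their
#'   scores agree and rejected otherwise.
#' @return an object of class \code{"compound_similarity_table"}.
#' @export
compound_similarity_table <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("a", "b", "score") %in% names(pairs)))
    stop("pairs must have columns a, b, score")
  if (nrow(pairs) == 0L)
    stop("empty compound similarity table: no mean score defined")
  a <- as.character(pairs$a)
  b <- as.character(pairs$b)
  score <- as.numeric(pairs$score)
  if (any(is.na(score)) || any(score < 0))
    stop("similarity scores must be non-negative numbers")
  key <- paste(pmin(a, b), pmax(a, b), sep = "\t")
  entries <- numeric(0)
  for (i in seq_along(key)) {
    prev <- entries[key[i]]
    if (!is.na(prev) && prev != score[i])
      stop("conflicting scores for pair (", a[i], ", ", b[i], "): ",
           prev, " vs ", score[i])
    entries[key[i]] <- score[i]
  }
  diag_mask <- pmin(a, b)[!duplicated(key)] == pmax(a, b)[!duplicated(key)]
  off <- entries[!diag_mask]
  structure(list(entries = entries,
                 mean_score = if (length(off)) mean(off) else NA_real_),
            class = "compound_similarity_table")
}

#' @export
print.compound_similarity_table <- function(x, ...) {
  cat("Compound similarity table:", length(x$entries), "stored pairs, mean",
      format(x$mean_score, digits = 4), "\n")
  invisible(x)
}

#' Look up a compound similarity score
#'
#' Returns the stored score for the pair, symmetric in its arguments.  A
#' missing pair is imputed with the table mean; a missing self-pair returns
#' 1 (a metabolite is maximally similar to itself).
#'
#' @param table a \code{\link{compound_similarity_table}}.
#' @param a,b compound ids.
#' @return similarity score.
#' @export
compound_similarity <- function(table, a, b) {
  stopifnot(inherits(table, "compound_similarity_table"))
  key <- paste(min(a, b), max(a, b), sep = "\t")
  s <- table$entries[key]
  if (!is.na(s)) return(unname(s))
  if (a == b) return(1)
  if (is.na(table$mean_score))
    stop("pair (", a, ", ", b, ") absent and the table stores no ",
         "off-diagonal pairs to impute from")
  table$mean_score
}

#' Enzyme census
#'
#' The multiset of EC numbers in scope, used as the denominator population
#' when scoring two enzymes by their shared EC class: the score is the
#' inverse of the number of census enzymes falling under the lowest shared
#' class, so a class crowded with enzymes confers little specificity.
#'
#' @param ec_numbers character vector of EC numbers (4 dot-separated
#'   fields); repeats are meaningful and kept.
#' @return an object of class \code{"enzyme_census"}.
#' @export
enzyme_census <- function(ec_numbers) {
  ec_numbers <- as.character(ec_numbers)
  if (!length(ec_numbers)) stop("empty enzyme census")
  fields <- strsplit(ec_numbers, ".", fixed = TRUE)
  bad <- lengths(fields) != 4L
  if (any(bad))
    stop("malformed EC number(s): ", paste(unique(ec_numbers[bad]), collapse = ", "))
  structure(list(ec_list = ec_numbers,
                 fields = do.call(rbind, fields)),
            class = "enzyme_census")
}

#' @export
print.enzyme_census <- function(x, ...) {
  cat("Enzyme census:", length(x$ec_list), "enzymes,",
      length(unique(x$ec_list)), "distinct EC numbers\n")
  invisible(x)
}

.ec_fields <- function(ec) {
  f <- strsplit(ec, ".", fixed = TRUE)[[1]]
  if (length(f) != 4L) stop("malformed EC number: ", ec)
  f
}

#' Lowest shared EC class of two enzymes
#'
#' EC numbers form a four-level hierarchy; the lowest shared class is the
#' longest common prefix of the two numbers, with the remaining fields
#' replaced by \code{"-"}.  A \code{"-"} field in either input matches
#' nothing, truncating the shared prefix there.
#'
#' @param ecA,ecB EC number strings, e.g. \code{"1.1.1.1"}.
#' @return the shared class, e.g. \code{"1.1.1.-"}; \code{"-.-.-.-"} when
#'   even the top class differs.
#' @examples
#' lowest_shared_class("1.1.1.1", "1.1.1.2")  # "1.1.1.-"
#' @export
lowest_shared_class <- function(ecA, ecB) {
  fa <- .ec_fields(ecA)
  fb <- .ec_fields(ecB)
  out <- rep("-", 4L)
  for (i in 1:4) {
    if (fa[i] == "-" || fb[i] == "-" || fa[i] != fb[i]) break
    out[i] <- fa[i]
  }
  paste(out, collapse = ".")
}

#' Enzyme similarity from the EC hierarchy
#'
#' The score is 1 over the number of census enzymes belonging to the lowest
#' EC class shared by the two enzymes.  Two enzymes sharing a rare specific
#' class score close to 1; a broad shared class dilutes the score.  Enzymes
#' with no shared class (different top-level EC field) score 0.
#'
#' @param ecA,ecB EC number strings.
#' @param census an \code{\link{enzyme_census}}.
#' @return similarity score in [0, 1].
#' @export
enzyme_similarity <- function(ecA, ecB, census) {
  stopifnot(inherits(census, "enzyme_census"))
  cls <- lowest_shared_class(ecA, ecB)
  cf <- .ec_fields(cls)
  depth <- match(TRUE, cf == "-", nomatch = 5L) - 1L
  if (depth == 0L) return(0)
  m <- rep(TRUE, nrow(census$fields))
  for (i in seq_len(depth))
    m <- m & census$fields[, i] == cf[i]
  n <- sum(m)
  if (n == 0L)
    stop("census contains no enzyme under shared class ", cls,
         "; census inconsistent with query (", ecA, ", ", ecB, ")")
  1 / n
}

#' Apply the vertex/edge balance factor
#'
#' The balance parameter lambda weights metabolite (vertex) similarity
#' against enzyme (hyperedge) similarity in the alignment score: vertex
#' scores are multiplied by lambda and edge scores by (1 - lambda).
#'
#' @param score non-negative similarity score.
#' @param role \code{"vertex"} or \code{"edge"}.
#' @param lambda balance parameter in [0, 1].
#' @return the weighted score.
#' @export
balance_score <- function(score, role = c("vertex", "edge"), lambda) {
  role <- match.arg(role)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (any(score < 0)) stop("score must be non-negative")
  if (role == "vertex") lambda * score else (1 - lambda) * score
}
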