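#' Read an incidence or stoichiometric matrix from TSV
#'
#' Format: first row holds reaction ids, first column metabolite ids, body
#' is 0/1 for an incidence matrix or any numeric for a stoichiometric
#' matrix (\code{mode = "stoichiometric"}, which is then binarized by the
#' caller).
#'
#' @param path TSV file path.
#' @param mode \code{"incidence"} (body must be 0/1) or
#'   \code{"stoichiometric"} (any numeric body).
#' @return numeric matrix with dimnames.
#' @export
read_incidence <- function(path, mode = c("incidence", "stoichiometric")) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-numeric cell at row '", rownames(m)[bad[1, 1]],
           "', column '", colnames(m)[bad[1, 2]], "' in ", path)
    storage.mode(m) <- "numeric"
  }
  if (anyNA(m)) stop("missing values in matrix file ", path)
  if (mode == "incidence" && !all(m %in% c(0, 1)))
    stop("incidence matrix body must be 0/1 (use mode = 'stoichiometric' ",
         "for signed coefficients): ", path)
  m
}

#' Write an incidence matrix to TSV
#'
#' @param inc matrix with dimnames.
#' @param path output file path.
#' @export
write_incidence <- function(inc, path) {
  df <- data.frame(id = rownames(inc), inc, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reaction EC annotations from a two-column TSV
#'
#' Format: \code{reaction_id<TAB>EC} without header.
#'
#' @param path TSV file path.
#' @return named character vector, reaction id to EC number.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("reaction_id", "ec"))
  if (anyDuplicated(df$reaction_id))
    stop("duplicate reaction id in annotations: ", path)
  stats::setNames(as.character(df$ec), as.character(df$reaction_id))
}

#' Read a long-format compound similarity table
#'
#' Format: \code{cid_a<TAB>cid_b<TAB>score} without header.
#'
#' @param path TSV file path.
#' @return a \code{\link{compound_similarity_table}}.
#' @export
read_compound_similarity <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("a", "b", "score"))
  compound_similarity_table(df)
}

#' Read an enzyme census (one EC number per line)
#'
#' @param path file path.
#' @return an \code{\link{enzyme_census}}.
#' @export
read_census <- function(path) {
  enzyme_census(readLines(path, warn = FALSE))
}

#' Dump a sparse tensor to TSV
#'
#' Format: a two-line header (\code{# K <order>}, \code{# n <dimension>})
#' followed by \code{i1,i2,...,iK<TAB>value} rows with canonical tuples.
#'
#' @param t a \code{\link{sparse_tensor}}.
#' @param path output file path.
#' @export
write_tensor <- function(t, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# K", t$K), paste("# n", t$n)), con)
  if (nrow(t$subs)) {
    keys <- do.call(paste, c(asplit(t$subs, 2), sep = ","))
    writeLines(paste(keys, format(t$values, digits = 17, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Load a sparse tensor dumped by \code{\link{write_tensor}}
#'
#' @param path TSV file path.
#' @return a \code{\link{sparse_tensor}}.
#' @export
read_tensor <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  getv <- function(tag) {
    h <- hdr[startsWith(hdr, paste("#", tag))]
    if (length(h) != 1L) stop("tensor file missing '# ", tag, "' header")
    as.integer(strsplit(h, " +")[[1]][3])
  }
  K <- getv("K"); n <- getv("n")
  if (!length(body))
    return(sparse_tensor(K, n, matrix(integer(0), 0, K), numeric(0)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  subs <- do.call(rbind, lapply(parts, function(p)
    as.integer(strsplit(p[1], ",", fixed = TRUE)[[1]])))
  sparse_tensor(K, n, subs, as.numeric(vapply(parts, `[`, character(1), 2)))
}

#' Write an alignment to TSV
#'
#' Format: \code{a_vertex<TAB>b_vertex<TAB>x_value} with header, where
#' \code{x_value} is the continuous alignment mass of the selected pair.
#'
#' @param aln a \code{"hypergraph_alignment"}.
#' @param path output file path.
#' @export
write_alignment <- function(aln, path) {
  m <- aln$matching
  xv <- if (nrow(m))
    aln$result$x[pair_to_flat(aln$index, m$a, m$b)] else numeric(0)
  utils::write.table(
    data.frame(a_vertex = m$a, b_vertex = m$b, x_value = xv),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run an alignment from a configuration list
#'
#' Orchestrates the pipeline from files to files: reads the two incidence
#' matrices, EC annotations and the compound similarity table, aligns, and
#' writes the alignment TSV, the per-iteration gamma history, a provenance
#' log (parameters, seed, association vertex and element counts, K), and,
#' when a truth file is supplied, an accuracy report.
#'
#' @param config list with paths \code{incidence_a}, \code{incidence_b},
#'   \code{ec_a}, \code{ec_b}, \code{compound_sim}, optional \code{census}
#'   and \code{truth}, parameters \code{lambda}, \code{alpha}, \code{beta},
#'   \code{tol}, \code{max_iter}, \code{seed}, \code{gap_score},
#'   \code{noise_fraction}, optional \code{stoichiometric} flag, and the
#'   output directory \code{out}.
#' @return invisibly, a list with the alignment and output paths.
#' @export
run_align <- function(config) {
  need <- c("incidence_a", "incidence_b", "compound_sim", "out")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config missing required entries: ", paste(miss, collapse = ", "))
  getp <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  stoich <- isTRUE(config$stoichiometric)
  mode <- if (stoich) "stoichiometric" else "incidence"
  read_net <- function(inc_path, ec_path) {
    m <- read_incidence(inc_path, mode = mode)
    if (stoich) m <- binarize_stoichiometry(m)
    ann <- if (!is.null(ec_path)) read_annotations(ec_path)
    build_hypergraph(m, ann)
  }
  ga <- stage("read network a", read_net(config$incidence_a, config$ec_a))
  gb <- stage("read network b", read_net(config$incidence_b, config$ec_b))
  sims <- stage("read compound similarity",
                read_compound_similarity(config$compound_sim))
  census <- if (!is.null(config$census))
    stage("read census", read_census(config$census))
  out <- config$out
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  aln <- stage("align", align_hypergraphs(
    ga, gb, sims, census = census,
    lambda = getp("lambda", 0.9), alpha = getp("alpha", 0.01),
    beta = getp("beta", 1), gap_score = getp("gap_score", 0),
    tol = getp("tol", 1e-8), max_iter = getp("max_iter", 1000L),
    seed = getp("seed", 1L), noise_fraction = getp("noise_fraction", 0)))
  paths <- list(alignment = file.path(out, "alignment.tsv"),
                history = file.path(out, "gamma_history.tsv"),
                provenance = file.path(out, "provenance.txt"))
  write_alignment(aln, paths$alignment)
  utils::write.table(
    data.frame(iteration = seq_along(aln$result$history),
               gamma = aln$result$history),
    paths$history, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- c(
    paste("n_association_vertices", aln$index$n),
    paste("n_stored_elements", nrow(aln$tensor$subs)),
    paste("K", aln$tensor$K),
    paste("iterations", aln$result$iterations),
    paste("converged", aln$result$converged),
    paste("gamma", format(aln$result$gamma, digits = 17)),
    paste("discrete_score", format(aln$discrete_score, digits = 17)),
    vapply(names(aln$params), function(k)
      paste(k, format(aln$params[[k]], digits = 17)), character(1)))
  writeLines(prov, paths$provenance)
  if (!is.null(config$truth)) {
    truth <- stage("read truth", utils::read.delim(
      config$truth, header = FALSE, stringsAsFactors = FALSE,
      col.names = c("a", "b")))
    g_small <- if (length(gb$edges) <= length(ga$edges)) gb else ga
    rep <- stage("evaluate", accuracy_report(
      aln$tensor, aln$matching, aln$index, truth, g_small))
    paths$accuracy <- file.path(out, "accuracy.tsv")
    utils::write.table(
      data.frame(metric = names(rep), value = unlist(rep)),
      paths$accuracy, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(alignment = aln, paths = paths))
}
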