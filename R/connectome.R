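# Connectivity matrices: construction from node time series, Fisher z
# transform, edge vectorization, file I/O and outlier QC.

# Clamp applied to Pearson r before atanh so perfectly (anti)correlated time
# courses give finite Fisher-z weights.
.R_CLAMP <- 1 - 1e-7

#' Construct a connectivity matrix object
#'
#' Validates symmetry and off-diagonal finiteness. The diagonal is undefined
#' by convention and stored as `NA`; it never enters any statistic.
#'
#' @param values square numeric matrix of Fisher-z edge weights.
#' @param subject_id subject identifier.
#' @return a `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(values, subject_id = "subject") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  n <- nrow(values)
  off <- values[upper.tri(values)] - t(values)[upper.tri(values)]
  if (any(abs(off) > 1e-10, na.rm = TRUE)) {
    stop("connectivity matrix is not symmetric (tolerance 1e-10)")
  }
  diag(values) <- NA_real_
  bad <- !is.finite(values) & !diag(n)
  if (any(bad)) {
    stop("non-finite off-diagonal edge weight(s) for subject ", subject_id)
  }
  structure(list(subject_id = as.character(subject_id),
                 values = values, n_nodes = n),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> subject", x$subject_id, "-", x$n_nodes, "nodes,",
      n_edges(x$n_nodes), "edges\n")
  invisible(x)
}

#' Compute a Fisher-z connectivity matrix from node time series
#'
#' Edge weight (i, j) is `atanh(r_ij)` where `r_ij` is the Pearson
#' correlation of node i's and node j's time courses, with r clamped to
#' \eqn{\pm(1 - 10^{-7})} so the transform stays finite. Nodes with a
#' zero-variance time course have undefined edges; they are reported via an
#' error rather than silently zeroed.
#'
#' @param node_timeseries numeric matrix, nodes in rows, timepoints in
#'   columns (>= 3 timepoints).
#' @param subject_id subject identifier.
#' @return a `connectivity_matrix`.
#' @export
compute_connectivity <- function(node_timeseries, subject_id = "subject") {
  stopifnot(is.matrix(node_timeseries), ncol(node_timeseries) >= 3)
  v <- apply(node_timeseries, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance time course for node(s) ",
         paste(which(v == 0), collapse = ", "),
         " of subject ", subject_id, "; their edges are undefined")
  }
  r <- stats::cor(t(node_timeseries))
  r <- pmin(pmax(r, -.R_CLAMP), .R_CLAMP)
  z <- atanh(r)
  z <- (z + t(z)) / 2  # enforce exact symmetry against rounding
  connectivity_matrix(z, subject_id)
}

#' Vectorize a connectivity matrix into the canonical edge vector
#'
#' Edges are ordered row-major over the upper triangle (i < j); see
#' [edge_pairs()]. The round trip with [devectorize_edges()] is exact.
#'
#' @param matrix a `connectivity_matrix` or a plain symmetric matrix.
#' @return named numeric vector of length `n_nodes * (n_nodes - 1) / 2`.
#' @export
vectorize_edges <- function(matrix) {
  m <- if (inherits(matrix, "connectivity_matrix")) matrix$values else matrix
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  v <- t(m)[lower.tri(m)]  # row-major upper triangle
  names(v) <- .edge_names(nrow(m))
  v
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' @param vector edge vector in canonical order.
#' @param n_nodes node count; inferred from the vector length if omitted.
#' @return symmetric numeric matrix with `NA` diagonal.
#' @export
devectorize_edges <- function(vector, n_nodes = NULL) {
  if (is.null(n_nodes)) {
    n_nodes <- .nodes_from_edges(length(vector))
    if (is.na(n_nodes)) {
      stop("edge vector length ", length(vector),
           " is not n*(n-1)/2 for any integer n")
    }
  }
  if (length(vector) != n_edges(n_nodes)) {
    stop("edge vector length ", length(vector), " does not match ",
         n_nodes, " nodes (expected ", n_edges(n_nodes), ")")
  }
  m <- matrix(NA_real_, n_nodes, n_nodes)
  m[lower.tri(m)] <- vector  # fills column-major lower = row-major upper of t
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Read / write a single-subject connectivity matrix
#'
#' Matrices are stored as square delimited text (whitespace or comma),
#' without row or column names; the diagonal is written as 0 and ignored on
#' read.
#'
#' @param path file path.
#' @param subject_id subject identifier (defaults to the file stem).
#' @return a `connectivity_matrix`.
#' @export
read_connectivity_matrix <- function(path, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  diag(m) <- 0
  connectivity_matrix(m, subject_id)
}

#' @rdname read_connectivity_matrix
#' @param matrix a `connectivity_matrix` to write.
#' @export
write_connectivity_matrix <- function(matrix, path) {
  m <- matrix$values
  diag(m) <- 0
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a cohort-level edge table
#'
#' Tab-separated, one row per subject: a `subject_id` column followed by one
#' column per edge named `i_j` (1-based node pair) in canonical order.
#'
#' @param path file path.
#' @return list with `subject_id` (character) and `edges`
#'   (subjects x edges numeric matrix).
#' @export
read_edge_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot("subject_id" %in% names(tab))
  ids <- as.character(tab$subject_id)
  X <- as.matrix(tab[, setdiff(names(tab), "subject_id"), drop = FALSE])
  nn <- .nodes_from_edges(ncol(X))
  if (is.na(nn)) stop("edge table has ", ncol(X), " edge columns; not n*(n-1)/2")
  if (!identical(colnames(X), .edge_names(nn))) {
    stop("edge columns are not in canonical i_j order")
  }
  rownames(X) <- ids
  list(subject_id = ids, edges = X)
}

#' @rdname read_edge_table
#' @param edges subjects x edges matrix with subject ids as row names.
#' @export
write_edge_table <- function(edges, path) {
  nn <- .nodes_from_edges(ncol(edges))
  stopifnot(!is.na(nn))
  tab <- data.frame(subject_id = rownames(edges), edges,
                    check.names = FALSE)
  colnames(tab) <- c("subject_id", .edge_names(nn))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag subjects whose edge-weight distribution is an outlier
#'
#' Each subject's edge vector is correlated with the elementwise median edge
#' vector of all other subjects; a subject is flagged when its score falls
#' below `Q1 - 1.5 IQR` of the score distribution. Flags are reported;
#' exclusion is left to the caller.
#'
#' @param matrices list of `connectivity_matrix` objects, or a subjects x
#'   edges matrix with subject ids as row names.
#' @return data.frame with `subject_id`, `score`, `flag`.
#' @export
flag_outlier_subjects <- function(matrices) {
  if (is.matrix(matrices)) {
    X <- matrices
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  } else {
    ids <- vapply(matrices, function(m) m$subject_id, character(1))
    X <- t(vapply(matrices, function(m) unname(vectorize_edges(m)),
                  numeric(n_edges(matrices[[1L]]$n_nodes))))
  }
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects to define outlier fences")
  # leave-one-out medians from per-edge order statistics: removing the
  # element of rank k from a sorted column shifts the order statistics at
  # or above k up by one, so only two order statistics per edge are needed
  E <- ncol(X)
  S <- apply(X, 2L, sort.int)
  K <- apply(X, 2L, rank, ties.method = "first")
  base <- (seq_len(E) - 1L) * n
  m <- n - 1L
  score <- numeric(n)
  for (i in seq_len(n)) {
    k <- K[i, ]
    med <- if (m %% 2L == 1L) {
      h <- (m + 1L) %/% 2L
      S[base + h + (k <= h)]
    } else {
      h1 <- m %/% 2L
      (S[base + h1 + (k <= h1)] + S[base + h1 + 1L + (k <= h1 + 1L)]) / 2
    }
    score[i] <- .safe_cor(X[i, ], med)
  }
  q <- stats::quantile(score, c(0.25, 0.75), names = FALSE)
  fence <- q[1L] - 1.5 * (q[2L] - q[1L])
  data.frame(subject_id = ids, score = score, flag = score < fence,
             stringsAsFactors = FALSE)
}
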