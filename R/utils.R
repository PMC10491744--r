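# Internal helpers shared across modules.

#' Number of unique undirected edges among `n_nodes` nodes
#'
#' @param n_nodes number of atlas nodes.
#' @return integer `n_nodes * (n_nodes - 1) / 2`.
#' @export
n_edges <- function(n_nodes) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1L, n_nodes >= 2)
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

# Invert n_edges: number of nodes whose upper triangle has `n_edge` entries,
# or NA if no integer solution exists.
.nodes_from_edges <- function(n_edge) {
  n <- (1 + sqrt(1 + 8 * n_edge)) / 2
  if (abs(n - round(n)) > 1e-8) return(NA_integer_)
  as.integer(round(n))
}

#' Canonical edge ordering: node pairs of the upper triangle
#'
#' Edges are ordered row-major over the upper triangle (i < j): (1,2), (1,3),
#' ..., (1,n), (2,3), ... This single convention is used everywhere an edge
#' vector, mask or index appears.
#'
#' @param n_nodes number of atlas nodes.
#' @return two-column integer matrix with columns `i`, `j` (1-based node ids).
#' @export
edge_pairs <- function(n_nodes) {
  n <- as.integer(n_nodes)
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

# Edge names "i_j" (1-based) used as column headers in cohort edge tables.
.edge_names <- function(n_nodes) {
  p <- edge_pairs(n_nodes)
  paste0(p[, 1L], "_", p[, 2L])
}

# Ordinary least squares with degenerate-regressor handling: a column of the
# design with (near-)zero variance gets coefficient 0 and is absorbed into
# the intercept. Returns c(intercept, slopes...) aligned with ncol(Z).
.ols_fit <- function(Z, y) {
  n <- length(y)
  k <- if (is.null(dim(Z))) 1L else ncol(Z)
  Z <- matrix(Z, nrow = n)
  if (n < k + 1L) {
    stop("need at least ", k + 1L, " observations to fit ", k,
         " slope(s) plus an intercept; got ", n)
  }
  keep <- apply(Z, 2L, function(z) stats::var(z) > 1e-12 * max(mean(z^2), 1))
  beta <- numeric(k)
  if (!any(keep)) {
    return(c(intercept = mean(y), beta))
  }
  fit <- stats::lm.fit(cbind(1, Z[, keep, drop = FALSE]), y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  beta[keep] <- cf[-1L]
  c(intercept = cf[[1L]], beta)
}

# Two-tailed p for a Pearson correlation via the t transform,
# t = r * sqrt(df / (1 - r^2)), df residual degrees of freedom.
# With df < 1 no test is possible and p = 1 throughout.
.pearson_p <- function(r, df) {
  if (df < 1) return(rep(1, length(r)))
  r <- pmin(1, pmax(-1, r))
  p <- numeric(length(r))
  sat <- (1 - r^2) <= .Machine$double.eps
  p[sat] <- 0
  t <- abs(r[!sat]) * sqrt(df / (1 - r[!sat]^2))
  p[!sat] <- 2 * stats::pt(-t, df)
  p
}

# Pearson r of two vectors with a zero-variance guard (returns 0).
.safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}
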