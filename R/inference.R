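# Whole-model inference: permutation testing, covariate-adjusted
# concordance, error metrics and confound checks.

#' Root mean square error
#'
#' @param predicted,observed aligned numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0L) stop("empty input")
  if (length(predicted) != length(observed)) stop("length mismatch")
  sqrt(mean((predicted - observed)^2))
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlates the least-squares residuals of `x` and `y` after regression on
#' the covariates plus an intercept; the two-tailed p uses
#' `df = n - 2 - n_covariates`. With no covariates this reduces to the plain
#' Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix / data.frame of control variables, or
#'   `NULL` for a plain correlation.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  k <- 0L
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    stopifnot(nrow(Z) == n)
    k <- ncol(Z)
    if (n <= k + 2L) stop("need n > n_covariates + 2")
    D <- cbind(1, Z)
    qd <- qr(D)
    if (qd$rank < ncol(D)) stop("rank-deficient covariate matrix")
    x <- stats::residuals(stats::lm.fit(D, x))
    y <- stats::residuals(stats::lm.fit(D, y))
  } else if (n <= 2L) {
    stop("need n > 2")
  }
  r <- .safe_cor(x, y)
  df <- n - 2L - k
  list(r = r, p = .pearson_p(r, df)[1L], df = df, n = n)
}

#' Permutation test of CPM predictive performance
#'
#' The correspondence between clinical scores and connectomes is shuffled
#' `n_perm` times (covariates stay attached to their subjects) and the full
#' leave-one-out pipeline — per-fold edge selection and model fitting — is
#' rerun on each shuffle. For each model the Monte-Carlo p is
#' `p_perm = (1 + #\{null r >= observed r\}) / (n_perm + 1)` (add-one
#' convention, weak ties counted); the raw proportion of null r at or above
#' the observed r is also reported.
#'
#' @param cohort a `cpm_cohort`.
#' @param target score column name.
#' @param alpha edge-selection threshold.
#' @param n_perm number of random shuffles (default 5000).
#' @param seed integer seed making the shuffles reproducible.
#' @param perms optional integer matrix (`n_perm` x n) of explicit subject
#'   orderings, e.g. the exhaustive set at small n; overrides random
#'   shuffling.
#' @return a `perm_result` with `observed` r per model, `null` (n_perm x 3
#'   matrix of null r), `p_perm`, `raw_proportion`, `n_perm`, `seed`.
#' @export
permutation_test <- function(cohort, target, alpha = 0.001, n_perm = 5000,
                             seed = NULL, perms = NULL) {
  y <- as.numeric(cohort$scores[[target]])
  if (anyNA(y)) stop("target '", target, "' has missing values; filter first")
  X <- cohort$edges
  n <- length(y)
  if (!is.null(perms)) {
    perms <- as.matrix(perms)
    stopifnot(ncol(perms) == n)
    n_perm <- nrow(perms)
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cs <- colSums(X)
  cq <- colSums(X * X)
  tX <- t(X)
  obs <- .loocv_engine(X, y, alpha, keep_masks = FALSE,
                       cs = cs, cq = cq, tX = tX)$r
  null_r <- matrix(NA_real_, n_perm, 3L,
                   dimnames = list(NULL, names(obs)))
  for (b in seq_len(n_perm)) {
    ord <- if (is.null(perms)) sample.int(n) else perms[b, ]
    null_r[b, ] <- .loocv_engine(X, y[ord], alpha, keep_masks = FALSE,
                                 cs = cs, cq = cq, tX = tX)$r
  }
  ge <- colSums(sweep(null_r, 2L, obs, `>=`))
  structure(list(observed = obs, null = null_r,
                 p_perm = (1 + ge) / (n_perm + 1),
                 raw_proportion = ge / n_perm,
                 n_perm = n_perm, seed = seed, target = target,
                 alpha = alpha, n = n),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("<perm_result> target", x$target, "|", x$n_perm, "shuffles\n")
  for (m in names(x$observed)) {
    cat(sprintf("  %-9s observed r = %.3f, p_perm = %.4f\n",
                m, x$observed[[m]], x$p_perm[[m]]))
  }
  invisible(x)
}

#' Head-motion and inter-scale confound checks
#'
#' Reports the Pearson correlation (with p) between mean framewise
#' displacement and each clinical target, and between the targets
#' themselves, mirroring the standard motion-confound audit for
#' connectome-based prediction.
#'
#' @param cohort a `cpm_cohort`.
#' @param targets score columns to check (default: all in the cohort).
#' @return data.frame with `pair`, `r`, `p`, `n`; rows for FD vs target are
#'   skipped with a warning when `mean_fd` is absent.
#' @export
confound_check <- function(cohort, targets = names(cohort$scores)) {
  rows <- list()
  add <- function(name, a, b) {
    ok <- stats::complete.cases(a, b)
    pr <- partial_pearson(a[ok], b[ok])
    rows[[length(rows) + 1L]] <<- data.frame(pair = name, r = pr$r,
                                             p = pr$p, n = pr$n)
  }
  fd <- cohort$covariates$mean_fd
  if (is.null(fd)) {
    warning("cohort has no mean_fd covariate; motion check skipped")
  } else {
    for (t in targets) add(paste0("mean_fd~", t), fd, cohort$scores[[t]])
  }
  if (length(targets) >= 2L) {
    cmb <- utils::combn(targets, 2L)
    for (k in seq_len(ncol(cmb))) {
      add(paste0(cmb[1L, k], "~", cmb[2L, k]),
          cohort$scores[[cmb[1L, k]]], cohort$scores[[cmb[2L, k]]])
    }
  }
  do.call(rbind, rows)
}
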