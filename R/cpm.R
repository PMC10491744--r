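# Connectome-based predictive modeling core: edge-wise selection, network
# strength, linear models, leave-one-out cross-validation, consensus edges.

#' Edge-wise association of connectivity with a clinical score
#'
#' Pearson r per edge plus a two-tailed p from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' Edges with (numerically) zero variance carry r = 0, p = 1 so they can
#' never be selected.
#'
#' @param edge_matrix subjects x edges numeric matrix.
#' @param scores per-subject clinical score (non-constant).
#' @return list with numeric vectors `r` and `p` (one entry per edge) and
#'   `n` subjects used.
#' @export
correlate_edges <- function(edge_matrix, scores) {
  X <- as.matrix(edge_matrix)
  y <- as.numeric(scores)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 4L) stop("need at least 4 subjects; got ", n)
  if (anyNA(y)) stop("scores contain NA; filter the cohort first")
  if (stats::var(y) == 0) stop("score vector is constant")
  yc <- y - mean(y)
  cs <- colMeans(X)
  num <- as.vector(crossprod(X, yc))           # sum x*yc = sum (x-mean) yc
  vx <- colSums(X^2) - n * cs^2
  vy <- sum(yc^2)
  const <- !(vx > 1e-12 * pmax(colSums(X^2), 1))
  r <- numeric(ncol(X))
  r[!const] <- num[!const] / sqrt(vx[!const] * vy)
  r <- pmin(1, pmax(-1, r))
  p <- .pearson_p(r, n - 2L)
  p[const] <- 1
  r[const] <- 0
  list(r = r, p = p, n = n)
}

#' Select predictive edges at a p-value threshold
#'
#' An edge enters the positive network iff `p < alpha` (strictly) and
#' `r > 0`; the negative network iff `p < alpha` and `r < 0`. The two masks
#' are disjoint by construction; empty masks are legal.
#'
#' @param stats edge statistics from [correlate_edges()].
#' @param alpha selection threshold (default 0.001).
#' @return list with sorted integer edge-index vectors `pos` and `neg`.
#' @export
select_edges <- function(stats, alpha = 0.001) {
  stopifnot(alpha > 0, alpha < 1)
  list(pos = which(stats$p < alpha & stats$r > 0),
       neg = which(stats$p < alpha & stats$r < 0))
}

#' Network strength: sum of edge weights over a mask
#'
#' @param edge_vector a subject's canonical edge vector, or a subjects x
#'   edges matrix (one strength per row).
#' @param mask integer edge indices or logical mask.
#' @return numeric strength(s); 0 for an empty mask.
#' @export
network_strength <- function(edge_vector, mask) {
  if (is.logical(mask)) {
    len <- length(mask)
    mask <- which(mask)
  } else {
    len <- NULL
  }
  if (is.matrix(edge_vector)) {
    if (!is.null(len) && len != ncol(edge_vector)) {
      stop("mask length does not match number of edges")
    }
    if (length(mask) && max(mask) > ncol(edge_vector)) {
      stop("mask indexes beyond the edge vector")
    }
    if (!length(mask)) return(numeric(nrow(edge_vector)))
    return(rowSums(edge_vector[, mask, drop = FALSE]))
  }
  if (!is.null(len) && len != length(edge_vector)) {
    stop("mask length does not match number of edges")
  }
  if (length(mask) && max(mask) > length(edge_vector)) {
    stop("mask indexes beyond the edge vector")
  }
  if (!length(mask)) return(0)
  sum(edge_vector[mask])
}

#' Fit the linear model relating network strength to the clinical score
#'
#' Ordinary least squares. For `model = "combined"` the design holds both
#' the positive- and negative-network strengths (two slopes plus intercept).
#' A strength column with zero variance (e.g. from an empty mask) gets slope
#' 0 and is absorbed into the intercept, so an intercept-only fit — the
#' training-mean prediction — is the degenerate limit.
#'
#' @param strengths numeric vector (single network) or two-column matrix
#'   (combined model).
#' @param scores per-subject clinical score.
#' @param model one of `"positive"`, `"negative"`, `"combined"`.
#' @return named numeric vector `c(intercept, slope...)`.
#' @export
fit_strength_model <- function(strengths, scores,
                               model = c("positive", "negative", "combined")) {
  model <- match.arg(model)
  y <- as.numeric(scores)
  if (model == "combined") {
    stopifnot(is.matrix(strengths), ncol(strengths) == 2L)
    cf <- .ols_fit(strengths, y)
    names(cf) <- c("intercept", "slope_pos", "slope_neg")
  } else {
    strengths <- as.numeric(strengths)
    cf <- .ols_fit(matrix(strengths, ncol = 1L), y)
    names(cf) <- c("intercept", "slope")
  }
  cf
}

#' Train a CPM network model on a full cohort
#'
#' Runs edge selection on all subjects and fits the positive, negative and
#' combined strength models. The result is the frozen, transferable
#' artifact: masks plus coefficients, applied to new data without any
#' re-selection or re-fitting.
#'
#' @param cohort a `cpm_cohort`.
#' @param target score column name.
#' @param alpha edge-selection threshold.
#' @return a `network_model`.
#' @export
train_cpm <- function(cohort, target, alpha = 0.001) {
  y <- cohort$scores[[target]]
  if (is.null(y)) stop("cohort has no target column '", target, "'")
  if (anyNA(y)) stop("target '", target, "' has missing values; filter first")
  es <- correlate_edges(cohort$edges, y)
  masks <- select_edges(es, alpha)
  sp <- network_strength(cohort$edges, masks$pos)
  sn <- network_strength(cohort$edges, masks$neg)
  structure(list(
    pos_mask = as.integer(masks$pos),
    neg_mask = as.integer(masks$neg),
    coefficients = list(
      positive = fit_strength_model(sp, y, "positive"),
      negative = fit_strength_model(sn, y, "negative"),
      combined = fit_strength_model(cbind(sp, sn), y, "combined")),
    target = target, alpha = alpha,
    n_train = length(y), n_nodes = cohort$n_nodes,
    n_edges = ncol(cohort$edges),
    training_subjects = cohort$subject_id,
    version = as.character(utils::packageVersion("moodcpm"))),
    class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> target", x$target, "| alpha", x$alpha,
      "| n_train", x$n_train, "\n  positive network:", length(x$pos_mask),
      "edges; negative network:", length(x$neg_mask), "edges\n")
  invisible(x)
}

#' Predict a clinical score from a frozen network model
#'
#' `intercept + sum(slope_k * strength_k)` using the model's frozen masks.
#'
#' @param model a `network_model`.
#' @param edge_vector one subject's canonical edge vector, or a subjects x
#'   edges matrix.
#' @param which model name: `"positive"`, `"negative"` or `"combined"`.
#' @return predicted score(s).
#' @export
predict_score <- function(model, edge_vector,
                          which = c("combined", "positive", "negative")) {
  which <- match.arg(which)
  ne <- if (is.matrix(edge_vector)) ncol(edge_vector) else length(edge_vector)
  if (ne != model$n_edges) {
    stop("edge vector length ", ne, " does not match model (",
         model$n_edges, " edges)")
  }
  cf <- model$coefficients[[which]]
  if (which == "combined") {
    sp <- network_strength(edge_vector, model$pos_mask)
    sn <- network_strength(edge_vector, model$neg_mask)
    cf[["intercept"]] + cf[["slope_pos"]] * sp + cf[["slope_neg"]] * sn
  } else {
    mask <- if (which == "positive") model$pos_mask else model$neg_mask
    cf[["intercept"]] + cf[["slope"]] * network_strength(edge_vector, mask)
  }
}

# LOOCV engine. For fold i, per-edge training statistics are derived from
# column sums of the full X (independent of the left-out score) and one
# matrix product crossprod(X, Y0), where column i of Y0 is the score vector
# with entry i zeroed — an exact training-only sum, with no subtract-back
# cancellation, so a perturbation of subject i's score provably leaves fold
# i untouched bit for bit. Selection p < alpha is applied through the
# equivalent critical threshold r^2 > rc2 (df is the same in every fold),
# avoiding per-edge t CDF evaluations: p < alpha <=> |t| > t_crit <=>
# r^2 > t_crit^2 / (df + t_crit^2), all inequalities strict.
.loocv_engine <- function(X, y, alpha, keep_masks = TRUE,
                          cs = NULL, cq = NULL, tX = NULL) {
  n <- nrow(X)
  E <- ncol(X)
  if (is.null(cs)) cs <- colSums(X)
  if (is.null(cq)) cq <- colSums(X * X)
  if (is.null(tX)) tX <- t(X)
  Y0 <- matrix(y, n, n)
  diag(Y0) <- 0
  P <- crossprod(X, Y0)                      # E x n; col i = training sums
  pred <- matrix(NA_real_, n, 3L,
                 dimnames = list(NULL, c("positive", "negative", "combined")))
  pos_count <- integer(E)
  neg_count <- integer(E)
  fold_masks <- if (keep_masks) vector("list", n) else NULL
  m <- n - 1L
  df <- m - 2L
  rc2 <- if (df >= 1L) {
    tc <- stats::qt(1 - alpha / 2, df)
    tc^2 / (df + tc^2)
  } else Inf                                  # df < 1: nothing selectable
  for (i in seq_len(n)) {
    xi <- tX[, i]
    yi <- y[-i]
    S <- cs - xi
    Q <- cq - xi * xi
    Sy <- sum(yi)
    vy <- sum((yi - Sy / m)^2)
    cov <- P[, i] - S * (Sy / m)
    vx <- Q - S * S / m
    ok <- (vy > 0) & (vx > 1e-12 * pmax(Q, 1))  # non-constant only
    sel <- ok & (cov * cov > rc2 * vx * vy)     # strict: r^2 > rc2
    pos <- which(sel & cov > 0)
    neg <- which(sel & cov < 0)
    pos_count[pos] <- pos_count[pos] + 1L
    neg_count[neg] <- neg_count[neg] + 1L
    if (keep_masks) fold_masks[[i]] <- list(pos = pos, neg = neg)
    sp <- network_strength(X, pos)
    sn <- network_strength(X, neg)
    # closed-form OLS on centered strengths; same degenerate-column rule as
    # .ols_fit (zero-variance regressor -> slope 0, absorbed in intercept)
    ybar <- Sy / m
    ycn <- yi - ybar
    p1 <- sp[-i]; p2 <- sn[-i]
    m1 <- mean(p1); m2 <- mean(p2)
    c1 <- p1 - m1; c2 <- p2 - m2
    v1 <- sum(c1 * c1); v2 <- sum(c2 * c2)
    ok1 <- v1 > 1e-12 * max(sum(p1 * p1) / m, 1) * (m - 1)
    ok2 <- v2 > 1e-12 * max(sum(p2 * p2) / m, 1) * (m - 1)
    b_p <- if (ok1) sum(c1 * ycn) / v1 else 0
    b_n <- if (ok2) sum(c2 * ycn) / v2 else 0
    pred[i, 1L] <- (ybar - b_p * m1) + b_p * sp[i]
    pred[i, 2L] <- (ybar - b_n * m2) + b_n * sn[i]
    if (ok1 && ok2) {
      c12 <- sum(c1 * c2)
      det <- v1 * v2 - c12 * c12
      if (det > 1e-12 * v1 * v2) {
        g1 <- sum(c1 * ycn); g2 <- sum(c2 * ycn)
        bc1 <- (v2 * g1 - c12 * g2) / det
        bc2 <- (v1 * g2 - c12 * g1) / det
      } else {                       # collinear strengths: keep first only
        bc1 <- b_p; bc2 <- 0
      }
    } else {
      bc1 <- b_p * ok1; bc2 <- b_n * ok2
    }
    pred[i, 3L] <- (ybar - bc1 * m1 - bc2 * m2) + bc1 * sp[i] + bc2 * sn[i]
  }
  r_mod <- vapply(1:3, function(k) .safe_cor(pred[, k], y), numeric(1))
  names(r_mod) <- colnames(pred)
  rmse_mod <- vapply(1:3, function(k) rmse(pred[, k], y), numeric(1))
  names(rmse_mod) <- colnames(pred)
  list(predictions = pred, r = r_mod, rmse = rmse_mod,
       consensus = list(pos = which(pos_count == n),
                        neg = which(neg_count == n)),
       fold_masks = fold_masks)
}

#' Leave-one-out cross-validated CPM
#'
#' For each subject i the full pipeline — edge selection at `alpha` and
#' strength-model fitting — is rerun on the remaining n - 1 subjects only,
#' and subject i's score is predicted from the fold's model. Folds run in
#' subject order; there is no randomness. Folds where a mask is empty
#' predict the training-mean score for that model (the degenerate limit of
#' the strength fit). Concordance r (0 if the predictions are constant) and
#' RMSE are computed over all n held-out predictions.
#'
#' @param cohort a `cpm_cohort`.
#' @param target score column name (must have no missing values; use
#'   [assemble_cohort()] to pre-filter).
#' @param alpha edge-selection threshold (default 0.001).
#' @param keep_fold_masks keep the per-fold selected edges (memory permitting).
#' @return a `cpm_result`: per-subject `predictions` (positive / negative /
#'   combined), `observed`, per-model `r` and `rmse`, `consensus` masks
#'   (edges selected in every fold), and optionally `fold_masks`.
#' @export
run_loocv <- function(cohort, target, alpha = 0.001, keep_fold_masks = TRUE) {
  y <- cohort$scores[[target]]
  if (is.null(y)) stop("cohort has no target column '", target, "'")
  if (anyNA(y)) stop("target '", target, "' has missing values; filter first")
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3L) stop("LOOCV needs at least 3 subjects")
  if (n < 10L) warning("fewer than 10 subjects; LOOCV estimates will be unstable")
  out <- .loocv_engine(cohort$edges, y, alpha, keep_masks = keep_fold_masks)
  structure(list(subject_id = cohort$subject_id,
                 observed = y, predictions = out$predictions,
                 r = out$r, rmse = out$rmse,
                 consensus = out$consensus, fold_masks = out$fold_masks,
                 target = target, alpha = alpha, n = n,
                 n_nodes = cohort$n_nodes, p_perm = NULL),
            class = "cpm_result")
}

#' @export
print.cpm_result <- function(x, ...) {
  cat("<cpm_result> target", x$target, "| n =", x$n, "| alpha", x$alpha, "\n")
  for (m in names(x$r)) {
    cat(sprintf("  %-9s r = %.3f, RMSE = %.2f\n", m, x$r[[m]], x$rmse[[m]]))
  }
  cat("  consensus edges: ", length(x$consensus$pos), "positive /",
      length(x$consensus$neg), "negative\n")
  invisible(x)
}

#' Consensus (common) edges across cross-validation folds
#'
#' An edge belongs to the consensus mask of a sign iff it was selected in
#' every fold's mask of that sign; these common edges are the basis for
#' network interpretation.
#'
#' @param fold_masks list of per-fold `list(pos=, neg=)` integer index masks.
#' @return list with sorted integer index vectors `pos` and `neg`.
#' @export
consensus_masks <- function(fold_masks) {
  stopifnot(length(fold_masks) >= 1L)
  list(pos = sort(Reduce(intersect, lapply(fold_masks, `[[`, "pos"))),
       neg = sort(Reduce(intersect, lapply(fold_masks, `[[`, "neg"))))
}

#' Serialize / deserialize a network model as JSON
#'
#' Masks are stored as sorted 1-based edge-index lists together with the
#' coefficients and training metadata; the round trip is lossless.
#'
#' @param model a `network_model`.
#' @param path output path.
#' @return `path` invisibly; `read_network_model()` returns the model.
#' @export
write_network_model <- function(model, path) {
  obj <- unclass(model)
  obj$coefficients <- lapply(obj$coefficients, as.list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_model
#' @export
read_network_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$pos_mask <- as.integer(obj$pos_mask)
  obj$neg_mask <- as.integer(obj$neg_mask)
  obj$coefficients <- lapply(obj$coefficients, unlist)
  structure(obj, class = "network_model")
}
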