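# Independent oracles: deliberately naive loop/closed-form implementations,
# kept free of the package's fast code paths.

# Pearson r from the raw covariance formula, elementwise loops only.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (k in seq_len(n)) {
    sx <- sx + x[k]; sy <- sy + y[k]
    sxx <- sxx + x[k]^2; syy <- syy + y[k]^2
    sxy <- sxy + x[k] * y[k]
  }
  num <- sxy - sx * sy / n
  den <- sqrt((sxx - sx^2 / n) * (syy - sy^2 / n))
  num / den
}

# Two-tailed p via the t transform, written out directly.
oracle_pearson_p <- function(r, df) {
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

oracle_edge_stats <- function(X, y) {
  E <- ncol(X)
  r <- numeric(E); p <- numeric(E)
  for (e in seq_len(E)) {
    if (stats::var(X[, e]) == 0) {
      r[e] <- 0; p[e] <- 1
    } else {
      r[e] <- oracle_pearson(X[, e], y)
      p[e] <- oracle_pearson_p(r[e], length(y) - 2)
    }
  }
  list(r = r, p = p)
}

# OLS by explicit normal equations solve.
oracle_ols <- function(Z, y) {
  D <- cbind(1, Z)
  solve(t(D) %*% D, t(D) %*% y)[, 1L]
}

# Partial correlation by two-stage residual regression using lm().
oracle_partial <- function(x, y, Z) {
  rx <- unname(stats::residuals(stats::lm(x ~ Z)))
  ry <- unname(stats::residuals(stats::lm(y ~ Z)))
  r <- oracle_pearson(rx, ry)
  df <- length(x) - 2 - ncol(as.matrix(Z))
  list(r = r, p = oracle_pearson_p(r, df))
}

oracle_rmse <- function(pred, obs) {
  s <- 0
  for (k in seq_along(pred)) s <- s + (pred[k] - obs[k])^2
  sqrt(s / length(pred))
}

oracle_strength <- function(v, mask_logical) {
  s <- 0
  for (e in seq_along(v)) if (mask_logical[e]) s <- s + v[e]
  s
}

# Naive LOOCV built from scratch: explicit subsetting, cor.test-style p via
# the t transform, lm() fits. Mirrors the published CPM protocol directly.
oracle_loocv <- function(X, y, alpha) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, 3L)
  fold_masks <- vector("list", n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    st <- oracle_edge_stats(Xtr, ytr)
    pos <- which(st$p < alpha & st$r > 0)
    neg <- which(st$p < alpha & st$r < 0)
    fold_masks[[i]] <- list(pos = pos, neg = neg)
    sp_tr <- if (length(pos)) rowSums(Xtr[, pos, drop = FALSE]) else numeric(n - 1)
    sn_tr <- if (length(neg)) rowSums(Xtr[, neg, drop = FALSE]) else numeric(n - 1)
    sp_te <- if (length(pos)) sum(X[i, pos]) else 0
    sn_te <- if (length(neg)) sum(X[i, neg]) else 0
    fit1 <- function(s_tr, s_te) {
      if (stats::var(s_tr) == 0) return(mean(ytr))
      cf <- stats::coef(stats::lm(ytr ~ s_tr))
      cf[[1L]] + cf[[2L]] * s_te
    }
    pred[i, 1L] <- fit1(sp_tr, sp_te)
    pred[i, 2L] <- fit1(sn_tr, sn_te)
    vp <- stats::var(sp_tr) > 0; vn <- stats::var(sn_tr) > 0
    pred[i, 3L] <- if (vp && vn) {
      cf <- stats::coef(stats::lm(ytr ~ sp_tr + sn_tr))
      cf[[1L]] + cf[[2L]] * sp_te + cf[[3L]] * sn_te
    } else if (vp) fit1(sp_tr, sp_te)
    else if (vn) fit1(sn_tr, sn_te)
    else mean(ytr)
  }
  r <- apply(pred, 2L, function(p) if (stats::sd(p) == 0) 0 else stats::cor(p, y))
  list(predictions = pred, r = r, fold_masks = fold_masks)
}

# Small helper: cohort straight from matrices for unit tests.
make_cohort <- function(X, y, target = "hdrs5", ids = NULL) {
  n <- nrow(X)
  if (is.null(ids)) ids <- sprintf("T%02d", seq_len(n))
  scores <- data.frame(hdrs5 = NA_real_, ymrs = NA_real_)
  scores <- scores[rep(1L, n), , drop = FALSE]
  scores[[target]] <- y
  cov <- data.frame(age = seq(20, 50, length.out = n),
                    gender = rep_len(c(0, 1), n),
                    mean_fd = seq(0.05, 0.15, length.out = n))
  cpm_cohort(ids, X, scores, cov)
}

# Random symmetric Fisher-z-like matrix (NA diagonal handled by the class).
random_symmetric <- function(n, sd = 0.3) {
  m <- matrix(stats::rnorm(n * n, 0, sd), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# devectorize with a 0 diagonal (connectivity_matrix input form)
devectorize_edges2 <- function(v) {
  m <- devectorize_edges(v)
  diag(m) <- 0
  m
}
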