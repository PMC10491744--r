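test_that("correlate_edges matches the closed-form oracle on a small table", {
  set.seed(21)
  X <- matrix(rnorm(8 * 5), 8, 5)
  X[, 4] <- 2.5                     # constant edge
  y <- rnorm(8)
  st <- correlate_edges(X, y)
  or <- oracle_edge_stats(X, y)
  expect_equal(st$r, or$r, tolerance = 1e-10)
  expect_equal(st$p, or$p, tolerance = 1e-10)
  expect_identical(st$r[4], 0)
  expect_identical(st$p[4], 1)
})

test_that("correlate_edges handles self-correlation and bad input", {
  y <- c(1, 3, 2, 5, 4, 7, 6, 8)
  X <- cbind(y, -y)
  st <- correlate_edges(X, y)
  expect_equal(st$r, c(1, -1))
  expect_equal(st$p, c(0, 0))
  expect_error(correlate_edges(X, rep(2, 8)), "constant")
  expect_error(correlate_edges(X[1:3, ], y[1:3]), "at least 4")
})

test_that("select_edges applies a strict threshold and sign split", {
  st <- list(r = c(0.4, -0.5, 0.6, 0.2, 0),
             p = c(0.0009, 0.0005, 0.001, 0.5, 1))
  masks <- select_edges(st, 0.001)
  expect_identical(masks$pos, 1L)        # p = 0.001 exactly is excluded
  expect_identical(masks$neg, 2L)
  empty <- select_edges(list(r = c(0.2, -0.2), p = c(1, 1)), 0.001)
  expect_identical(lengths(empty), c(pos = 0L, neg = 0L))
  # alpha = 1 partitions all non-constant edges by the sign of r
  set.seed(2)
  X <- matrix(rnorm(20 * 30), 20)
  st2 <- correlate_edges(X, rnorm(20))
  m2 <- select_edges(st2, 1 - 1e-12)
  expect_identical(sort(c(m2$pos, m2$neg)), seq_len(30L))
  expect_length(intersect(m2$pos, m2$neg), 0)
})

test_that("network_strength sums masked edges and is linear", {
  expect_identical(network_strength(c(0.3, -0.1, 0.5), integer(0)), 0)
  expect_equal(network_strength(c(0.3, -0.1, 0.5), c(1L, 2L)), 0.2)
  set.seed(9)
  v <- rnorm(40); w <- rnorm(40)
  mask <- runif(40) < 0.3
  expect_equal(network_strength(v, mask), oracle_strength(v, mask),
               tolerance = 1e-12)
  expect_equal(network_strength(2 * v + 3 * w, mask),
               2 * network_strength(v, mask) + 3 * network_strength(w, mask),
               tolerance = 1e-10)
  expect_error(network_strength(v, rep(TRUE, 10)), "mask length")
})

test_that("fit_strength_model matches the normal-equations oracle", {
  set.seed(33)
  s <- rnorm(6); y6 <- 2 + 0.8 * s + rnorm(6, 0, 0.1)
  cf <- fit_strength_model(s, y6, "positive")
  expect_equal(unname(cf), unname(oracle_ols(matrix(s), y6)),
               tolerance = 1e-10)
  S2 <- cbind(rnorm(9), rnorm(9)); y9 <- rnorm(9)
  cf2 <- fit_strength_model(S2, y9, "combined")
  expect_equal(unname(cf2), unname(oracle_ols(S2, y9)), tolerance = 1e-10)
  # identity fit and degenerate regressor
  cf_id <- fit_strength_model(y6, y6, "positive")
  expect_equal(unname(cf_id), c(0, 1), tolerance = 1e-10)
  cf_const <- fit_strength_model(rep(4, 6), y6, "negative")
  expect_equal(unname(cf_const), c(mean(y6), 0), tolerance = 1e-12)
  expect_error(fit_strength_model(cbind(1:2, 3:4), 1:2, "combined"),
               "at least")
})

test_that("predict_score applies frozen coefficients over frozen masks", {
  set.seed(40)
  X <- matrix(rnorm(12 * n_edges(8), 0.2, 0.4), 12)
  y <- rnorm(12, 5, 2)
  co <- make_cohort(X, y)
  model <- train_cpm(co, "hdrs5", alpha = 0.5)
  # in-sample fitted value recomputed by hand for one subject
  sp <- network_strength(X[3, ], model$pos_mask)
  sn <- network_strength(X[3, ], model$neg_mask)
  cf <- model$coefficients$combined
  expect_equal(predict_score(model, X[3, ], "combined"),
               cf[["intercept"]] + cf[["slope_pos"]] * sp +
                 cf[["slope_neg"]] * sn, tolerance = 1e-12)
  expect_equal(predict_score(model, X, "positive")[3],
               predict_score(model, X[3, ], "positive"), tolerance = 1e-12)
  expect_error(predict_score(model, X[3, 1:5]), "does not match")
  expect_error(predict_score(model, X[3, ], "quadratic"))
})

test_that("run_loocv agrees with a from-scratch naive LOOCV", {
  set.seed(55)
  for (rep in 1:3) {
    n <- 16
    X <- matrix(rnorm(n * 21, 0.2, 0.3), n)
    y <- rnorm(n, 4, 2)
    X[, 3] <- X[, 3] + 0.25 * scale(y)[, 1]   # a few informative edges
    X[, 11] <- X[, 11] - 0.25 * scale(y)[, 1]
    co <- make_cohort(X, y)
    res <- run_loocv(co, "hdrs5", alpha = 0.1)
    or <- oracle_loocv(X, y, alpha = 0.1)
    expect_equal(unname(res$predictions), unname(or$predictions),
                 tolerance = 1e-8)
    expect_equal(unname(res$r), unname(or$r), tolerance = 1e-8)
    for (i in seq_len(n)) {
      expect_identical(res$fold_masks[[i]]$pos, or$fold_masks[[i]]$pos)
      expect_identical(res$fold_masks[[i]]$neg, or$fold_masks[[i]]$neg)
    }
    expect_identical(res$consensus, consensus_masks(or$fold_masks))
  }
})

test_that("run_loocv yields one held-out prediction per subject", {
  X <- matrix(rnorm(3 * 6), 3)
  co <- make_cohort(X, c(1, 5, 3))
  expect_warning(res <- run_loocv(co, "hdrs5"), "fewer than 10")
  expect_identical(nrow(res$predictions), 3L)
  expect_true(all(is.finite(res$predictions)))
})

test_that("empty-mask folds predict the training mean", {
  set.seed(60)
  X <- matrix(rnorm(12 * 10), 12)     # pure noise at a tiny alpha
  y <- rnorm(12)
  co <- make_cohort(X, y)
  res <- run_loocv(co, "hdrs5", alpha = 1e-9)
  means <- vapply(1:12, function(i) mean(y[-i]), numeric(1))
  expect_equal(unname(res$predictions[, "combined"]), means,
               tolerance = 1e-12)
  # leave-one-out means are exactly anti-correlated with the observed score
  expect_equal(res$r[["combined"]], cor(means, y), tolerance = 1e-12)
})

test_that("no leakage: a left-out subject's score cannot influence its fold", {
  set.seed(66)
  n <- 14
  X <- matrix(rnorm(n * 28, 0.2, 0.3), n)
  y <- rnorm(n, 4, 2)
  co <- make_cohort(X, y)
  res <- run_loocv(co, "hdrs5", alpha = 0.1)
  for (i in c(1L, 7L, 14L)) {
    y2 <- y
    y2[i] <- y2[i] + 100
    res2 <- run_loocv(make_cohort(X, y2), "hdrs5", alpha = 0.1)
    expect_identical(res2$fold_masks[[i]], res$fold_masks[[i]])
    expect_identical(res2$predictions[i, ], res$predictions[i, ])
  }
})

test_that("consensus_masks intersects fold masks", {
  same <- list(list(pos = c(2L, 5L), neg = 7L),
               list(pos = c(2L, 5L), neg = 7L))
  expect_identical(consensus_masks(same), list(pos = c(2L, 5L), neg = 7L))
  disjoint <- list(list(pos = 1L, neg = 2L), list(pos = 3L, neg = 4L))
  expect_identical(lengths(consensus_masks(disjoint)),
                   c(pos = 0L, neg = 0L))
  three <- list(list(pos = c(1L, 4L, 9L), neg = integer(0)),
                list(pos = c(1L, 2L, 9L), neg = 5L),
                list(pos = c(9L, 1L, 7L), neg = 5L))
  expect_identical(consensus_masks(three)$pos, c(1L, 9L))
})

test_that("network models serialize losslessly to JSON", {
  set.seed(70)
  X <- matrix(rnorm(12 * n_edges(8), 0.2, 0.4), 12)
  co <- make_cohort(X, rnorm(12, 5, 2))
  model <- train_cpm(co, "hdrs5", alpha = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_model(model, path)
  back <- read_network_model(path)
  expect_identical(back$pos_mask, model$pos_mask)
  expect_identical(back$neg_mask, model$neg_mask)
  expect_equal(back$coefficients, model$coefficients, tolerance = 1e-12)
  expect_identical(back$training_subjects, model$training_subjects)
  expect_equal(predict_score(back, X[1, ]), predict_score(model, X[1, ]),
               tolerance = 1e-12)
})
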