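test_that("plant_networks builds disjoint masks, star topologies and is deterministic", {
  cfg <- sim_config(n_nodes = 30, n_pos_edges = 10, n_neg_edges = 10,
                    n_hubs = 1, hub_bias = 1, seed = 5)
  t1 <- plant_networks(cfg)
  t2 <- plant_networks(cfg)
  expect_identical(t1, t2)
  expect_length(intersect(t1$pos, t1$neg), 0)
  ep <- edge_pairs(30)
  expect_true(all(ep[t1$pos, 1] == t1$hubs_pos |
                  ep[t1$pos, 2] == t1$hubs_pos))
  expect_error(plant_networks(sim_config(n_nodes = 5, n_pos_edges = 6,
                                         n_neg_edges = 5, seed = 1)))
})

test_that("uniform planting spreads edges like uniform pair sampling", {
  # oracle: the max-degree distribution of 40 edges drawn uniformly over
  # all choose(120, 2) pairs, sampled directly and independently
  set.seed(801)
  direct <- replicate(200, {
    idx <- sample.int(choose(120, 2), 40)
    ep <- edge_pairs(120)[idx, , drop = FALSE]
    max(tabulate(c(ep[, 1], ep[, 2]), nbins = 120))
  })
  maxdeg <- vapply(1:10, function(s) {
    truth <- plant_networks(sim_config(n_nodes = 120, hub_bias = 0,
                                       seed = 800 + s))
    ep <- edge_pairs(120)[truth$pos, , drop = FALSE]
    max(tabulate(c(ep[, 1], ep[, 2]), nbins = 120))
  }, numeric(1))
  expect_lt(mean(maxdeg), mean(direct) + 1)
  expect_lte(max(maxdeg), max(direct) + 1)
})

test_that("generated scores match the configured clinical moments", {
  g <- generate_cohort(sim_config(n_subjects = 400, n_nodes = 10, n_pos_edges = 3,
                                  n_neg_edges = 3, seed = 42))
  s <- g$cohort$scores$hdrs5
  # HDRS-5-like: mean/SD within 3 standard errors of 3.4/3.4, range 0-13
  expect_lt(abs(mean(s) - 3.4), 3 * 3.4 / sqrt(400))
  expect_lt(abs(sd(s) - 3.4), 3 * 3.4 / sqrt(200))
  expect_true(all(s >= 0 & s <= 13))
  expect_true(all(s == round(s)))
  y <- g$cohort$scores$ymrs
  expect_true(all(y >= 0 & y <= 23))
  expect_lt(abs(mean(y) - 6.5), 3 * 6.1 / sqrt(400))
  age <- g$cohort$covariates$age
  expect_true(all(age >= 18 & age <= 55))
  expect_true(all(g$cohort$covariates$mean_fd < 0.2))
})

test_that("planted edges attain the configured per-edge correlation", {
  g <- generate_cohort(sim_config(n_subjects = 150, n_nodes = 60,
                                  effect_r = 0.6, seed = 7))
  X <- g$cohort$edges
  y <- g$cohort$scores$hdrs5
  r_pos <- apply(X[, g$truth$pos, drop = FALSE], 2, cor, y = y)
  r_neg <- apply(X[, g$truth$neg, drop = FALSE], 2, cor, y = y)
  bg <- setdiff(seq_len(ncol(X)), c(g$truth$pos, g$truth$neg))
  r_bg <- apply(X[, sample(bg, 200), drop = FALSE], 2, cor, y = y)
  expect_lt(abs(mean(r_pos) - 0.6), 0.08)
  expect_lt(abs(mean(r_neg) + 0.6), 0.08)
  expect_lt(abs(mean(r_bg)), 0.05)
})

test_that("a null generator calibrates the edge-selection false-positive rate", {
  # effect_r = 0: per-edge selection at alpha should fire at ~alpha
  alpha <- 0.05
  fpr <- vapply(1:8, function(s) {
    g <- generate_cohort(sim_config(n_subjects = 50, n_nodes = 40,
                                    effect_r = 0, seed = 900 + s))
    st <- correlate_edges(g$cohort$edges, g$cohort$scores$hdrs5)
    mean(st$p < alpha)
  }, numeric(1))
  expect_lt(abs(mean(fpr) - alpha), 0.02)
})

test_that("generation is deterministic end to end", {
  cfg <- sim_config(n_subjects = 15, n_nodes = 12, n_pos_edges = 5,
                    n_neg_edges = 5, seed = 77)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$edges, g2$cohort$edges)
  expect_identical(g1$cohort$scores, g2$cohort$scores)
  expect_identical(g1$truth, g2$truth)
  r1 <- run_loocv(g1$cohort, "hdrs5")
  r2 <- run_loocv(g2$cohort, "hdrs5")
  expect_identical(r1$predictions, r2$predictions)
})

test_that("generated cohorts satisfy the connectivity-matrix invariants", {
  g <- generate_cohort(sim_config(n_subjects = 6, n_nodes = 15, n_pos_edges = 5,
                                  n_neg_edges = 5, seed = 30))
  for (i in 1:6) {
    m <- devectorize_edges(g$cohort$edges[i, ])
    diag(m) <- 0
    cm <- connectivity_matrix(m, g$cohort$subject_id[i])  # validates
    expect_true(all(is.finite(cm$values[upper.tri(cm$values)])))
  }
})

test_that("a planted aberrant subject is the single QC exclusion", {
  # study-scale conditions: 81 subjects, 368 nodes, one aberrant subject
  g <- generate_cohort(sim_config(n_outliers = 1, seed = 1))
  qc <- flag_outlier_subjects(g$cohort$edges)
  expect_identical(qc$subject_id[qc$flag], g$truth$outlier_subjects)
  expect_identical(qc$subject_id[which.min(qc$score)],
                   g$truth$outlier_subjects)
})

test_that("recovery_metrics computes confusion rates per sign", {
  truth <- list(pos = 1:10, neg = 11:20)
  exact <- recovery_metrics(list(pos = 1:10, neg = 11:20), truth, 100)
  expect_equal(exact$sensitivity, c(1, 1))
  expect_equal(exact$fdp, c(0, 0))
  expect_equal(exact$specificity, c(1, 1))
  none <- recovery_metrics(list(pos = integer(0), neg = integer(0)), truth, 100)
  expect_equal(none$sensitivity, c(0, 0))
  expect_equal(none$fdp, c(0, 0))          # empty-selection convention
  half <- recovery_metrics(list(pos = c(1:5, 90:94), neg = 11:20), truth, 100)
  expect_equal(half$sensitivity, c(0.5, 1))
  expect_equal(half$fdp, c(0.5, 0))
  # random selection: expected sensitivity ~ m / n_edges
  set.seed(4)
  sens <- replicate(300, {
    sel <- sample.int(100, 20)
    recovery_metrics(list(pos = sel, neg = integer(0)), truth, 100)$sensitivity[1]
  })
  expect_lt(abs(mean(sens) - 20 / 100), 0.02)
})
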