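test_that("a frozen model applied to its training cohort reproduces fits", {
  set.seed(44)
  g <- generate_cohort(sim_config(n_subjects = 30, n_nodes = 20,
                                  n_pos_edges = 8, n_neg_edges = 8,
                                  effect_r = 0.6, seed = 31))
  model <- train_cpm(g$cohort, "hdrs5")
  pred <- apply_trained_model(model, g$cohort, allow_training_overlap = TRUE)
  # in-sample fitted values recomputed independently via lm()
  sp <- network_strength(g$cohort$edges, model$pos_mask)
  sn <- network_strength(g$cohort$edges, model$neg_mask)
  y <- g$cohort$scores$hdrs5
  expect_equal(unname(pred[, "combined"]),
               unname(fitted(lm(y ~ sp + sn))), tolerance = 1e-9)
  expect_equal(unname(pred[, "positive"]),
               unname(fitted(lm(y ~ sp))), tolerance = 1e-9)
})

test_that("transfer refuses overlapping subjects and mismatched edges", {
  g <- generate_cohort(sim_config(n_subjects = 12, n_nodes = 10, n_pos_edges = 3,
                                  n_neg_edges = 3, seed = 3))
  model <- train_cpm(g$cohort, "hdrs5")
  expect_error(apply_trained_model(model, g$cohort), "overlaps")
  g2 <- generate_cohort(sim_config(n_subjects = 8, n_nodes = 12, n_pos_edges = 3,
                                   n_neg_edges = 3, seed = 4))
  expect_error(apply_trained_model(model, g2$cohort), "edges")
})

test_that("zero-slope models predict the intercept everywhere", {
  g <- generate_cohort(sim_config(n_subjects = 10, n_nodes = 10,
                                  n_pos_edges = 3, n_neg_edges = 3,
                                  effect_r = 0, seed = 8))
  model <- train_cpm(g$cohort, "hdrs5", alpha = 1e-9)  # selects nothing
  expect_length(model$pos_mask, 0)
  g2 <- generate_cohort(sim_config(n_subjects = 6, n_nodes = 10,
                                   n_pos_edges = 3, n_neg_edges = 3,
                                   effect_r = 0, id_prefix = "V", seed = 9))
  pred <- apply_trained_model(model, g2$cohort)
  expect_true(all(pred == model$coefficients$combined[["intercept"]]))
})

test_that("evaluate_transfer reports plain and partial concordance", {
  set.seed(50)
  obs <- rnorm(12, 5, 2)
  perfect <- evaluate_transfer(obs, obs)
  expect_equal(perfect$r, 1)
  expect_identical(perfect$rmse, 0)
  pred <- obs + rnorm(12)
  Z <- cbind(age = rnorm(12, 30, 10), gender = rbinom(12, 1, 0.5))
  rep <- evaluate_transfer(pred, obs, Z)
  or_plain <- oracle_pearson(pred, obs)
  or_part <- oracle_partial(pred, obs, Z)
  expect_equal(rep$r, or_plain, tolerance = 1e-10)
  expect_equal(rep$r_partial, or_part$r, tolerance = 1e-10)
  expect_equal(rep$p_partial, or_part$p, tolerance = 1e-10)
  expect_identical(rep$df, 10L)          # n - 2
  expect_identical(rep$df_partial, 8L)   # n - 2 - 2
  expect_error(evaluate_transfer(pred, rep(3, 12)), "constant")
})

test_that("missing validation scores are excluded and counted", {
  set.seed(51)
  obs <- rnorm(43, 6.5, 6)
  obs[c(5, 19)] <- NA                     # two subjects without the score
  pred <- ifelse(is.na(obs), 0, obs) + rnorm(43)
  rep <- evaluate_transfer(pred, obs)
  expect_identical(rep$n, 41L)
  expect_identical(rep$n_excluded, 2L)
})

test_that("transfer evaluation never mutates the frozen model", {
  g <- generate_cohort(sim_config(n_subjects = 20, n_nodes = 14,
                                  n_pos_edges = 5, n_neg_edges = 5,
                                  effect_r = 0.6, seed = 12))
  model <- train_cpm(g$cohort, "hdrs5")
  p1 <- withr::local_tempfile(fileext = ".json")
  write_network_model(model, p1)
  gv <- generate_cohort(sim_config(n_subjects = 15, n_nodes = 14,
                                   n_pos_edges = 5, n_neg_edges = 5,
                                   effect_r = 0.6, id_prefix = "V",
                                   seed = 13), truth = g$truth)
  pred <- apply_trained_model(model, gv$cohort)
  invisible(evaluate_transfer(pred[, "combined"], gv$cohort$scores$hdrs5,
                              gv$cohort$covariates[, c("age", "gender")]))
  p2 <- withr::local_tempfile(fileext = ".json")
  write_network_model(model, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("transfer r approaches within-sample r as validation n grows", {
  cfg <- sim_config(n_subjects = 60, n_nodes = 30, n_pos_edges = 10,
                    n_neg_edges = 10, effect_r = 0.6, seed = 20)
  g <- generate_cohort(cfg)
  model <- train_cpm(g$cohort, "hdrs5")
  med_r <- vapply(c(15, 120), function(nv) {
    rs <- vapply(1:5, function(s) {
      cfgv <- sim_config(n_subjects = nv, n_nodes = 30, n_pos_edges = 10,
                         n_neg_edges = 10, effect_r = 0.6, id_prefix = "V",
                         seed = 700 + s)
      gv <- generate_cohort(cfgv, truth = g$truth)
      pred <- apply_trained_model(model, gv$cohort)
      evaluate_transfer(pred[, "combined"], gv$cohort$scores$hdrs5)$r
    }, numeric(1))
    median(rs)
  }, numeric(1))
  expect_gt(med_r[1], 0)
  expect_gt(med_r[2], 0)
})
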