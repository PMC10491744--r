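# Synthetic-cohort generator: planted positive/negative predictive networks
# over a shared group-mean connectome, truncated-rounded clinical scores
# with realistic moments, and nuisance covariates. This is the test bed
# standing in for (non-deposited) clinical fMRI data.

#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the training-sample conditions of a bipolar-disorder
#' task-fMRI cohort: 81 subjects, a 368-node whole-brain atlas, an HDRS-5-
#' like depressed-mood target (truncated-rounded normal, mean 3.4, SD 3.4,
#' range 0-13) alongside a YMRS-like elevated-mood score (6.5, 6.1, 0-23)
#' and an HDRS-29-like total, age 29.3 +/- 11.1 years (18-55), 63% female,
#' and mean framewise displacement below 0.2 mm. Sparse positive and
#' negative predictive networks (40 edges each, concentrated on 2 hub nodes
#' per sign with probability `hub_bias`) are planted with per-edge
#' edge-score correlation `effect_r`.
#'
#' @param n_subjects cohort size.
#' @param n_nodes atlas size.
#' @param n_pos_edges,n_neg_edges planted network sizes.
#' @param n_hubs hub nodes per sign on which planted edges concentrate.
#' @param hub_bias probability a planted edge is forced incident to a hub.
#' @param effect_r target per-edge Pearson correlation between a planted
#'   edge's weight and the (standardized) target score; the additive loading
#'   is `beta = effect_r / sqrt(1 - effect_r^2) * edge_noise_sd`. 0 plants
#'   nothing (null cohort).
#' @param edge_noise_sd SD of subject-level edge noise around the group-mean
#'   connectome (Fisher-z units).
#' @param group_mean_sd SD of the group-mean edge weights across edges.
#' @param group_mean_center mean of the group-mean edge weights.
#' @param score list `(mean, sd, floor, ceiling)` for the target score
#'   distribution; see [score_spec()].
#' @param target which score the planted networks predict
#'   (`"hdrs5"` or `"ymrs"`).
#' @param noise_scale_range per-subject multiplier range for
#'   `edge_noise_sd`, e.g. `c(0.8, 1.3)` to emulate heterogeneous
#'   acquisition in a validation sample; `c(1, 1)` is homogeneous.
#' @param confound_age couple age to the latent score (r ~ 0.4) to exercise
#'   covariate adjustment.
#' @param quadratic_effect inject the effect in the standardized score
#'   squared instead of linearly (misspecification switch for robustness
#'   tests).
#' @param n_outliers subjects whose edge vector is replaced by an
#'   independently permuted one (aberrant edge-weight distribution).
#' @param n_missing_ymrs subjects with the YMRS score set missing.
#' @param id_prefix subject-id prefix (use a distinct prefix for validation
#'   cohorts so training/validation rosters cannot collide).
#' @param seed integer seed; the generator is fully reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 81, n_nodes = 368,
                       n_pos_edges = 40, n_neg_edges = 40,
                       n_hubs = 2, hub_bias = 0.5,
                       effect_r = 0.5, edge_noise_sd = 0.2,
                       group_mean_sd = 0.3, group_mean_center = 0.25,
                       score = score_spec("hdrs5"), target = "hdrs5",
                       noise_scale_range = c(1, 1),
                       confound_age = FALSE, quadratic_effect = FALSE,
                       n_outliers = 0, n_missing_ymrs = 0, id_prefix = "S",
                       seed = 1L) {
  stopifnot(n_subjects >= 4, n_nodes >= 4,
            effect_r >= 0, effect_r < 1,
            hub_bias >= 0, hub_bias <= 1,
            n_pos_edges + n_neg_edges <= n_edges(n_nodes))
  structure(as.list(environment()), class = "sim_config")
}

#' Score-distribution presets
#'
#' Truncated-rounded normal parameters for the clinical scales emulated by
#' the generator: HDRS-5 (mean 3.4, SD 3.4, range 0-13), YMRS total (6.5,
#' 6.1, 0-23) and HDRS-29 total (12.3, 10.1, 0-40).
#'
#' @param scale one of `"hdrs5"`, `"ymrs"`, `"hdrs29"`.
#' @return list with `mean`, `sd`, `floor`, `ceiling`.
#' @export
score_spec <- function(scale = c("hdrs5", "ymrs", "hdrs29")) {
  switch(match.arg(scale),
         hdrs5 = list(mean = 3.4, sd = 3.4, floor = 0, ceiling = 13),
         ymrs = list(mean = 6.5, sd = 6.1, floor = 0, ceiling = 23),
         hdrs29 = list(mean = 12.3, sd = 10.1, floor = 0, ceiling = 40))
}

# Moments of a normal truncated to [lo, hi].
.tn_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  lam <- (stats::dnorm(a) - stats::dnorm(b)) / Z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for the untruncated (mu, sigma) whose truncation to [lo, hi] comes
# closest (least squares) to the requested post-truncation mean and SD.
# Floor-heavy clinical scales push the parent normal far below the floor
# (exponential-like limit); printed moments of strongly skewed scales can
# sit slightly outside the family's attainable region, in which case the
# closest member is used (documented in the methods vignette).
.tn_solve <- function(target_m, target_s, lo, hi) {
  obj <- function(p) {
    mm <- .tn_moments(p[1L], exp(p[2L]), lo, hi)
    if (!all(is.finite(mm))) return(1e6)
    (mm[1L] - target_m)^2 + (mm[2L] - target_s)^2
  }
  best <- NULL
  for (start in list(c(target_m, log(target_s)),
                     c(target_m - 2 * target_s, log(2 * target_s)),
                     c(target_m - 6 * target_s, log(3 * target_s)))) {
    o <- stats::optim(start, obj, control = list(maxit = 2000,
                                                 reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(mu = best$par[1L], sigma = exp(best$par[2L]))
}

# Exact truncated-normal draws by inverse CDF; optional rounding to integer
# scale scores.
.rtruncnorm <- function(n, mu, sigma, lo, hi, round = TRUE) {
  pa <- stats::pnorm(lo, mu, sigma)
  pb <- stats::pnorm(hi, mu, sigma)
  x <- stats::qnorm(stats::runif(n, pa, pb), mu, sigma)
  x <- pmin(hi, pmax(lo, x))
  if (round) round(x) else x
}

# Draws whose post-truncation moments match the requested ones as closely
# as the support and family allow (a bounded interval caps the attainable
# SD).
.rtrunc_target <- function(n, mean, sd, lo, hi, round = TRUE) {
  p <- .tn_solve(mean, sd, lo, hi)
  .rtruncnorm(n, p$mu, p$sigma, lo, hi, round)
}

#' Plant positive and negative predictive networks
#'
#' Samples disjoint positive and negative edge sets. With `hub_bias > 0` a
#' corresponding fraction of each sign's edges is forced incident to that
#' sign's designated hub nodes, so degree-based interpretation has planted
#' signal; with `hub_bias = 0` planted edges are uniform over all pairs.
#'
#' @param config a [sim_config()] (its `seed` is used).
#' @return list with integer edge-index vectors `pos`, `neg` and hub node
#'   ids `hubs_pos`, `hubs_neg`.
#' @export
plant_networks <- function(config) {
  set.seed(config$seed)
  .plant_networks_impl(config)
}

.plant_networks_impl <- function(config) {
  n <- config$n_nodes
  ne <- n_edges(n)
  if (config$n_pos_edges + config$n_neg_edges > ne) {
    stop("requested planted edges exceed available edges")
  }
  hubs <- sample.int(n, 2L * config$n_hubs)
  hubs_pos <- hubs[seq_len(config$n_hubs)]
  hubs_neg <- hubs[config$n_hubs + seq_len(config$n_hubs)]
  # row-major upper-triangle index of unordered pair (a, b)
  pair_index <- function(a, b) {
    i <- pmin(a, b); j <- pmax(a, b)
    (i - 1L) * n - i * (i - 1L) / 2 + (j - i)
  }
  draw_sign <- function(k, hub_nodes, taken) {
    chosen <- integer(0)
    while (length(chosen) < k) {
      need <- k - length(chosen)
      use_hub <- stats::runif(need) < config$hub_bias
      a <- ifelse(use_hub,
                  hub_nodes[sample.int(length(hub_nodes), need, replace = TRUE)],
                  sample.int(n, need, replace = TRUE))
      b <- sample.int(n, need, replace = TRUE)
      ok <- a != b
      cand <- unique(pair_index(a[ok], b[ok]))
      cand <- setdiff(cand, c(chosen, taken))
      chosen <- c(chosen, cand[seq_len(min(length(cand), need))])
    }
    as.integer(sort(chosen))
  }
  pos <- draw_sign(config$n_pos_edges, hubs_pos, integer(0))
  neg <- draw_sign(config$n_neg_edges, hubs_neg, pos)
  list(pos = pos, neg = neg, hubs_pos = sort(hubs_pos),
       hubs_neg = sort(hubs_neg))
}

#' Generate a synthetic cohort with planted predictive networks
#'
#' Per subject, the target score is a truncated-rounded normal with the
#' configured moments. Edge weights are i.i.d. normal around a shared
#' group-mean connectome; planted positive edges additionally receive
#' `+beta * z`, negative edges `-beta * z`, where `z` is the score
#' standardized by its realized sample moments (so the configured per-edge
#' correlation `effect_r` is attained irrespective of truncation
#' attenuation). Covariates are drawn independently of the connectome unless
#' `confound_age` couples age to the score. Everything is reproducible from
#' the seed.
#'
#' @param config a [sim_config()].
#' @param truth optional ground truth from a previous [generate_cohort()]
#'   call: reuses its planted masks, hub nodes and group-mean connectome, so
#'   an independent validation cohort is drawn from the same generative
#'   process as its training cohort (fresh seed, same planted networks).
#' @return list with `cohort` (a [cpm_cohort()]) and `truth` (planted masks,
#'   hub nodes, group-mean connectome, latent scores, `beta`).
#' @export
generate_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(truth)) {
    truth <- .plant_networks_impl(config)
  } else {
    stopifnot(all(c("pos", "neg") %in% names(truth)))
    truth <- truth[c("pos", "neg", "hubs_pos", "hubs_neg", "group_mean")]
  }
  n <- config$n_subjects
  ne <- n_edges(config$n_nodes)
  sc <- config$score
  latent <- .rtrunc_target(n, sc$mean, sc$sd, sc$floor, sc$ceiling,
                           round = FALSE)
  target_score <- round(latent)
  # standardize by realized moments so effect_r is attained
  z <- as.numeric(scale(target_score))
  if (config$quadratic_effect) z <- (z^2 - mean(z^2)) / stats::sd(z^2)
  beta <- if (config$effect_r > 0) {
    config$effect_r / sqrt(1 - config$effect_r^2) * config$edge_noise_sd
  } else 0
  mu <- truth$group_mean
  if (is.null(mu)) {
    mu <- stats::rnorm(ne, config$group_mean_center, config$group_mean_sd)
  }
  if (length(mu) != ne) stop("reused ground truth does not match n_nodes")
  scale_i <- stats::runif(n, config$noise_scale_range[1L],
                          config$noise_scale_range[2L])
  X <- matrix(stats::rnorm(n * ne), n, ne) *
    (config$edge_noise_sd * scale_i) +
    matrix(mu, n, ne, byrow = TRUE)
  if (beta > 0) {
    X[, truth$pos] <- X[, truth$pos] + beta * z
    X[, truth$neg] <- X[, truth$neg] - beta * z
  }
  # aberrant subjects: group pattern destroyed by permuting their edges
  outlier_ids <- integer(0)
  if (config$n_outliers > 0) {
    outlier_ids <- sample.int(n, config$n_outliers)
    for (i in outlier_ids) X[i, ] <- X[i, sample.int(ne)]
  }
  # remaining clinical scores: independent of the connectome by design
  other <- if (config$target == "hdrs5") "ymrs" else "hdrs5"
  other_sc <- score_spec(other)
  other_score <- .rtrunc_target(n, other_sc$mean, other_sc$sd,
                                other_sc$floor, other_sc$ceiling)
  scores <- data.frame(hdrs5 = NA_integer_, hdrs29 = NA_integer_,
                       ymrs = NA_integer_)[rep(1L, n), , drop = FALSE]
  scores[[config$target]] <- as.integer(target_score)
  scores[[other]] <- as.integer(other_score)
  hd5 <- scores$hdrs5
  # HDRS-29-like total: the five depression items plus the remaining items
  scores$hdrs29 <- as.integer(pmin(40, hd5 +
    .rtruncnorm(n, 8.9, 7.5, 0, 40)))
  if (config$n_missing_ymrs > 0) {
    scores$ymrs[sample.int(n, config$n_missing_ymrs)] <- NA_integer_
  }
  # the printed age SD slightly exceeds the maximum attainable on [18, 55];
  # the closest truncated normal (near-uniform) is used
  age <- .rtrunc_target(n, 29.3, 11.1, 18, 55, round = FALSE)
  if (config$confound_age) {
    age <- 29.3 + 0.4 * 11.1 * z +
      sqrt(1 - 0.4^2) * 11.1 * stats::rnorm(n)
    age <- pmin(55, pmax(18, age))
  }
  covariates <- data.frame(
    age = age,
    gender = as.integer(stats::runif(n) < 0.63),  # female = 1
    mean_fd = pmin(0.199, pmax(0.02, stats::rnorm(n, 0.10, 0.04))))
  ids <- sprintf("%s%03d", config$id_prefix, seq_len(n))
  cohort <- cpm_cohort(ids, X, scores, covariates)
  truth$group_mean <- mu
  truth$latent <- latent
  truth$beta <- beta
  truth$outlier_subjects <- ids[outlier_ids]
  list(cohort = cohort, truth = truth)
}

#' Recovery metrics for selected edges against planted ground truth
#'
#' Standard confusion-matrix rates per network sign: sensitivity (planted
#' edges recovered), specificity (background edges left unselected) and
#' false-discovery proportion (selected edges not planted; 0 when nothing
#' is selected, by convention).
#'
#' @param selected list with integer index masks `pos`, `neg`.
#' @param truth ground truth from [generate_cohort()] / [plant_networks()].
#' @param n_edges_total total number of edges.
#' @return data.frame with one row per sign.
#' @export
recovery_metrics <- function(selected, truth, n_edges_total) {
  one <- function(sel, tru) {
    tp <- length(intersect(sel, tru))
    fp <- length(setdiff(sel, tru))
    fn <- length(setdiff(tru, sel))
    tn <- n_edges_total - tp - fp - fn
    data.frame(
      sensitivity = if (length(tru)) tp / length(tru) else NA_real_,
      specificity = tn / (tn + fp),
      fdp = if (length(sel)) fp / length(sel) else 0)
  }
  out <- rbind(one(selected$pos, truth$pos), one(selected$neg, truth$neg))
  cbind(sign = c("positive", "negative"), out)
}
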