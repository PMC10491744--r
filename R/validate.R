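# External validation: apply a frozen network model to an independent
# cohort and evaluate transfer performance.

#' Apply a frozen network model to an independent cohort
#'
#' Network strengths are computed from the model's frozen masks and
#' predictions from its frozen coefficients; there is no re-selection and no
#' re-fitting. The validation cohort must share no subject with the
#' training cohort.
#'
#' @param model a `network_model`.
#' @param cohort a `cpm_cohort`.
#' @param allow_training_overlap set `TRUE` only for the in-sample closure
#'   check (applying a model back to its own training cohort).
#' @return n x 3 matrix of predictions (positive / negative / combined).
#' @export
apply_trained_model <- function(model, cohort, allow_training_overlap = FALSE) {
  if (ncol(cohort$edges) != model$n_edges) {
    stop("cohort has ", ncol(cohort$edges), " edges; model expects ",
         model$n_edges)
  }
  overlap <- intersect(cohort$subject_id, model$training_subjects)
  if (length(overlap) && !allow_training_overlap) {
    stop("validation cohort overlaps training subjects: ",
         paste(overlap, collapse = ", "))
  }
  pred <- cbind(positive = predict_score(model, cohort$edges, "positive"),
                negative = predict_score(model, cohort$edges, "negative"),
                combined = predict_score(model, cohort$edges, "combined"))
  rownames(pred) <- cohort$subject_id
  pred
}

#' Evaluate transfer of predictions to an independent sample
#'
#' Reports plain and covariate-adjusted (partial) Pearson concordance
#' between predicted and observed scores, with RMSE and the n actually
#' used; subjects missing the observed score are excluded and counted, as
#' in per-target complete-case analysis.
#'
#' @param predictions numeric vector of predicted scores (e.g. the
#'   `combined` column of [apply_trained_model()]).
#' @param observed numeric vector of observed scores, `NA` for missing.
#' @param covariates optional data.frame/matrix (e.g. age, gender) for the
#'   partial correlation.
#' @return list with `n`, `n_excluded`, `r`, `p`, `df` (plain),
#'   `r_partial`, `p_partial`, `df_partial`, `rmse`.
#' @export
evaluate_transfer <- function(predictions, observed, covariates = NULL) {
  stopifnot(length(predictions) == length(observed))
  ok <- !is.na(observed)
  n_excluded <- sum(!ok)
  pred <- as.numeric(predictions[ok])
  obs <- as.numeric(observed[ok])
  if (length(obs) < 4L) stop("fewer than 4 subjects with observed scores")
  if (stats::sd(obs) == 0) stop("observed scores are constant")
  Z <- if (!is.null(covariates)) as.matrix(covariates)[ok, , drop = FALSE]
  plain <- partial_pearson(pred, obs, NULL)
  part <- if (!is.null(Z)) partial_pearson(pred, obs, Z) else plain
  list(n = length(obs), n_excluded = n_excluded,
       r = plain$r, p = plain$p, df = plain$df,
       r_partial = part$r, p_partial = part$p, df_partial = part$df,
       rmse = rmse(pred, obs))
}
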