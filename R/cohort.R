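# Clinical predictor variables and cohort assembly.

#' Five HDRS items with the highest loading for depressed mood
#'
#' The depressed-mood severity target (HDRS-5) is the sum of these five
#' Hamilton Depression Rating Scale items.
#' @export
HDRS5_ITEMS <- c("depressed_mood", "work_and_interests", "guilt",
                 "psychomotor_retardation", "suicide")

#' HDRS-5 depressed-mood score
#'
#' Sums exactly the five depression-loading HDRS items (depressed mood, work
#' and interests, guilt, psychomotor retardation, suicide). Items are keyed
#' by canonical lower-case names, not by instrument item numbers.
#'
#' @param items named list or vector of non-negative integer item scores;
#'   must contain all five [HDRS5_ITEMS] (extra items are ignored).
#' @return integer sum of the five items.
#' @export
hdrs5_score <- function(items) {
  items <- unlist(items)
  miss <- setdiff(HDRS5_ITEMS, names(items))
  if (length(miss)) {
    stop("missing HDRS item(s): ", paste(miss, collapse = ", "))
  }
  vals <- items[HDRS5_ITEMS]
  if (anyNA(vals) || any(vals < 0)) stop("HDRS items must be non-negative")
  as.integer(sum(vals))
}

#' YMRS total score
#'
#' The elevated-mood severity target is the one-factor Young Mania Rating
#' Scale total: the sum of all eleven items.
#'
#' @param items numeric vector of exactly 11 non-negative integer scores.
#' @return integer sum.
#' @export
ymrs_total <- function(items) {
  items <- unlist(items)
  if (length(items) != 11L) {
    stop("YMRS has 11 items; got ", length(items))
  }
  if (anyNA(items) || any(items < 0)) stop("YMRS items must be non-negative")
  as.integer(sum(items))
}

#' Construct a CPM cohort object
#'
#' @param subject_id character vector of unique subject ids.
#' @param edges subjects x edges numeric matrix (canonical edge order).
#' @param scores data.frame of per-subject clinical targets (columns such as
#'   `hdrs5`, `hdrs29`, `ymrs`); `NA` marks a missing score.
#' @param covariates data.frame with `age`, `gender` (0/1 indicator,
#'   female = 1) and optionally `mean_fd` (mm).
#' @return a `cpm_cohort` object.
#' @export
cpm_cohort <- function(subject_id, edges, scores, covariates) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicated subject id(s)")
  n <- length(subject_id)
  stopifnot(is.matrix(edges), nrow(edges) == n,
            nrow(scores) == n, nrow(covariates) == n)
  rownames(edges) <- subject_id
  nn <- .nodes_from_edges(ncol(edges))
  if (is.na(nn)) stop("edge matrix width is not n*(n-1)/2 for integer n")
  structure(list(subject_id = subject_id, edges = edges,
                 scores = as.data.frame(scores),
                 covariates = as.data.frame(covariates),
                 n_nodes = nn),
            class = "cpm_cohort")
}

#' @export
print.cpm_cohort <- function(x, ...) {
  cat("<cpm_cohort>", length(x$subject_id), "subjects,", x$n_nodes,
      "nodes (", ncol(x$edges), "edges ), targets:",
      paste(names(x$scores), collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a `cpm_cohort`.
#' @export
n_subjects <- function(cohort) length(cohort$subject_id)

#' Assemble an analysis cohort for one clinical target
#'
#' Aligns connectivity data with a phenotype table for a given target score.
#' Subjects with a connectivity matrix but no phenotype row are dropped with
#' a warning; subjects missing the requested target score are excluded from
#' that target's analysis (and the exclusion reported via a message), as in
#' per-target complete-case analysis. Output subjects are sorted by id.
#'
#' @param matrices list of `connectivity_matrix` objects or a subjects x
#'   edges matrix with subject-id row names.
#' @param phenotypes data.frame with `subject_id`, target column(s), and
#'   covariates `age`, `gender`, optionally `mean_fd`.
#' @param target name of the score column to analyse (e.g. `"hdrs5"`,
#'   `"ymrs"`).
#' @return a `cpm_cohort` containing only subjects with the target observed.
#' @export
assemble_cohort <- function(matrices, phenotypes, target) {
  stopifnot(target %in% names(phenotypes))
  if (is.matrix(matrices)) {
    X <- matrices
    if (is.null(rownames(X))) stop("edge matrix needs subject-id row names")
  } else {
    ids <- vapply(matrices, function(m) m$subject_id, character(1))
    X <- t(vapply(matrices, function(m) unname(vectorize_edges(m)),
                  numeric(n_edges(matrices[[1L]]$n_nodes))))
    rownames(X) <- ids
  }
  ph <- phenotypes
  ph$subject_id <- as.character(ph$subject_id)
  if (!all(ph$subject_id %in% rownames(X))) {
    stop("phenotype subject(s) without connectivity data: ",
         paste(setdiff(ph$subject_id, rownames(X)), collapse = ", "))
  }
  unmatched <- setdiff(rownames(X), ph$subject_id)
  if (length(unmatched)) {
    warning("dropping ", length(unmatched),
            " subject(s) without phenotype rows: ",
            paste(unmatched, collapse = ", "))
  }
  missing_target <- ph$subject_id[is.na(ph[[target]])]
  if (length(missing_target)) {
    message("excluding ", length(missing_target), " subject(s) missing ",
            target, ": ", paste(missing_target, collapse = ", "))
  }
  keep <- sort(setdiff(ph$subject_id, missing_target))
  if (!length(keep)) stop("no subjects remain with ", target, " observed")
  ph <- ph[match(keep, ph$subject_id), , drop = FALSE]
  score_cols <- intersect(c("hdrs5", "hdrs29", "ymrs"), names(ph))
  cov_cols <- intersect(c("age", "gender", "mean_fd"), names(ph))
  cpm_cohort(keep, X[keep, , drop = FALSE],
             ph[, score_cols, drop = FALSE],
             ph[, cov_cols, drop = FALSE])
}

#' Read a phenotype table
#'
#' Tab-separated with header `subject_id age gender mean_fd hdrs5
#' hdrs29 ymrs` (any score/covariate subset), plus optional item columns
#' `hdrs_<name>` and `ymrs_<k>` from which totals are derived when the total
#' columns are absent.
#'
#' @param path file path.
#' @return data.frame, one row per subject.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("subject_id" %in% names(tab))
  hdrs_items <- grep("^hdrs_", names(tab), value = TRUE)
  if (!"hdrs5" %in% names(tab) && length(hdrs_items)) {
    items <- tab[, hdrs_items, drop = FALSE]
    names(items) <- sub("^hdrs_", "", names(items))
    tab$hdrs5 <- vapply(seq_len(nrow(tab)),
                        function(i) hdrs5_score(items[i, ]), integer(1))
  }
  ymrs_items <- grep("^ymrs_[0-9]+$", names(tab), value = TRUE)
  if (!"ymrs" %in% names(tab) && length(ymrs_items)) {
    tab$ymrs <- vapply(seq_len(nrow(tab)),
                       function(i) ymrs_total(tab[i, ymrs_items]),
                       integer(1))
  }
  tab
}

#' Subset a cohort to a set of subjects
#'
#' @param cohort a `cpm_cohort`.
#' @param ids subject ids to keep (order preserved as given).
#' @return the reduced `cpm_cohort`.
#' @export
subset_cohort <- function(cohort, ids) {
  sel <- match(ids, cohort$subject_id)
  if (anyNA(sel)) {
    stop("unknown subject id(s): ",
         paste(ids[is.na(sel)], collapse = ", "))
  }
  cpm_cohort(cohort$subject_id[sel],
             cohort$edges[sel, , drop = FALSE],
             cohort$scores[sel, , drop = FALSE],
             cohort$covariates[sel, , drop = FALSE])
}
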