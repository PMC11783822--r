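#' ROC area under the curve
#'
#' Mann-Whitney rank formulation with midrank tie handling:
#' `AUC = (sum of positive ranks - n1(n1+1)/2) / (n1 * n0)`.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa for binary agreement
#'
#' `(p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the marginal
#' products. When both raters are constant and identical (`p_e = 1` with
#' perfect agreement) the kappa is defined as 1.
#'
#' @param pred,truth equal-length 0/1 (or logical) vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(pred, truth) {
  pred <- as.integer(as.logical(pred)); truth <- as.integer(as.logical(truth))
  if (length(pred) != length(truth)) stop("length mismatch")
  n <- length(pred)
  if (!n) stop("empty input")
  po <- mean(pred == truth)
  pe <- mean(pred) * mean(truth) + (1 - mean(pred)) * (1 - mean(truth))
  if (pe >= 1) {
    if (po == 1) return(1)
    stop("degenerate marginals with imperfect agreement")
  }
  (po - pe) / (1 - pe)
}

#' Grade every patient of a cohort from its detections
#'
#' Runs the full inference path per patient: fuse the 2D detections over
#' all augmented scans, threshold the per-type confidences into the high-
#' and low-confidence sets, and grade with the Bayesian model. `method`
#' selects the evidence used: `"high"` and `"low"` grade directly on the
#' respective detection set; `"refine"` additionally runs the retrieval
#' loop starting from the high-confidence set.
#'
#' @param patients patient table (needs `patient_id`, `age_years`).
#' @param detections detections covering the cohort.
#' @param spec,cpds the grading network and fitted CPDs.
#' @param th a [thresholds()] object.
#' @param K number of augmented scans per patient.
#' @param method `"refine"`, `"high"`, or `"low"`.
#' @return data.frame with one row per patient: `p_R`, `p_T`, `pred_R`,
#'   `pred_T` (0.5-thresholded), `tile`, and for `"refine"` the number of
#'   retrieved fractures `n_added`.
#' @export
grade_cohort <- function(patients, detections, spec, cpds,
                         th = thresholds(), K,
                         method = c("refine", "high", "low")) {
  method <- match.arg(method)
  det_by_patient <- if (nrow(detections))
    split(detections, detections$patient_id) else list()
  has_age <- "age60" %in% spec$nodes
  res <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    age60 <- if (has_age) age_flag(patients$age_years[i]) else NULL
    d <- det_by_patient[[pid]]
    fused <- fuse_patient(if (is.null(d)) empty_detections() else d,
                          K = K, keep_2d = th$keep_2d)
    sets <- detect_sets(type_confidence(fused), th)
    if (method == "refine") {
      r <- refine(spec, cpds, sets$high, sets$low, age60, th)
      data.frame(patient_id = pid, p_R = r$p_R_final, p_T = r$p_T_final,
                 tile = r$tile_final, n_added = nrow(r$added),
                 stringsAsFactors = FALSE)
    } else {
      g <- initial_grade(spec, cpds,
                         if (method == "high") sets$high else sets$low, age60)
      data.frame(patient_id = pid, p_R = g$p_R, p_T = g$p_T,
                 tile = g$tile, n_added = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$pred_R <- as.integer(out$p_R >= 0.5)
  out$pred_T <- as.integer(out$p_T >= 0.5)
  out
}

metric_or_na <- function(f, scores, labels) {
  if (length(unique(labels[!is.na(labels)])) < 2L) return(NA_real_)
  f(scores, labels)
}

#' Stratified k-fold cross-validation of the grading pipeline
#'
#' Splits patients into `k` folds stratified by the translational
#' instability label (the rarer instability, keeping folds two-class;
#' plain shuffling when labels are absent). In each fold the CPDs are fit
#' on the training patients' ground-truth booleans and the full
#' fusion + refinement + grading path is evaluated on the held-out
#' patients. A fold whose test labels are single-class gets `NA` for the
#' affected metric rather than a fabricated value.
#'
#' @param patients labeled patient table (truth columns present).
#' @param detections detections covering the cohort.
#' @param spec grading network structure.
#' @param th a [thresholds()] object.
#' @param K number of augmented scans per patient.
#' @param k number of folds.
#' @param seed RNG seed for the fold assignment.
#' @param pseudocount CPD smoothing pseudocount.
#' @return A `metrics_report`: per-fold AUC and kappa for R and T plus
#'   mean/sd summaries.
#' @export
cross_validate <- function(patients, detections, spec, th = thresholds(),
                           K, k = 5L, seed = 1L, pseudocount = 1) {
  n <- nrow(patients)
  if (n < k) stop("need at least `k` patients")
  set.seed(seed)
  strata <- if (!is.null(patients$truth_T) && !anyNA(patients$truth_T))
    patients$truth_T else rep(0L, n)
  fold <- integer(n)
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  has_age <- "age60" %in% spec$nodes
  per_fold <- lapply(seq_len(k), function(f) {
    train <- patients[fold != f, , drop = FALSE]
    test <- patients[fold == f, , drop = FALSE]
    tab <- data.frame(R = train$truth_R, T = train$truth_T)
    for (t in fracture_types()) tab[[t]] <- train[[paste0("truth_", t)]]
    if (has_age) tab$age60 <- age_flag(train$age_years)
    cpds <- fit_cpds(spec, tab, pseudocount)
    graded <- grade_cohort(test, detections[detections$patient_id %in%
                                              test$patient_id, , drop = FALSE],
                           spec, cpds, th, K, method = "refine")
    data.frame(fold = f,
               auc_R = metric_or_na(roc_auc, graded$p_R, test$truth_R),
               auc_T = metric_or_na(roc_auc, graded$p_T, test$truth_T),
               kappa_R = metric_or_na(cohen_kappa, graded$pred_R, test$truth_R),
               kappa_T = metric_or_na(cohen_kappa, graded$pred_T, test$truth_T))
  })
  per_fold <- do.call(rbind, per_fold)
  summary <- data.frame(
    metric = c("auc_R", "auc_T", "kappa_R", "kappa_T"),
    mean = vapply(per_fold[, -1], mean, numeric(1), na.rm = TRUE),
    sd = vapply(per_fold[, -1], sd, numeric(1), na.rm = TRUE),
    n_folds = vapply(per_fold[, -1], function(x) sum(!is.na(x)), numeric(1)))
  rownames(summary) <- NULL
  structure(list(per_fold = per_fold, summary = summary, k = k, seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d-fold cross-validation (seed %d)\n", x$k, x$seed))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-8s %.3f +/- %.3f (%d folds)\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i], x$summary$n_folds[i]))
  invisible(x)
}

#' Sweep a confidence threshold and compare prediction variants
#'
#' Re-grades the cohort at each grid value of `z_low` or `z_star`, keeping
#' the other thresholds fixed, and reports the instability AUCs of the
#' three prediction variants: `LOW` (grade directly on the low-confidence
#' set), `HIGH` (grade on the high-confidence set), and `REFINE` (retrieval
#' starting from the high-confidence set).
#'
#' @param axis `"z_low"` or `"z_star"`.
#' @param grid numeric grid of threshold values.
#' @param fixed a [thresholds()] object supplying the other thresholds.
#' @param patients,detections,spec,cpds,K as in [grade_cohort()].
#' @return data.frame with one row per (grid value, variant): `auc_R`,
#'   `auc_T`.
#' @export
threshold_sweep <- function(axis = c("z_low", "z_star"), grid, fixed = thresholds(),
                            patients, detections, spec, cpds, K) {
  axis <- match.arg(axis)
  if (!length(grid)) stop("empty threshold grid")
  rows <- lapply(grid, function(v) {
    th <- if (axis == "z_low")
      thresholds(fixed$keep_2d, fixed$z_high, v, fixed$z_star)
    else
      thresholds(fixed$keep_2d, fixed$z_high, fixed$z_low, v)
    do.call(rbind, lapply(c("low", "high", "refine"), function(mth) {
      g <- grade_cohort(patients, detections, spec, cpds, th, K, method = mth)
      data.frame(value = v, variant = toupper(mth),
                 auc_R = metric_or_na(roc_auc, g$p_R, patients$truth_R),
                 auc_T = metric_or_na(roc_auc, g$p_T, patients$truth_T),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
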