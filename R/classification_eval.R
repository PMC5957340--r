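#' Select the optimal scale by group separation
#'
#' Scans scales and returns the one whose entropy values best separate two
#' groups, measured by the area under the ROC curve computed in whichever
#' direction exceeds 0.5 (separation is direction-free). Scales with fewer
#' than one defined value in either group are skipped; ties are broken
#' toward the smallest scale, so identical groups (all AUC = 0.5) yield
#' scale 1.
#'
#' @param profiles tidy [profile_table()] with `label` filled, or a list of
#'   profiles; exactly two groups expected.
#' @param method which profile method to scan (default: the only one
#'   present, error if ambiguous).
#' @return the selected scale (integer). The per-scale separation table is
#'   attached as `attr(, "auc_by_scale")`.
#' @export
select_optimal_scale <- function(profiles, method = NULL) {
  df <- if (is.data.frame(profiles)) profiles else profile_table(profiles)
  if (is.null(method)) {
    method <- unique(df$method)
    if (length(method) != 1L)
      stop("several methods present; pick one via `method`")
  }
  df <- df[df$method == method, ]
  gr <- unique(df$label[!is.na(df$label)])
  if (length(gr) != 2L) stop("optimal-scale selection needs exactly two groups")
  scales <- sort(unique(df$scale))
  sep <- rep(NA_real_, length(scales))
  for (i in seq_along(scales)) {
    ds <- df[df$scale == scales[i] & !is.na(df$value), ]
    v1 <- ds$value[ds$label == gr[1]]
    v2 <- ds$value[ds$label == gr[2]]
    if (!length(v1) || !length(v2)) next
    a <- auc(v1, v2)
    sep[i] <- max(a, 1 - a)
  }
  if (all(is.na(sep))) stop("no scale has defined values in both groups")
  best <- scales[which.max(sep)]  # which.max takes the first maximum: smallest scale
  attr(best, "auc_by_scale") <- data.frame(scale = scales, separation = sep)
  best
}

#' Classification accuracy from confusion counts
#'
#' `CA = (TP + TN) / (TP + TN + FP + FN) * 100`, in percent.
#'
#' @param tp,tn,fp,fn non-negative confusion-matrix counts.
#' @return accuracy in percent.
#' @export
classification_accuracy <- function(tp, tn, fp, fn) {
  cnt <- c(tp, tn, fp, fn)
  if (any(cnt < 0)) stop("confusion counts must be non-negative")
  tot <- sum(cnt)
  if (tot == 0) stop("confusion counts sum to zero")
  (tp + tn) / tot * 100
}

#' Build a feature table from entropy profiles
#'
#' One row per subject with the entropy at scale 1 and at the optimal
#' (max-separation) scale, per method — the feature set used to classify
#' subjects from their complexity profiles. The optimal scale is selected
#' per method on the full data via [select_optimal_scale()] unless given.
#' Subjects with an undefined entropy at a selected scale are excluded and
#' reported via a message and `attr(, "excluded")`.
#'
#' @param profiles tidy [profile_table()] with `label` filled, or a list of
#'   profiles.
#' @param optimal_scale optional named vector / single integer forcing the
#'   optimal scale per method.
#' @return data.frame with columns `subject_id`, `label`, and
#'   `<method>_s1`, `<method>_opt` per method; the selected scales are in
#'   `attr(, "scales")`.
#' @export
build_feature_table <- function(profiles, optimal_scale = NULL) {
  df <- if (is.data.frame(profiles)) profiles else profile_table(profiles)
  if (anyNA(df$label)) stop("profiles carry no group labels")
  methods <- unique(df$method)
  subjects <- unique(df[, c("source_id", "label")])
  feat <- data.frame(subject_id = subjects$source_id, label = subjects$label,
                     stringsAsFactors = FALSE)
  scales_used <- list()
  for (meth in methods) {
    dm <- df[df$method == meth, ]
    opt <- if (!is.null(optimal_scale)) {
      if (!is.null(names(optimal_scale))) optimal_scale[[meth]] else optimal_scale
    } else as.integer(select_optimal_scale(dm, method = meth))
    scales_used[[meth]] <- c(s1 = 1L, opt = as.integer(opt))
    v1 <- dm[dm$scale == 1L, ]
    vo <- dm[dm$scale == opt, ]
    feat[[paste0(tolower(meth), "_s1")]] <- v1$value[match(feat$subject_id, v1$source_id)]
    feat[[paste0(tolower(meth), "_opt")]] <- vo$value[match(feat$subject_id, vo$source_id)]
  }
  ok <- stats::complete.cases(feat)
  if (any(!ok)) {
    message(sum(!ok), " subject(s) excluded for undefined entropy at a selected scale: ",
            paste(feat$subject_id[!ok], collapse = ", "))
  }
  out <- feat[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scales") <- scales_used
  attr(out, "excluded") <- feat$subject_id[!ok]
  out
}

#' Cross-validated classification of subjects from entropy features
#'
#' Evaluates a classifier on a feature table under one of two resampling
#' schemes: `"loocv"` (leave-one-out: every subject is held out once) or
#' `"ten_by_ten_fcv"` (stratified 10-fold cross-validation repeated 10
#' times with fresh random partitions; the reported accuracy is the mean
#' over the 10 repetitions). Folds are stratified by class so that both
#' classes appear in every training set. Confusion counts treat the first
#' class level (alphabetical) as "positive".
#'
#' @param features a [build_feature_table()] result, or any data.frame with
#'   `subject_id`, `label` and numeric feature columns.
#' @param classifier `"svm_rbf"`, `"rf"` or `"knn3"`.
#' @param scheme `"loocv"` or `"ten_by_ten_fcv"`.
#' @param seed integer seed controlling fold assignment (and the forest's
#'   bootstrap); identical seeds give identical partitions and results.
#' @param n_folds,n_repeats fold count and repetition count of the repeated
#'   CV scheme (defaults 10 and 10).
#' @param ... passed to the classifier fitter (e.g. `ntree`, `C`, `gamma`).
#' @return a `classification_result`: list with `classifier`, `scheme`,
#'   `ca` (percent), confusion counts `tp`, `tn`, `fp`, `fn` (summed over
#'   folds; over repetitions for FCV with per-repetition accuracies in
#'   `ca_per_rep`), and `seed`.
#' @export
evaluate_classifier <- function(features,
                                classifier = c("svm_rbf", "rf", "knn3"),
                                scheme = c("loocv", "ten_by_ten_fcv"),
                                seed = 1L, n_folds = 10L, n_repeats = 10L, ...) {
  classifier <- match.arg(classifier)
  scheme <- match.arg(scheme)
  if (!all(c("subject_id", "label") %in% names(features)))
    stop("`features` needs subject_id and label columns")
  fcols <- setdiff(names(features), c("subject_id", "label"))
  x <- as.matrix(features[, fcols, drop = FALSE])
  if (!is.numeric(x) || anyNA(x)) stop("feature columns must be numeric and complete")
  y <- as.character(features$label)
  lev <- sort(unique(y))
  if (length(lev) < 2L) stop("need at least two classes")
  pos <- lev[1L]
  n <- nrow(x)

  confusion <- function(truth, pred) {
    c(tp = sum(truth == pos & pred == pos),
      tn = sum(truth != pos & pred != pos),
      fp = sum(truth != pos & pred == pos),
      fn = sum(truth == pos & pred != pos))
  }
  run_folds <- function(fold_of) {
    cm <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (f in sort(unique(fold_of))) {
      test <- fold_of == f
      fit <- fit_classifier(x[!test, , drop = FALSE], y[!test], classifier, ...)
      cm <- cm + confusion(y[test], predict_cls(fit, x[test, , drop = FALSE]))
    }
    cm
  }

  if (scheme == "loocv") {
    cm <- with_seed(seed, run_folds(seq_len(n)))
    ca <- classification_accuracy(cm["tp"], cm["tn"], cm["fp"], cm["fn"])
    ca_per_rep <- NULL
  } else {
    cls_n <- table(y)
    if (any(cls_n < n_folds))
      stop("every class needs >= ", n_folds,
           " subjects for ", n_folds, "-fold CV; consider scheme = \"loocv\"")
    res <- with_seed(seed, {
      lapply(seq_len(n_repeats), function(rep) {
        fold_of <- integer(n)
        for (cl in lev) {         # stratified: spread each class over folds
          idx <- sample(which(y == cl))
          fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
        }
        cm <- run_folds(fold_of)
        list(cm = cm, ca = classification_accuracy(cm["tp"], cm["tn"], cm["fp"], cm["fn"]))
      })
    })
    cm <- Reduce(`+`, lapply(res, `[[`, "cm"))
    ca_per_rep <- vapply(res, `[[`, numeric(1), "ca")
    ca <- mean(ca_per_rep)
  }
  structure(list(classifier = classifier, scheme = scheme,
                 ca = unname(ca), tp = unname(cm["tp"]), tn = unname(cm["tn"]),
                 fp = unname(cm["fp"]), fn = unname(cm["fn"]),
                 ca_per_rep = ca_per_rep, positive = pos, seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s / %s: CA = %.2f%%\n",
              x$classifier, x$scheme, x$ca))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d  (positive = %s, seed = %s)\n",
              x$tp, x$tn, x$fp, x$fn, x$positive, x$seed))
  invisible(x)
}
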