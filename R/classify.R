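#' SVM hyperparameter specification
#'
#' One kernel plus its kernel-specific parameter: a Gaussian (radial) kernel
#' carries a `kernel_scale` sigma, a polynomial kernel a `degree` 2-4, and a
#' linear kernel neither. `box_constraint` is the soft-margin cost C.
#'
#' @param kernel `"gaussian"`, `"polynomial"` or `"linear"`.
#' @param box_constraint positive cost C.
#' @param kernel_scale positive Gaussian sigma (gaussian kernel only).
#' @param degree integer 2-4 (polynomial kernel only).
#' @return object of class `svm_spec`.
#' @export
svm_spec <- function(kernel, box_constraint = 1, kernel_scale = NULL,
                     degree = NULL) {
  kernel <- match.arg(kernel, c("gaussian", "polynomial", "linear"))
  stopifnot(box_constraint > 0)
  if (kernel == "gaussian") {
    if (is.null(kernel_scale) || kernel_scale <= 0 || !is.null(degree))
      stop("gaussian kernel needs kernel_scale > 0 and no degree")
  } else if (kernel == "polynomial") {
    if (is.null(degree) || !degree %in% 2:4 || !is.null(kernel_scale))
      stop("polynomial kernel needs degree in 2..4 and no kernel_scale")
  } else {
    if (!is.null(degree) || !is.null(kernel_scale))
      stop("linear kernel takes no kernel-specific parameter")
  }
  structure(list(kernel = kernel, box_constraint = box_constraint,
                 kernel_scale = kernel_scale, degree = degree),
            class = "svm_spec")
}

#' @export
print.svm_spec <- function(x, ...) {
  extra <- switch(x$kernel,
    gaussian = sprintf(", scale %.4g", x$kernel_scale),
    polynomial = sprintf(", degree %d", x$degree), "")
  cat(sprintf("SVM spec: %s kernel, C = %.4g%s\n", x$kernel,
              x$box_constraint, extra))
  invisible(x)
}

# labels as a two-level factor with the positive class last
as_class_factor <- function(labels, positive = "aud") {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2) stop("need exactly two classes, got ", length(cls))
  if (!positive %in% cls) positive <- cls[1]
  factor(labels, levels = c(setdiff(cls, positive), positive))
}

fit_svm <- function(x, y, spec) {
  args <- list(x = x, y = y, cost = spec$box_constraint, scale = FALSE)
  args <- c(args, switch(spec$kernel,
    gaussian = list(kernel = "radial",
                    gamma = 1 / (2 * spec$kernel_scale^2)),
    polynomial = list(kernel = "polynomial", degree = spec$degree,
                      gamma = 1 / ncol(x), coef0 = 1),
    linear = list(kernel = "linear")))
  do.call(e1071::svm, args)
}

# decision scores oriented so larger = more positive-class
svm_scores <- function(fit, x, positive) {
  pred <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sides <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  score <- dv[, 1]
  if (sides[1] != positive) score <- -score
  list(class = as.character(pred), score = unname(score))
}

# stratified fold assignment over rows; subject-grouped keeps a subject's
# rows in a single fold (folds stratified by class at the subject level)
make_folds <- function(labels, k, split = "segment", subject_id = NULL) {
  if (split == "segment") {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    return(fold)
  }
  stopifnot(!is.null(subject_id))
  subj <- unique(data.frame(subject_id = subject_id, labels = labels,
                            stringsAsFactors = FALSE))
  sfold <- integer(nrow(subj))
  for (cl in unique(subj$labels)) {
    idx <- which(subj$labels == cl)
    if (length(idx) < k)
      stop("subject-grouped split needs >= ", k, " subjects per class")
    sfold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  sfold[match(subject_id, subj$subject_id)]
}

cv_accuracy <- function(x, y, spec, fold) {
  k <- max(fold)
  correct <- 0L
  for (j in seq_len(k)) {
    te <- fold == j
    if (length(unique(y[!te])) < 2)
      stop("degenerate single-class training fold")
    fit <- fit_svm(x[!te, , drop = FALSE], y[!te], spec)
    correct <- correct + sum(stats::predict(fit, x[te, , drop = FALSE]) == y[te])
  }
  correct / length(y)
}

#' Tune SVM hyperparameters by seeded sequential search
#'
#' Maximizes k-fold cross-validated accuracy over the kernel family and its
#' parameters within a fixed evaluation budget: the first ~60% of the budget
#' explores the space at random (box constraint log-uniform on 1e-3..1e3,
#' Gaussian scale log-uniform on 1e-2..1e2, polynomial degree 2-4), the
#' remainder refines around the incumbent with Gaussian steps in log-space.
#' The whole search, including fold assignment, is a pure function of the
#' seed.
#'
#' @param x rows x features matrix.
#' @param labels class label per row (two classes, >= 10 rows each).
#' @param budget number of candidate evaluations (default 30).
#' @param k CV folds used by the tuning objective.
#' @param kernels kernel families searched.
#' @param positive positive class name.
#' @param seed integer seed.
#' @return the best [svm_spec()], with attributes `"cv_accuracy"` and
#'   `"trace"` (per-candidate data.frame).
#' @export
tune_svm <- function(x, labels, budget = 30, k = 5,
                     kernels = c("gaussian", "polynomial", "linear"),
                     positive = "aud", seed = 1) {
  x <- as.matrix(x)
  y <- as_class_factor(labels, positive)
  if (min(table(y)) < 10) stop("need >= 10 rows per class to tune")
  n_random <- ceiling(0.6 * budget)
  withr::with_seed(seed, {
    fold <- make_folds(y, k)
    best <- NULL; best_acc <- -Inf
    trace <- vector("list", budget)
    for (i in seq_len(budget)) {
      cand <- if (i <= n_random || is.null(best)) {
        kern <- sample(kernels, 1)
        switch(kern,
          gaussian = svm_spec("gaussian", 10^stats::runif(1, -3, 3),
                              kernel_scale = 10^stats::runif(1, -2, 2)),
          polynomial = svm_spec("polynomial", 10^stats::runif(1, -3, 3),
                                degree = sample(2:4, 1)),
          linear = svm_spec("linear", 10^stats::runif(1, -3, 3)))
      } else {
        C2 <- 10^(log10(best$box_constraint) + stats::rnorm(1, sd = 0.5))
        C2 <- min(max(C2, 1e-3), 1e3)
        if (best$kernel == "gaussian") {
          s2 <- 10^(log10(best$kernel_scale) + stats::rnorm(1, sd = 0.5))
          svm_spec("gaussian", C2, kernel_scale = min(max(s2, 1e-2), 1e2))
        } else if (best$kernel == "polynomial") {
          svm_spec("polynomial", C2, degree = best$degree)
        } else svm_spec("linear", C2)
      }
      acc <- cv_accuracy(x, y, cand, fold)
      trace[[i]] <- data.frame(i = i, kernel = cand$kernel,
                               C = cand$box_constraint,
                               scale = cand$kernel_scale %||% NA_real_,
                               degree = cand$degree %||% NA_integer_,
                               cv_accuracy = acc)
      if (acc > best_acc) { best <- cand; best_acc <- acc }
    }
    attr(best, "cv_accuracy") <- best_acc
    attr(best, "trace") <- do.call(rbind, trace)
    best
  })
}

#' ROC curve, AUC and Youden operating point from decision scores
#'
#' Standard threshold sweep over the pooled scores (ties grouped), starting
#' at (0, 0) and ending at (1, 1); AUC by the trapezoidal rule; operating
#' point at maximal Youden's J = TPR - FPR.
#'
#' @param scores numeric decision scores, larger = more positive.
#' @param labels class label per score.
#' @param positive positive class name.
#' @return list with `roc` (data.frame `fpr`, `tpr`), `auc`,
#'   `operating_point` (named vector `fpr`, `tpr`).
#' @export
roc_curve <- function(scores, labels, positive = "aud") {
  pos <- as.character(labels) == positive
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  grp_last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(p)[grp_last] / P)
  fpr <- c(0, cumsum(!p)[grp_last] / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- which.max(tpr - fpr)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       operating_point = c(fpr = fpr[j], tpr = tpr[j]))
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, sensitivity (TPR), specificity (TNR) and precision from the
#' four counts, with the positive class the AUD-like cohort. A ratio with a
#' zero denominator is reported as `NA` with a warning, never silently 0.
#'
#' @param tp,tn,fp,fn non-negative counts, total > 0.
#' @return named list of the four metrics plus the counts.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: zero denominator"); NA_real_ }
    else num / den
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = safe(tp, tp + fn, "sensitivity"),
       specificity = safe(tn, tn + fp, "specificity"),
       precision = safe(tp, tp + fp, "precision"))
}

#' Evaluate an SVM specification by repeated cross-validation
#'
#' Repeated stratified k-fold CV (`split = "segment"`, the default protocol)
#' or subject-grouped folds (`split = "subject"`, leakage-free: all of a
#' subject's segments stay in one fold). Confusion counts accumulate over
#' every held-out fold of every repeat; accuracy is reported as mean +/- sd
#' over repeats; the ROC pools held-out decision scores across all repeats.
#'
#' @param x rows x features matrix.
#' @param labels class label per row.
#' @param spec an [svm_spec()].
#' @param split `"segment"` or `"subject"`.
#' @param k folds; `repeats` repetitions with re-drawn folds.
#' @param subject_id required for subject-grouped splits.
#' @param positive positive class name.
#' @param seed integer seed (fold draws are a pure function of it).
#' @param repeats number of CV repetitions.
#' @return object of class `evaluation_report`: counts, metrics,
#'   `accuracy_mean`, `accuracy_sd`, `roc`, `auc`, `operating_point`,
#'   `split`, `k`, `repeats`.
#' @export
evaluate_svm <- function(x, labels, spec, split = c("segment", "subject"),
                         k = 5, repeats = 5, subject_id = NULL,
                         positive = "aud", seed = 1) {
  split <- match.arg(split)
  x <- as.matrix(x)
  y <- as_class_factor(labels, positive)
  positive <- levels(y)[2]
  stopifnot(k >= 2)
  withr::with_seed(seed, {
    tp <- tn <- fp <- fn <- 0L
    acc_rep <- numeric(repeats)
    all_scores <- numeric(0); all_truth <- character(0)
    for (r in seq_len(repeats)) {
      fold <- make_folds(y, k, split, subject_id)
      correct <- 0L
      for (j in seq_len(k)) {
        te <- fold == j
        fit <- fit_svm(x[!te, , drop = FALSE], y[!te], spec)
        sc <- svm_scores(fit, x[te, , drop = FALSE], positive)
        truth <- as.character(y[te])
        tp <- tp + sum(sc$class == positive & truth == positive)
        tn <- tn + sum(sc$class != positive & truth != positive)
        fp <- fp + sum(sc$class == positive & truth != positive)
        fn <- fn + sum(sc$class != positive & truth == positive)
        correct <- correct + sum(sc$class == truth)
        all_scores <- c(all_scores, sc$score)
        all_truth <- c(all_truth, truth)
      }
      acc_rep[r] <- correct / length(y)
    }
    roc <- roc_curve(all_scores, all_truth, positive)
    structure(c(confusion_metrics(tp, tn, fp, fn),
                list(accuracy_mean = mean(acc_rep),
                     accuracy_sd = stats::sd(acc_rep),
                     accuracy_per_repeat = acc_rep,
                     roc = roc$roc, auc = roc$auc,
                     operating_point = roc$operating_point,
                     split = split, k = k, repeats = repeats,
                     positive = positive)),
              class = "evaluation_report")
  })
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("Evaluation (%s split, %dx%d-fold CV):\n",
                     "  accuracy %.1f%% +/- %.2f | sens %.3f spec %.3f ",
                     "prec %.3f | AUC %.3f\n"),
              x$split, x$repeats, x$k, 100 * x$accuracy_mean,
              100 * (x$accuracy_sd %||% 0), x$sensitivity, x$specificity,
              x$precision, x$auc))
  invisible(x)
}

#' Tune and evaluate an SVM independently for every band
#'
#' For each band's feature table, hyperparameters are tuned (or a fixed spec
#' reused) and the model evaluated by repeated CV; returns all reports, the
#' per-band accuracy table, the accuracy-ranked top-5 bands and the
#' cross-band mean accuracy.
#'
#' @param fset a `feature_set` containing every requested band.
#' @param bands band indices to sweep.
#' @param tune tune per band (`TRUE`) or reuse `spec`.
#' @param spec fixed [svm_spec()] when `tune = FALSE`.
#' @param budget tuning budget per band.
#' @param split,k,repeats,positive,seed passed to [evaluate_svm()].
#' @return list: `reports` (named by band), `accuracy` (data.frame: band,
#'   accuracy_mean, accuracy_sd, auc), `top_bands` (top 5 by mean accuracy,
#'   ties broken by lower band index), `mean_accuracy`.
#' @export
per_band_sweep <- function(fset, bands = fset$bands, tune = TRUE, spec = NULL,
                           budget = 30, split = "segment", k = 5, repeats = 5,
                           positive = "aud", seed = 1) {
  key <- paste0("band", bands)
  missing <- setdiff(key, names(fset$tables))
  if (length(missing) > 0)
    stop("bands missing from feature set: ",
         paste(sub("band", "", missing), collapse = ", "))
  if (!tune && is.null(spec)) stop("tune = FALSE requires a fixed spec")
  labels <- fset$meta$class_label
  reports <- vector("list", length(bands))
  names(reports) <- key
  for (i in seq_along(bands)) {
    xb <- fset$tables[[key[i]]]
    sp <- if (tune) tune_svm(xb, labels, budget = budget, positive = positive,
                             seed = derive_seed(seed, bands[i], salt = 11))
          else spec
    reports[[i]] <- evaluate_svm(
      xb, labels, sp, split = split, k = k, repeats = repeats,
      subject_id = fset$meta$subject_id, positive = positive,
      seed = derive_seed(seed, bands[i], salt = 13))
  }
  acc <- data.frame(
    band = bands,
    accuracy_mean = vapply(reports, `[[`, numeric(1), "accuracy_mean"),
    accuracy_sd = vapply(reports, `[[`, numeric(1), "accuracy_sd"),
    auc = vapply(reports, `[[`, numeric(1), "auc"), row.names = NULL)
  rank <- order(-acc$accuracy_mean, acc$band)
  list(reports = reports, accuracy = acc,
       top_bands = acc$band[rank][seq_len(min(5, length(bands)))],
       mean_accuracy = mean(acc$accuracy_mean))
}
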