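blobs <- function(n = 40, sep = 6, seed = 1) {
  withr::with_seed(seed, list(
    x = rbind(matrix(rnorm(n, mean = 0), n / 2, 2),
              matrix(rnorm(n, mean = sep), n / 2, 2)),
    labels = rep(c("aud", "control"), each = n / 2)))
}

test_that("svm_spec enforces one kernel-specific parameter set", {
  expect_s3_class(svm_spec("gaussian", 1, kernel_scale = 2), "svm_spec")
  expect_error(svm_spec("gaussian", 1), "kernel_scale")
  expect_error(svm_spec("gaussian", 1, kernel_scale = 1, degree = 2),
               "no degree")
  expect_error(svm_spec("polynomial", 1, degree = 5), "2..4")
  expect_error(svm_spec("linear", 1, degree = 2), "no kernel-specific")
  expect_error(svm_spec("gaussian", -1, kernel_scale = 1))
})

test_that("tuning separable blobs reaches near-perfect CV accuracy", {
  d <- blobs(n = 60, sep = 6)
  sp <- tune_svm(d$x, d$labels, budget = 15, seed = 2)
  expect_gte(attr(sp, "cv_accuracy"), 0.99)
})

test_that("tuning on pure noise does not leak optimistic accuracy", {
  d <- withr::with_seed(9, list(x = matrix(rnorm(120 * 6), 120, 6),
                                labels = rep(c("aud", "control"), 60)))
  sp <- tune_svm(d$x, d$labels, budget = 15, seed = 4)
  rep5 <- evaluate_svm(d$x, d$labels, sp, k = 5, repeats = 5, seed = 10)
  expect_gte(rep5$accuracy_mean, 0.40)
  expect_lte(rep5$accuracy_mean, 0.60)
})

test_that("tuning and evaluation are bit-reproducible under a fixed seed", {
  d <- blobs(n = 40, sep = 2, seed = 3)
  s1 <- tune_svm(d$x, d$labels, budget = 10, seed = 7)
  s2 <- tune_svm(d$x, d$labels, budget = 10, seed = 7)
  expect_identical(unclass(s1)[1:4], unclass(s2)[1:4])
  r1 <- evaluate_svm(d$x, d$labels, s1, seed = 5)
  r2 <- evaluate_svm(d$x, d$labels, s1, seed = 5)
  expect_identical(r1$accuracy_mean, r2$accuracy_mean)
  expect_identical(r1$accuracy_sd, r2$accuracy_sd)
  expect_identical(r1$roc, r2$roc)
})

test_that("evaluation report satisfies the confusion/ROC identities", {
  d <- blobs(n = 60, sep = 1.5, seed = 5)
  r <- evaluate_svm(d$x, d$labels, svm_spec("linear", 1), k = 5, repeats = 3,
                    seed = 2)
  expect_equal(r$tp + r$tn + r$fp + r$fn, 60 * 3)  # every row, every repeat
  expect_equal(r$accuracy, (r$tp + r$tn) / (60 * 3))
  expect_equal(r$sensitivity, r$tp / (r$tp + r$fn))
  expect_equal(r$specificity, r$tn / (r$tn + r$fp))
  expect_equal(r$precision, r$tp / (r$tp + r$fp))
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
})

test_that("permuted labels give chance-level accuracy and AUC", {
  d <- blobs(n = 80, sep = 6, seed = 6)
  perm <- withr::with_seed(13, sample(d$labels))
  r <- evaluate_svm(d$x, perm, svm_spec("linear", 1), k = 5, repeats = 5,
                    seed = 3)
  n_eval <- 80 * 5
  ci <- qbinom(c(0.005, 0.995), n_eval, 0.5) / n_eval
  expect_gte(r$accuracy, ci[1])
  expect_lte(r$accuracy, ci[2])
  expect_gte(r$auc, 0.40)
  expect_lte(r$auc, 0.60)
})

test_that("a perfect ranking gives AUC 1 and operating point (0, 1)", {
  scores <- c(rnorm(30, 10), rnorm(30, -10))
  labels <- rep(c("aud", "control"), each = 30)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$auc, 1)
  expect_equal(unname(rc$operating_point), c(0, 1))
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  for (s in 1:20) {
    withr::with_seed(s, {
      n1 <- sample(10:40, 1); n2 <- sample(10:40, 1)
      scores <- c(rnorm(n1, 0.5), rnorm(n2))
      labels <- rep(c("aud", "control"), c(n1, n2))
    })
    rc <- roc_curve(scores, labels)
    u <- wilcox.test(scores[labels == "aud"],
                     scores[labels == "control"], exact = FALSE)$statistic
    expect_equal(rc$auc, unname(u) / (n1 * n2), tolerance = 1e-12)
  }
})

test_that("confusion metrics match direct formula evaluation", {
  m <- confusion_metrics(50, 50, 0, 0)
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "precision")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 precision = 1))
  expect_equal(confusion_metrics(0, 0, 10, 10)$accuracy, 0)
  withr::with_seed(17, {
    for (i in 1:1000) {
      k <- rpois(4, 20) + c(1, 1, 0, 0)  # keep totals positive
      m <- confusion_metrics(k[1], k[2], k[3], k[4])
      expect_identical(m$accuracy, (k[1] + k[2]) / sum(k))
      expect_identical(m$sensitivity, k[1] / (k[1] + k[4]))
      expect_identical(m$specificity, k[2] / (k[2] + k[3]))
      expect_identical(m$precision, k[1] / (k[1] + k[3]))
    }
  })
  expect_warning(m0 <- confusion_metrics(0, 5, 0, 1), "precision undefined")
  expect_true(is.na(m0$precision))
  expect_equal(m0$sensitivity, 0)
})

test_that("subject-grouped splits remove the segment-level leakage optimism", {
  # features carry a strong subject-specific offset and only a weak class
  # signal: segment-level folds can memorize subjects, grouped folds cannot
  diffs <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      n_subj <- 8; n_seg <- 12
      subj_eff <- matrix(rnorm(2 * n_subj * 5, sd = 1.5), 2 * n_subj, 5)
      rows <- lapply(seq_len(2 * n_subj), function(i) {
        cls <- if (i <= n_subj) 0.3 else 0
        sweep(matrix(rnorm(n_seg * 5), n_seg, 5), 2,
              subj_eff[i, ] + cls, `+`)
      })
      x <- do.call(rbind, rows)
      labels <- rep(c("aud", "control"), each = n_subj * n_seg)
      subject <- rep(sprintf("s%02d", seq_len(2 * n_subj)), each = n_seg)
    })
    sp <- svm_spec("linear", 1)
    seg <- evaluate_svm(x, labels, sp, split = "segment", k = 4,
                        repeats = 1, seed = s)
    grp <- evaluate_svm(x, labels, sp, split = "subject", k = 4,
                        repeats = 1, subject_id = subject, seed = s)
    seg$accuracy_mean - grp$accuracy_mean
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs >= 0), 15)
})

test_that("subject-grouped split refuses too few subjects", {
  x <- matrix(rnorm(40), 20, 2)
  labels <- rep(c("aud", "control"), each = 10)
  subject <- rep(c("a1", "a2", "c1", "c2"), each = 5)
  expect_error(evaluate_svm(x, labels, svm_spec("linear", 1),
                            split = "subject", k = 5, subject_id = subject),
               ">= 5 subjects")
})

test_that("per-band sweep returns one tuned report per band with ranking", {
  fset <- local({
    withr::with_seed(21, {
      n <- 60
      tables <- list(
        band10 = matrix(rnorm(n * 8), n, 8),
        band50 = rbind(matrix(rnorm(n / 2 * 8, 1.5), n / 2, 8),
                       matrix(rnorm(n / 2 * 8), n / 2, 8)))
      structure(list(tables = tables,
                     meta = data.frame(
                       subject_id = rep(c("a", "c"), each = n / 2),
                       class_label = rep(c("aud", "control"), each = n / 2),
                       segment_index = rep(1:(n / 2), 2)),
                     bands = c(10, 50), node_labels = NULL),
                class = "feature_set")
    })
  })
  sw <- per_band_sweep(fset, tune = FALSE, spec = svm_spec("linear", 1),
                       k = 3, repeats = 2, seed = 5)
  expect_length(sw$reports, 2)
  expect_equal(sw$accuracy$band, c(10, 50))
  expect_equal(sw$top_bands[1], 50)  # the band carrying the signal wins
  expect_equal(sw$mean_accuracy, mean(sw$accuracy$accuracy_mean))
  expect_error(per_band_sweep(fset, bands = c(10, 11), tune = FALSE,
                              spec = svm_spec("linear", 1)), "missing")
})
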