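test_that("rhythm ranges match the band map and partition 1..64", {
  expect_identical(rhythm_bands("delta"), 1:6)
  expect_identical(rhythm_bands("theta"), 7:12)
  expect_identical(rhythm_bands("alpha"), 13:19)
  expect_identical(rhythm_bands("beta"), 20:47)
  expect_identical(rhythm_bands("gamma"), 48:64)
  all_bands <- unlist(lapply(rhythm_names(), rhythm_bands))
  expect_identical(sort(all_bands), 1:64)
  expect_equal(anyDuplicated(all_bands), 0)
  expect_error(rhythm_bands("mu"), "unknown rhythm")
})

make_fake_fset <- function(n_seg = 12, bands = 1:64, n_feat = 324, seed = 1) {
  withr::with_seed(seed, {
    tables <- lapply(bands, function(b)
      matrix(runif(n_seg * n_feat), n_seg, n_feat,
             dimnames = list(NULL, sprintf("f%03d", 1:n_feat))))
    names(tables) <- paste0("band", bands)
    structure(list(
      tables = tables,
      meta = data.frame(
        subject_id = rep(c("a1", "c1"), each = n_seg / 2),
        class_label = rep(c("aud", "control"), each = n_seg / 2),
        segment_index = rep(seq_len(n_seg / 2), 2)),
      bands = bands, node_labels = montage_1020()[1:18]),
      class = "feature_set")
  })
}

test_that("band concatenation produces N_fb x l_f columns in band order", {
  fset <- make_fake_fset()
  gamma <- concat_bands(fset, rhythm_bands("gamma"))
  expect_equal(ncol(gamma$x), 17 * 324)  # 5508
  single <- concat_bands(fset, 25)
  expect_equal(ncol(single$x), 324)
  expect_identical(unname(single$x), unname(fset$tables[["band25"]]))
  mask <- structure(list(p_values = rep(c(0.001, 0.5), c(210, 114)),
                         alpha = 0.04,
                         keep = rep(c(TRUE, FALSE), c(210, 114)),
                         n_kept = 210L), class = "selection_mask")
  reduced <- concat_bands(fset, rhythm_bands("gamma"), mask = mask)
  expect_equal(ncol(reduced$x), 17 * 210)  # 3570
  expect_error(concat_bands(make_fake_fset(bands = 1:10), c(9, 11)),
               "not present")
})

test_that("mask application commutes with band concatenation", {
  fset <- make_fake_fset(bands = 48:64)
  mask <- structure(list(p_values = runif(324), alpha = 0.5,
                         keep = runif(324) < 0.5, n_kept = 0L),
                    class = "selection_mask")
  mask$n_kept <- sum(mask$keep)
  a <- concat_bands(fset, 48:64, mask = mask)$x
  full <- concat_bands(fset, 48:64)$x
  cols <- as.vector(outer(which(mask$keep), (0:16) * 324, `+`))
  expect_equal(unname(a), unname(full[, sort(cols)]))
})

test_that("two-group ANOVA F equals squared pooled t and matches aov", {
  set.seed(31)
  x <- matrix(rnorm(60 * 8), 60, 8)
  g <- rep(c("aud", "control"), c(25, 35))
  mask <- anova_select(x, g, alpha = 0.05)
  for (j in c(1, 4, 8)) {
    p_aov <- summary(aov(x[, j] ~ factor(g)))[[1]][["Pr(>F)"]][1]
    expect_equal(mask$p_values[j], p_aov, tolerance = 1e-12)
    tt <- t.test(x[, j] ~ factor(g), var.equal = TRUE)
    expect_equal(mask$p_values[j], tt$p.value, tolerance = 1e-12)
  }
})

test_that("null features are kept at about the nominal rate", {
  # 324 independent null tests: kept fraction within the exact binomial
  # 99% interval around alpha
  set.seed(7)
  x <- matrix(rnorm(400 * 324), 400, 324)
  g <- rep(c("aud", "control"), each = 200)
  for (alpha in c(0.01, 0.04)) {
    kept <- anova_select(x, g, alpha)$n_kept
    ci <- qbinom(c(0.005, 0.995), 324, alpha)
    expect_gte(kept, ci[1])
    expect_lte(kept, ci[2])
  }
})

test_that("a one-SD shift on 40 connectivities is reliably detected", {
  # power oracle: F(1, 398) with noncentrality n/4 * shift^2 = 100 at
  # alpha 0.01 has power ~ 1 - pf(qf(.99, 1, 398), 1, 398, ncp = 100) ~ 1,
  # so all 40 shifted features should be kept in nearly every run
  hits <- vapply(1:100, function(s) {
    d <- shifted_features(n_per_class = 200, n_shift = 40, shift = 1,
                          seed = s)
    all(anova_select(d$x, d$labels, 0.01)$keep[1:40])
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("selection is monotone in alpha and affine-invariant", {
  d <- shifted_features(n_per_class = 50, seed = 3)
  m1 <- anova_select(d$x, d$labels, 0.01)
  m2 <- rethreshold_mask(m1, 0.04)
  expect_true(all(m2$keep[m1$keep]))  # keep(0.01) subset of keep(0.04)
  expect_gte(m2$n_kept, m1$n_kept)
  scaled <- anova_select(3.2 * d$x - 17, d$labels, 0.01)
  expect_equal(scaled$p_values, m1$p_values, tolerance = 1e-9)
})

test_that("degenerate inputs are handled explicitly", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(anova_select(x, rep("aud", 20), 0.01), "two classes")
  x[, 2] <- 1  # zero variance
  g <- rep(c("aud", "control"), each = 10)
  expect_warning(m <- anova_select(x, g, 0.01), "zero-variance")
  expect_equal(m$p_values[2], 1)
})

test_that("masks serialize to JSON with electrode pair names", {
  d <- shifted_features(n_per_class = 30, seed = 5)
  mask <- anova_select(d$x, d$labels, 0.01)
  js <- jsonlite::fromJSON(write_mask_json(mask, montage_1020()[1:18]))
  expect_equal(js$alpha, 0.01)
  expect_length(js$connectivity, 324)
  expect_equal(js$connectivity[19], "FP2<-FP1")  # row-major index 19 = (2,1)
  expect_equal(sum(js$keep), mask$n_kept)
})
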