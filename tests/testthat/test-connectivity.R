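test_that("band grid tiles 0.1-70 Hz with width 1.092 Hz", {
  e <- band_edges()
  expect_equal(nrow(e), 64)
  expect_equal(band_width(), (70 - 0.1) / 64)
  expect_equal(unname(e[1, "lo"]), 0.1)
  expect_equal(unname(e[64, "hi"]), 70)
  expect_equal(unname(e[-1, "lo"]), unname(e[-64, "hi"]))  # exact tiling
  expect_error(band_edges(65), "out of range")
})

test_that("OLS recovers MVAR coefficients on long realizations", {
  m <- bivariate_model()
  rec <- simulate_mvar(m, 1e5, seed = 3)
  fit <- fit_mvar(rec$data, order = 1, exclude = NULL)
  expect_lt(max(abs(fit$coeffs[[1]] - m$coeffs[[1]])), 0.02)
  expect_lt(max(abs(fit$noise_cov - diag(2))), 0.05)
})

test_that("null-model coefficient estimates stay within the noise bound", {
  # 512-sample white-noise segments, forced order 1: 99th percentile of
  # |c_hat| over 100 seeded segments below 0.15
  m <- mvar_model(list(matrix(0, 4, 4)))
  maxima <- vapply(1:100, function(s) {
    rec <- simulate_mvar(m, 512, burn_in = 0, seed = s)
    max(abs(fit_mvar(rec$data, order = 1, exclude = NULL)$coeffs[[1]]))
  }, numeric(1))
  expect_lte(unname(quantile(maxima, 0.99)), 0.15)
})

test_that("BIC order selection finds the generating order", {
  hits <- sum(vapply(1:100, function(s) {
    m <- random_stable_mvar(3, 3, sd = 0.35, seed = s + 400)
    rec <- simulate_mvar(m, 5000, seed = s)
    fit_mvar(rec$data, order = "auto", exclude = NULL, max_order = 10)$order == 3
  }, logical(1)))
  expect_gte(hits, 90)
})

test_that("fit_mvar validates its inputs", {
  seg <- segment_recording(
    eeg_recording(matrix(rnorm(19 * 512), 19), 256, montage_1020()))[[1]]
  expect_error(fit_mvar(seg, order = 5, exclude = "XX"), "not present")
  fit <- fit_mvar(seg, order = 5)  # drops CZ -> 18 nodes
  expect_equal(fit$n_channels, 18)
  expect_false("CZ" %in% fit$node_labels)
  const <- matrix(1, 3, 512)  # constant channels -> collinear regressors
  expect_error(fit_mvar(const, order = 2, exclude = NULL), "rank-deficient")
  expect_error(fit_mvar(matrix(rnorm(40), 4, 10), order = 5, exclude = NULL),
               "too short")
})

test_that("spectral transform matches closed forms", {
  m0 <- mvar_model(list(matrix(0, 3, 3)))
  for (w in c(0, 1, pi))
    expect_equal(spectral_transform(m0, w)$A_bar[[1]], diag(3) + 0i)
  m <- bivariate_model()
  expect_equal(spectral_transform(m, 0)$A_bar[[1]],
               (diag(2) - m$coeffs[[1]]) + 0i)
  expect_equal(spectral_transform(m, pi)$A_bar[[1]],
               (diag(2) + m$coeffs[[1]]) + 0i)
  expect_error(spectral_transform(m, numeric(0)), "non-empty")
})

test_that("band PDC stack has the right shape, range and null behavior", {
  seg <- segment_recording(simulate_mvar(
    default_backbone(), 512, seed = 1,
    channel_labels = montage_1020()))[[1]]
  stack <- band_pdcam(fit_mvar(seg, order = 5), subject_id = "s1",
                      segment_index = 1)
  expect_equal(dim(stack$values), c(64, 18, 18))
  expect_true(all(stack$values >= 0 & stack$values <= 1))
  # independent white-noise channels: little apparent coupling
  m <- mvar_model(list(matrix(0, 6, 6)))
  off <- vapply(1:100, function(s) {
    rec <- simulate_mvar(m, 512, burn_in = 0, seed = s + 50)
    st <- band_pdcam(fit_mvar(rec$data, order = 1, exclude = NULL))
    mask <- array(rep(row(diag(6)) != col(diag(6)), each = 64), c(64, 6, 6))
    mean(st$values[mask])
  }, numeric(1))
  expect_lt(mean(off), 0.1)
})

test_that("pre-exclusion PDC columns sum to one at single frequencies", {
  rec <- simulate_mvar(default_backbone(), 2048, seed = 9,
                       channel_labels = montage_1020())
  fit19 <- fit_mvar(rec$data, order = 3, exclude = NULL)  # all 19 channels
  for (w in c(0.3, 1.1, 2.4)) {
    P <- pdc(spectral_transform(fit19, w))[[1]]
    expect_lt(max(abs(colSums(P) - 1)), 1e-10)
  }
})

test_that("vectorization is row-major and exactly invertible", {
  seg <- segment_recording(simulate_mvar(
    default_backbone(), 512, seed = 2,
    channel_labels = montage_1020()))[[1]]
  stack <- band_pdcam(fit_mvar(seg, order = 5))
  v <- vectorize(stack, 10)
  expect_length(v, 324)
  m <- pdcam_matrix(stack, 10)
  expect_identical(unvectorize(v), unname(m))
  expect_identical(unname(v[19]), m[2, 1])  # (v=2, w=1) -> index 19
  expect_error(vectorize(stack, 65), "not present")
})

test_that("estimated band PDC converges to the analytic oracle with n", {
  m <- random_stable_mvar(4, 2, seed = 77)
  truth <- analytic_band_pdc(m)
  mae <- vapply(c(2^10, 2^13, 2^16), function(n) {
    rec <- simulate_mvar(m, n, seed = 5)
    median(abs(analytic_band_pdc(fit_mvar(rec$data, order = 2,
                                          exclude = NULL)) - truth))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))  # monotone decrease over the n ladder
  expect_lt(mae[3], 0.02)
})
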