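# Shared fixtures for the suite. Everything is generated in code; the
# bivariate model below is the worked example used across the MVAR and PDC
# tests: one-way coupling 1 -> 2 of 0.4, self-terms 0.5.
bivariate_model <- function() {
  mvar_model(list(matrix(c(0.5, 0.4, 0, 0.5), 2, 2)))
}

# small two-class cohort config at test scale (the full study conditions --
# 35 subjects/class, 5-minute recordings -- are the cohort_config defaults)
small_cohort_config <- function(n = 4, duration_s = 28, seed = 42, ...) {
  cohort_config(n_subjects_per_class = n, duration_s = duration_s,
                seed = seed, ...)
}

# feature matrix with a known class shift in the first `n_shift` columns
shifted_features <- function(n_per_class = 200, n_feat = 324, n_shift = 40,
                             shift = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * n_feat), 2 * n_per_class, n_feat)
    x[seq_len(n_per_class), seq_len(n_shift)] <-
      x[seq_len(n_per_class), seq_len(n_shift)] + shift
    list(x = x, labels = rep(c("aud", "control"), each = n_per_class))
  })
}

# Yule-Walker lag-0 / lag-1 autocovariances of a stable VAR(1):
# vec(G0) = (I - C (x) C)^{-1} vec(Sigma);  G1 = C G0
yule_walker_var1 <- function(C, Sigma) {
  S <- nrow(C)
  G0 <- matrix(solve(diag(S^2) - kronecker(C, C), as.vector(Sigma)), S, S)
  list(G0 = G0, G1 = C %*% G0)
}
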