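#' Multivariate autoregressive (MVAR) model
#'
#' Container for an order-`p` vector autoregression
#' \deqn{y(t) = \sum_{k=1}^{p} C_k \, y(t-k) + e(t),}
#' where each `C_k` is an `S x S` coefficient matrix (row = target channel,
#' column = source channel) and `e(t)` is zero-mean multivariate Gaussian
#' white noise with covariance `noise_cov`. This is the generative model
#' behind every synthetic EEG cohort and the estimand of [fit_mvar()].
#'
#' @param coeffs list of `S x S` numeric matrices, one per lag (length = order).
#' @param noise_cov `S x S` symmetric positive-definite innovation covariance.
#'   Defaults to the identity.
#' @param check if `TRUE` (default), validate dimensions, symmetry,
#'   positive-definiteness and stability; a violation is an error.
#'
#' @return An object of class `mvar_model` with fields `n_channels`, `order`,
#'   `coeffs`, `noise_cov`.
#' @export
#' @examples
#' m <- mvar_model(list(matrix(c(0.5, 0.4, 0, 0.5), 2, 2)))
#' m$order
mvar_model <- function(coeffs, noise_cov = NULL, check = TRUE) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  stopifnot(is.list(coeffs), length(coeffs) >= 1)
  S <- nrow(coeffs[[1]])
  if (is.null(noise_cov)) noise_cov <- diag(S)
  m <- structure(
    list(n_channels = S, order = length(coeffs),
         coeffs = lapply(coeffs, function(x) {
           x <- as.matrix(x)
           storage.mode(x) <- "double"
           x
         }),
         noise_cov = as.matrix(noise_cov)),
    class = "mvar_model")
  if (check) validate_mvar(m)
  m
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("MVAR model: %d channels, order %d, spectral radius %.3f\n",
              x$n_channels, x$order, mvar_spectral_radius(x)))
  invisible(x)
}

validate_mvar <- function(model) {
  S <- model$n_channels
  ok_dim <- all(vapply(model$coeffs, function(C) all(dim(C) == c(S, S)), logical(1)))
  if (!ok_dim) stop("every coefficient matrix must be ", S, " x ", S)
  Sg <- model$noise_cov
  if (!all(dim(Sg) == c(S, S)) || max(abs(Sg - t(Sg))) > 1e-10)
    stop("noise_cov must be a symmetric ", S, " x ", S, " matrix")
  ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("noise_cov must be positive definite (min eigenvalue ",
                         format(min(ev)), ")")
  if (!is_stable(model))
    stop("MVAR model is unstable (companion spectral radius ",
         format(mvar_spectral_radius(model), digits = 4), " >= 1)")
  invisible(model)
}

#' Companion-matrix spectral radius of an MVAR model
#'
#' The process is (covariance-)stationary iff all eigenvalues of the
#' `Sp x Sp` companion matrix lie strictly inside the unit circle,
#' equivalently all roots of `det(I - sum_k C_k z^k)` lie outside it.
#'
#' @param model an [mvar_model()].
#' @return largest eigenvalue modulus of the companion matrix.
#' @export
mvar_spectral_radius <- function(model) {
  S <- model$n_channels
  p <- model$order
  comp <- matrix(0, S * p, S * p)
  comp[1:S, ] <- do.call(cbind, model$coeffs)
  if (p > 1) comp[(S + 1):(S * p), 1:(S * (p - 1))] <- diag(S * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' @rdname mvar_spectral_radius
#' @export
is_stable <- function(model) mvar_spectral_radius(model) < 1

#' Simulate a stationary MVAR process
#'
#' Iterates the autoregression from a zero initial state with Gaussian
#' innovations, discarding an initial burn-in so the retained samples are
#' (approximately) draws from the stationary distribution. The output plays
#' the role of a multichannel EEG recording.
#'
#' @param model a stable [mvar_model()].
#' @param n_samples number of samples to return (after burn-in).
#' @param burn_in samples discarded from the zero start; default 1000.
#' @param seed integer seed; the draw is a pure function of
#'   `(model, n_samples, burn_in, seed)`.
#' @param fs sampling rate attached to the returned recording (Hz).
#' @param channel_labels optional channel names; defaults to `ch1...chS`.
#' @param subject_id,class_label provenance carried on the recording.
#'
#' @return an [eeg_recording()] whose `data` is `S x n_samples`.
#' @export
simulate_mvar <- function(model, n_samples, burn_in = 1000, seed = 1,
                          fs = 256, channel_labels = NULL,
                          subject_id = "sim", class_label = NA_character_) {
  validate_mvar(model)
  stopifnot(n_samples >= 1, burn_in >= 0)
  S <- model$n_channels
  p <- model$order
  total <- n_samples + burn_in
  L <- t(chol(model$noise_cov))
  eps <- withr::with_seed(seed,
    L %*% matrix(stats::rnorm(S * total), S, total))
  y <- matrix(0, S, total + p)  # p leading zero columns as initial state
  C <- model$coeffs
  for (t in seq_len(total)) {
    acc <- eps[, t]
    for (k in seq_len(p)) acc <- acc + C[[k]] %*% y[, t + p - k]
    y[, t + p] <- acc
  }
  out <- y[, (p + burn_in + 1):(p + total), drop = FALSE]
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(S))
  eeg_recording(out, fs = fs, channel_labels = channel_labels,
                subject_id = subject_id, class_label = class_label)
}

#' Spectral coefficient matrix of an MVAR model
#'
#' Returns `A(w) = I - sum_k C_k exp(-i w k)`, the frequency-domain
#' coefficient matrix whose columns PDC normalizes over. At `w = 0` the
#' matrix is real; for a model with no dynamics it is the identity at
#' every frequency.
#'
#' @param model an [mvar_model()] (or a plain list with `coeffs`).
#' @param omega_grid angular frequencies in `[0, pi]` (radians/sample).
#' @return object of class `spectral_coeffs`: list with `omega_grid` and
#'   `A_bar`, a list of complex `S x S` matrices (one per grid point).
#' @export
spectral_transform <- function(model, omega_grid) {
  if (length(omega_grid) == 0) stop("omega_grid must be non-empty")
  if (any(omega_grid < 0 | omega_grid > pi))
    stop("omega values must lie in [0, pi]")
  S <- nrow(model$coeffs[[1]])
  A <- lapply(omega_grid, function(w) {
    Ab <- diag(S) + 0i
    for (k in seq_along(model$coeffs))
      Ab <- Ab - model$coeffs[[k]] * exp(-1i * w * k)
    Ab
  })
  structure(list(omega_grid = omega_grid, A_bar = A, n_channels = S),
            class = "spectral_coeffs")
}

#' Squared partial directed coherence at given frequencies
#'
#' For each frequency, entry `(v, w)` is
#' `|A_vw(w)|^2 / sum_v' |A_v'w(w)|^2`: the share of source channel `w`'s
#' outgoing influence directed at target `v`. Each column sums to exactly 1,
#' and a structurally absent coupling (`c_vw(k) = 0` for all lags, `v != w`)
#' gives exactly 0 — the Granger-nullity property.
#'
#' @param spec a `spectral_coeffs` object from [spectral_transform()].
#' @param squared if `FALSE` return magnitude PDC `|psi|` instead of the
#'   default squared form.
#' @return list of `S x S` real matrices in `[0, 1]`, one per frequency.
#' @export
pdc <- function(spec, squared = TRUE) {
  stopifnot(inherits(spec, "spectral_coeffs"))
  lapply(spec$A_bar, function(Ab) {
    num <- Mod(Ab)^2
    den <- colSums(num)
    if (any(den == 0)) stop("degenerate spectral matrix: zero column norm")
    out <- sweep(num, 2, den, "/")
    if (!squared) out <- sqrt(out)
    out
  })
}

#' Ground-truth PDC from known MVAR coefficients
#'
#' Computes squared PDC directly from a model's true coefficient matrices at
#' one angular frequency. This is the oracle against which segment-level
#' estimates ([band_pdcam()] on fitted models) are validated.
#'
#' @param model a stable [mvar_model()].
#' @param omega angular frequency in `[0, pi]`.
#' @inheritParams pdc
#' @return `S x S` matrix of reals in `[0, 1]`.
#' @export
#' @examples
#' m <- mvar_model(list(matrix(c(0.5, 0.4, 0, 0.5), 2, 2)))
#' analytic_pdc(m, 0)[2, 1]  # 0.16 / 0.41
analytic_pdc <- function(model, omega, squared = TRUE) {
  validate_mvar(model)
  stopifnot(length(omega) == 1)
  pdc(spectral_transform(model, omega), squared = squared)[[1]]
}

#' Band-averaged ground-truth PDC
#'
#' Averages [analytic_pdc()] over `k_per_band` frequencies inside each band of
#' the analysis grid — the exact counterpart of what [band_pdcam()] computes
#' from an estimated model.
#'
#' @inheritParams analytic_pdc
#' @param fs sampling rate in Hz used to convert band edges to radians.
#' @param bands integer band indices (subset of 1..64 by default).
#' @param k_per_band frequencies averaged per band.
#' @return `length(bands) x S x S` array.
#' @export
analytic_band_pdc <- function(model, fs = 256, bands = 1:64, k_per_band = 4) {
  band_pdc_core(model, fs = fs, bands = bands, k_per_band = k_per_band)
}

#' Random stable MVAR model
#'
#' Draws i.i.d. Gaussian coefficient entries and shrinks all lags
#' geometrically until the companion spectral radius is below `radius`.
#' Used throughout the test suite as a source of arbitrary stationary
#' processes.
#'
#' @param n_channels,order model dimensions.
#' @param sd coefficient scale before shrinking.
#' @param radius target upper bound on the spectral radius.
#' @param seed integer seed.
#' @return a stable [mvar_model()].
#' @export
random_stable_mvar <- function(n_channels = 5, order = 3, sd = 0.3,
                               radius = 0.95, seed = 1) {
  coeffs <- withr::with_seed(seed, lapply(seq_len(order), function(k)
    matrix(stats::rnorm(n_channels^2, sd = sd / k), n_channels)))
  repeat {
    m <- structure(list(n_channels = n_channels, order = order,
                        coeffs = coeffs, noise_cov = diag(n_channels)),
                   class = "mvar_model")
    if (mvar_spectral_radius(m) < radius) return(m)
    coeffs <- lapply(coeffs, function(C) C * 0.9)
  }
}
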