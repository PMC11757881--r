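#' Default 19-channel MVAR backbone
#'
#' A sparse order-3 backbone shared by both synthetic cohorts: every channel
#' has self-dynamics 0.4 / -0.15 / 0.05 at lags 1..3, plus a seeded sparse
#' set of random off-diagonal lag-1 couplings. If the random graph makes the
#' process non-stationary the couplings are shrunk geometrically until the
#' companion spectral radius drops below 1.
#'
#' @param n_channels number of channels (default 19, the 10-20 montage).
#' @param n_couplings number of random directed couplings.
#' @param coupling coupling magnitude (sign randomized).
#' @param self_coeffs per-lag self-coefficients; their length sets the order.
#' @param seed seed for the random coupling graph.
#' @return a stable [mvar_model()].
#' @export
default_backbone <- function(n_channels = 19, n_couplings = 24,
                             coupling = 0.12,
                             self_coeffs = c(0.4, -0.15, 0.05), seed = 101) {
  p <- length(self_coeffs)
  coeffs <- lapply(self_coeffs, function(a) diag(a, n_channels))
  pairs <- withr::with_seed(seed, {
    off <- which(diag(n_channels) == 0)
    idx <- sample(off, n_couplings)
    sgn <- sample(c(-1, 1), n_couplings, replace = TRUE)
    list(idx = idx, sgn = sgn)
  })
  g <- coupling
  repeat {
    C1 <- coeffs[[1]]
    C1[pairs$idx] <- g * pairs$sgn
    m <- structure(list(n_channels = n_channels, order = p,
                        coeffs = c(list(C1), coeffs[-1]),
                        noise_cov = diag(n_channels)),
                   class = "mvar_model")
    if (is_stable(m)) return(m)
    g <- g * 0.8
  }
}

#' Pad an MVAR model with zero coefficient matrices to a higher order
#' @param model an [mvar_model()].
#' @param order target order (>= current order).
#' @return an equivalent model of the requested order.
#' @export
pad_order <- function(model, order) {
  stopifnot(order >= model$order)
  S <- model$n_channels
  extra <- replicate(order - model$order, matrix(0, S, S), simplify = FALSE)
  mvar_model(c(model$coeffs, extra), model$noise_cov)
}

#' Class-effect coupling entries localized to the gamma bands
#'
#' Builds, for each requested directed pair, a 5-lag coupling whose frequency
#' response is a symmetric FIR band-pass with zeros placed in the low/mid
#' bands, so the added influence (and hence the between-class PDC difference)
#' concentrates in the upper (gamma) bands of the 64-band grid. The amplitude
#' at angular frequency `w` is
#' `strength * (cos w - cos z1)(cos w - cos z2)`, with zeros `z1`, `z2`
#' (radians/sample) defaulting to 0 (suppressing the slow delta/theta end)
#' and 1.1 (suppressing beta just below the gamma range).
#'
#' @param pairs two-column matrix (target `v`, source `w`) of directed pairs.
#' @param strength overall gain of the coupling filter.
#' @param zeros length-2 angular frequencies where the response vanishes.
#' @return data.frame with columns `target`, `source`, `lag`, `delta` —
#'   the `class_effect` format of [cohort_config()].
#' @export
gamma_band_effect <- function(pairs = cbind(c(7, 8, 4), c(5, 6, 3)),
                              strength = 1, zeros = c(0, 1.1)) {
  pairs <- matrix(pairs, ncol = 2)
  x1 <- cos(zeros[1]); x2 <- cos(zeros[2])
  # (cos w - x1)(cos w - x2) expanded into cos(0), cos(w), cos(2w) terms,
  # realized as the symmetric 5-tap filter [a2 a1 b a1 a2] centered at lag 3
  b <- strength * (0.5 + x1 * x2)
  a1 <- strength * (-(x1 + x2) / 2)
  a2 <- strength * 0.25
  taps <- c(a2, a1, b, a1, a2)
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    data.frame(target = pairs[i, 1], source = pairs[i, 2],
               lag = 1:5, delta = taps)))
}

#' Apply class-effect deltas to a model's coefficients
#' @param model an [mvar_model()].
#' @param effect data.frame with `target`, `source`, `lag`, `delta`.
#' @param check validate (incl. stability) the perturbed model.
#' @return perturbed [mvar_model()].
#' @export
apply_class_effect <- function(model, effect, check = TRUE) {
  if (is.null(effect) || nrow(effect) == 0) return(model)
  if (max(effect$lag) > model$order)
    model <- pad_order(model, max(effect$lag))
  coeffs <- model$coeffs
  for (i in seq_len(nrow(effect)))
    coeffs[[effect$lag[i]]][effect$target[i], effect$source[i]] <-
      coeffs[[effect$lag[i]]][effect$target[i], effect$source[i]] + effect$delta[i]
  mvar_model(coeffs, model$noise_cov, check = check)
}

#' Configuration of a two-class synthetic EEG cohort
#'
#' Defaults mirror the emulated study conditions: 35 subjects per class,
#' 5-minute recordings at 256 Hz on the 19-channel 10-20 montage, a shared
#' sparse backbone, a gamma-band-localized coupling effect added to the
#' AUD-like class, and mild per-subject coupling jitter.
#'
#' @param n_subjects_per_class subjects in each class.
#' @param duration_s recording length, seconds; with `fs` must give at least
#'   one whole 2-s segment.
#' @param fs sampling rate, Hz.
#' @param base_model shared backbone [mvar_model()].
#' @param class_effect data.frame (`target`, `source`, `lag`, `delta`) added
#'   to AUD-like subjects; `NULL` or empty for a null cohort.
#' @param subject_jitter_sd SD of per-subject Gaussian jitter applied to the
#'   class-effect couplings and the lag-1 self-terms.
#' @param seed master seed; all per-subject seeds derive from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_class = 35, duration_s = 300,
                          fs = 256,
                          base_model = default_backbone(),
                          class_effect = gamma_band_effect(),
                          subject_jitter_sd = 0.02, seed = 20) {
  stopifnot(n_subjects_per_class >= 1, duration_s > 0, fs > 0,
            subject_jitter_sd >= 0)
  if (floor(duration_s / 2) < 1)
    stop("duration_s and fs must allow at least one 2-s segment")
  if (!is.null(class_effect) && nrow(class_effect) > 0)
    apply_class_effect(base_model, class_effect)  # errors if unstable
  structure(list(n_subjects_per_class = n_subjects_per_class,
                 duration_s = duration_s, fs = fs, base_model = base_model,
                 class_effect = class_effect,
                 subject_jitter_sd = subject_jitter_sd, seed = seed),
            class = "cohort_config")
}

# deterministic per-subject seed stream, kept below 2^31
derive_seed <- function(seed, i, salt = 0) {
  as.integer((as.numeric(seed) * 10007 + i * 7919 + salt * 104729) %% 2147483629)
}

# jitter the designated coupling entries; retry on instability
jitter_model <- function(model, effect, sd, seed, max_attempts = 20) {
  if (sd == 0) return(model)
  entries <- unique(rbind(
    if (!is.null(effect) && nrow(effect) > 0)
      effect[, c("target", "source", "lag")]
    else NULL,
    data.frame(target = seq_len(model$n_channels),
               source = seq_len(model$n_channels), lag = 1)))
  for (attempt in seq_len(max_attempts)) {
    dz <- withr::with_seed(derive_seed(seed, attempt, salt = 3),
                           stats::rnorm(nrow(entries), sd = sd))
    coeffs <- model$coeffs
    for (i in seq_len(nrow(entries)))
      coeffs[[entries$lag[i]]][entries$target[i], entries$source[i]] <-
        coeffs[[entries$lag[i]]][entries$target[i], entries$source[i]] + dz[i]
    cand <- structure(list(n_channels = model$n_channels, order = model$order,
                           coeffs = coeffs, noise_cov = model$noise_cov),
                      class = "mvar_model")
    if (is_stable(cand)) return(cand)
  }
  stop("subject jitter destabilized the model after ", max_attempts,
       " attempts")
}

#' Generate a labelled two-class synthetic cohort
#'
#' AUD-like subjects are simulated from the backbone plus the class effect
#' plus per-subject jitter; control-like subjects from the backbone plus
#' jitter only. Every subject's jitter and innovation seeds derive
#' deterministically from `config$seed`, so the same config reproduces the
#' same cohort bit for bit.
#'
#' @param config a [cohort_config()].
#' @return list with `recordings` (list of [eeg_recording()]), `models`
#'   (per-subject ground-truth [mvar_model()]s), and `manifest`
#'   (data.frame: subject_id, class_label, seed).
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects_per_class
  n_samples <- round(config$duration_s * config$fs)
  base_A <- apply_class_effect(config$base_model, config$class_effect)
  base_B <- if (!is.null(config$class_effect) &&
                nrow(config$class_effect %||% data.frame()) > 0 &&
                max(config$class_effect$lag) > config$base_model$order)
    pad_order(config$base_model, max(config$class_effect$lag))
  else config$base_model
  recordings <- vector("list", 2 * n)
  models <- vector("list", 2 * n)
  ids <- character(2 * n)
  classes <- character(2 * n)
  seeds <- integer(2 * n)
  for (i in seq_len(2 * n)) {
    is_aud <- i <= n
    ids[i] <- sprintf("%s%02d", if (is_aud) "aud" else "ctl",
                      if (is_aud) i else i - n)
    classes[i] <- if (is_aud) "aud" else "control"
    sseed <- derive_seed(config$seed, i)
    seeds[i] <- sseed
    m <- tryCatch(
      jitter_model(if (is_aud) base_A else base_B, config$class_effect,
                   config$subject_jitter_sd, sseed),
      error = function(e) stop("subject ", ids[i], ": ", conditionMessage(e)))
    models[[i]] <- m
    recordings[[i]] <- simulate_mvar(
      m, n_samples = n_samples, burn_in = 1000,
      seed = derive_seed(config$seed, i, salt = 7), fs = config$fs,
      channel_labels = montage_1020()[seq_len(m$n_channels)],
      subject_id = ids[i], class_label = classes[i])
  }
  list(recordings = recordings, models = models,
       manifest = data.frame(subject_id = ids, class_label = classes,
                             seed = seeds, stringsAsFactors = FALSE))
}

#' Segment a whole cohort
#'
#' Convenience wrapper: [segment_recording()] each recording (optionally
#' after [reject_segments()]) and concatenate.
#'
#' @param cohort result of [make_cohort()] (or any list of recordings).
#' @param window_s segment length, seconds.
#' @param amplitude_limit optional rejection threshold (off by default, as
#'   synthetic recordings contain no artifacts).
#' @return flat list of `eeg_segment`.
#' @export
segment_cohort <- function(cohort, window_s = 2, amplitude_limit = Inf) {
  recs <- if (!is.null(cohort$recordings)) cohort$recordings else cohort
  segs <- unlist(lapply(recs, segment_recording, window_s = window_s),
                 recursive = FALSE)
  if (is.finite(amplitude_limit))
    segs <- reject_segments(segs, amplitude_limit)
  segs
}
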