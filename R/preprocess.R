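#' Multichannel EEG recording
#'
#' Lightweight container: a channels-by-samples numeric matrix plus sampling
#' rate, amplitude unit and provenance. Channel labels follow the 10-20
#' montage for cohort data ([montage_1020()]), but any unique labels are
#' accepted.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate, Hz.
#' @param channel_labels unique channel names, one per row.
#' @param unit amplitude unit, `"uV"` or `"nV"`.
#' @param subject_id subject identifier.
#' @param class_label optional cohort label (`"aud"` / `"control"` or `NA`).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          unit = "uV", subject_id = "unknown",
                          class_label = NA_character_) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must equal the number of rows")
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  if (!unit %in% c("uV", "nV")) stop("unknown amplitude unit: ", unit)
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 unit = unit, subject_id = subject_id,
                 class_label = class_label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording '%s': %d channels x %d samples @ %g Hz (%s)%s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs, x$unit,
              if (is.na(x$class_label)) "" else paste0(", class ", x$class_label)))
  invisible(x)
}

#' Standard 19-electrode 10-20 montage labels
#'
#' Order fixed to the convention used throughout the package: the 18 network
#' nodes first, then the Cz reference last.
#' @return character vector of length 19.
#' @export
montage_1020 <- function() {
  c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "FZ", "PZ", "CZ")
}

#' Resample and rescale a recording to the common representation
#'
#' Downsamples to `target_fs` with a polyphase anti-aliasing resampler
#' (exact rational conversion, e.g. 500 -> 256 Hz is 64/125) and converts
#' nanovolt amplitudes to microvolts. Recordings already at the target rate
#' and unit pass through unchanged; upsampling is refused.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate, Hz (default 256).
#' @param target_unit target unit (only `"uV"` supported).
#' @return standardized [eeg_recording()].
#' @export
standardize <- function(rec, target_fs = 256, target_unit = "uV") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_unit != "uV") stop("target_unit must be 'uV'")
  if (rec$fs < target_fs)
    stop("refusing to upsample: recording at ", rec$fs, " Hz < target ",
         target_fs, " Hz")
  data <- rec$data
  if (rec$unit == "nV") data <- data * 1e-3
  if (rec$fs > target_fs) {
    frac <- rational_ratio(target_fs / rec$fs)
    data <- t(apply(data, 1, resample_poly, p = frac[1], q = frac[2]))
  }
  eeg_recording(data, fs = target_fs, channel_labels = rec$channel_labels,
                unit = "uV", subject_id = rec$subject_id,
                class_label = rec$class_label)
}

# smallest integer p/q with p/q == r (within 1e-9), q bounded
rational_ratio <- function(r, max_q = 10000) {
  for (q in seq_len(max_q)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express resampling ratio ", r, " as a small rational")
}

# polyphase rational resampling by p/q: zero-stuff, long windowed-sinc
# anti-aliasing FIR (flat passband), decimate; group delay compensated
resample_poly <- function(x, p, q) {
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, n * p, by = p)] <- x
  half <- 10 * max(p, q)
  h <- p * signal::fir1(2 * half, 1 / max(p, q), "low")
  y <- signal::fftfilt(h, c(up, numeric(half)))
  y[seq(half + 1, half + n * p, by = q)]
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase filtering per channel: a 4th-order Butterworth band-pass
#' (default 0.1-70 Hz) applied forward-backward, followed by a second-order
#' IIR notch (default 50 Hz mains, quality factor 30), also zero-phase.
#' Output length equals input length.
#'
#' @param rec an [eeg_recording()] at 256 Hz.
#' @param band length-2 pass band in Hz.
#' @param notch notch center frequency in Hz; `NULL` disables.
#' @param notch_q notch quality factor (center / -3 dB bandwidth).
#' @param butter_order Butterworth order of the underlying one-pass design.
#' @return filtered [eeg_recording()].
#' @export
filter_signal <- function(rec, band = c(0.1, 70), notch = 50, notch_q = 30,
                          butter_order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (any(band >= nyq)) stop("band edges must be below the Nyquist frequency ",
                             nyq, " Hz")
  bp <- signal::butter(butter_order, band / nyq, type = "pass")
  data <- t(apply(rec$data, 1, function(x)
    signal::filtfilt(bp, x)))
  if (!is.null(notch)) {
    if (notch >= nyq) stop("notch frequency must be below Nyquist")
    nf <- biquad_notch(notch, rec$fs, notch_q)
    data <- t(apply(data, 1, function(x)
      signal::filtfilt(nf$b, nf$a, x)))
  }
  eeg_recording(data, fs = rec$fs, channel_labels = rec$channel_labels,
                unit = rec$unit, subject_id = rec$subject_id,
                class_label = rec$class_label)
}

# RBJ biquad notch at f0 Hz; Q = f0 / bandwidth
biquad_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Cut a recording into contiguous analysis segments
#'
#' Non-overlapping windows of `window_s` seconds in temporal order; a
#' trailing remainder shorter than one window is discarded. A 5-minute
#' recording at 256 Hz yields 150 two-second segments of 512 samples.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds (default 2).
#' @return list of `eeg_segment` objects (possibly empty, with a warning).
#' @export
segment_recording <- function(rec, window_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0)
  L <- round(window_s * rec$fs)
  n_seg <- floor(ncol(rec$data) / L)
  if (n_seg == 0) {
    warning("recording '", rec$subject_id, "' shorter than one window: ",
            "0 segments")
    return(list())
  }
  lapply(seq_len(n_seg), function(i) {
    structure(list(
      data = rec$data[, ((i - 1) * L + 1):(i * L), drop = FALSE],
      fs = rec$fs, index = i, channel_labels = rec$channel_labels,
      subject_id = rec$subject_id, class_label = rec$class_label),
      class = "eeg_segment")
  })
}

#' Drop segments exceeding an amplitude limit
#'
#' Stand-in for manual artifact screening: any segment whose maximum absolute
#' amplitude exceeds `amplitude_limit` (microvolts) is removed; order is
#' preserved. Synthetic cohorts are typically clean, so the default pipeline
#' leaves this off.
#'
#' @param segments list of `eeg_segment`.
#' @param amplitude_limit positive limit in the data's units; `Inf` keeps all.
#' @return filtered list.
#' @export
reject_segments <- function(segments, amplitude_limit = 100) {
  stopifnot(amplitude_limit > 0)
  Filter(function(s) max(abs(s$data)) <= amplitude_limit, segments)
}
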