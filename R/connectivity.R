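#' The 64-band analysis frequency grid
#'
#' The analysis range 0.1-70 Hz is tiled by 64 equal bands of width
#' (70 - 0.1)/64 ~ 1.092 Hz; band `b` covers
#' `[0.1 + (b-1) d, 0.1 + b d)` Hz.
#'
#' @param bands integer band indices in 1..64.
#' @param f_lo,f_hi range endpoints in Hz.
#' @param n_bands number of bands tiling the range.
#' @return numeric matrix with columns `lo`, `hi` (one row per requested band).
#' @export
band_edges <- function(bands = 1:64, f_lo = 0.1, f_hi = 70, n_bands = 64) {
  if (any(bands < 1 | bands > n_bands)) stop("band index out of range 1..", n_bands)
  d <- (f_hi - f_lo) / n_bands
  cbind(lo = f_lo + (bands - 1) * d, hi = f_lo + bands * d)
}

#' @rdname band_edges
#' @export
band_width <- function(f_lo = 0.1, f_hi = 70, n_bands = 64) (f_hi - f_lo) / n_bands

# shared by analytic_band_pdc() and band_pdcam(): mean squared PDC over
# k_per_band equally spaced frequencies (sub-interval midpoints) per band
band_pdc_core <- function(model, fs, bands, k_per_band, squared = TRUE) {
  edges <- band_edges(bands)
  if (max(edges[, "hi"]) >= fs / 2)
    stop("band upper edge reaches the Nyquist frequency ", fs / 2, " Hz")
  S <- nrow(model$coeffs[[1]])
  out <- array(NA_real_, c(length(bands), S, S))
  for (i in seq_along(bands)) {
    f <- edges[i, "lo"] + (seq_len(k_per_band) - 0.5) *
      (edges[i, "hi"] - edges[i, "lo"]) / k_per_band
    mats <- pdc(spectral_transform(model, 2 * pi * f / fs), squared = squared)
    out[i, , ] <- Reduce(`+`, mats) / length(mats)
  }
  out
}

#' Fit an MVAR model to a segment by least squares
#'
#' Each channel at time `t` is regressed on the `order` previous samples of
#' every retained channel (ordinary least squares, shared regressor matrix).
#' With `order = "auto"` the order minimizing the multivariate BIC
#' `log det(Sigma_hat) + log(n) * order * S^2 / n` over `1..max_order` is
#' selected. The reference electrode (default Cz) is dropped before fitting,
#' so a 19-channel segment yields an 18-node model.
#'
#' @param seg an `eeg_segment`, [eeg_recording()], or channels-by-samples
#'   matrix.
#' @param order positive integer, or `"auto"` for BIC selection.
#' @param exclude electrode name dropped before fitting; `NULL` keeps all
#'   channels (and is the default for unlabelled matrices).
#' @param max_order upper end of the `"auto"` search.
#' @return an [mvar_model()] (not re-checked for stability: a finite-sample
#'   fit may sit near the unit circle) with attribute `"bic"` when `"auto"`.
#' @export
fit_mvar <- function(seg, order = "auto", exclude = "CZ", max_order = 20) {
  if (inherits(seg, c("eeg_segment", "eeg_recording"))) {
    Y <- seg$data
    labels <- seg$channel_labels
    who <- paste0("subject ", seg$subject_id,
                  if (!is.null(seg$index)) paste0(" segment ", seg$index) else "")
  } else {
    Y <- as.matrix(seg)
    labels <- rownames(Y)
    who <- "matrix input"
  }
  if (!is.null(exclude) && !is.null(labels)) {
    if (!exclude %in% labels)
      stop("excluded electrode '", exclude, "' not present in ", who)
    keep <- labels != exclude
    Y <- Y[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  S <- nrow(Y)
  N <- ncol(Y)
  fit_at <- function(p) {
    if (N < (p + 1) * S)
      stop("segment too short for order ", p, " with ", S, " channels (", who, ")")
    n_eff <- N - p
    X <- matrix(NA_real_, n_eff, S * p)
    for (k in seq_len(p))
      X[, ((k - 1) * S + 1):(k * S)] <- t(Y[, (p - k + 1):(N - k), drop = FALSE])
    Z <- t(Y[, (p + 1):N, drop = FALSE])
    qx <- qr(X)
    if (qx$rank < ncol(X))
      stop("rank-deficient regressor matrix while fitting ", who)
    B <- qr.coef(qx, Z)                       # (S*p) x S
    res <- Z - X %*% B
    sigma_ml <- crossprod(res) / n_eff
    coeffs <- lapply(seq_len(p), function(k)
      t(B[((k - 1) * S + 1):(k * S), , drop = FALSE]))
    list(coeffs = coeffs, sigma = sigma_ml, n_eff = n_eff,
         bic = determinant(sigma_ml, logarithm = TRUE)$modulus[1] +
           log(n_eff) * p * S^2 / n_eff)
  }
  if (identical(order, "auto")) {
    fits <- lapply(seq_len(max_order), fit_at)
    bics <- vapply(fits, `[[`, numeric(1), "bic")
    best <- which.min(bics)
    f <- fits[[best]]
  } else {
    stopifnot(is.numeric(order), order >= 1)
    f <- fit_at(as.integer(order))
  }
  # symmetrize against numerical asymmetry; jitter a non-PD residual cov
  sig <- (f$sigma + t(f$sigma)) / 2
  m <- structure(list(n_channels = S, order = length(f$coeffs),
                      coeffs = f$coeffs, noise_cov = sig,
                      node_labels = labels),
                 class = "mvar_model")
  attr(m, "bic") <- f$bic
  m
}

#' PDC adjacency stack over the band grid
#'
#' Evaluates squared PDC of a (typically fitted) MVAR model at `k_per_band`
#' frequencies inside each requested band of the 64-band grid and averages
#' within bands, yielding a bands x S x S tensor of values in [0, 1] — the
#' per-segment PDC adjacency matrices (PDCaM).
#'
#' @param model an [mvar_model()], usually from [fit_mvar()].
#' @param fs sampling rate in Hz (band edges are interpreted against it).
#' @param bands band indices (default all 64).
#' @param k_per_band intra-band frequencies averaged (default 4).
#' @param squared squared PDC (default) or magnitude.
#' @param node_labels,subject_id,segment_index provenance.
#' @return object of class `pdc_stack`: `values` array, `band_edges`,
#'   `bands`, `node_labels`, `subject_id`, `segment_index`.
#' @export
band_pdcam <- function(model, fs = 256, bands = 1:64, k_per_band = 4,
                       squared = TRUE, node_labels = model$node_labels,
                       subject_id = NA_character_, segment_index = NA_integer_) {
  vals <- band_pdc_core(model, fs = fs, bands = bands,
                        k_per_band = k_per_band, squared = squared)
  if (is.null(node_labels)) node_labels <- paste0("ch", seq_len(model$n_channels))
  structure(list(values = vals, band_edges = band_edges(bands), bands = bands,
                 node_labels = node_labels, subject_id = subject_id,
                 segment_index = segment_index),
            class = "pdc_stack")
}

#' @export
print.pdc_stack <- function(x, ...) {
  cat(sprintf("PDC adjacency stack: %d bands x %d x %d nodes\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}

#' Extract one band's adjacency matrix from a stack
#' @param stack a `pdc_stack`.
#' @param band band index (must be among `stack$bands`).
#' @return S x S matrix (target `v` = row, source `w` = column).
#' @export
pdcam_matrix <- function(stack, band) {
  i <- match(band, stack$bands)
  if (is.na(i)) stop("band ", band, " not present in this stack")
  m <- stack$values[i, , ]
  dimnames(m) <- list(stack$node_labels, stack$node_labels)
  m
}

#' Flatten a band's adjacency matrix to a feature vector
#'
#' Row-major (target-major) flattening: entry `(v, w)` lands at index
#' `(v - 1) * S + w`, so an 18 x 18 matrix becomes the 324-length feature
#' vector used for classification. [unvectorize()] inverts it exactly.
#'
#' @inheritParams pdcam_matrix
#' @return numeric vector of length `S^2`.
#' @export
vectorize <- function(stack, band) {
  m <- pdcam_matrix(stack, band)
  v <- as.vector(t(m))
  names(v) <- sprintf("f%03d", seq_along(v))
  v
}

#' @rdname vectorize
#' @param v a vector produced by [vectorize()].
#' @export
unvectorize <- function(v) {
  S <- sqrt(length(v))
  if (S != round(S)) stop("vector length is not a perfect square")
  matrix(v, S, S, byrow = TRUE)
}

#' Per-band feature tables for a cohort of segments
#'
#' Runs [fit_mvar()] + [band_pdcam()] on every segment and collects, for each
#' requested band, a segments x S^2 feature matrix, along with per-row
#' subject and class metadata — the input to feature selection and
#' classification.
#'
#' @param segments list of `eeg_segment` (e.g. from [segment_recording()]
#'   applied across a cohort).
#' @param bands band indices to tabulate.
#' @param order MVAR order policy passed to [fit_mvar()]; the package's
#'   reference analyses fix `order = 5` for reproducibility.
#' @param exclude reference electrode dropped before fitting.
#' @param fs,k_per_band passed to [band_pdcam()].
#' @return object of class `feature_set`: `tables` (named list of matrices,
#'   one per band), `meta` (data.frame: subject_id, class_label,
#'   segment_index), `bands`, `node_labels`.
#' @export
extract_features <- function(segments, bands = 1:64, order = 5,
                             exclude = "CZ", fs = 256, k_per_band = 4) {
  stopifnot(length(segments) >= 1)
  n <- length(segments)
  stacks <- vector("list", n)
  for (i in seq_len(n)) {
    m <- fit_mvar(segments[[i]], order = order, exclude = exclude)
    stacks[[i]] <- band_pdcam(m, fs = fs, bands = bands,
                              k_per_band = k_per_band,
                              subject_id = segments[[i]]$subject_id,
                              segment_index = segments[[i]]$index)
  }
  S <- length(stacks[[1]]$node_labels)
  tables <- lapply(bands, function(b) {
    t(vapply(stacks, function(st) as.vector(t(st$values[match(b, st$bands), , ])),
             numeric(S * S)))
  })
  names(tables) <- paste0("band", bands)
  for (b in seq_along(tables))
    colnames(tables[[b]]) <- sprintf("f%03d", seq_len(S * S))
  meta <- data.frame(
    subject_id = vapply(segments, `[[`, character(1), "subject_id"),
    class_label = vapply(segments, function(s)
      as.character(s$class_label %||% NA_character_), character(1)),
    segment_index = vapply(segments, function(s)
      as.integer(s$index %||% NA_integer_), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(tables = tables, meta = meta, bands = bands,
                 node_labels = stacks[[1]]$node_labels),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set: %d bands x %d segments x %d features\n",
              length(x$bands), nrow(x$meta), ncol(x$tables[[1]])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
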