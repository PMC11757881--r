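#' Brain-rhythm to band-index map
#'
#' The five conventional EEG rhythms partition the 64-band grid:
#' delta 1-6, theta 7-12, alpha 13-19, beta 20-47, gamma 48-64.
#' The ranges are disjoint and their union is exactly 1..64.
#'
#' @param rhythm one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @return integer vector of band indices.
#' @export
#' @examples
#' rhythm_bands("gamma")  # 48..64
rhythm_bands <- function(rhythm) {
  map <- list(delta = 1:6, theta = 7:12, alpha = 13:19,
              beta = 20:47, gamma = 48:64)
  if (!rhythm %in% names(map)) stop("unknown rhythm: ", rhythm)
  map[[rhythm]]
}

#' @rdname rhythm_bands
#' @export
rhythm_names <- function() c("delta", "theta", "alpha", "beta", "gamma")

#' Pool a connectivity's values across a band set
#'
#' Averages each connectivity over the set's bands, one pooled value per
#' segment — the observation unit fed to per-connectivity ANOVA when
#' selecting over a whole rhythm. Averaging (rather than stacking the
#' bands as extra rows) keeps one observation per segment, so the
#' segment-level F-test stays calibrated despite the strong correlation of
#' a connectivity's values across neighbouring bands.
#'
#' @param fset a `feature_set` from [extract_features()].
#' @param bands band indices (must all be present in `fset`).
#' @return list with `x` (segments x connectivities matrix of band means),
#'   `labels` (class per row), `subject_id` (per row).
#' @export
pool_band_values <- function(fset, bands) {
  key <- paste0("band", bands)
  missing <- setdiff(key, names(fset$tables))
  if (length(missing) > 0)
    stop("bands not present in feature set: ",
         paste(sub("band", "", missing), collapse = ", "))
  x <- Reduce(`+`, fset$tables[key]) / length(key)
  list(x = x, labels = fset$meta$class_label,
       subject_id = fset$meta$subject_id)
}

#' Per-connectivity ANOVA feature selection
#'
#' For each of the `S^2` connectivities a one-way two-group ANOVA F-test
#' compares segment-level values between the classes; connectivities with
#' raw `p < alpha` are kept (no multiple-testing correction — the selection
#' thresholds raw p-values). For two groups the F statistic equals the
#' square of the pooled two-sample t statistic; the implementation computes
#' it vectorised over columns. A zero-variance connectivity gets `p = 1` by
#' convention, with a warning.
#'
#' @param x observations x connectivities numeric matrix (segment-level
#'   values, possibly pooled across a rhythm's bands via
#'   [pool_band_values()]).
#' @param labels class label per row; exactly two classes, each with at
#'   least 2 rows.
#' @param alpha selection threshold on the raw p-value.
#' @return object of class `selection_mask`: `p_values`, `alpha`, `keep`
#'   (logical), `n_kept`.
#' @export
anova_select <- function(x, labels, alpha = 0.01) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2)
    stop("anova_select needs exactly two classes, got ", length(cls))
  i1 <- labels == cls[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  if (n1 < 2 || n2 < 2) stop("each class needs at least 2 rows")
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[!i1, , drop = FALSE])
  v1 <- colSums(sweep(x[i1, , drop = FALSE], 2, m1)^2)
  v2 <- colSums(sweep(x[!i1, , drop = FALSE], 2, m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)                # pooled variance
  Fstat <- (m1 - m2)^2 / (sp2 * (1 / n1 + 1 / n2))  # = t^2
  p <- stats::pf(Fstat, 1, n1 + n2 - 2, lower.tail = FALSE)
  degenerate <- sp2 == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance connectivities set to p = 1")
    p[degenerate] <- 1
  }
  structure(list(p_values = unname(p), alpha = alpha,
                 keep = unname(p < alpha), n_kept = sum(p < alpha)),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("Selection mask: %d / %d connectivities kept at alpha = %g\n",
              x$n_kept, length(x$keep), x$alpha))
  invisible(x)
}

#' Re-threshold an existing mask at a different alpha
#' @param mask a `selection_mask`.
#' @param alpha new threshold.
#' @return updated `selection_mask` (same p-values).
#' @export
rethreshold_mask <- function(mask, alpha) {
  structure(list(p_values = mask$p_values, alpha = alpha,
                 keep = mask$p_values < alpha,
                 n_kept = sum(mask$p_values < alpha)),
            class = "selection_mask")
}

#' Concatenate per-band feature vectors into a classification table
#'
#' Columns are the named bands' vectors side by side in ascending band
#' order; with a [selection_mask()] each band's vector is first filtered to
#' the kept connectivities (the same mask for every band), giving
#' `N_fb x l_f` columns for `N_fb` bands and `l_f` kept features.
#'
#' @param fset a `feature_set` from [extract_features()].
#' @param bands band indices to concatenate.
#' @param mask optional `selection_mask` applied to every band.
#' @return list with `x` (segments x `N_fb * l_f` matrix), `labels`,
#'   `subject_id`, `bands`, `l_f`.
#' @export
concat_bands <- function(fset, bands, mask = NULL) {
  bands <- sort(bands)
  key <- paste0("band", bands)
  missing <- setdiff(key, names(fset$tables))
  if (length(missing) > 0)
    stop("bands not present in feature set: ",
         paste(sub("band", "", missing), collapse = ", "))
  keep <- if (is.null(mask)) rep(TRUE, ncol(fset$tables[[key[1]]]))
          else mask$keep
  blocks <- lapply(key, function(k) fset$tables[[k]][, keep, drop = FALSE])
  x <- do.call(cbind, blocks)
  colnames(x) <- paste0(rep(key, each = sum(keep)), "_",
                        rep(sprintf("f%03d", which(keep)), length(key)))
  list(x = x, labels = fset$meta$class_label,
       subject_id = fset$meta$subject_id, bands = bands, l_f = sum(keep))
}

#' Serialize a selection mask to JSON
#'
#' Records electrode-pair names, p-values, alpha and the kept set, so a
#' selection can be re-applied or inspected outside R.
#'
#' @param mask a `selection_mask`.
#' @param node_labels electrode names defining the pair labels
#'   (target <- source, row-major order matching [vectorize()]).
#' @param path file to write; `NULL` returns the JSON string.
#' @export
write_mask_json <- function(mask, node_labels, path = NULL) {
  S <- length(node_labels)
  pairs <- paste0(rep(node_labels, each = S), "<-", rep(node_labels, S))
  obj <- list(alpha = mask$alpha, n_kept = mask$n_kept,
              connectivity = pairs, p_value = mask$p_values,
              keep = mask$keep)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
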