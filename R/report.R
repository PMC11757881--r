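#' t-SNE embedding of feature vectors
#'
#' Exact (non-tree-accelerated) t-distributed stochastic neighbour
#' embedding: per-point bandwidths calibrated to the target perplexity by
#' binary search, PCA initialization with small seeded jitter, early
#' exaggeration, and momentum gradient descent with adaptive gains. Suited
#' to the few hundred to few thousand segment vectors a cohort produces.
#'
#' @param x rows x features matrix.
#' @param dims embedding dimension (default 3, for the 3-D scatter).
#' @param perplexity effective neighbourhood size; rows must be at least
#'   `3 * perplexity + 1`.
#' @param max_iter gradient-descent iterations.
#' @param seed integer seed; the embedding is deterministic given it.
#' @return rows x `dims` coordinate matrix (all finite).
#' @export
tsne_embed <- function(x, dims = 3, perplexity = 30, max_iter = 300,
                       seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3 * perplexity + 1)
    stop("need at least 3 * perplexity + 1 = ", 3 * perplexity + 1,
         " rows, got ", n)
  # PCA to at most 50 dims for the input similarities
  xc <- scale(x, scale = FALSE)
  if (ncol(xc) > 50) {
    sv <- svd(xc, nu = 0, nv = 50)
    xc <- xc %*% sv$v
  }
  D <- as.matrix(stats::dist(xc))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else          { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  # PCA init + seeded jitter
  sv <- svd(xc, nu = dims, nv = 0)
  Y <- sv$u[, seq_len(dims), drop = FALSE]
  Y <- scale(Y, scale = apply(Y, 2, stats::sd) * 1e4)  # sd 1e-4 columns
  Y <- Y + withr::with_seed(seed, matrix(stats::rnorm(n * dims, sd = 1e-5),
                                         n, dims))
  exag <- 12; stop_exag <- 80
  eta <- 100; momentum <- 0.5
  dY <- matrix(0, n, dims); gains <- matrix(1, n, dims)
  Pe <- P * exag
  for (it in seq_len(max_iter)) {
    if (it == stop_exag + 1) Pe <- P
    if (it == 51) momentum <- 0.8
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- scale(Y, scale = FALSE)
  }
  stopifnot(all(is.finite(Y)))
  unname(Y[, , drop = FALSE])
}

#' 2-D layout coordinates of the 19-electrode 10-20 montage
#'
#' Approximate top-view scalp positions (nose up), used by the directed
#' connectivity diagram.
#' @return data.frame with `electrode`, `x`, `y`.
#' @export
electrode_layout <- function() {
  data.frame(
    electrode = montage_1020(),
    x = c(-0.31, 0.31, -0.42, 0.42, -0.55, 0.55, -0.42, 0.42, -0.31, 0.31,
          -0.74, 0.74, -0.92, 0.92, -0.74, 0.74, 0, 0, 0),
    y = c(0.95, 0.95, 0.5, 0.5, 0, 0, -0.5, -0.5, -0.95, -0.95,
          0.59, 0.59, 0, 0, -0.59, -0.59, 0.55, -0.55, 0))
}

#' Render the standard analysis figures and summary tables
#'
#' Writes, for whatever inputs are supplied: a segments x features colorplot
#' per subject, the per-band accuracy chart with its mean line, an
#' 18 x 18 p-value grid with sub-alpha cells highlighted, a directed-edge
#' diagram of significant connections (arrow from source to target), and a
#' machine-readable summary table (rhythm x alpha: l_f and accuracy).
#'
#' @param out_dir output directory (created if needed).
#' @param fset optional `feature_set` (colorplot; first band used).
#' @param sweep optional [per_band_sweep()] result (accuracy chart).
#' @param mask optional `selection_mask` (p-value grid + edge diagram).
#' @param node_labels electrode names for the grid/diagram.
#' @param summary_table optional data.frame written as `summary.csv`.
#' @return character vector of files written.
#' @export
render_outputs <- function(out_dir, fset = NULL, sweep = NULL, mask = NULL,
                           node_labels = NULL, summary_table = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  save_fig <- function(plot, name, w = 7, h = 5) {
    path <- file.path(out_dir, name)
    ggplot2::ggsave(path, plot, width = w, height = h, dpi = 120)
    written <<- c(written, path)
  }
  if (!is.null(fset)) {
    tb <- fset$tables[[1]]
    subj <- fset$meta$subject_id
    first <- subj == subj[1]
    df <- expand.grid(segment = seq_len(sum(first)), feature = seq_len(ncol(tb)))
    df$value <- as.vector(tb[first, , drop = FALSE])
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$segment,
                                          fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
      ggplot2::labs(title = paste("PDC feature colorplot:", subj[1]),
                    x = "connectivity feature", y = "segment")
    save_fig(p, "colorplot.png")
  }
  if (!is.null(sweep)) {
    acc <- sweep$accuracy
    p <- ggplot2::ggplot(acc, ggplot2::aes(.data$band, .data$accuracy_mean)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_hline(yintercept = sweep$mean_accuracy,
                          linetype = "dashed", colour = "red") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(title = "Per-band classification accuracy",
                    subtitle = sprintf("mean accuracy %.1f%%",
                                       100 * sweep$mean_accuracy),
                    x = "frequency band", y = "held-out accuracy")
    save_fig(p, "band_accuracy.png")
  }
  if (!is.null(mask)) {
    if (is.null(node_labels))
      node_labels <- montage_1020()[seq_len(sqrt(length(mask$p_values)))]
    S <- length(node_labels)
    grid <- expand.grid(source = seq_len(S), target = seq_len(S))
    # row-major vector order: index = (target - 1) * S + source
    idx <- (grid$target - 1) * S + grid$source
    grid$p <- mask$p_values[idx]
    grid$kept <- mask$keep[idx]
    p1 <- ggplot2::ggplot(grid, ggplot2::aes(.data$source, .data$target,
                                             fill = .data$p)) +
      ggplot2::geom_tile() +
      ggplot2::geom_tile(data = grid[grid$kept, ], fill = NA,
                         colour = "yellow", linewidth = 0.7) +
      ggplot2::scale_fill_viridis_c(direction = -1) +
      ggplot2::scale_x_continuous(breaks = seq_len(S), labels = node_labels) +
      ggplot2::scale_y_reverse(breaks = seq_len(S), labels = node_labels) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90)) +
      ggplot2::labs(title = sprintf(
        "Connectivity p-values (%d kept at alpha = %g)", mask$n_kept,
        mask$alpha), x = "source electrode", y = "target electrode")
    save_fig(p1, "pvalue_grid.png", w = 7, h = 6)
    lay <- electrode_layout()
    kept <- grid[grid$kept & grid$source != grid$target, ]
    if (nrow(kept) > 0) {
      kept$x0 <- lay$x[match(node_labels[kept$source], lay$electrode)]
      kept$y0 <- lay$y[match(node_labels[kept$source], lay$electrode)]
      kept$x1 <- lay$x[match(node_labels[kept$target], lay$electrode)]
      kept$y1 <- lay$y[match(node_labels[kept$target], lay$electrode)]
      p2 <- ggplot2::ggplot() +
        ggplot2::geom_segment(
          data = kept,
          ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                       yend = .data$y1),
          arrow = ggplot2::arrow(length = ggplot2::unit(5, "pt")),
          alpha = 0.4, colour = "firebrick") +
        ggplot2::geom_point(data = lay, ggplot2::aes(.data$x, .data$y),
                            size = 7, colour = "grey80") +
        ggplot2::geom_text(data = lay,
                           ggplot2::aes(.data$x, .data$y,
                                        label = .data$electrode), size = 2.5) +
        ggplot2::coord_equal() + ggplot2::theme_void() +
        ggplot2::labs(title = "Significant directed connections (source -> target)")
      save_fig(p2, "connectivity_arrows.png", w = 6, h = 6)
    }
  }
  if (!is.null(summary_table)) {
    path <- file.path(out_dir, "summary.csv")
    utils::write.csv(summary_table, path, row.names = FALSE)
    written <- c(written, path)
  }
  written
}

#' Pipeline configuration
#'
#' A fully serializable description of one end-to-end run: cohort
#' generation, preprocessing, connectivity extraction, per-band sweep,
#' rhythm-level ANOVA selection and reduced-feature classification.
#'
#' @param cohort a [cohort_config()].
#' @param filter apply the band-pass/notch filter chain to each recording.
#' @param amplitude_limit segment rejection threshold (microvolts;
#'   `Inf` = off, the synthetic default).
#' @param bands bands extracted and swept.
#' @param order MVAR order policy for [fit_mvar()].
#' @param rhythm rhythm used for the selection/reduction stage (its bands
#'   must be a subset of `bands`), or `NULL` to skip it.
#' @param alpha ANOVA selection threshold.
#' @param tune,budget per-band tuning policy for the sweep.
#' @param spec fixed [svm_spec()] when `tune = FALSE`.
#' @param split,k,repeats cross-validation policy.
#' @param seed master seed of the run.
#' @param out_dir where figures and the manifest are written.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), filter = TRUE,
                            amplitude_limit = Inf, bands = 1:64, order = 5,
                            rhythm = "gamma", alpha = 0.01, tune = TRUE,
                            budget = 30, spec = NULL, split = "segment",
                            k = 5, repeats = 5, seed = 1,
                            out_dir = tempfile("pdcnet_run_")) {
  if (!is.null(rhythm) && !all(rhythm_bands(rhythm) %in% bands))
    stop("rhythm '", rhythm, "' bands must be a subset of the extracted bands")
  structure(list(cohort = cohort, filter = filter,
                 amplitude_limit = amplitude_limit, bands = bands,
                 order = order, rhythm = rhythm, alpha = alpha, tune = tune,
                 budget = budget, spec = spec, split = split, k = k,
                 repeats = repeats, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

# hash of the run *structure*: everything except seed and output location,
# so manifests of two runs differing only in seed differ only in that field
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), c("out_dir", "seed"))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Synthetic cohort -> preprocessing -> per-segment MVAR + PDC adjacency
#' stacks -> per-band SVM sweep -> rhythm-level ANOVA selection and
#' reduced-feature classification -> figures and a JSON run manifest
#' (config hash, seeds, per-subject segment counts).
#'
#' @param config a [pipeline_config()].
#' @return list: `sweep`, `mask`, `full_report`, `reduced_report`,
#'   `manifest`, `files`, `fset`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "': ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("simulate", make_cohort(config$cohort))
  recs <- cohort$recordings
  if (config$filter)
    recs <- stage("preprocess", lapply(recs, function(r)
      filter_signal(standardize(r))))
  segs <- stage("segment",
                segment_cohort(recs, amplitude_limit = config$amplitude_limit))
  seg_counts <- table(vapply(segs, `[[`, character(1), "subject_id"))
  fset <- stage("connectivity",
                extract_features(segs, bands = config$bands,
                                 order = config$order,
                                 fs = config$cohort$fs))
  sweep <- stage("classify", per_band_sweep(
    fset, tune = config$tune, spec = config$spec, budget = config$budget,
    split = config$split, k = config$k, repeats = config$repeats,
    seed = config$seed))
  mask <- NULL; full_report <- NULL; reduced_report <- NULL
  if (!is.null(config$rhythm)) {
    rb <- rhythm_bands(config$rhythm)
    pooled <- stage("features", pool_band_values(fset, rb))
    mask <- stage("features",
                  anova_select(pooled$x, pooled$labels, config$alpha))
    fit_tbl <- function(m) {
      tb <- concat_bands(fset, rb, mask = m)
      sp <- if (config$tune)
        tune_svm(tb$x, tb$labels, budget = config$budget,
                 seed = derive_seed(config$seed, 600 + !is.null(m)))
      else config$spec
      evaluate_svm(tb$x, tb$labels, sp, split = config$split, k = config$k,
                   repeats = config$repeats, subject_id = tb$subject_id,
                   seed = derive_seed(config$seed, 700 + !is.null(m)))
    }
    full_report <- stage("classify", fit_tbl(NULL))
    reduced_report <- if (mask$n_kept >= 1) stage("classify", fit_tbl(mask))
  }
  manifest <- list(
    config_hash = config_hash(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("pdcnet")),
    n_subjects = length(cohort$recordings),
    segments_per_subject = as.list(seg_counts),
    bands = config$bands, order = config$order,
    rhythm = config$rhythm, alpha = config$alpha,
    split = config$split, k = config$k, repeats = config$repeats)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- render_outputs(config$out_dir, fset = fset, sweep = sweep,
                          mask = mask, node_labels = fset$node_labels)
  list(sweep = sweep, mask = mask, full_report = full_report,
       reduced_report = reduced_report, manifest = manifest,
       files = c(manifest_path, files), fset = fset)
}
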