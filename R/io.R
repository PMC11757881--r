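#' Write a cohort as per-subject delimited matrices plus a manifest
#'
#' Each subject's recording goes to `<subject_id>.tsv` (channels as columns,
#' one sample per row, tab-separated, header = channel labels); the cohort
#' manifest (`manifest.csv`) records subject ID, class, seed, sampling rate,
#' unit and the file path. [read_cohort()] inverts this exactly up to text
#' rounding.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @param digits significant digits written.
#' @return path of the manifest file.
#' @export
write_cohort <- function(cohort, dir, digits = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$fs <- vapply(cohort$recordings, `[[`, numeric(1), "fs")
  man$unit <- vapply(cohort$recordings, `[[`, character(1), "unit")
  man$file <- paste0(man$subject_id, ".tsv")
  for (i in seq_along(cohort$recordings)) {
    r <- cohort$recordings[[i]]
    utils::write.table(signif(t(r$data), digits),
                       file.path(dir, man$file[i]), sep = "\t",
                       row.names = FALSE, col.names = r$channel_labels,
                       quote = FALSE)
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  path
}

#' @rdname write_cohort
#' @param manifest_path path to a `manifest.csv` written by [write_cohort()].
#' @return `read_cohort`: list with `recordings` and `manifest`.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  recordings <- lapply(seq_len(nrow(man)), function(i) {
    m <- utils::read.table(file.path(dir, man$file[i]), header = TRUE,
                           sep = "\t", check.names = FALSE)
    eeg_recording(t(as.matrix(m)), fs = man$fs[i],
                  channel_labels = colnames(m), unit = man$unit[i],
                  subject_id = man$subject_id[i],
                  class_label = man$class_label[i])
  })
  list(recordings = recordings, manifest = man)
}

#' Write per-band feature tables as delimited text
#'
#' One row per segment-band: `subject_id`, `class_label`, `segment_index`,
#' `band`, then `f001..fNNN`.
#'
#' @param fset a `feature_set` from [extract_features()].
#' @param path output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fset, path) {
  rows <- lapply(seq_along(fset$bands), function(i) {
    cbind(fset$meta, band = fset$bands[i],
          as.data.frame(fset$tables[[i]]))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an evaluation report to JSON
#'
#' Counts, the four metrics, accuracy mean/sd, the ROC points, AUC and the
#' operating point, suitable for machine reading.
#'
#' @param report an `evaluation_report` from [evaluate_svm()].
#' @param path file to write; `NULL` returns the JSON string.
#' @export
write_report_json <- function(report, path = NULL) {
  obj <- list(
    counts = report[c("tp", "tn", "fp", "fn")],
    metrics = report[c("accuracy", "sensitivity", "specificity", "precision")],
    accuracy_mean = report$accuracy_mean, accuracy_sd = report$accuracy_sd,
    auc = report$auc,
    operating_point = as.list(report$operating_point),
    roc = report$roc,
    protocol = report[c("split", "k", "repeats", "positive")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
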