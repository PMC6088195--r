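#' Write a cohort to a directory of delimited-text matrices
#'
#' One TSV per recording and band (`sub-<s>_ses-<e>_band-<name>.tsv`,
#' samples x ROIs, with a header comment carrying fs and the band edges),
#' plus a JSON sidecar `ground_truth.json` with the planted labels,
#' transition rates and occupancies.
#'
#' @param cohort A [Cohort-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort@config
  for (s in seq_len(nSubjects(cohort))) for (e in seq_len(nSessions(cohort))) {
    for (b in seq_along(cfg$bands)) {
      bd <- cfg$bands[[b]]
      f <- file.path(dir, sprintf("sub-%d_ses-%d_band-%s.tsv", s, e, bd$name))
      con <- file(f, "w")
      writeLines(sprintf("# fs=%g f_low=%g f_high=%g", cfg$fs, bd$f_low, bd$f_high), con)
      write.table(signif(recordingMatrix(cohort, s, e, b), 8), con, sep = "\t",
                  row.names = FALSE, col.names = paste0("roi", seq_len(cfg$n_rois)))
      close(con)
    }
  }
  truth <- cohort@truth
  truth$config <- cfg[c("n_subjects", "n_sessions", "duration", "fs", "n_rois",
                        "state_count", "session_jitter", "noise_sd",
                        "segment_samples", "seed")]
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one recording matrix written by [writeCohort()]
#'
#' @param path Path to a recording TSV.
#' @return `samples x n_rois` matrix with attributes `fs`, `f_low`, `f_high`.
#' @export
readRecording <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- as.numeric(sub(".*=", "", strsplit(sub("^# ", "", hdr), " ")[[1]]))
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, comment.char = "#"))
  attr(m, "fs") <- meta[1]; attr(m, "f_low") <- meta[2]; attr(m, "f_high") <- meta[3]
  m
}

#' Write a connectivity graph as a square-matrix TSV
#'
#' @param W Weight matrix.
#' @param path Output file.
#' @param labels Optional node labels (default `roi1..roiN`).
#' @export
writeGraphTSV <- function(W, path, labels = paste0("roi", seq_len(nrow(W)))) {
  dimnames(W) <- list(labels, labels)
  write.table(signif(W, 10), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a graph written by [writeGraphTSV()]
#' @param path Path to the TSV.
#' @return Weight matrix.
#' @export
readGraphTSV <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                       check.names = FALSE))
}

#' Write a graph as a sparse edge-list TSV (node_i, node_j, weight)
#' @inheritParams writeGraphTSV
#' @export
writeEdgeListTSV <- function(W, path) {
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  df <- data.frame(node_i = ut[, 1], node_j = ut[, 2],
                   weight = signif(W[ut], 10))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a reliability report to JSON
#'
#' Numeric output uses full precision and a canonical field order, so a
#' fixed-seed rerun reproduces the file byte for byte.
#'
#' @param report A report from [runStudy()].
#' @param path Output file.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write per-ROI reliability tables as TSV
#'
#' Long-format table (roi_label, metric, band, estimator, r, p) across all
#' static nodal metrics of a report.
#'
#' @param report A report from [runStudy()].
#' @param path Output file.
#' @export
writeNodalReliabilityTSV <- function(report, path) {
  rows <- list()
  for (key in names(report$results)) {
    en <- report$results[[key]]
    if (is.null(en$nodal_reliability)) next
    for (metric in names(en$nodal_reliability)) {
      nr <- en$nodal_reliability[[metric]]
      rows[[length(rows) + 1L]] <- data.frame(
        roi_label = paste0("roi", seq_along(nr$r)), metric = metric,
        band = en$band, estimator = en$estimator,
        r = signif(nr$r, 10), p = signif(nr$p, 10))
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
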