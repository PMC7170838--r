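# Waveform tables: a plain CSV format (one row per measurement:
# eye_id, replicate_id, quality_index, s000..s399), the manufacturer-style
# quality filter, and triplicate averaging.

#' Construct a waveform set
#'
#' Container pairing per-measurement metadata with a traces matrix
#' (one row per measurement).
#'
#' @param meta data.frame with columns `eye_id`, `replicate_id`,
#'   `quality_index`.
#' @param traces Numeric matrix, `nrow(meta)` rows, one column per sample.
#' @return Object of class `waveform_set`.
#' @export
waveform_set <- function(meta, traces) {
  traces <- as.matrix(traces)
  stopifnot(is.data.frame(meta),
            all(c("eye_id", "replicate_id", "quality_index") %in% names(meta)),
            nrow(meta) == nrow(traces))
  if (any(!is.finite(traces))) stop("traces contain non-finite samples")
  if (any(!is.finite(meta$quality_index))) {
    stop("quality_index must be finite")
  }
  colnames(traces) <- sprintf("s%03d", seq_len(ncol(traces)) - 1)
  rownames(traces) <- NULL
  rownames(meta) <- NULL
  structure(list(meta = meta, traces = traces), class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("waveform_set: %d measurements of %d eyes, %d samples each\n",
              nrow(x$meta), length(unique(x$meta$eye_id)), ncol(x$traces)))
  invisible(x)
}

#' Number of measurements in a waveform set
#' @param ws A `waveform_set`.
#' @return Integer count.
#' @export
n_records <- function(ws) nrow(ws$meta)

#' Write a waveform table to CSV
#'
#' One row per measurement: `eye_id`, `replicate_id`, `quality_index`, then
#' one column per sample (`s000`, `s001`, ...). Comma-separated, UTF-8,
#' header row required.
#'
#' @param ws A [waveform_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_table <- function(ws, path) {
  stopifnot(inherits(ws, "waveform_set"))
  df <- cbind(ws$meta[c("eye_id", "replicate_id", "quality_index")],
              as.data.frame(ws$traces))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a waveform table from CSV
#'
#' Validates that every row carries exactly `trace_len` samples and that all
#' samples are finite; malformed rows are reported by row number.
#'
#' @param path CSV file written by [write_waveform_table()] (or compatible).
#' @param trace_len Declared trace length (default 400).
#' @return A [waveform_set()].
#' @export
read_waveform_table <- function(path, trace_len = 400) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  expected <- 3 + trace_len
  nf <- count.fields(path, sep = ",")
  bad <- which(nf != expected)
  bad <- setdiff(bad, 1L)  # header checked separately
  if (length(bad) > 0) {
    stop(sprintf(
      "parse error: row(s) %s have wrong field count (expected %d samples)",
      paste(bad - 1, collapse = ", "), trace_len))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "replicate_id", "quality_index")
  if (!all(need %in% names(df))) {
    stop("parse error: header must contain eye_id, replicate_id, quality_index")
  }
  traces <- as.matrix(df[setdiff(names(df), need)])
  storage.mode(traces) <- "double"
  if (ncol(traces) != trace_len) {
    stop(sprintf("parse error: %d sample columns found, expected %d",
                 ncol(traces), trace_len))
  }
  nonfin <- which(apply(!is.finite(traces), 1, any))
  if (length(nonfin) > 0) {
    stop("parse error: non-finite sample in row(s) ",
         paste(nonfin, collapse = ", "))
  }
  waveform_set(df[need], traces)
}

#' Filter measurements by quality index
#'
#' Keeps measurements whose quality index is strictly greater than the
#' threshold (the manufacturer recommendation is "higher than 7.5").
#' Preserves input order and reports the number removed.
#'
#' @param ws A [waveform_set()].
#' @param threshold Quality threshold (default 7.5); records with
#'   `quality_index > threshold` are kept.
#' @return Filtered `waveform_set`.
#' @export
filter_by_quality <- function(ws, threshold = 7.5) {
  stopifnot(inherits(ws, "waveform_set"), is.finite(threshold))
  keep <- ws$meta$quality_index > threshold
  removed <- sum(!keep)
  if (removed > 0) {
    message(sprintf("filter_by_quality: removed %d of %d measurements (QI <= %g)",
                    removed, length(keep), threshold))
  }
  waveform_set(ws$meta[keep, , drop = FALSE],
               ws$traces[keep, , drop = FALSE])
}

#' Average replicate measurements per eye
#'
#' Pointwise mean trace and mean quality index per eye; the averaged record
#' is marked with `replicate_id = 0`. Eye order follows first appearance.
#' Eyes listed in `expected_eyes` but absent from `ws` (e.g. all replicates
#' removed by the quality filter) are reported with a warning and listed in
#' the `dropped_eyes` attribute of the result.
#'
#' @param ws A [waveform_set()].
#' @param expected_eyes Optional character vector of eyes that should be
#'   present.
#' @return A `waveform_set` with one record per eye.
#' @export
average_replicates <- function(ws, expected_eyes = NULL) {
  stopifnot(inherits(ws, "waveform_set"))
  if (nrow(ws$meta) == 0) stop("no measurements to average")
  eye <- factor(ws$meta$eye_id, levels = unique(ws$meta$eye_id))
  counts <- as.vector(table(eye))
  traces <- rowsum(ws$traces, eye, reorder = FALSE) / counts
  qi <- as.vector(rowsum(ws$meta$quality_index, eye, reorder = FALSE)) / counts
  meta <- data.frame(eye_id = levels(eye),
                     replicate_id = 0L,
                     quality_index = qi,
                     stringsAsFactors = FALSE)
  out <- waveform_set(meta, traces)
  dropped <- character(0)
  if (!is.null(expected_eyes)) {
    dropped <- setdiff(expected_eyes, meta$eye_id)
    if (length(dropped) > 0) {
      warning("average_replicates: eye(s) with no surviving measurements ",
              "dropped: ", paste(dropped, collapse = ", "))
    }
  }
  attr(out, "dropped_eyes") <- dropped
  out
}

#' Write per-eye covariates to CSV
#'
#' @param covariates data.frame with `eye_id`, covariate columns and `PRAA`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covariate_table <- function(covariates, path) {
  stopifnot(is.data.frame(covariates), "eye_id" %in% names(covariates))
  write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-eye covariates from CSV
#'
#' @param path CSV written by [write_covariate_table()] (or compatible).
#' @return data.frame of covariates.
#' @export
read_covariate_table <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"eye_id" %in% names(df)) stop("parse error: eye_id column required")
  df
}
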