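#' Per-sample peak list
#'
#' Holds one sample's detected MS1 features before alignment. Peaks are
#' sorted by (retention time, m/z) on ingestion.
#'
#' @param sample_id Nonempty sample identifier.
#' @param peaks `data.frame` with columns `mz` (Da, > 0), `rt` (min, >= 0),
#'   `area` (counts, >= 0), `charge` (integer) and `quality_score` (0-100).
#'   Extra columns (e.g. a ground-truth `feature` id) are carried along.
#' @param origin Optional origin label.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(sample_id, peaks, origin = NA_character_) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop_field("sample_id", "must be a nonempty string")
  need <- c("mz", "rt", "area", "charge", "quality_score")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks)))
    stop_field("peaks", paste("must be a data.frame with columns",
                              paste(need, collapse = ", ")))
  if (nrow(peaks) > 0) {
    if (any(peaks$mz <= 0)) stop_field("peaks$mz", "must be positive")
    if (any(peaks$rt < 0)) stop_field("peaks$rt", "must be nonnegative")
    if (any(peaks$area < 0)) stop_field("peaks$area", "must be nonnegative")
    peaks <- peaks[order(peaks$rt, peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(sample_id = sample_id, origin = origin, peaks = peaks),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> sample %s (%s): %d peaks\n", x$sample_id,
              ifelse(is.na(x$origin), "origin unknown", x$origin),
              nrow(x$peaks)))
  invisible(x)
}

#' Screen peaks by area, charge state and quality score
#'
#' Retains peaks whose area strictly exceeds `min_area`, whose charge state
#' equals `charge`, and whose quality score strictly exceeds `min_quality` --
#' the screening applied by the acquisition workstation before alignment.
#'
#' @param pl A [peak_list()].
#' @param min_area Area threshold in counts (default 1000, strict `>`).
#' @param charge Required charge state (default 1).
#' @param min_quality Quality-score threshold (default 60, strict `>`).
#' @return The screened [peak_list()]; peak order is preserved.
#' @export
screen_peaks <- function(pl, min_area = 1000, charge = 1L, min_quality = 60) {
  stopifnot(inherits(pl, "peak_list"))
  check_number(min_area, "min_area", lower = 0)
  check_number(min_quality, "min_quality", lower = 0)
  p <- pl$peaks
  keep <- p$area > min_area & p$charge == charge & p$quality_score > min_quality
  pl$peaks <- p[keep, , drop = FALSE]
  rownames(pl$peaks) <- NULL
  pl
}

#' Relative standard deviation, in percent
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; the
#' repeatability statistic computed on QC-sample m/z, retention-time and
#' peak-area series.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return RSD as a percentage.
#' @export
compute_rsd <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values))
    stop_field("values", "need at least two non-missing values")
  m <- mean(values)
  if (m == 0) stop_field("values", "mean is zero; RSD undefined")
  100 * sd(values) / m
}

#' Write / read peak lists as CSV
#'
#' One CSV per sample with columns `mz, rt, area, charge, quality_score`
#' (plus any extra columns present, e.g. ground-truth `feature`).
#'
#' @param pls List of [peak_list()] objects.
#' @param dir Output directory (created if needed).
#' @return `write_peak_lists` returns the written paths invisibly;
#'   `read_peak_list` returns a [peak_list()].
#' @export
write_peak_lists <- function(pls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(pls, function(pl) {
    path <- file.path(dir, paste0(pl$sample_id, ".csv"))
    write.csv(pl$peaks, path, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname write_peak_lists
#' @param path CSV file holding one sample's peaks.
#' @param sample_id,origin Identifier and optional origin label for the sample;
#'   `sample_id` defaults to the file name.
#' @export
read_peak_list <- function(path, sample_id = sub("\\.csv$", "", basename(path)),
                           origin = NA_character_) {
  peak_list(sample_id, read.csv(path), origin = origin)
}
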