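#' Aligned samples-by-features peak-area table
#'
#' The central container after peak alignment: a nonnegative area matrix
#' (0 = not detected), per-feature consensus m/z and retention time, and
#' optional per-sample origin labels.
#'
#' @param areas Numeric matrix, samples in rows, features in columns, all
#'   entries >= 0.
#' @param sample_ids Character vector, one id per row.
#' @param origins Optional character vector of origin labels per sample.
#' @param feature_meta `data.frame` with columns `feature`, `mz`, `rt`; a
#'   `presence_count` column is (re)computed from the matrix.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(areas, sample_ids, origins = NULL, feature_meta) {
  areas <- as.matrix(areas)
  if (any(areas < 0)) stop_field("areas", "must be nonnegative")
  n <- nrow(areas); p <- ncol(areas)
  if (length(sample_ids) != n)
    stop_field("sample_ids", "length must equal nrow(areas)")
  if (!is.null(origins) && length(origins) != n)
    stop_field("origins", "length must equal nrow(areas)")
  if (!is.data.frame(feature_meta) ||
      !all(c("feature", "mz", "rt") %in% names(feature_meta)) ||
      nrow(feature_meta) != p)
    stop_field("feature_meta", "must have columns feature, mz, rt with one row per feature")
  feature_meta$presence_count <- colSums(areas > 0)
  rownames(feature_meta) <- NULL
  dimnames(areas) <- list(sample_ids, feature_meta$feature)
  structure(list(areas = areas, sample_ids = sample_ids, origins = origins,
                 feature_meta = feature_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features", nrow(x$areas), ncol(x$areas)))
  if (!is.null(x$origins))
    cat(sprintf("; origins: %s", paste(names(table(x$origins)),
                                       table(x$origins), sep = "=", collapse = " ")))
  cat(sprintf("; %.1f%% zeros\n", 100 * mean(x$areas == 0)))
  invisible(x)
}

#' Align peak lists into a feature table
#'
#' Greedy centroid clustering: all peaks from all samples are processed in
#' descending area order (ties broken by ascending m/z, RT, sample id). A
#' peak joins the closest existing feature whose running consensus m/z is
#' within `mz_tol_ppm` and consensus RT within `rt_tol`, provided that
#' feature has no peak from the same sample yet; otherwise it founds a new
#' feature. Consensus m/z and RT are running means over member peaks. If a
#' sample offers two candidate peaks for one feature the larger-area one
#' wins (it is processed first) and the other founds or joins another
#' feature.
#'
#' @param pls List of [peak_list()] objects.
#' @param mz_tol_ppm Relative m/z tolerance in ppm (> 0, default 10).
#' @param rt_tol Absolute retention-time tolerance in minutes (> 0, default 0.2).
#' @return A [feature_table()]; features ordered by consensus RT then m/z.
#' @export
align_peaks <- function(pls, mz_tol_ppm = 10, rt_tol = 0.2) {
  if (!is.list(pls) || length(pls) < 1L ||
      !all(vapply(pls, inherits, logical(1), "peak_list")))
    stop_field("pls", "must be a nonempty list of peak_list objects")
  if (!is.numeric(mz_tol_ppm) || mz_tol_ppm <= 0)
    stop_field("mz_tol_ppm", "must be > 0")
  if (!is.numeric(rt_tol) || rt_tol <= 0)
    stop_field("rt_tol", "must be > 0")

  sample_ids <- vapply(pls, `[[`, character(1), "sample_id")
  if (anyDuplicated(sample_ids)) stop_field("pls", "duplicate sample ids")
  origins <- vapply(pls, function(pl) as.character(pl$origin), character(1))
  if (all(is.na(origins))) origins <- NULL

  all_peaks <- do.call(rbind, lapply(seq_along(pls), function(s) {
    p <- pls[[s]]$peaks
    if (nrow(p) == 0) return(NULL)
    data.frame(mz = p$mz, rt = p$rt, area = p$area, sample = s)
  }))
  if (is.null(all_peaks)) stop_field("pls", "no peaks to align")
  ord <- order(-all_peaks$area, all_peaks$mz, all_peaks$rt,
               sample_ids[all_peaks$sample])
  all_peaks <- all_peaks[ord, , drop = FALSE]

  npk <- nrow(all_peaks)
  cons_mz <- numeric(npk); cons_rt <- numeric(npk); cnt <- integer(npk)
  nfeat <- 0L
  n <- length(pls)
  has_sample <- matrix(FALSE, nrow = npk, ncol = n)
  areas_assign <- matrix(0, nrow = n, ncol = npk)

  for (i in seq_len(npk)) {
    mz <- all_peaks$mz[i]; rt <- all_peaks$rt[i]; s <- all_peaks$sample[i]
    f <- 0L
    if (nfeat > 0L) {
      idx <- seq_len(nfeat)
      dmz_ppm <- abs(mz - cons_mz[idx]) / cons_mz[idx] * 1e6
      ok <- dmz_ppm <= mz_tol_ppm & abs(rt - cons_rt[idx]) <= rt_tol &
        !has_sample[idx, s]
      if (any(ok)) {
        cand <- idx[ok]
        f <- cand[order(dmz_ppm[cand], abs(rt - cons_rt[cand]))][1]
      }
    }
    if (f == 0L) {
      nfeat <- nfeat + 1L
      f <- nfeat
      cons_mz[f] <- mz; cons_rt[f] <- rt; cnt[f] <- 1L
    } else {
      cons_mz[f] <- (cons_mz[f] * cnt[f] + mz) / (cnt[f] + 1L)
      cons_rt[f] <- (cons_rt[f] * cnt[f] + rt) / (cnt[f] + 1L)
      cnt[f] <- cnt[f] + 1L
    }
    has_sample[f, s] <- TRUE
    areas_assign[s, f] <- all_peaks$area[i]
  }

  keep <- seq_len(nfeat)
  ordf <- keep[order(cons_rt[keep], cons_mz[keep])]
  meta <- data.frame(feature = sprintf("F%04d", seq_along(ordf)),
                     mz = cons_mz[ordf], rt = cons_rt[ordf])
  feature_table(areas_assign[, ordf, drop = FALSE], sample_ids = sample_ids,
                origins = origins, feature_meta = meta)
}

#' Drop features missing in too many samples
#'
#' Removes features whose missing fraction (zero entries / samples) is
#' strictly greater than `max_missing_frac`; a feature missing in exactly
#' that fraction is kept. The default 0.8 implements the "lacking in more
#' than 80% of samples" common-peak rule; set it to just under `1/n` to force
#' presence in every sample.
#'
#' @param ft A [feature_table()].
#' @param max_missing_frac Allowed missing fraction, in (0, 1).
#' @return A new [feature_table()] with surviving features in original order.
#' @export
filter_common_peaks <- function(ft, max_missing_frac = 0.8) {
  stopifnot(inherits(ft, "feature_table"))
  if (!is.numeric(max_missing_frac) || max_missing_frac <= 0 || max_missing_frac >= 1)
    stop_field("max_missing_frac", "must lie strictly in (0, 1)")
  missing_frac <- colMeans(ft$areas == 0)
  keep <- which(missing_frac <= max_missing_frac)
  feature_table(ft$areas[, keep, drop = FALSE], sample_ids = ft$sample_ids,
                origins = ft$origins,
                feature_meta = ft$feature_meta[keep, c("feature", "mz", "rt"),
                                               drop = FALSE])
}

#' Write / read a feature table as CSV
#'
#' The sample table has `sample_id` and `origin` first, then one column per
#' feature; a companion `features.csv` stores consensus m/z and RT.
#'
#' @param ft A [feature_table()].
#' @param path Path of the sample x feature CSV; the companion metadata file
#'   is written next to it as `<stem>_features.csv`.
#' @return `write_feature_table` returns the paths invisibly;
#'   `read_feature_table` the [feature_table()].
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(sample_id = ft$sample_ids,
                   origin = if (is.null(ft$origins)) "" else ft$origins,
                   ft$areas, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta_path <- sub("(\\.csv)?$", "_features.csv", path)
  write.csv(ft$feature_meta, meta_path, row.names = FALSE)
  invisible(c(path, meta_path))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- read.csv(sub("(\\.csv)?$", "_features.csv", path))
  origins <- as.character(df$origin)
  if (all(!nzchar(origins) | is.na(origins))) origins <- NULL
  areas <- as.matrix(df[, -(1:2), drop = FALSE])
  feature_table(areas, sample_ids = as.character(df$sample_id),
                origins = origins,
                feature_meta = meta[, c("feature", "mz", "rt")])
}
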