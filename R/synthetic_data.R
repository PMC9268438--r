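#' Specification for synthetic aligned peak-area data
#'
#' Describes a simulated multi-origin LC-MS experiment: a fixed universe of
#' features (consensus m/z and retention time, per-feature intensity scale),
#' a small planted set of origin-discriminative features, log-normal peak
#' areas, and sporadic missingness. The defaults mirror a three-origin
#' ginseng design: 4 Liaoning (LN), 8 Heilongjiang (HLJ) and 19 Jilin (JL)
#' batches and 69 aligned ginsenoside features.
#'
#' Class signal is a mean shift on the log scale (multiplicative on areas):
#' the planted informative features are split into (near-)equal disjoint
#' groups, one per class, and group g is shifted by
#' `effect_size * class_effect[g]` log units in samples of class g only, so
#' every class is separable from both others.
#'
#' @param n_per_class Integer count of samples per origin class; recycled to
#'   `length(class_names)`.
#' @param class_names Origin labels, default `c("LN","HLJ","JL")`.
#' @param n_features Total number of aligned features.
#' @param n_informative Number of planted origin-discriminative features.
#' @param effect_size Per-class mean shift in log-intensity units (>= 0).
#' @param log_mu,log_sigma Baseline natural-log mean of peak areas and the
#'   feature-specific residual log-sd.
#' @param sample_log_sigma Sd of the shared per-sample log-intensity factor
#'   (injection volume, extraction yield, total saponin content), the
#'   correlated component of batch-to-batch variability in LC-MS peak
#'   areas; total marginal log-sd is
#'   `sqrt(log_sigma^2 + sample_log_sigma^2)`.
#' @param scale_spread Per-feature multiplicative scale heterogeneity: each
#'   feature's areas are multiplied by `10^u`, `u ~ U(0, log10(scale_spread))`.
#' @param missing_prob Probability a feature is undetected (area 0) in a sample.
#' @param mz_range,rt_range Intervals (Da, minutes) for consensus feature
#'   positions; defaults span the MS1 scan range and elution window.
#' @param mz_jitter_ppm,rt_jitter_min Within-feature measurement noise used by
#'   [generate_peak_lists()].
#' @param class_effect Optional per-class multiplier on `effect_size`
#'   (default 1 for every class), exposing unequal class separability.
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(4L, 8L, 19L),
                           class_names = c("LN", "HLJ", "JL"),
                           n_features = 69L,
                           n_informative = 6L,
                           effect_size = 2,
                           log_mu = log(1e5),
                           log_sigma = 0.5,
                           sample_log_sigma = 0.1,
                           scale_spread = 1e3,
                           missing_prob = 0.02,
                           mz_range = c(400, 1700),
                           rt_range = c(1, 32),
                           mz_jitter_ppm = 5,
                           rt_jitter_min = 0.05,
                           class_effect = NULL,
                           seed = 1L) {
  if (!is.character(class_names) || length(class_names) < 2L)
    stop_field("class_names", "need at least two origin classes")
  if (anyDuplicated(class_names))
    stop_field("class_names", "labels must be distinct")
  nc <- length(class_names)
  if (!is.numeric(n_per_class) || anyNA(n_per_class) || any(n_per_class < 1))
    stop_field("n_per_class", "must be positive counts")
  n_per_class <- as.integer(rep_len(n_per_class, nc))
  check_number(n_features, "n_features", lower = 1)
  check_number(n_informative, "n_informative", lower = 0)
  if (n_informative > n_features)
    stop_field("n_informative", "cannot exceed n_features")
  check_number(effect_size, "effect_size", lower = 0)
  check_number(log_mu, "log_mu")
  check_number(log_sigma, "log_sigma", lower = 0)
  check_number(sample_log_sigma, "sample_log_sigma", lower = 0)
  check_number(scale_spread, "scale_spread", lower = 1)
  check_number(missing_prob, "missing_prob", lower = 0, upper = 1)
  check_number(mz_range, "mz_range", lower = 0, len = 2L)
  check_number(rt_range, "rt_range", lower = 0, len = 2L)
  if (diff(mz_range) <= 0) stop_field("mz_range", "must be an increasing interval")
  if (diff(rt_range) <= 0) stop_field("rt_range", "must be an increasing interval")
  check_number(mz_jitter_ppm, "mz_jitter_ppm", lower = 0)
  check_number(rt_jitter_min, "rt_jitter_min", lower = 0)
  if (is.null(class_effect)) class_effect <- rep(1, nc)
  check_number(class_effect, "class_effect", lower = 0, len = nc)
  check_number(seed, "seed")

  structure(list(
    n_per_class = n_per_class, class_names = class_names,
    n_features = as.integer(n_features), n_informative = as.integer(n_informative),
    effect_size = effect_size, log_mu = log_mu, log_sigma = log_sigma,
    sample_log_sigma = sample_log_sigma,
    scale_spread = scale_spread, missing_prob = missing_prob,
    mz_range = mz_range, rt_range = rt_range,
    mz_jitter_ppm = mz_jitter_ppm, rt_jitter_min = rt_jitter_min,
    class_effect = class_effect, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Feature-universe parameters (consensus m/z, RT, per-feature scale,
# informative set and its class-group assignment) drawn under spec$seed so
# that tables generated with different sample_seed values share one universe.
feature_universe <- function(spec) {
  p <- spec$n_features
  nc <- length(spec$class_names)
  with_seed(spec$seed, {
    spacing_mz <- diff(spec$mz_range) / p
    spacing_rt <- diff(spec$rt_range) / p
    mz <- spec$mz_range[1] + (seq_len(p) - 1) * spacing_mz +
      runif(p, 0.25 * spacing_mz, 0.75 * spacing_mz)
    rt <- spec$rt_range[1] + (seq_len(p) - 1) * spacing_rt +
      runif(p, 0.25 * spacing_rt, 0.75 * spacing_rt)
    scale <- 10^runif(p, 0, log10(spec$scale_spread))
    informative <- sort(sample.int(p, spec$n_informative))
    group <- rep_len(seq_len(nc), spec$n_informative)
    list(mz = mz, rt = rt, scale = scale,
         informative = informative, group = group)
  })
}

#' Generate a labelled synthetic feature table
#'
#' Draws an aligned samples-by-features peak-area matrix from a
#' [synthetic_spec()]: log-normal areas with per-class mean shifts on the
#' planted informative features, per-feature scale factors, and independent
#' Bernoulli missingness encoded as 0 (undetected).
#'
#' @param spec A [synthetic_spec()].
#' @param n_per_class Optional override of the per-class sample counts (the
#'   feature universe stays that of `spec`, so tables drawn with different
#'   `sample_seed`s share features and can serve as training and held-out sets).
#' @param sample_seed Seed for the sample-level draws; defaults to `spec$seed`.
#' @param sample_prefix Prefix for sample identifiers.
#' @return A [feature_table()] with origin labels and a `truth` attribute
#'   (informative feature indices, their class groups, per-feature scales).
#' @export
generate_feature_table <- function(spec, n_per_class = spec$n_per_class,
                                   sample_seed = spec$seed,
                                   sample_prefix = "S") {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_per_class <- as.integer(rep_len(n_per_class, length(spec$class_names)))
  uni <- feature_universe(spec)
  p <- spec$n_features
  n <- sum(n_per_class)
  origins <- rep(spec$class_names, n_per_class)
  sample_ids <- sprintf("%s%02d", sample_prefix, seq_len(n))

  shift <- matrix(0, nrow = length(spec$class_names), ncol = p)
  for (g in seq_along(uni$informative)) {
    cls <- uni$group[g]
    shift[cls, uni$informative[g]] <- spec$effect_size * spec$class_effect[cls]
  }

  areas <- with_seed(sample_seed, {
    u <- rnorm(n, 0, spec$sample_log_sigma)
    logx <- matrix(rnorm(n * p, spec$log_mu, spec$log_sigma), n, p) + u
    logx <- logx + shift[match(origins, spec$class_names), , drop = FALSE]
    x <- exp(logx) * rep(uni$scale, each = n)
    if (spec$missing_prob > 0)
      x[matrix(runif(n * p) < spec$missing_prob, n, p)] <- 0
    x
  })

  meta <- data.frame(feature = sprintf("F%04d", seq_len(p)),
                     mz = uni$mz, rt = uni$rt)
  ft <- feature_table(areas, sample_ids = sample_ids, origins = origins,
                      feature_meta = meta)
  attr(ft, "truth") <- list(informative = uni$informative, group = uni$group,
                            scale = uni$scale, shift = shift)
  ft
}

#' Generate per-sample peak lists
#'
#' Derives one peak list per sample from [generate_feature_table()]: every
#' detected feature occurrence becomes a peak at the consensus m/z and RT
#' jittered by at most `mz_jitter_ppm` / `rt_jitter_min` (uniform), with unit
#' charge and a quality score passing the default screening threshold.
#' Undetected (zero-area) entries are omitted. The ground-truth feature
#' identity of every peak is kept in a `feature` column for recovery tests.
#'
#' @inheritParams generate_feature_table
#' @return A list of [peak_list()] objects with the source [feature_table()]
#'   attached as attribute `source_table`.
#' @export
generate_peak_lists <- function(spec, n_per_class = spec$n_per_class,
                                sample_seed = spec$seed,
                                sample_prefix = "S") {
  ft <- generate_feature_table(spec, n_per_class = n_per_class,
                               sample_seed = sample_seed,
                               sample_prefix = sample_prefix)
  meta <- ft$feature_meta
  min_gap_mz <- min(diff(sort(meta$mz)))
  min_gap_rt <- min(diff(sort(meta$rt)))
  jitter_da <- spec$mz_jitter_ppm * 1e-6 * max(meta$mz)
  if (jitter_da > min_gap_mz / 2 && spec$rt_jitter_min > min_gap_rt / 2)
    warning("jitter exceeds half the minimum inter-feature spacing; ",
            "alignment may be ambiguous")

  pls <- with_seed(derive_seed(sample_seed, 1L), {
    lapply(seq_along(ft$sample_ids), function(s) {
      det <- which(ft$areas[s, ] > 0)
      nd <- length(det)
      mz <- meta$mz[det] * (1 + runif(nd, -1, 1) * spec$mz_jitter_ppm * 1e-6)
      rt <- meta$rt[det] + runif(nd, -1, 1) * spec$rt_jitter_min
      peaks <- data.frame(mz = mz, rt = rt, area = ft$areas[s, det],
                          charge = 1L, quality_score = runif(nd, 61, 100),
                          feature = meta$feature[det])
      peak_list(ft$sample_ids[s], peaks, origin = ft$origins[s])
    })
  })
  attr(pls, "source_table") <- ft
  pls
}
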