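#' Names of the inclination-signature features, in registry order
#'
#' The 33-feature registry: 13 kinematic scalars followed by 10 exclusive-bin
#' occupancy fractions of the raw inclination over `[0, 180]` degrees and 10
#' occupancy fractions of the max-normalized inclination over `[0, 1]`.
#'
#' @param n_bins Bins per amplitude curve (default 10).
#' @return Character vector of feature names.
#' @export
is_feature_names <- function(n_bins = 10L) {
  c("dur_event", "dur_lift", "dur_sip", "dur_place",
    "theta_max", "t_max_frac",
    "theta_sip_start", "theta_sip_end", "theta_sip_mean",
    "dtheta_max", "dtheta_min",
    "integral_sip", "integral_event",
    sprintf("raw_bin_%02d", seq_len(n_bins)),
    sprintf("norm_bin_%02d", seq_len(n_bins)))
}

exclusive_bin_fractions <- function(x, lo, hi, n_bins) {
  # each sample falls in exactly one bin; values at hi go to the last bin
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = n_bins) / length(x)
}

trapz_integral <- function(theta, rate) {
  if (length(theta) < 2) return(0)
  pracma::trapz(seq_along(theta) / rate, theta)
}

#' Extract the 33 inclination-signature features for one drink
#'
#' Computes the hand-engineered descriptor of the container's inclination
#' curve over a macro-event: event and micro-event durations, maximum
#' inclination and its (fractional) timing, inclination at the sip
#' boundaries, mean sip inclination, extreme inclination rates, trapezoidal
#' integrals over the sip and over the scope window, and exclusive-bin
#' amplitude histograms of the raw and max-normalized curve. Exclusive
#' binning makes the occupancy fractions a partition of the samples (they
#' sum to 1), which keeps the binned features weakly correlated.
#'
#' With `scope = "sip"` the scalar curve descriptors (max, timing, rates,
#' bins and the scope integral) are computed over the sip micro-event only;
#' with `scope = "macro"` over the whole event. Durations and sip-boundary
#' features always refer to the partition.
#'
#' @param theta Inclination in degrees over one macro-event.
#' @param partition One-row partition tibble from [partition_micro_events()].
#' @param scope `"macro"` (whole event) or `"sip"`.
#' @param rate Sampling rate in Hz (default 20).
#' @param n_bins Bins per amplitude histogram (default 10).
#' @return One-row tibble with the 33 features of [is_feature_names()].
#' @export
extract_is_features <- function(theta, partition, scope = c("macro", "sip"),
                                rate = 20, n_bins = 10L) {
  scope <- match.arg(scope)
  n <- length(theta)
  stopifnot(partition$place_end[1] - 1L == n)
  sip_idx <- seq.int(partition$sip_start[1], partition$sip_end[1] - 1L)
  win <- if (scope == "sip") theta[sip_idx] else theta
  theta_sip <- theta[sip_idx]

  theta_max <- max(win)
  i_max <- which.max(win)
  t_max_frac <- if (length(win) > 1) (i_max - 1) / (length(win) - 1) else 0
  d <- if (length(win) > 1) diff(win) * rate else 0

  if (theta_max <= 0) {
    warn("theta_max is zero; normalized bins collapse to the first bin")
    norm_bins <- c(1, rep(0, n_bins - 1L))
  } else {
    norm_bins <- exclusive_bin_fractions(win / theta_max, 0, 1, n_bins)
  }
  raw_bins <- exclusive_bin_fractions(win, 0, 180, n_bins)

  vals <- c(
    dur_event = length(win) / rate,
    dur_lift = (partition$lift_end[1] - partition$lift_start[1]) / rate,
    dur_sip = length(sip_idx) / rate,
    dur_place = (partition$place_end[1] - partition$place_start[1]) / rate,
    theta_max = theta_max,
    t_max_frac = t_max_frac,
    theta_sip_start = theta_sip[1],
    theta_sip_end = theta_sip[length(theta_sip)],
    theta_sip_mean = mean(theta_sip),
    dtheta_max = max(d),
    dtheta_min = min(d),
    integral_sip = trapz_integral(theta_sip, rate),
    integral_event = trapz_integral(win, rate)
  )
  out <- c(vals, stats::setNames(raw_bins, sprintf("raw_bin_%02d", seq_len(n_bins))),
           stats::setNames(norm_bins, sprintf("norm_bin_%02d", seq_len(n_bins))))
  as_tibble(as.list(out))
}

#' Extract the single-factor benchmark features
#'
#' Sip duration and integral of inclination over the sip are the motion
#' features used by earlier wrist-worn volume estimators; maximum
#' inclination is the single-factor benchmark for fill-ratio estimation.
#'
#' @inheritParams extract_is_features
#' @return One-row tibble with `sip_duration` (s), `integral_theta`
#'   (degree-seconds over the sip) and `max_theta` (degrees over the event).
#' @export
extract_benchmark_features <- function(theta, partition, rate = 20) {
  sip_len <- partition$sip_end[1] - partition$sip_start[1]
  if (sip_len < 1) {
    abort("empty sip micro-event", class = "sipsense_validation_error")
  }
  sip_idx <- seq.int(partition$sip_start[1], partition$sip_end[1] - 1L)
  tibble(sip_duration = sip_len / rate,
         integral_theta = trapz_integral(theta[sip_idx], rate),
         max_theta = max(theta))
}

#' Featurize a conditioned trial
#'
#' Runs segmentation and feature extraction over one conditioned recording:
#' detects macro-events, partitions each into lift/sip/place on the
#' cross-sectional angle, and extracts both the inclination-signature and
#' benchmark features per drink.
#'
#' @param cond Conditioned recording (see [condition()]); `theta`/`alpha`
#'   columns are computed if absent.
#' @param cfg A [segmentation_config()].
#' @param scope Feature scope, `"macro"` or `"sip"` (see
#'   [extract_is_features()]).
#' @param n_bins Bins per amplitude histogram.
#' @return Tibble with one row per detected drink: `trial_id`,
#'   `drink_index`, the micro-event ranges (absolute sample indices), the
#'   benchmark features and the 33 IS features.
#' @export
featurize_trial <- function(cond, cfg = segmentation_config(),
                            scope = "macro", n_bins = 10L) {
  rate <- attr(cond, "rate") %||% 20
  if (!"theta" %in% names(cond)) cond <- compute_inclination(cond)
  if (!"alpha" %in% names(cond)) cond <- compute_axial_angle(cond)
  events <- detect_macro_events(cond, cfg)
  if (nrow(events) == 0) {
    return(tibble(trial_id = character(), drink_index = integer()))
  }
  purrr::pmap_dfr(events, function(drink_index, start, end) {
    idx <- seq.int(start, end - 1L)
    part <- partition_micro_events(cond$alpha[idx], cfg)
    theta <- cond$theta[idx]
    dplyr::bind_cols(
      tibble(trial_id = attr(cond, "trial_id") %||% NA_character_,
             drink_index = drink_index,
             event_start = start, event_end = end,
             sip_start = start + part$sip_start - 1L,
             sip_end = start + part$sip_end - 1L),
      extract_benchmark_features(theta, part, rate),
      extract_is_features(theta, part, scope = scope, rate = rate,
                          n_bins = n_bins)
    )
  })
}

#' Featurize a cohort of recordings
#'
#' Applies bias estimation, conditioning and [featurize_trial()] to each raw
#' recording and row-binds the per-drink feature tables.
#'
#' @param recordings List of [recording()] objects.
#' @param cfg A [segmentation_config()].
#' @param scope,n_bins Passed to [featurize_trial()].
#' @param target_rate,ma_window Passed to [condition()].
#' @return Tibble of per-drink features across the cohort.
#' @export
featurize_cohort <- function(recordings, cfg = segmentation_config(),
                             scope = "macro", n_bins = 10L,
                             target_rate = 20, ma_window = 2L) {
  purrr::map_dfr(recordings, function(rec) {
    cond <- condition(rec, target_rate = target_rate, ma_window = ma_window)
    featurize_trial(cond, cfg, scope = scope, n_bins = n_bins)
  })
}
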