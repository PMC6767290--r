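#' Segmentation parameters
#'
#' Controls the threshold-based macro-event detector and the
#' lift/sip/place micro-event partition.
#'
#' Macro-events are intervals where the bottle is in motion; between drinks
#' it rests on the table, so motion is flagged when either the acceleration
#' magnitude departs from 1 g (`mag_dev_thresh`) or the inclination varies
#' within a short rolling window (`theta_std_thresh` over `theta_std_window_s`).
#' The micro-event partition thresholds the sample-over-sample difference of
#' the cross-sectional angle at `alpha_diff_max` degrees and merges compliant
#' intervals separated by fewer than `merge_gap` samples; the largest merged
#' interval is the sip.
#'
#' @param alpha_diff_max Maximum |delta alpha| per sample, degrees (default 8).
#' @param merge_gap Compliant runs separated by fewer than this many
#'   non-compliant samples are merged (default 2, i.e. single-sample gaps).
#' @param mag_dev_thresh Motion threshold on | |a| - 1 | in g (default 0.05).
#' @param theta_std_thresh Motion threshold on the rolling standard deviation
#'   of inclination, degrees (default 2).
#' @param theta_std_window_s Rolling window for the inclination std, seconds
#'   (default 0.5).
#' @param min_event_s Minimum macro-event duration, seconds (default 1).
#' @param min_still_s Minimum stillness gap separating macro-events, seconds
#'   (default 1); shorter gaps are bridged.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(alpha_diff_max = 8,
                                merge_gap = 2L,
                                mag_dev_thresh = 0.05,
                                theta_std_thresh = 2,
                                theta_std_window_s = 0.5,
                                min_event_s = 1,
                                min_still_s = 1) {
  cfg <- list(alpha_diff_max = alpha_diff_max, merge_gap = as.integer(merge_gap),
              mag_dev_thresh = mag_dev_thresh, theta_std_thresh = theta_std_thresh,
              theta_std_window_s = theta_std_window_s,
              min_event_s = min_event_s, min_still_s = min_still_s)
  stopifnot(all(unlist(cfg) > 0))
  structure(cfg, class = "segmentation_config")
}

runs_of <- function(flag) {
  # maximal runs of TRUE as a tibble of 1-based half-open [start, end)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep] + 1L)
}

#' Detect drinking macro-events in a conditioned trial
#'
#' A sample is flagged as motion when `| ||a|| - 1 | > mag_dev_thresh` or the
#' rolling standard deviation of inclination over `theta_std_window_s`
#' exceeds `theta_std_thresh`. Maximal motion runs separated by stillness
#' shorter than `min_still_s` are bridged, and runs longer than `min_event_s`
#' become macro-events, numbered 1..K in time order.
#'
#' @param rec A conditioned recording; the `theta` column is computed on the
#'   fly if absent.
#' @param cfg A [segmentation_config()].
#' @return Tibble with columns `drink_index`, `start`, `end` (1-based,
#'   half-open sample ranges into `rec`). Zero rows when no motion is found.
#' @export
detect_macro_events <- function(rec, cfg = segmentation_config()) {
  rate <- attr(rec, "rate") %||% 20
  if (!"theta" %in% names(rec)) rec <- compute_inclination(rec)
  mag <- sqrt(rec$ax^2 + rec$ay^2 + rec$az^2)
  w <- max(3L, as.integer(round(cfg$theta_std_window_s * rate)))
  roll_sd <- zoo::rollapply(rec$theta, width = w, FUN = sd,
                            fill = NA, align = "center", partial = TRUE)
  m <- (abs(mag - 1) > cfg$mag_dev_thresh) |
    (!is.na(roll_sd) & roll_sd > cfg$theta_std_thresh)
  runs <- runs_of(m)
  if (nrow(runs) == 0) {
    return(tibble(drink_index = integer(), start = integer(), end = integer()))
  }
  min_still <- as.integer(round(cfg$min_still_s * rate))
  min_event <- as.integer(round(cfg$min_event_s * rate))
  # bridge stillness gaps shorter than min_still
  merged <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)]
      if (gap < min_still) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- dplyr::bind_rows(merged, runs[i, ])
      }
    }
  }
  merged <- merged[(merged$end - merged$start) > min_event, ]
  if (nrow(merged) == 0) {
    return(tibble(drink_index = integer(), start = integer(), end = integer()))
  }
  tibble(drink_index = seq_len(nrow(merged)),
         start = merged$start, end = merged$end)
}

#' Partition a macro-event into lift, sip and place micro-events
#'
#' The sip is the stretch over which the cross-sectional angle `alpha` is
#' stationary. Compliance is defined per sample as
#' `|alpha[n] - alpha[n-1]| <= alpha_diff_max` (the first sample is
#' compliant by convention); maximal compliant runs separated by fewer than
#' `merge_gap` non-compliant samples are merged, gap samples included, and
#' the longest merged run is the sip (ties break to the earliest). The lift
#' is everything before the sip and the place everything after, so the three
#' ranges tile the macro-event exactly.
#'
#' @param alpha Numeric vector of cross-sectional angles (degrees) over one
#'   macro-event, length at least 3.
#' @param cfg A [segmentation_config()].
#' @return One-row tibble with half-open 1-based ranges `lift_start,
#'   lift_end, sip_start, sip_end, place_start, place_end` (relative to the
#'   macro-event) and a logical `fallback` flag set when no compliant run
#'   exists and the whole event is returned as the sip.
#' @export
partition_micro_events <- function(alpha, cfg = segmentation_config()) {
  n <- length(alpha)
  if (n < 3) {
    abort("alpha series must have at least 3 samples",
          class = "sipsense_validation_error")
  }
  compliant <- c(TRUE, abs(diff(alpha)) <= cfg$alpha_diff_max)
  if (!any(compliant)) {
    warn("no alpha-stationary interval found; treating whole event as sip")
    return(tibble(lift_start = 1L, lift_end = 1L,
                  sip_start = 1L, sip_end = n + 1L,
                  place_start = n + 1L, place_end = n + 1L,
                  fallback = TRUE))
  }
  runs <- runs_of(compliant)
  # merge runs separated by gaps of fewer than merge_gap samples; the merged
  # span keeps the gap samples so the sip stays contiguous
  merged <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)]
      if (gap < cfg$merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- dplyr::bind_rows(merged, runs[i, ])
      }
    }
  }
  len <- merged$end - merged$start
  best <- which.max(len)  # ties -> earliest
  s <- merged$start[best]; e <- merged$end[best]
  tibble(lift_start = 1L, lift_end = s,
         sip_start = s, sip_end = e,
         place_start = e, place_end = n + 1L,
         fallback = FALSE)
}

#' Serialize micro-event partitions to JSON
#'
#' @param partitions Tibble of partitions with `trial_id` and `drink_index`
#'   columns alongside the range columns of [partition_micro_events()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path) {
  jsonlite::write_json(partitions, path, digits = NA)
  invisible(path)
}
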