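#' Mean absolute percentage error
#'
#' `mean(100 * |pred - truth| / truth)`, on the 0–100 scale.
#'
#' @param pred Predictions.
#' @param truth Positive ground-truth values, same length.
#' @return Percentage (scalar).
#' @export
mape <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  zero <- which(truth <= 0)
  if (length(zero) > 0) {
    abort(sprintf("non-positive truth value at index %d", zero[1]),
          class = "sipsense_validation_error")
  }
  mean(100 * abs(pred - truth) / truth)
}

#' Overall absolute percentage error of summed consumption
#'
#' `100 * |sum(pred[1:n]) - sum(truth[1:n])| / sum(truth[1:n])` for one
#' trial. Errors of opposite sign across a drink sequence cancel in the
#' sums, so the OAPE of a sequence can fall below every per-drink APE.
#'
#' @param pred,truth Per-drink predictions and truths, in drink order.
#' @param n Number of leading drinks to aggregate (default: all).
#' @return Percentage (scalar).
#' @export
oape <- function(pred, truth, n = length(truth)) {
  stopifnot(length(pred) == length(truth), n >= 1, n <= length(truth))
  100 * abs(sum(pred[1:n]) - sum(truth[1:n])) / sum(truth[1:n])
}

#' Mean overall absolute percentage error across trials
#'
#' Computes OAPE over the first `n` drinks of each trial and averages across
#' trials. Trials with fewer than `n` drinks are skipped with a warning.
#'
#' @param results Tibble with `trial_id`, `drink_index`, `pred`, `truth`
#'   (e.g. a [loto_evaluate()] result).
#' @param n Drinks per trial to aggregate.
#' @return Percentage (scalar).
#' @export
moape <- function(results, n) {
  per_trial <- trial_oape(results, n)
  mean(per_trial$oape)
}

trial_oape <- function(results, n) {
  results <- dplyr::arrange(results, .data$trial_id, .data$drink_index)
  out <- results |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(n_drinks = dplyr::n(),
                     oape = if (dplyr::n() >= n) oape(.data$pred, .data$truth, n)
                            else NA_real_,
                     .groups = "drop")
  short <- out$trial_id[is.na(out$oape)]
  if (length(short) > 0) {
    warn(sprintf("skipping %d trial(s) with fewer than %d drinks", length(short), n))
  }
  dplyr::filter(out, !is.na(.data$oape))
}

#' Residual aggregate-consumption estimate from endpoint fill ratios
#'
#' Aggregate consumption between two fill-ratio readings is
#' `V = beta * (fr_i - fr_f1)`, where `beta` is the container's linear
#' density (mL per unit fill ratio), `fr_i` the fill ratio at the initiation
#' of the first drink and `fr_f1` the fill ratio at the initiation of the
#' drink after the last one counted.
#'
#' @param fr_i,fr_f1 Fill ratios in `[0, 1]`.
#' @param geom A [container_geometry()].
#' @return Estimated volume in mL; a negative value (estimates out of
#'   order) is returned with a warning.
#' @export
residual_volume_estimate <- function(fr_i, fr_f1, geom = container_geometry()) {
  stopifnot(all(fr_i >= 0 & fr_i <= 1), all(fr_f1 >= 0 & fr_f1 <= 1))
  v <- geom$beta_ml * (fr_i - fr_f1)
  if (any(v < 0)) warn("negative residual volume estimate (fill ratios out of order)")
  v
}

#' Distortion of fill-ratio accuracy under residual-volume aggregation
#'
#' Converting a fill-ratio error into an aggregate-consumption error
#' normalizes by the consumed fraction: for an error on the endpoint fill
#' ratio, `OAPE = APE / (1 - FR_next)`. The distortion is most severe when
#' little has been consumed (`FR_next` near 1) and vanishes for an emptied
#' container (`FR_next = 0`, where OAPE equals APE).
#'
#' @param ape_next Absolute error of the endpoint fill-ratio estimate, in
#'   fill-ratio units (the fill ratio is already normalized to `[0, 1]`, so
#'   this is the error as a fraction of the full container).
#' @param fr_next True endpoint fill ratio, in `[0, 1)`.
#' @return OAPE as a fraction (same scale as `ape_next`).
#' @export
oape_distortion <- function(ape_next, fr_next) {
  if (any(fr_next >= 1)) {
    abort("fr_next = 1 means no consumption; OAPE undefined",
          class = "sipsense_validation_error")
  }
  stopifnot(all(fr_next >= 0))
  ape_next / (1 - fr_next)
}

#' Compare cumulative and residual aggregate-consumption strategies
#'
#' Cumulative estimation sums the per-drink volume predictions over the
#' first `n` drinks; residual estimation converts the fill-ratio estimates
#' at drink 1 and drink `n + 1` into a volume via the container geometry.
#' Both are scored as MOAPE(`n`) against the summed true masses. Trials
#' without a drink `n + 1` (needed for the residual endpoint) are excluded
#' from both strategies so the comparison stays paired.
#'
#' @param volume_results LOTO results for a volume model (`trial_id`,
#'   `drink_index`, `pred`, `truth` in grams/mL).
#' @param fr_results LOTO results for a fill-ratio model on the same trials.
#' @param geom A [container_geometry()].
#' @param n Drinks to aggregate (default 11, the longest span assessable
#'   with initial fill-ratio estimates in a 12-drink protocol).
#' @return Tibble with one row per strategy: `strategy`, `moape`,
#'   `n_trials`.
#' @export
compare_aggregation <- function(volume_results, fr_results,
                                geom = container_geometry(), n = 11L) {
  vol_trials <- sort(unique(volume_results$trial_id))
  fr_trials <- sort(unique(fr_results$trial_id))
  if (!identical(vol_trials, fr_trials)) {
    abort("volume and fill-ratio results cover different trial sets",
          class = "sipsense_validation_error")
  }
  fr_results <- dplyr::arrange(fr_results, .data$trial_id, .data$drink_index)
  volume_results <- dplyr::arrange(volume_results, .data$trial_id, .data$drink_index)

  per_trial <- purrr::map_dfr(vol_trials, function(tr) {
    vol <- volume_results[volume_results$trial_id == tr, ]
    fr <- fr_results[fr_results$trial_id == tr, ]
    if (nrow(vol) < n || nrow(fr) < n + 1) {
      return(tibble(trial_id = tr, cumulative = NA_real_, residual = NA_real_))
    }
    truth_sum <- sum(vol$truth[1:n])
    cum_est <- sum(vol$pred[1:n])
    # regression estimates of a ratio can stray outside [0, 1]; clamp before
    # converting to volume
    res_est <- suppressWarnings(
      residual_volume_estimate(min(max(fr$pred[1], 0), 1),
                               min(max(fr$pred[n + 1], 0), 1), geom)
    )
    tibble(trial_id = tr,
           cumulative = 100 * abs(cum_est - truth_sum) / truth_sum,
           residual = 100 * abs(res_est - truth_sum) / truth_sum)
  })
  skipped <- is.na(per_trial$cumulative)
  if (any(skipped)) {
    warn(sprintf("excluding %d trial(s) without drink %d", sum(skipped), n + 1))
    per_trial <- per_trial[!skipped, ]
  }
  tibble(strategy = c("cumulative", "residual"),
         moape = c(mean(per_trial$cumulative), mean(per_trial$residual)),
         n_trials = nrow(per_trial))
}

#' Summarise a LOTO evaluation
#'
#' Builds the standard report for a model run: per-trial MAPE, pooled MAPE
#' (over all drinks and as the mean of trial MAPEs — the two conventions can
#' differ when trial lengths differ), the standard deviation of MAPE across
#' trials, and MOAPE over the requested drink counts.
#'
#' @param results A [loto_evaluate()] result (or any tibble with
#'   `trial_id`, `drink_index`, `pred`, `truth`).
#' @param ns Drink counts for MOAPE (default `c(3, 6, 9, 12)`).
#' @return A list of class `evaluation_report` with elements `per_trial`
#'   (tibble of per-trial MAPE and OAPE values), `pooled_mape`,
#'   `mean_trial_mape`, `mape_sd`, `moape` (named by `n`).
#' @export
evaluation_report <- function(results, ns = c(3, 6, 9, 12)) {
  per_trial <- results |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(n_drinks = dplyr::n(),
                     mape = mape(.data$pred, .data$truth),
                     .groups = "drop")
  moapes <- vapply(ns, function(n) suppressWarnings(moape(results, n)), numeric(1))
  structure(list(per_trial = per_trial,
                 pooled_mape = mape(results$pred, results$truth),
                 mean_trial_mape = mean(per_trial$mape),
                 mape_sd = sd(per_trial$mape),
                 moape = stats::setNames(moapes, paste0("moape_", ns)),
                 ns = ns),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d trials, %d drinks\n",
              nrow(x$per_trial), sum(x$per_trial$n_drinks)))
  cat(sprintf("  pooled MAPE %.2f%%  (mean of trial MAPEs %.2f%%, sd %.2f%%)\n",
              x$pooled_mape, x$mean_trial_mape, x$mape_sd))
  for (i in seq_along(x$moape)) {
    cat(sprintf("  MOAPE(%d) %.2f%%\n", x$ns[i], x$moape[i]))
  }
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) x$per_trial

#' @export
glance.evaluation_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(pooled_mape = x$pooled_mape,
           mean_trial_mape = x$mean_trial_mape,
           mape_sd = x$mape_sd,
           n_trials = nrow(x$per_trial)),
    as_tibble(as.list(x$moape))
  )
}

#' Write an evaluation report to JSON
#'
#' @param report An [evaluation_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(pooled_mape = report$pooled_mape,
         mean_trial_mape = report$mean_trial_mape,
         mape_sd = report$mape_sd,
         moape = as.list(report$moape),
         per_trial = report$per_trial),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
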