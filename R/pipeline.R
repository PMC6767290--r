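#' Join per-drink features with ground-truth labels
#'
#' Features come from the signal (detected drinks, ordered in time); labels
#' from the scale. They are joined on `(trial_id, drink_index)`. Drinks
#' present on only one side are dropped with a warning — a mismatch usually
#' means the macro-event detector found a different number of events than
#' the protocol scripted.
#'
#' @param features Output of [featurize_cohort()].
#' @param labels Label tibble (see [read_labels()]).
#' @return Joined tibble, one row per matched drink.
#' @export
join_labels <- function(features, labels) {
  labels <- validate_labels(labels)
  joined <- dplyr::inner_join(features, labels,
                              by = c("trial_id", "drink_index"))
  lost <- nrow(features) + nrow(labels) - 2 * nrow(joined)
  if (lost > 0) {
    warn(sprintf("%d drink(s) unmatched between features and labels", lost))
  }
  joined
}

#' Run the full estimation pipeline over a dataset
#'
#' Conditions and featurizes every recording, joins labels, and evaluates
#' each requested model under leave-one-trial-out validation.
#'
#' @param recordings Named list of [recording()]s (or a directory path
#'   containing trace CSVs plus `labels.csv`, as written by
#'   [simulate_dataset()]).
#' @param labels Label tibble; ignored when `recordings` is a path.
#' @param specs Named list of [model_spec()]s. The default set mirrors the
#'   standard comparison: single-factor benchmarks and IS SVMs for volume,
#'   and a coarse-kernel SVM plus max-inclination benchmark for fill ratio.
#' @param seg_cfg A [segmentation_config()].
#' @param scope Feature scope (see [extract_is_features()]).
#' @param ns Drink counts for MOAPE reporting.
#' @return List of class `pipeline_result` with `features` (labelled
#'   feature table), `results` (named list of [loto_evaluate()] outputs) and
#'   `reports` (named list of [evaluation_report()]s).
#' @export
run_pipeline <- function(recordings, labels = NULL,
                         specs = default_model_specs(),
                         seg_cfg = segmentation_config(),
                         scope = "macro",
                         ns = c(3, 6, 9, 12)) {
  if (is.character(recordings) && length(recordings) == 1) {
    dir <- recordings
    labels <- read_labels(file.path(dir, "labels.csv"))
    paths <- setdiff(list.files(dir, pattern = "\\.csv$", full.names = TRUE),
                     file.path(dir, "labels.csv"))
    recordings <- lapply(paths, read_recording)
    names(recordings) <- vapply(recordings, attr, "", "trial_id")
  }
  features <- featurize_cohort(recordings, seg_cfg, scope = scope)
  data <- join_labels(features, labels)
  results <- lapply(specs, function(sp) loto_evaluate(data, sp))
  reports <- lapply(results, evaluation_report, ns = ns)
  structure(list(features = data, results = results, reports = reports),
            class = "pipeline_result")
}

#' Default model comparison set
#'
#' @return Named list of [model_spec()]s.
#' @export
default_model_specs <- function() {
  list(
    vol_lr_duration = model_spec("volume", "lr", lr_feature = "sip_duration"),
    vol_lr_integral = model_spec("volume", "lr", lr_feature = "integral_theta"),
    vol_svm_linear = model_spec("volume", "svm", kernel = "linear"),
    vol_svm_medium = model_spec("volume", "svm", kernel = "medium"),
    vol_svm_coarse = model_spec("volume", "svm", kernel = "coarse"),
    fr_lr_maxtheta = model_spec("fill_ratio", "lr", lr_feature = "max_theta"),
    fr_svm_coarse = model_spec("fill_ratio", "svm", kernel = "coarse")
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d drinks, %d model(s)\n",
              nrow(x$features), length(x$reports)))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-18s pooled MAPE %6.2f%%  sd %6.2f%%\n",
                nm, r$pooled_mape, r$mape_sd))
  }
  invisible(x)
}

#' Correlation of motion features with drink volume across fill-level tiers
#'
#' Reproduces the standard diagnostic: Pearson correlations of the
#' micro-event durations (whole data), and of sip duration and
#' integral-of-inclination with volume within nested fill-ratio
#' restrictions.
#'
#' @param data Labelled feature table (see [join_labels()]).
#' @param tiers Lower fill-ratio bounds for the nested restrictions
#'   (default `c(0, 0.5, 0.7, 0.9)`; 0 is the whole dataset).
#' @return List with `durations` (tibble of duration–volume correlations)
#'   and `tiers` (tibble of per-tier correlations for sip duration and sip
#'   integral, with the tier sample size).
#' @export
correlation_analysis <- function(data, tiers = c(0, 0.5, 0.7, 0.9)) {
  durations <- tibble(
    feature = c("dur_lift", "dur_sip", "dur_place"),
    correlation = vapply(c("dur_lift", "dur_sip", "dur_place"),
                         function(f) cor(data[[f]], data$mass_g), numeric(1))
  )
  tier_tab <- purrr::map_dfr(tiers, function(lo) {
    sub <- data[data$fill_ratio_pre > lo, ]
    tibble(fr_min = lo, n = nrow(sub),
           sip_duration = cor(sub$sip_duration, sub$mass_g),
           integral_theta = cor(sub$integral_theta, sub$mass_g))
  })
  list(durations = durations, tiers = tier_tab)
}
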