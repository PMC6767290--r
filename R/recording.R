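#' Construct a recording of one experimental trial
#'
#' A recording is a tibble of timestamped triaxial accelerometer samples in
#' units of g, with trial metadata stored as attributes. The sensor frame is
#' aligned with the bottle: `ax` along the bottle's vertical axis (reads +1 g
#' when the bottle stands upright and still), `ay` tangential and `az` normal
#' to the bottle surface.
#'
#' @param samples Data frame with numeric columns `t` (seconds, strictly
#'   increasing), `ax`, `ay`, `az` (g).
#' @param trial_id Trial identifier (scalar character or coercible).
#' @param subject_id Subject identifier.
#' @param nominal_rate Nominal sampling rate in Hz. If `NULL`, inferred as the
#'   reciprocal of the median inter-sample interval.
#' @param exclusions Optional data frame with columns `t_start`, `t_end`
#'   giving half-open `[t_start, t_end)` intervals to drop during
#'   conditioning (stand-in for proctor-noted protocol variations).
#' @param min_samples Minimum number of samples required (the bias estimator
#'   needs an initial stationary stretch); default 50.
#'
#' @return A tibble of class `sip_recording` with columns `t, ax, ay, az` and
#'   attributes `trial_id`, `subject_id`, `nominal_rate`, `exclusions`.
#' @export
#' @examples
#' rec <- recording(
#'   data.frame(t = seq(0, 2.5, by = 0.05), ax = 1, ay = 0, az = 0),
#'   trial_id = "T1", subject_id = "S1"
#' )
#' attr(rec, "nominal_rate")
recording <- function(samples, trial_id, subject_id = NA_character_,
                      nominal_rate = NULL, exclusions = NULL,
                      min_samples = 50L) {
  required <- c("t", "ax", "ay", "az")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("recording is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "sipsense_format_error")
  }
  samples <- as_tibble(samples)[required]
  if (nrow(samples) < min_samples) {
    abort(sprintf("recording has %d samples; at least %d are required",
                  nrow(samples), min_samples),
          class = "sipsense_validation_error")
  }
  if (!all(vapply(samples, is.numeric, logical(1)))) {
    abort("t, ax, ay, az must all be numeric", class = "sipsense_format_error")
  }
  if (anyNA(samples) || !all(vapply(samples, function(x) all(is.finite(x)), logical(1)))) {
    abort("recording contains non-finite values", class = "sipsense_validation_error")
  }
  bad <- which(diff(samples$t) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("timestamps must be strictly increasing; first violation at row %d",
                  bad[1] + 1L),
          class = "sipsense_validation_error")
  }
  mag <- sqrt(samples$ax^2 + samples$ay^2 + samples$az^2)
  if (any(mag > 8)) {
    warn("acceleration magnitude exceeds 8 g for some samples (sensor range guard)")
  }
  if (is.null(nominal_rate)) {
    nominal_rate <- 1 / stats::median(diff(samples$t))
  }
  if (!is.null(exclusions)) {
    stopifnot(all(c("t_start", "t_end") %in% names(exclusions)))
    exclusions <- as_tibble(exclusions)[c("t_start", "t_end")]
  }
  structure(samples,
            trial_id = as.character(trial_id),
            subject_id = as.character(subject_id),
            nominal_rate = nominal_rate,
            exclusions = exclusions,
            class = c("sip_recording", class(samples)))
}

#' @export
print.sip_recording <- function(x, ...) {
  cat(sprintf("<sip_recording> trial %s, subject %s, %d samples @ %.3g Hz nominal\n",
              attr(x, "trial_id"), attr(x, "subject_id"),
              nrow(x), attr(x, "nominal_rate")))
  NextMethod()
}

#' Read a trial trace from CSV
#'
#' Expects a header row with columns `t,ax,ay,az` (seconds and g). An optional
#' sidecar JSON file `<path>.exclusions.json` holding an array of
#' `{"t_start": ..., "t_end": ...}` objects is picked up automatically and
#' attached as exclusion intervals (applied later, during conditioning — rows
#' inside exclusions are retained here).
#'
#' @param path Path to the trace CSV.
#' @param trial_id,subject_id Identifiers; `trial_id` defaults to the file
#'   name without extension.
#' @param exclusions Optional exclusions data frame overriding the sidecar.
#' @return A [recording()].
#' @export
read_recording <- function(path, trial_id = NULL, subject_id = NA_character_,
                           exclusions = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "sipsense_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(trial_id)) {
    trial_id <- tools::file_path_sans_ext(basename(path))
  }
  if (is.null(exclusions)) {
    sidecar <- paste0(path, ".exclusions.json")
    if (file.exists(sidecar)) {
      ex <- jsonlite::fromJSON(sidecar)
      if (length(ex) > 0) exclusions <- as_tibble(ex)
    }
  }
  recording(df, trial_id = trial_id, subject_id = subject_id,
            exclusions = exclusions)
}

#' Write a trial trace to CSV
#'
#' Full double precision is preserved so that a write/read cycle reproduces
#' the recording within 1e-9 g. Exclusion intervals, if any, go to a sidecar
#' JSON next to the CSV.
#'
#' @param rec A [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sip_recording"))
  df <- as_tibble(rec)[c("t", "ax", "ay", "az")]
  out <- tryCatch(
    readr::write_csv(df, path, progress = FALSE),
    error = function(e) abort(paste0("cannot write ", path, ": ", conditionMessage(e)),
                              class = "sipsense_io_error")
  )
  ex <- attr(rec, "exclusions")
  if (!is.null(ex) && nrow(ex) > 0) {
    jsonlite::write_json(ex, paste0(path, ".exclusions.json"), digits = NA)
  }
  invisible(path)
}

#' Read per-drink ground-truth labels
#'
#' The label file has one row per drink with columns `trial_id`,
#' `drink_index` (1-based order within trial), `mass_g` (scale ground truth;
#' water density 1 g/mL makes this interchangeable with volume in mL) and
#' `fill_ratio_pre` (fill ratio at drink initiation, in `[0, 1]`).
#'
#' Output is grouped and sorted by `(trial_id, drink_index)` regardless of
#' file row order. A fill ratio that increases with drink index within a
#' trial is physically impossible under the protocol and triggers a warning
#' naming the trial.
#'
#' @param path Path to the label CSV.
#' @return Tibble sorted by `(trial_id, drink_index)`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "sipsense_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_labels(df)
}

#' @rdname read_labels
#' @param labels A data frame of labels to validate and sort.
#' @export
validate_labels <- function(labels) {
  required <- c("trial_id", "drink_index", "mass_g", "fill_ratio_pre")
  missing_cols <- setdiff(required, names(labels))
  if (length(missing_cols) > 0) {
    abort(paste0("label table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "sipsense_format_error")
  }
  labels <- as_tibble(labels)
  labels$trial_id <- as.character(labels$trial_id)
  if (any(labels$mass_g <= 0)) {
    abort("mass_g must be positive", class = "sipsense_validation_error")
  }
  if (any(labels$fill_ratio_pre < 0 | labels$fill_ratio_pre > 1)) {
    abort("fill_ratio_pre must lie in [0, 1]", class = "sipsense_validation_error")
  }
  labels <- dplyr::arrange(labels, .data$trial_id, .data$drink_index)
  bad <- labels |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(increasing = any(diff(.data$fill_ratio_pre) > 0),
                     .groups = "drop") |>
    dplyr::filter(.data$increasing)
  if (nrow(bad) > 0) {
    warn(paste0("fill_ratio_pre increases within trial(s): ",
                paste(bad$trial_id, collapse = ", ")))
  }
  labels
}

#' Write per-drink labels to CSV
#'
#' @param labels Label tibble (see [read_labels()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  labels <- validate_labels(labels)
  readr::write_csv(labels, path, progress = FALSE)
  invisible(path)
}

#' Container geometry
#'
#' `beta_ml` is the container-specific linear density parameter: the volume
#' in mL released per unit drop in fill ratio. For a cylinder-like bottle it
#' equals the capacity.
#'
#' @param beta_ml mL per unit fill ratio; must be positive.
#' @param capacity_ml Bottle capacity in mL.
#' @return A list of class `container_geometry`.
#' @export
container_geometry <- function(beta_ml = 750, capacity_ml = 750) {
  stopifnot(beta_ml > 0, capacity_ml > 0)
  structure(list(beta_ml = beta_ml, capacity_ml = capacity_ml),
            class = "container_geometry")
}
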