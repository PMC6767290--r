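#' Configuration of the scripted drinking-trial simulator
#'
#' The simulator emulates the study design the pipeline targets: each trial
#' is 12 scripted drinks from a 750 mL bottle starting full, with the bottle
#' resting on the table between drinks. Drink volumes are drawn from a
#' small/medium/large mixture (right-skewed), so pre-drink fill ratios pool
#' into a distribution skewed toward high values (every trial contributes a
#' first drink at fill ratio 1 and later drinks fan out downward).
#'
#' Kinematics follow two laws, both configurable:
#' * tilt law — the maximum inclination of drink `k` is
#'   `theta_base + theta_span * (1 - FR_post) * tilt_k`, rising as the
#'   bottle empties (more tilt is needed to reach the liquid);
#' * duration law — the sip lasts
#'   `(d0 + d_per_ml * v) * (1 + d_fr * (1 - FR_pre)) * dur_k` seconds:
#'   affine in volume, and slowed at low fill levels where the steeper tilt
#'   makes the pour slower. The fill-level factor is what couples volume and
#'   fill level in the motion signature; restricting analysis to narrow
#'   fill-level bands removes it and strengthens the duration–volume
#'   correlation.
#'
#' `tilt_k`/`dur_k` are per-subject multiplicative random effects
#' (log-normal), standing in for biomechanic differences across
#' individuals. The sip tilt trajectory is a raised-cosine envelope rising
#' to the maximum (continuing the lift, so the inclination never pauses
#' mid-air) with a small half-rectified sway dipping below it — drinkers do
#' not hold a bottle perfectly still; transport phases carry a
#' fast axial wobble so the cross-sectional angle is only stationary during
#' the sip. Accelerometer components are reconstructed gravity-only
#' (`ax = cos(theta)`, `ay = sin(theta) cos(alpha)`,
#' `az = sin(theta) sin(alpha)`) plus per-axis white noise, a per-trial
#' constant bias, and timestamp jitter emulating the base-station polling
#' variability.
#'
#' @param n_subjects,trials_per_subject Cohort size (default 40 x 1).
#' @param drinks_per_trial Scripted drinks per trial (default 12).
#' @param capacity_ml,beta_ml Bottle capacity and linear density (mL).
#' @param rate_hz Sampling rate (default 20).
#' @param theta_base,theta_span Tilt law, degrees (defaults 30, 60).
#' @param d0,d_per_ml,d_fr Duration law: intercept (s), slope (s/mL), and
#'   fill-level slowdown factor (defaults 1, 0.05, 1).
#' @param dur_noise_sd Additive sip-duration noise, seconds.
#' @param vol_p,vol_mean,vol_sd Small/medium/large volume mixture: component
#'   probabilities, means and sds in mL.
#' @param vol_min Floor on drawn volumes (mL).
#' @param accel_noise_sd Per-axis accelerometer noise sd, g.
#' @param bias_sd Sd of the per-trial constant sensor bias, g.
#' @param time_jitter_s Half-width of uniform timestamp jitter, seconds.
#' @param subject_tilt_sd,subject_dur_sd,subject_noise_sd Log-scale sds of
#'   the per-subject random effects.
#' @param lift_s,place_s,still_s,initial_still_s Transport/rest durations
#'   (s); the initial stillness must cover the 50-sample bias window.
#' @param transport_noise_sd Relative per-drink jitter on transport durations.
#' @param rise_frac Fraction of the sip spent rising to the maximum.
#' @param sway_deg,sway_hz Amplitude (one-sided, dipping below the
#'   envelope) and frequency of the sip-phase sway.
#' @param axial_wobble_deg,axial_wobble_hz Transport-phase axial wobble.
#' @param seed Master seed; each trial gets an independent substream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 40L, trials_per_subject = 1L,
                       drinks_per_trial = 12L,
                       capacity_ml = 750, beta_ml = capacity_ml,
                       rate_hz = 20,
                       theta_base = 30, theta_span = 60,
                       d0 = 1, d_per_ml = 0.05, d_fr = 1,
                       dur_noise_sd = 0.1,
                       vol_p = c(0.50, 0.30, 0.20),
                       vol_mean = c(15, 35, 70),
                       vol_sd = c(4, 8, 20),
                       vol_min = 5,
                       accel_noise_sd = 0.01,
                       bias_sd = 0.005,
                       time_jitter_s = 0.005,
                       subject_tilt_sd = 0.05,
                       subject_dur_sd = 0.18,
                       subject_noise_sd = 0.20,
                       lift_s = 1.5, place_s = 1.5,
                       still_s = 3, initial_still_s = 4,
                       transport_noise_sd = 0.15,
                       rise_frac = 0.3,
                       sway_deg = 8, sway_hz = 2.5,
                       axial_wobble_deg = 30, axial_wobble_hz = 3,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(drinks_per_trial >= 1, capacity_ml > 0, rate_hz > 0,
            length(vol_p) == length(vol_mean),
            length(vol_p) == length(vol_sd),
            abs(sum(vol_p) - 1) < 1e-9,
            initial_still_s * rate_hz >= 50)
  structure(cfg, class = "sim_config")
}

#' Zero out the stochastic nuisance terms of a simulator configuration
#'
#' Keeps the scripted structure and the random drink volumes but removes
#' accelerometer noise, sensor bias, timestamp jitter, duration noise and
#' inter-subject random effects — the regime in which the pipeline should
#' recover the generating laws exactly.
#'
#' @param cfg A [sim_config()].
#' @return The modified config.
#' @export
zero_noise <- function(cfg) {
  cfg$accel_noise_sd <- 0
  cfg$bias_sd <- 0
  cfg$time_jitter_s <- 0
  cfg$dur_noise_sd <- 0
  cfg$transport_noise_sd <- 0
  cfg$subject_tilt_sd <- 0
  cfg$subject_dur_sd <- 0
  cfg$subject_noise_sd <- 0
  cfg
}

#' Draw a subject's biomechanic profile
#'
#' @param cfg A [sim_config()].
#' @return List with positive multipliers `tilt`, `dur`, `noise`.
#' @export
subject_profile <- function(cfg) {
  list(tilt = exp(rnorm(1, 0, cfg$subject_tilt_sd)),
       dur = exp(rnorm(1, 0, cfg$subject_dur_sd)),
       noise = exp(rnorm(1, 0, cfg$subject_noise_sd)))
}

raised_cosine <- function(from, to, n) {
  if (n <= 0) return(numeric(0))
  s <- (1 - cos(pi * seq_len(n) / n)) / 2
  from + (to - from) * s
}

draw_volumes <- function(cfg) {
  k <- cfg$drinks_per_trial
  comp <- sample.int(length(cfg$vol_p), k, replace = TRUE, prob = cfg$vol_p)
  v <- pmax(cfg$vol_min, rnorm(k, cfg$vol_mean[comp], cfg$vol_sd[comp]))
  if (sum(v) > cfg$capacity_ml) {
    warn("drawn volumes exceed capacity; rescaling trial")
    v <- v * cfg$capacity_ml / sum(v)
  }
  v
}

#' Simulate one scripted drinking trial
#'
#' Generates the raw accelerometer trace and per-drink ground-truth labels
#' for one trial under the current RNG state (use [simulate_cohort()] for
#' seeded multi-trial generation).
#'
#' @param cfg A [sim_config()].
#' @param profile A [subject_profile()] (identity multipliers by default).
#' @param trial_id,subject_id Identifiers stamped on the outputs.
#' @return List with elements `recording` (a [recording()]) and `labels`
#'   (tibble with `trial_id`, `drink_index`, `mass_g`, `fill_ratio_pre`,
#'   plus `fill_ratio_post` for convenience).
#' @export
simulate_trial <- function(cfg, profile = list(tilt = 1, dur = 1, noise = 1),
                           trial_id = "T1", subject_id = "S1") {
  dt <- 1 / cfg$rate_hz
  v <- draw_volumes(cfg)
  fr_pre <- 1 - c(0, cumsum(v[-length(v)])) / cfg$capacity_ml
  fr_post <- fr_pre - v / cfg$capacity_ml

  theta_seg <- list()
  alpha_seg <- list()
  add <- function(theta, alpha) {
    theta_seg[[length(theta_seg) + 1L]] <<- theta
    alpha_seg[[length(alpha_seg) + 1L]] <<- alpha
  }
  nsamp <- function(dur) max(1L, as.integer(round(dur / dt)))

  still <- function(dur) add(rep(0, nsamp(dur)), rep(0, nsamp(dur)))
  wobble <- function(n, target) {
    # fast axial wobble with an envelope vanishing at both ends, so alpha
    # lands exactly on `target` and the per-sample step exceeds the sip
    # compliance threshold through most of the transport
    tt <- seq_len(n) * dt
    env <- sin(pi * seq_len(n) / (n + 1))^2
    target + cfg$axial_wobble_deg * sin(2 * pi * cfg$axial_wobble_hz * tt) * env
  }

  still(cfg$initial_still_s)
  for (k in seq_along(v)) {
    theta_max <- min(170, cfg$theta_base +
                       cfg$theta_span * (1 - fr_post[k]) * profile$tilt)
    dur_sip <- (cfg$d0 + cfg$d_per_ml * v[k]) *
      (1 + cfg$d_fr * (1 - fr_pre[k])) * profile$dur +
      rnorm(1, 0, cfg$dur_noise_sd)
    dur_sip <- max(dur_sip, 1)
    alpha_sip <- runif(1, -180, 180)

    jit <- function(x) x * (1 + rnorm(1, 0, cfg$transport_noise_sd))
    n_lift <- nsamp(jit(cfg$lift_s))
    n_rise <- nsamp(cfg$rise_frac * dur_sip)
    n_hold <- max(12L, nsamp(dur_sip) - n_rise)
    # the lift flows continuously into the tilt-up: one raised cosine spans
    # both, so the inclination never pauses mid-air (the axial wobble stops
    # at the lift/sip boundary, which is what defines the sip)
    theta_up <- raised_cosine(0, theta_max, n_lift + n_rise)
    add(theta_up[seq_len(n_lift)], wobble(n_lift, alpha_sip))
    # half-rectified sway: one-sided dips below the envelope whose flat tops
    # leave theta_max attained over runs of samples (so smoothing preserves
    # it) while keeping the hold visibly non-stationary
    env <- c(theta_up[n_lift + seq_len(n_rise)], rep(theta_max, n_hold))
    tt_sip <- seq_len(n_rise + n_hold) * dt
    dip <- cfg$sway_deg * pmax(0, sin(2 * pi * cfg$sway_hz * tt_sip))
    theta_sip <- pmax(0, env - dip)
    add(theta_sip, rep(alpha_sip, length(theta_sip)))

    n_place <- nsamp(jit(cfg$place_s))
    alpha_rest <- runif(1, -180, 180)
    add(raised_cosine(tail(theta_sip, 1), 0, n_place),
        wobble(n_place, alpha_rest))
    still(cfg$still_s)
  }

  theta <- unlist(theta_seg) * pi / 180
  alpha <- unlist(alpha_seg) * pi / 180
  n <- length(theta)
  noise_sd <- cfg$accel_noise_sd * profile$noise
  bias <- rnorm(3, 0, cfg$bias_sd)
  t_grid <- (seq_len(n) - 1L) * dt
  if (cfg$time_jitter_s > 0) {
    t_grid <- t_grid + runif(n, -cfg$time_jitter_s, cfg$time_jitter_s)
    t_grid[1] <- max(t_grid[1], 0)
  }
  samples <- tibble(
    t = t_grid,
    ax = cos(theta) + bias[1] + rnorm(n, 0, noise_sd),
    ay = sin(theta) * cos(alpha) + bias[2] + rnorm(n, 0, noise_sd),
    az = sin(theta) * sin(alpha) + bias[3] + rnorm(n, 0, noise_sd)
  )
  labels <- tibble(trial_id = trial_id,
                   drink_index = seq_along(v),
                   mass_g = v,
                   fill_ratio_pre = fr_pre,
                   fill_ratio_post = fr_post)
  list(recording = recording(samples, trial_id = trial_id,
                             subject_id = subject_id,
                             nominal_rate = cfg$rate_hz),
       labels = labels)
}

#' Simulate a full cohort in memory
#'
#' Draws one independent, named random substream per trial from the master
#' seed, so any trial can be regenerated in isolation and generation order
#' does not matter.
#'
#' @param cfg A [sim_config()].
#' @return List with `recordings` (named list of [recording()]s), `labels`
#'   (row-bound label tibble) and `config` (the config used).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  n_trials <- cfg$n_subjects * cfg$trials_per_subject
  set.seed(cfg$seed)
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)
  subject_seeds <- sample.int(.Machine$integer.max, cfg$n_subjects)

  recordings <- list()
  labels <- list()
  i <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    set.seed(subject_seeds[s])
    prof <- subject_profile(cfg)
    for (r in seq_len(cfg$trials_per_subject)) {
      i <- i + 1L
      trial_id <- sprintf("S%03d_T%d", s, r)
      set.seed(trial_seeds[i])
      sim <- simulate_trial(cfg, prof, trial_id = trial_id,
                            subject_id = sprintf("S%03d", s))
      recordings[[trial_id]] <- sim$recording
      labels[[trial_id]] <- sim$labels
    }
  }
  list(recordings = recordings,
       labels = dplyr::bind_rows(labels),
       config = cfg)
}

#' Write a simulated dataset to disk
#'
#' One trace CSV per trial, one label CSV for the dataset, and a
#' `manifest.json` recording the full configuration and seed, so the
#' dataset is reproducible byte for byte.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param force Overwrite a non-empty directory.
#' @return `dir`, invisibly.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(paste0("directory not empty: ", dir, " (use force = TRUE)"),
          class = "sipsense_io_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(cfg)
  for (id in names(cohort$recordings)) {
    write_recording(cohort$recordings[[id]], file.path(dir, paste0(id, ".csv")))
  }
  write_labels(cohort$labels, file.path(dir, "labels.csv"))
  jsonlite::write_json(list(config = unclass(cfg),
                            n_trials = length(cohort$recordings),
                            trial_ids = names(cohort$recordings)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
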