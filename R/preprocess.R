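#' Estimate per-axis accelerometer bias from the initial stationary stretch
#'
#' The trial protocol starts with the bottle standing upright and still, so
#' the first `n_init` samples should read (1, 0, 0) g. The bias is the mean
#' deviation from that reading: `bx = mean(ax) - 1`, `by = mean(ay)`,
#' `bz = mean(az)`. Defining the x offset relative to +1 g keeps gravity in
#' the corrected signal, which the inclination estimate relies on.
#'
#' @param rec A [recording()].
#' @param n_init Number of initial samples to average (default 50).
#' @return A list of class `bias_estimate` with elements `bx`, `by`, `bz` (g).
#' @export
estimate_bias <- function(rec, n_init = 50L) {
  if (nrow(rec) < n_init) {
    abort(sprintf("recording has %d samples; bias estimation needs %d",
                  nrow(rec), n_init),
          class = "sipsense_validation_error")
  }
  idx <- seq_len(n_init)
  b <- list(bx = mean(rec$ax[idx]) - 1,
            by = mean(rec$ay[idx]),
            bz = mean(rec$az[idx]))
  if (any(abs(unlist(b)) >= 0.5)) {
    warn("estimated bias exceeds 0.5 g; was the bottle stationary and upright?")
  }
  structure(b, class = "bias_estimate")
}

causal_ma <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(x)
  y <- numeric(n)
  # partial windows at the head (y[1] = x[1] for the two-sample filter)
  head_n <- min(window - 1L, n)
  y[seq_len(head_n)] <- cs[seq_len(head_n)] / seq_len(head_n)
  if (n >= window) {
    i <- window:n
    y[i] <- (cs[i] - c(0, cs)[i - window + 1L]) / window
  }
  y
}

#' Condition a raw recording
#'
#' Applies, in order: per-axis bias subtraction; removal of samples inside
#' exclusion intervals; resampling by linear interpolation onto a uniform
#' `1/target_rate` grid spanning the recording (the base station polls at a
#' slightly variable interval, so raw timestamps are only approximately
#' uniform); a causal two-sample moving average
#' `y[n] = (x[n] + x[n-1]) / 2` (with `y[1] = x[1]`) per axis.
#'
#' @param rec A [recording()].
#' @param bias A `bias_estimate` (see [estimate_bias()]); `NULL` estimates it
#'   from `rec` first.
#' @param target_rate Target uniform rate in Hz (default 20).
#' @param ma_window Moving-average length in samples (default 2).
#' @return A tibble of class `sip_conditioned` with columns `t, ax, ay, az`
#'   on the uniform grid; attributes carry the trial metadata, the rate and
#'   the conditioning provenance.
#' @export
condition <- function(rec, bias = NULL, target_rate = 20, ma_window = 2L) {
  stopifnot(target_rate > 0, ma_window >= 1L)
  if (is.null(bias)) bias <- estimate_bias(rec)
  df <- tibble(t = rec$t,
               ax = rec$ax - bias$bx,
               ay = rec$ay - bias$by,
               az = rec$az - bias$bz)
  ex <- attr(rec, "exclusions")
  if (!is.null(ex) && nrow(ex) > 0) {
    drop <- rep(FALSE, nrow(df))
    for (i in seq_len(nrow(ex))) {
      drop <- drop | (df$t >= ex$t_start[i] & df$t < ex$t_end[i])
    }
    df <- df[!drop, ]
  }
  if (nrow(df) < 2) {
    abort("fewer than 2 samples remain after exclusions",
          class = "sipsense_validation_error")
  }
  dt <- 1 / target_rate
  grid <- seq(df$t[1], df$t[nrow(df)], by = dt)
  out <- tibble(
    t = grid,
    ax = approx(df$t, df$ax, xout = grid, rule = 2)$y,
    ay = approx(df$t, df$ay, xout = grid, rule = 2)$y,
    az = approx(df$t, df$az, xout = grid, rule = 2)$y
  )
  out$ax <- causal_ma(out$ax, ma_window)
  out$ay <- causal_ma(out$ay, ma_window)
  out$az <- causal_ma(out$az, ma_window)
  structure(out,
            trial_id = attr(rec, "trial_id"),
            subject_id = attr(rec, "subject_id"),
            rate = target_rate,
            conditioning = list(bias = unclass(bias), ma_window = ma_window,
                                excluded = !is.null(ex) && nrow(ex) > 0),
            class = c("sip_conditioned", class(out)))
}

angle_carry_forward <- function(values, defined, init = 0) {
  n <- length(values)
  out <- values
  prev <- init
  for (i in seq_len(n)) {
    if (defined[i]) prev <- out[i] else out[i] <- prev
  }
  out
}

#' Estimate container inclination from static acceleration
#'
#' Under negligible dynamic acceleration the gravity vector dominates the
#' accelerometer reading, and the inclination of the bottle's vertical axis
#' with respect to gravity is
#' `theta = atan2(sqrt(ay^2 + az^2), ax)` (degrees, in `[0, 180]`).
#' The four-quadrant form keeps upside-down orientations (`ax < 0`) on the
#' `(90, 180]` branch. When both arguments fall below `eps` in magnitude the
#' angle is undefined and the previous value is carried forward (0 at the
#' first sample).
#'
#' @param rec A conditioned recording (see [condition()]), or any data frame
#'   with `ax, ay, az` columns.
#' @param eps Degeneracy guard in g (default 1e-6).
#' @return The input with a `theta` column (degrees) appended, so calls
#'   chain: `cond |> compute_inclination() |> compute_axial_angle()`.
#' @export
compute_inclination <- function(rec, eps = 1e-6) {
  rho <- sqrt(rec$ay^2 + rec$az^2)
  theta <- atan2(rho, rec$ax) * 180 / pi
  defined <- !(rho < eps & abs(rec$ax) < eps)
  rec$theta <- angle_carry_forward(theta, defined, init = 0)
  rec
}

#' Estimate the sensor's angular position in the bottle's cross-sectional plane
#'
#' `alpha = atan2(az, ay)` in degrees, range `(-180, 180]`. Rotations of the
#' bottle about its own vertical axis show up as changes in `alpha`; during a
#' sip the drinker avoids such rotations (spilling), so `alpha` is stationary
#' there — the property the micro-event partition exploits. Near the upright
#' orientation (`sqrt(ay^2 + az^2) < eps`) the angle is undefined and the
#' previous defined value is carried forward (0 if none yet).
#'
#' @inheritParams compute_inclination
#' @return The input with an `alpha` column (degrees) appended.
#' @export
compute_axial_angle <- function(rec, eps = 1e-6) {
  rho <- sqrt(rec$ay^2 + rec$az^2)
  alpha <- atan2(rec$az, rec$ay) * 180 / pi
  rec$alpha <- angle_carry_forward(alpha, rho >= eps, init = 0)
  rec
}
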