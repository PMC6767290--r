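const_recording <- function(ax, ay, az, n = 100, rate = 20, ...) {
  recording(tibble::tibble(t = (seq_len(n) - 1) / rate,
                           ax = ax, ay = ay, az = az), trial_id = "T1", ...)
}

test_that("bias estimation averages the initial stationary samples", {
  rec <- const_recording(1.00, 0.00, 0.00)
  b <- estimate_bias(rec)
  expect_equal(unclass(b), list(bx = 0, by = 0, bz = 0))

  rec <- const_recording(1.02, 0.01, -0.03)
  b <- estimate_bias(rec)
  expect_equal(b$bx, 0.02)
  expect_equal(b$by, 0.01)
  expect_equal(b$bz, -0.03)

  # alternating ay in {0.02, 0.04} -> arithmetic mean 0.03
  df <- tibble::tibble(t = (0:99) / 20, ax = 1,
                       ay = rep(c(0.02, 0.04), 50), az = 0)
  b <- estimate_bias(recording(df, "T1"))
  expect_equal(b$by, 0.03)

  expect_error(estimate_bias(const_recording(1, 0, 0, n = 50), n_init = 60),
               class = "sipsense_validation_error")
})

test_that("conditioning preserves constants and has the MA(2) impulse response", {
  rec <- const_recording(0.8, 0.1, -0.2, n = 200)
  cond <- condition(rec, bias = structure(list(bx = 0, by = 0, bz = 0),
                                          class = "bias_estimate"))
  expect_equal(diff(cond$t), rep(0.05, nrow(cond) - 1))
  expect_true(all(abs(cond$ax - 0.8) < 1e-12))
  expect_true(all(abs(cond$ay - 0.1) < 1e-12))

  # unit impulse on ay at a grid node -> 0.5 at that node and the next
  df <- tibble::tibble(t = (0:99) / 20, ax = 1, ay = 0, az = 0)
  df$ay[50] <- 1
  cond <- condition(recording(df, "T1"),
                    bias = structure(list(bx = 0, by = 0, bz = 0),
                                     class = "bias_estimate"))
  expect_equal(cond$ay[49:52], c(0, 0.5, 0.5, 0))
})

test_that("linear resampling is exact on affine signals under timestamp jitter", {
  set.seed(21)
  t <- (0:199) / 20 + runif(200, -0.01, 0.01)
  t <- sort(t); t <- t + seq_along(t) * 1e-9
  df <- tibble::tibble(t = t, ax = 1, ay = 0.4 * t - 2, az = 0)  # ay affine in t
  cond <- condition(recording(df, "T1"),
                    bias = structure(list(bx = 0, by = 0, bz = 0),
                                     class = "bias_estimate"),
                    ma_window = 1L)
  inside <- cond$t >= t[1] & cond$t <= t[length(t)]
  expect_true(max(abs(cond$ay[inside] - (0.4 * cond$t[inside] - 2))) < 1e-9)
})

test_that("resampling at the same rate is idempotent", {
  set.seed(5)
  df <- tibble::tibble(t = (0:199) / 20, ax = rnorm(200, 1, 0.1),
                       ay = rnorm(200), az = rnorm(200))
  zero_bias <- structure(list(bx = 0, by = 0, bz = 0), class = "bias_estimate")
  once <- condition(recording(df, "T1"), bias = zero_bias, ma_window = 1L)
  again <- condition(recording(as.data.frame(once), "T1"),
                     bias = zero_bias, ma_window = 1L)
  expect_true(max(abs(again$ay - once$ay)) < 1e-9)
})

test_that("exclusion intervals are removed during conditioning", {
  df <- tibble::tibble(t = (0:199) / 20, ax = 1, ay = 0, az = 0)
  df$ay[df$t >= 3 & df$t < 4] <- 5  # contamination inside the exclusion
  rec <- recording(df, "T1", exclusions = tibble::tibble(t_start = 3, t_end = 4))
  cond <- condition(rec, bias = structure(list(bx = 0, by = 0, bz = 0),
                                          class = "bias_estimate"))
  # interpolation bridges the gap between clean neighbours, so the
  # contaminated plateau never reaches the conditioned signal
  expect_true(max(abs(cond$ay)) < 1e-9)
})

test_that("inclination and axial angle match hand trigonometry", {
  cond <- make_conditioned(ax = c(1, 0, 0.7071, 0, -1),
                           ay = c(0, 0.6, 0.5, 0, 0),
                           az = c(0, 0.8, 0.5, 1, 0))
  theta <- compute_inclination(cond)$theta
  expect_equal(theta[1], 0)
  expect_equal(theta[2], 90)
  expect_equal(theta[3], 45, tolerance = 1e-4)
  expect_equal(theta[5], 180)

  alpha <- compute_axial_angle(cond)$alpha
  expect_equal(alpha[2], atan2(0.8, 0.6) * 180 / pi)
  expect_equal(alpha[3], 45)
  expect_equal(alpha[4], 90)
})

test_that("degenerate angle inputs carry the previous value forward", {
  cond <- make_conditioned(ax = c(0.5, 0, 0.5), ay = c(0.5, 0, 0), az = 0)
  theta <- compute_inclination(cond)$theta
  expect_equal(theta[2], theta[1])  # both arguments below eps
  expect_equal(theta[3], 0)

  # alpha undefined while upright: holds last defined value, 0 if none
  cond2 <- make_conditioned(ax = c(1, 1, 0.5, 1), ay = c(0, 0, 0.5, 0),
                            az = c(0, 0, 0.5, 0))
  alpha <- compute_axial_angle(cond2)$alpha
  expect_equal(alpha[1:2], c(0, 0))
  expect_equal(alpha[3], 45)
  expect_equal(alpha[4], 45)
})

test_that("inclination is invariant to rotations within the cross-sectional plane", {
  set.seed(9)
  n <- 200
  ax <- runif(n, -1, 1); ay <- runif(n, -1, 1); az <- runif(n, -1, 1)
  phi <- runif(1, 0, 2 * pi)
  base <- compute_inclination(make_conditioned(ax, ay, az))$theta
  rot <- compute_inclination(make_conditioned(
    ax,
    cos(phi) * ay - sin(phi) * az,
    sin(phi) * ay + cos(phi) * az))$theta
  expect_equal(rot, base, tolerance = 1e-9)
})
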