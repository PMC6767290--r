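test_that("MAPE matches hand arithmetic", {
  expect_equal(mape(c(110, 80), c(100, 100)), 15)
  expect_equal(mape(50, 100), 50)
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(mape(c(1, 2), c(1, 0)), class = "sipsense_validation_error")
  expect_error(mape(1, c(1, 2)))
})

test_that("OAPE aggregates before scoring, so signed errors cancel", {
  truth <- c(100, 100)
  pred <- c(120, 80)           # +20 and -20
  expect_equal(oape(pred, truth), 0)
  expect_equal(mape(pred, truth), 20)
  expect_equal(oape(pred, truth, n = 1), 20)
  expect_equal(oape(c(55, 55), c(50, 50)), 10)
})

test_that("OAPE never exceeds the largest APE when errors share a sign", {
  set.seed(23)
  for (i in 1:50) {
    truth <- runif(8, 20, 80)
    err <- abs(rnorm(8, 0, 10))
    pred <- truth + err          # all over-estimates
    apes <- 100 * err / truth
    expect_lte(oape(pred, truth), max(apes) + 1e-12)
    expect_gte(oape(pred, truth), min(apes) - 1e-12)
  }
})

test_that("MOAPE averages per-trial OAPEs and skips short trials", {
  results <- tibble::tibble(
    trial_id = rep(c("A", "B"), each = 2),
    drink_index = rep(1:2, 2),
    pred = c(120, 80, 55, 55),
    truth = c(100, 100, 50, 50))
  expect_equal(moape(results, 2), mean(c(0, 10)))
  # moape at n = 1 on one-drink prefixes equals per-drink APE of drink 1
  expect_equal(moape(results, 1), mean(c(20, 10)))

  short <- dplyr::bind_rows(results,
                            tibble::tibble(trial_id = "C", drink_index = 1,
                                           pred = 60, truth = 50))
  expect_warning(m <- moape(short, 2), "fewer than 2")
  expect_equal(m, mean(c(0, 10)))
})

test_that("moape(n = 1) equals the MAPE of the first drinks", {
  set.seed(41)
  results <- tibble::tibble(
    trial_id = rep(paste0("T", 1:6), each = 4),
    drink_index = rep(1:4, 6),
    pred = runif(24, 10, 90),
    truth = runif(24, 10, 90))
  first <- results[results$drink_index == 1, ]
  expect_equal(moape(results, 1), mape(first$pred, first$truth))
})

test_that("residual volume estimate follows the container's linear density", {
  geom <- container_geometry(beta_ml = 750)
  expect_equal(residual_volume_estimate(1, 0.6, geom), 300)
  expect_equal(residual_volume_estimate(0.5, 0.5, geom), 0)
  expect_equal(residual_volume_estimate(1, 0, container_geometry(beta_ml = 500)),
               500)
  expect_warning(residual_volume_estimate(0.4, 0.6, geom), "negative")
  expect_error(residual_volume_estimate(1.2, 0.5, geom))
})

test_that("OAPE distortion of a fill-ratio error matches the closed form", {
  expect_equal(oape_distortion(0.05, 0.9), 0.5)
  expect_equal(oape_distortion(0.05, 0), 0.05)   # emptied container: no distortion
  expect_equal(oape_distortion(0.02, 0.5), 0.04)
  expect_error(oape_distortion(0.05, 1), class = "sipsense_validation_error")
  # monotone in fr_next: the less is consumed, the worse the distortion
  fr <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(oape_distortion(0.03, fr)) > 0))
})

test_that("aggregation comparison pairs the two strategies on identical trials", {
  # two 3-drink trials; aggregate the first 2 drinks
  vol <- tibble::tibble(
    trial_id = rep(c("A", "B"), each = 3), drink_index = rep(1:3, 2),
    pred = c(110, 90, 50, 60, 40, 30), truth = c(100, 100, 50, 50, 50, 30))
  geom <- container_geometry(beta_ml = 1000)
  fr_truth_a <- c(1, 0.9, 0.8)          # beta 1000: 100 mL per 0.1
  fr_truth_b <- c(1, 0.95, 0.90)
  fr <- tibble::tibble(
    trial_id = rep(c("A", "B"), each = 3), drink_index = rep(1:3, 2),
    pred = c(1, 0.9, 0.81, 1, 0.95, 0.92), truth = c(fr_truth_a, fr_truth_b))
  out <- compare_aggregation(vol, fr, geom = geom, n = 2L)
  expect_equal(out$strategy, c("cumulative", "residual"))
  expect_equal(out$n_trials, c(2L, 2L))
  # cumulative: A sums to 200 vs 200 -> 0; B sums to 100 vs 100 -> 0
  expect_equal(out$moape[out$strategy == "cumulative"], 0)
  # residual: A 1000*(1-0.81)=190 vs 200 -> 5%; B 1000*(1-0.92)=80 vs 100 -> 20%
  expect_equal(out$moape[out$strategy == "residual"], mean(c(5, 20)))

  # fill-ratio predictions outside [0,1] are clamped, not rejected
  fr$pred[1] <- 1.3
  expect_silent(out2 <- compare_aggregation(vol, fr, geom = geom, n = 2L))
  expect_equal(out2$moape[1], 0)

  expect_error(compare_aggregation(vol, fr[fr$trial_id == "A", ], geom = geom),
               class = "sipsense_validation_error")
})

test_that("the evaluation report exposes both MAPE conventions and MOAPE columns", {
  set.seed(57)
  results <- tibble::tibble(
    trial_id = rep(paste0("T", 1:5), each = 12),
    drink_index = rep(1:12, 5),
    truth = runif(60, 10, 90))
  results$pred <- results$truth * runif(60, 0.7, 1.3)
  rep_ <- evaluation_report(results)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(nrow(rep_$per_trial), 5)
  # equal-length trials: pooled MAPE is exactly the mean of trial MAPEs
  expect_equal(rep_$pooled_mape, rep_$mean_trial_mape)
  expect_equal(names(rep_$moape), paste0("moape_", c(3, 6, 9, 12)))
  expect_equal(rep_$moape[["moape_12"]], moape(results, 12))

  g <- glance(rep_)
  expect_true(all(c("pooled_mape", "mape_sd", "moape_3", "moape_12") %in% names(g)))
  expect_equal(tidy(rep_), rep_$per_trial)

  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$pooled_mape, rep_$pooled_mape, tolerance = 1e-12)
  expect_equal(back$moape$moape_6, rep_$moape[["moape_6"]], tolerance = 1e-12)
})
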