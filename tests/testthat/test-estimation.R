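test_that("with ample capacity the training residuals stay inside the epsilon tube", {
  set.seed(2)
  X <- as.data.frame(matrix(rnorm(40 * 5), 40, 5))
  y <- rnorm(40, 50, 5)
  # a narrow kernel makes the Gram matrix near-identity, so a hard tube
  # (large cost) is feasible at every training point
  spec <- model_spec("volume", "svm", kernel = "medium", kernel_scale = 0.5,
                     box_constraint = 1e4, epsilon_tube = 0.5)
  m <- fit(spec, X, y)
  expect_true(all(abs(predict(m, X) - y) <= 0.5 + 1e-2))
})

test_that("linear-kernel SVR recovers an exact linear relation", {
  set.seed(3)
  X <- data.frame(x1 = seq(0.5, 10, length.out = 20),
                  x2 = rnorm(20))
  y <- 2 * X$x1
  spec <- model_spec("volume", "svm", kernel = "linear",
                     box_constraint = 1e3, epsilon_tube = 0.01)
  m <- fit(spec, X, y)
  expect_equal(predict(m, data.frame(x1 = 3, x2 = 0)), 6, tolerance = 0.1)
})

test_that("gaussian SVR agrees with an independent solver on a small problem", {
  skip_if_not_installed("kernlab")
  set.seed(14)
  n <- 60
  X <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  y <- sin(X$x1) + 0.5 * X$x2
  ks <- 5.7
  spec <- model_spec("volume", "svm", kernel = "medium",
                     box_constraint = 10, epsilon_tube = 0.05)
  m <- fit(spec, X, y)
  # same objective solved by a different QP implementation
  mu <- colMeans(X); sdev <- apply(X, 2, sd)
  Xs <- scale(as.matrix(X), mu, sdev)
  ref <- kernlab::ksvm(Xs, y, type = "eps-svr", C = 10, epsilon = 0.05,
                       kernel = "rbfdot", kpar = list(sigma = 1 / ks^2),
                       scaled = FALSE)
  grid <- data.frame(x1 = seq(-1.5, 1.5, length.out = 9), x2 = 0)
  grid_s <- scale(as.matrix(grid), mu, sdev)
  expect_equal(predict(m, grid), as.numeric(kernlab::predict(ref, grid_s)),
               tolerance = 0.02)
})

test_that("the named kernel scales are stored and used", {
  expect_equal(model_spec("volume", "svm", kernel = "medium")$kernel_scale, 5.7)
  expect_equal(model_spec("volume", "svm", kernel = "coarse")$kernel_scale, 23)
  set.seed(6)
  X <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  y <- X$x1 + rnorm(30, 0, 0.1)
  m <- fit(model_spec("volume", "svm", kernel = "medium"), X, y)
  expect_equal(m$fit$gamma, 1 / 5.7^2)
})

test_that("single-factor LR matches the closed-form normal equations", {
  expect_equal(
    unname(coef(fit_lr_single("sip_duration",
                              data.frame(sip_duration = c(1, 2, 3)),
                              c(2, 4, 6))$fit)),
    c(0, 2), tolerance = 1e-12)

  m <- fit_lr_single("max_theta", data.frame(max_theta = c(1, 2, 3)), c(5, 5, 5))
  expect_equal(unname(coef(m$fit))[2], 0, tolerance = 1e-12)

  set.seed(12)
  x <- rnorm(50); y <- 3 + 0.5 * x + rnorm(50)
  m <- fit_lr_single("integral_theta", data.frame(integral_theta = x), y)
  expect_equal(unname(coef(m$fit)), unname(oracle_ols(x, y)), tolerance = 1e-9)

  expect_error(fit_lr_single("sip_duration",
                             data.frame(sip_duration = rep(1, 10)), 1:10),
               class = "sipsense_validation_error")
})

test_that("fill-ratio conditioning selects the k nearest labels, stably", {
  expect_equal(condition_training_set(c(0.1, 0.5, 0.9), 0.55, k = 1), 2L)
  expect_equal(condition_training_set(c(0.1, 0.5, 0.9), 0.55, k = 3), 1:3)
  expect_error(condition_training_set(c(0.1, 0.5), 0.5, k = 3),
               class = "sipsense_validation_error")

  set.seed(19)
  labels <- runif(1000)
  q <- 0.42
  got <- condition_training_set(labels, q, k = 150)
  ord <- order(abs(labels - q))     # brute-force sort-then-prefix oracle
  expect_setequal(got, ord[1:150])

  # exact ties break to the earlier row
  expect_equal(condition_training_set(c(0.4, 0.6, 0.3), 0.5, k = 1), 1L)
})

test_that("appending the fill ratio widens the matrix and records provenance", {
  X <- as.data.frame(matrix(rnorm(20 * 33), 20, 33))
  X2 <- append_fill_ratio_feature(X, runif(20), source = "estimate")
  expect_equal(ncol(X2), 34)
  expect_equal(attr(X2, "fr_source"), "estimate")
  expect_error(append_fill_ratio_feature(X, runif(5), "truth"),
               class = "sipsense_validation_error")
  set.seed(1)
  m <- fit(model_spec("volume", "svm", kernel = "linear"), X2, rnorm(20, 50, 10))
  expect_equal(glance(m)$fr_source, "estimate")
})

small_loto_data <- function(n_trials = 4, drinks = 6, seed = 99) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_trials), function(tr) {
    x <- runif(drinks, 1, 8)
    tibble::tibble(trial_id = paste0("T", tr), drink_index = seq_len(drinks),
                   sip_duration = x, integral_theta = x * 30 + rnorm(drinks),
                   max_theta = runif(drinks, 20, 80),
                   mass_g = 10 * x + rnorm(drinks),
                   fill_ratio_pre = seq(1, 0.5, length.out = drinks))
  })
}

test_that("LOTO produces one fold per trial and never trains on the held-out trial", {
  data <- small_loto_data()
  res <- loto_evaluate(data, model_spec("volume", "lr", lr_feature = "sip_duration"))
  expect_equal(sort(unique(res$trial_id)), paste0("T", 1:4))
  expect_equal(nrow(res), nrow(data))
  expect_true(all(res$n_train == nrow(data) - 6))
  expect_error(loto_evaluate(data[data$trial_id == "T1", ],
                             model_spec("volume", "lr", lr_feature = "sip_duration")),
               class = "sipsense_validation_error")
})

test_that("duplicating a trial only changes that trial's own training size", {
  data <- small_loto_data()
  dup <- data[data$trial_id == "T1", ]
  dup$trial_id <- "T9"
  res <- loto_evaluate(dplyr::bind_rows(data, dup),
                       model_spec("volume", "lr", lr_feature = "sip_duration"))
  per_fold <- dplyr::distinct(tibble::as_tibble(res)[c("trial_id", "n_train")])
  expect_true(all(per_fold$n_train == 24))  # every fold trains on the other 4 trials
})

test_that("standardization parameters are learned per training fold", {
  data <- small_loto_data(n_trials = 3)
  res <- suppressWarnings(
    loto_evaluate(data, model_spec("volume", "svm", kernel = "medium"),
                  feature_cols = c("sip_duration", "integral_theta", "max_theta")))
  folds <- attr(res, "folds")
  centers <- purrr::map(folds, "center")
  expect_length(folds, 3)
  expect_false(isTRUE(all.equal(centers[[1]], centers[[2]])))
  expect_false(isTRUE(all.equal(centers[[2]], centers[[3]])))
})

test_that("multi-target strategies run and keep the fold structure", {
  data <- small_loto_data(n_trials = 4, drinks = 8)
  spec <- model_spec("volume", "svm", kernel = "coarse")
  fc <- c("sip_duration", "integral_theta", "max_theta")
  res_app <- suppressWarnings(
    loto_evaluate(data, spec, feature_cols = fc, multi_target = "append"))
  expect_equal(nrow(res_app), nrow(data))
  res_par <- suppressWarnings(
    loto_evaluate(data, spec, feature_cols = fc, multi_target = "partition",
                  k_nearest = 10L))
  expect_equal(nrow(res_par), nrow(data))
  expect_true(all(res_par$n_train == 10))
})
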