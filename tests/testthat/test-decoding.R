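test_that("feature building bins time and fixes the cell subset by seed", {
  # 20 s at 30 Hz with 500 ms bins -> 40 bins of 15 frames
  snips <- array(rnorm(4 * 30 * 600), c(4, 30, 600))
  labels <- data.frame(animal = rep(c("a1", "a2"), 2),
                       condition = rep(c("x", "y"), 2),
                       stimulus_type = "airpuff")
  tt <- trial_tensor(snips, labels)
  f <- build_condition_features(tt, n_cells = 10, seed = 3)
  expect_equal(dim(f$features), c(4L, 10L, 40L))
  f2 <- build_condition_features(tt, n_cells = 10, seed = 3)
  expect_identical(f$cells, f2$cells)
  expect_identical(f$features, f2$features)
  # constant traces give constant features
  ttc <- trial_tensor(array(2.5, c(4, 6, 60)), labels)
  fc <- build_condition_features(ttc, n_cells = 6)
  expect_true(all(fc$features == 2.5))
  # asking for more cells than available uses all, with a message
  expect_message(build_condition_features(ttc, n_cells = 500),
                 "6 cells available")
  expect_error(build_condition_features(
    trial_tensor(array(0, c(4, 6, 10)), labels), bin_ms = 500),
    "shorter than one")
})

test_that("trial tensors validate labels and snippet shapes", {
  expect_error(trial_tensor(array(0, c(3, 2, 10)),
                            data.frame(animal = "a")), "do not match")
  expect_error(trial_tensor(array(0, c(1, 2, 10)),
                            data.frame(animal = "a")), "missing column")
})

test_that("ridge logistic agrees with an independent penalised fit", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  lam <- 0.05
  fit <- ridge_logistic(X, c("a", "b")[y + 1], lambda = lam)
  ref <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lam / n, standardize = FALSE,
                        thresh = 1e-12)
  expect_equal(as.numeric(fit$fits[[1]]$coef), as.numeric(ref$beta),
               tolerance = 1e-5)
  expect_equal(fit$fits[[1]]$intercept, as.numeric(ref$a0),
               tolerance = 1e-5)
  # dual solve (features > trials) reaches the same optimum
  Xw <- matrix(rnorm(30 * 300), 30, 300)
  yw <- rbinom(30, 1, 0.5)
  fw <- ridge_logistic(Xw, c("a", "b")[yw + 1], lambda = 0.05)
  rw <- glmnet::glmnet(Xw, yw, family = "binomial", alpha = 0,
                       lambda = 0.05 / 30, standardize = FALSE,
                       thresh = 1e-14, maxit = 1e6)
  expect_equal(as.numeric(fw$fits[[1]]$coef), as.numeric(rw$beta),
               tolerance = 1e-3)
  # inverse-strength convention
  fC <- ridge_logistic(X, c("a", "b")[y + 1], lambda = 1 / lam,
                       penalty = "C")
  expect_equal(fC$fits[[1]]$coef, fit$fits[[1]]$coef, tolerance = 1e-8)
})

test_that("condition decoding is subject-wise and deterministic", {
  tt <- simulate_condition_experiment(effect = 3, seed = 31)
  f <- build_condition_features(tt, n_cells = 20, seed = 31)
  r1 <- train_condition_classifier(f, seed = 31)
  r2 <- train_condition_classifier(f, seed = 31)
  expect_identical(r1$bin_accuracy, r2$bin_accuracy)
  expect_length(intersect(r1$train_animals, r1$test_animals), 0)
  # a strong planted effect is decodable near ceiling
  expect_gte(r1$max_accuracy, 0.9)
  # single animal per class: subject-wise split impossible
  tt1 <- simulate_condition_experiment(n_animals = 2, seed = 1)
  f1 <- build_condition_features(tt1, n_cells = 20, seed = 1)
  expect_error(train_condition_classifier(f1, seed = 1),
               "impossible")
})

test_that("permutation thresholds behave at the quantile edge cases", {
  tt <- simulate_condition_experiment(effect = 0, seed = 17)
  f <- build_condition_features(tt, n_cells = 10, seed = 17)
  expect_warning(perm <- permutation_significance(f, n_perm = 60,
                                                  seed = 17),
                 "unstable")
  # alpha = 1: threshold is the minimum of the null sample
  suppressWarnings(
    p1 <- permutation_significance(f, n_perm = 60, alpha = 1, seed = 17))
  expect_equal(p1$threshold, min(p1$null_accuracy))
  expect_gte(perm$threshold, 0.5 - 1e-9)
})

test_that("features independent of labels decode at chance", {
  accs <- vapply(1:8, function(s) {
    tt <- simulate_condition_experiment(effect = 0,
                                        trials_per_animal = 20,
                                        seed = 400 + s)
    f <- build_condition_features(tt, n_cells = 10, seed = s)
    mean(train_condition_classifier(f, seed = s)$bin_accuracy)
  }, 0)
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("stimulus-type decoder separates disjoint patterns", {
  tt <- simulate_stimulus_experiment(effect = 4, seed = 51)
  res <- stimulus_type_decoder(tt, n_cells = 20, seed = 51)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_features, 20 * 60)   # cells x frames, flattened
  # effect-free patterns decode near chance (3 classes)
  acc0 <- vapply(1:5, function(s) {
    t0 <- simulate_stimulus_experiment(effect = 0, seed = 600 + s)
    stimulus_type_decoder(t0, n_cells = 20, seed = s)$accuracy
  }, 0)
  expect_lt(mean(acc0), 0.6)
  # recording-wise CV needs >= 2 recordings
  one <- simulate_stimulus_experiment(n_recordings = 1, seed = 1)
  expect_error(stimulus_type_decoder(one, seed = 1), ">= 2 recordings")
})
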