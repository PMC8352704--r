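test_that("sample_batch draws without replacement, deterministically, and validates size", {
  ds <- as.list(1:10)
  withr::with_seed(1L, {
    b <- sample_batch(ds, 10L)
    expect_setequal(b, 1:10)           # whole set, order permuted
    expect_length(sample_batch(ds, 1L), 1L)
  })
  i1 <- withr::with_seed(2L, sample_batch(ds, 4L))
  i2 <- withr::with_seed(2L, sample_batch(ds, 4L))
  expect_identical(i1, i2)
  expect_error(sample_batch(ds, 11L), "exceeds")
})

test_that("batch sampling inclusion frequencies are uniform (chi-square)", {
  ds <- as.list(1:10)
  counts <- withr::with_seed(99L, {
    tab <- integer(10)
    for (i in 1:10000) {
      b <- sample_batch(ds, 3L)
      tab[b] <- tab[b] + 1L
    }
    tab
  })
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("zero learning rate leaves parameters and loss unchanged", {
  ds <- tiny_cohort(16L, seed = 2L)
  net <- build_network(2L, seed = 1L, "CT")
  res <- train_model(net, ds, train_config(25L, 8L, learning_rate = 0,
                                           seed = 3L, record_every = 5L))
  expect_identical(res$model[c("conv1", "conv2", "fc1", "fc2")],
                   net[c("conv1", "conv2", "fc1", "fc2")])
  expect_identical(nrow(res$history), 5L)
  expect_true(is.unsorted(res$history$update) == FALSE)
})

test_that("training is bit-reproducible from (config, data, seed)", {
  ds <- tiny_cohort(20L, seed = 4L)
  cfg <- train_config(30L, 8L, seed = 11L)
  r1 <- train_model(build_network(2L, 5L, "CT"), ds, cfg)
  r2 <- train_model(build_network(2L, 5L, "CT"), ds, cfg)
  expect_identical(r1$model, r2$model)
  expect_identical(r1$history$mean_batch_loss, r2$history$mean_batch_loss)
  r3 <- train_model(build_network(2L, 5L, "CT"), ds,
                    train_config(30L, 8L, seed = 12L))
  expect_false(identical(r1$model, r3$model))
})

test_that("training reduces loss on a separable cohort and batch size is validated", {
  ds <- generate_cohort(cohort_spec(40L, 0.5, ct_effect = 2, xray_effect = 2,
                                    noise_sd = 0, seed = 6L))
  cfg <- train_config(120L, 8L, seed = 1L, record_every = 120L)
  res <- train_model(build_network(2L, seed = 2L, "CT"), ds, cfg)
  first_loss <- copdfusion:::net_forward(
    build_network(2L, seed = 2L, "CT"),
    copdfusion:::images_to_batch(res$model, ds),
    labels = vapply(ds, `[[`, integer(1), "label"))$loss
  expect_lt(utils::tail(res$history$mean_batch_loss, 1L), first_loss)
  expect_error(train_model(res$model, ds, train_config(10L, 100L)), "exceeds")
})

test_that("a validation set selects the best recorded checkpoint", {
  ds <- generate_cohort(cohort_spec(60L, 0.5, ct_effect = 1, xray_effect = 1,
                                    noise_sd = 0.2, seed = 21L))
  sp <- split_cohort(ds, 0.7, seed = 1L)
  cfg <- train_config(60L, 8L, seed = 2L, record_every = 10L)
  net0 <- build_network(2L, seed = 3L, "CT")
  val_rec <- function(m) metrics(confusion(predict(m, sp$test),
                                           vapply(sp$test, `[[`, integer(1), "label")))$recognition
  final <- train_model(net0, sp$train, cfg)$model
  best <- train_model(net0, sp$train, cfg, validation_set = sp$test)$model
  expect_gte(val_rec(best), val_rec(final))
  # without a validation set the final checkpoint is returned unchanged
  again <- train_model(net0, sp$train, cfg)$model
  expect_identical(again, final)
})

test_that("iteration sweep trains fresh models per grid point and records rows", {
  ds <- generate_cohort(cohort_spec(40L, 0.5, ct_effect = 2, xray_effect = 2,
                                    noise_sd = 0.05, seed = 8L))
  sp <- split_cohort(ds, 0.75, seed = 1L)
  cfg <- train_config(batch_size = 8L, seed = 2L)
  # one-point grid degenerates to a single train + evaluate
  one <- sweep_iterations(sp, 15L, cfg, models = "CT-CNN")
  expect_identical(nrow(one), 1L)
  res <- sweep_iterations(sp, c(10L, 40L), cfg, models = c("CT-CNN", "FUSION"))
  expect_identical(nrow(res), 4L)
  expect_setequal(unique(res$model), c("CT-CNN", "FUSION"))
  expect_true(all(res$recognition >= 0 & res$recognition <= 1))
  # training time grows with the iteration count for each model
  for (tag in unique(res$model)) {
    tt <- res$train_seconds[res$model == tag]
    expect_true(all(diff(tt) > 0))
  }
  expect_error(sweep_iterations(sp, c(40L, 10L), cfg), "ascending")
  expect_error(sweep_iterations(sp, integer(), cfg), "empty")
})

test_that("batch sweep keeps the epoch budget fixed and stays in metric range", {
  ds <- generate_cohort(cohort_spec(40L, 0.5, ct_effect = 2, xray_effect = 2,
                                    noise_sd = 0.05, seed = 9L))
  sp <- split_cohort(ds, 0.75, seed = 1L)
  cfg <- train_config(batch_size = 8L, seed = 3L)
  n_train <- length(sp$train)
  # full-batch grid point -> one update per epoch
  expect_identical(max(1L, as.integer(round(2 * n_train / n_train))), 2L)
  res <- sweep_batches(sp, c(5L, 10L, 30L), cfg, epochs = 5,
                       models = "CT-CNN")
  expect_identical(nrow(res), 3L)
  expect_true(all(res$recognition >= 0 & res$recognition <= 1))
  expect_true(all(is.na(res$sensitivity) | (res$sensitivity >= 0 & res$sensitivity <= 1)))
  # fixed-epoch budget: updates * batch constant to within one batch
  updates <- vapply(c(5L, 10L, 30L), function(b) max(1L, as.integer(round(5 * n_train / b))),
                    integer(1))
  seen <- updates * c(5L, 10L, 30L)
  expect_true(all(abs(seen - 5 * n_train) <= c(5L, 10L, 30L)))
  expect_error(sweep_batches(sp, 1000L, cfg), "exceeds")
})
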