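test_that("model spec validates geometry and reports the receptive field", {
  spec <- mpra_model_spec()
  expect_equal(spec$receptive_field, 13L)  # 1 + 3 * (5 - 1), no pooling
  expect_equal(mpra_model_spec(n_tasks = 1)$n_tasks, 1L)
  expect_error(mpra_model_spec(fragment_length = 10), "receptive field")
  expect_error(mpra_model_spec(p_dropout = 1), "p_dropout")
})

test_that("an untrained default model has a linear 4-output head", {
  m <- build_model(mpra_model_spec(filters_per_layer = 8), seed = 1)
  p <- predict(m, random_seq(145))
  expect_equal(dim(p), c(1L, 4L))
  expect_equal(colnames(p), mpra_tasks())
  m1 <- build_model(mpra_model_spec(filters_per_layer = 8, n_tasks = 1),
                    seed = 1)
  expect_equal(ncol(predict(m1, random_seq(145))), 1L)
})

test_that("prediction is deterministic and batch-order invariant", {
  fit <- tiny_model()
  set.seed(99)
  seqs <- replicate(30, random_seq(145))
  p1 <- predict(fit, seqs)
  p2 <- predict(fit, seqs)
  expect_identical(p1, p2)
  one_at_a_time <- t(vapply(seqs, function(s) predict(fit, s)[1, ],
                            numeric(4)))
  dimnames(one_at_a_time) <- dimnames(p1)
  expect_equal(p1, one_at_a_time, tolerance = 1e-5)
  p_small_batches <- predict(fit, seqs, batch_size = 7)
  expect_equal(p1, p_small_batches, tolerance = 1e-12)
  expect_equal(dim(predict(fit, character(0))), c(0L, 4L))
  expect_error(predict(fit, "ACGT"), "length")
})

test_that("training is seed-reproducible and logs its history", {
  fit <- tiny_model()
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$train_mse)))
  expect_lt(fit$history$train_mse[2], fit$history$train_mse[1])
  ## same data, same seed, fresh run: identical validation trace
  fit2 <- mpra_cnn(tiny_dataset(), mpra_model_spec(filters_per_layer = 24),
                   mpra_train_control(epochs = 2, learning_rate = 3e-3,
                                      seed = 3))
  expect_equal(fit2$history$val_mse, fit$history$val_mse, tolerance = 1e-5)
})

test_that("zero-epoch training returns the initialized model unchanged", {
  ds <- tiny_dataset()
  spec <- mpra_model_spec(filters_per_layer = 8)
  f0 <- mpra_cnn(ds, spec, mpra_train_control(epochs = 0, seed = 5))
  init <- build_model(spec, seed = 5)
  s <- random_seq(145)
  expect_equal(predict(f0, s), predict(init, s))
  expect_false(f0$trained)
})

test_that("model persistence round-trips predictions", {
  fit <- tiny_model()
  dir <- withr::local_tempdir()
  save_model(fit, dir)
  back <- load_model(dir)
  s <- replicate(5, random_seq(145))
  expect_equal(predict(back, s), predict(fit, s), tolerance = 1e-12)
  expect_equal(back$normalization$mean, fit$normalization$mean)
})
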