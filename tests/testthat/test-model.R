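test_that("configs validate their invariants", {
  expect_error(model_config(input_size = 100, n_levels = 5), "divisible")
  expect_silent(model_config(input_size = 128, n_levels = 5))
  expect_error(train_config(max_epochs = 0))
  cfg <- train_config()
  expect_equal(cfg$max_epochs, 12L)
  expect_equal(cfg$minibatch_size, 7L)
  expect_equal(cfg$initial_learning_rate, 1e-4)
  expect_equal(cfg$validation_frequency, 200L)
  expect_equal(cfg$validation_patience, 10L)
})

test_that("the network honors its shape and boundedness contracts", {
  cfg <- model_config(input_size = 64, n_levels = 5, base_filters = 4)
  net <- build_model(cfg, seed = 2)
  out <- predict_heatmaps(net, matrix(0, 64, 64))
  expect_equal(dim(out), c(64, 64, 6))
  expect_true(all(is.finite(out)))
  expect_true(all(out >= 0 & out <= 1))
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(predict_heatmaps(net, img), predict_heatmaps(net, img))
  expect_error(predict_heatmaps(net, matrix(0, 32, 32)), "wrong input size")
})

test_that("RMSE loss matches its closed forms", {
  a <- array(0, c(8, 8, 6))
  expect_equal(rmse_loss(a, a), 0)
  expect_equal(rmse_loss(a + 0.5, a), 0.5)
  expect_equal(rmse_loss(a, a + 1), 1)
  expect_error(rmse_loss(a, array(0, c(4, 4, 6))), "shape mismatch")
})

test_that("analytic gradients match finite differences on a tiny net", {
  cfg <- model_config(input_size = 8, n_levels = 2, base_filters = 2)
  net <- build_model(cfg, seed = 3)
  set.seed(7)
  x <- matrix(runif(64), 8, 8)
  y <- array(runif(8 * 8 * 6), c(8, 8, 6))
  g <- boneaxis:::cpp_unet_grad(net$weights, x, y, 2)
  eps <- 1e-6
  for (nm in names(net$weights)) {
    for (i in seq_len(min(4, length(net$weights[[nm]])))) {
      wp <- net$weights; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- net$weights; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (boneaxis:::cpp_unet_eval(wp, list(x), list(y), 2) -
               boneaxis:::cpp_unet_eval(wm, list(x), list(y), 2)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training overfits a single phantom and keeps its bookkeeping", {
  p <- generate_phantom(phantom_spec(image_height = 64, image_width = 64,
                                     noise_sd = 0.02))
  hm <- make_heatmaps(p$annotation)
  net <- build_model(model_config(input_size = 64, n_levels = 5,
                                  base_filters = 4), seed = 1)
  tcfg <- train_config(max_epochs = 600, minibatch_size = 1,
                       initial_learning_rate = 3e-3,
                       validation_frequency = 100,
                       validation_patience = 50, seed = 42)
  trained <- train_model(net, list(x = list(p$image), y = list(hm)),
                         list(x = list(p$image), y = list(hm)), tcfg)
  h <- trained$history$trace
  expect_lte(nrow(h), 600)  # <= ceil(epochs * n / minibatch) iterations
  first <- h$train_rmse[1]
  last <- tail(h$train_rmse, 1)
  expect_lt(last, 0.2 * first)
  # prediction of the overfit image resembles its target closely
  pred <- predict_heatmaps(trained, p$image)
  expect_lt(rmse_loss(pred, hm), 0.1)
  expect_error(train_model(net, list(), list(), tcfg), "empty")
})

test_that("checkpoints round-trip and reject mismatched weights", {
  net <- build_model(model_config(input_size = 32, n_levels = 3,
                                  base_filters = 2), seed = 9)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(net, path)
  back <- load_model(path)
  expect_identical(back$weights, net$weights)
  expect_identical(back$config, net$config)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict_heatmaps(back, img), predict_heatmaps(net, img))
  # corrupt: drop a layer
  bad <- net; bad$weights$enc2_W <- NULL
  saveRDS(list(format = "boneaxis_checkpoint", config = bad$config,
               weights = bad$weights), path)
  expect_error(load_model(path), "corrupt checkpoint")
  saveRDS(list(format = "something"), path)
  expect_error(load_model(path), "not a boneaxis checkpoint")
})
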