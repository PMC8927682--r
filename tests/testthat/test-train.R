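test_that("logistic link hits its closed forms and stays stable", {
  expect_equal(fv_sigmoid(0), 0.5)
  expect_equal(fv_sigmoid(log(3)), 0.75)
  x <- seq(-6, 6, by = 0.37)
  expect_equal(fv_sigmoid(-x), 1 - fv_sigmoid(x))
  expect_equal(fv_sigmoid(1e3), 1)
  expect_equal(fv_sigmoid(-1e3), 0)
  expect_true(all(is.finite(fv_sigmoid(c(-1e6, 1e6)))))
})

test_that("episode BCE matches its closed forms and the scalar oracle", {
  y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_lt(fv_bce_loss(y, y), 1e-6)           # perfect prediction
  half <- matrix(0.5, 4, 4)
  expect_equal(fv_bce_loss(half, y), log(2), tolerance = 1e-12)
  expect_equal(fv_bce_loss(matrix(0.25, 4, 4), matrix(1, 4, 4)), log(4),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:10) {
    probs <- replicate(3, matrix(runif(16), 4, 4), simplify = FALSE)
    ys <- replicate(3, matrix(rbinom(16, 1, 0.4), 4, 4), simplify = FALSE)
    expect_equal(fv_bce_loss(probs, ys), oracle_bce(probs, ys),
                 tolerance = 1e-6)
  }
  expect_error(fv_bce_loss(list(half), list(y, y)), "counts differ")
  # the logit-space loss used in training agrees with the probability form
  logits <- matrix(rnorm(16), 4, 4)
  tape_loss <- local({
    fewvessel:::tp_begin()
    on.exit(fewvessel:::tp_end())
    lg <- fewvessel:::tp_const(array(logits, c(4, 4, 1)))
    fewvessel:::ad_bce_logits(lg, array(y, c(4, 4, 1)))$v
  })
  expect_equal(tape_loss, fv_bce_loss(fv_sigmoid(logits), y),
               tolerance = 1e-9)
})

test_that("one small gradient step on a fixed episode decreases its loss", {
  ep <- fx_tiny_episode(side = 16L, C = 1L, K = 1L, seed = 3L)
  mc <- fv_model_config("baseline", channel_scale = 0.05)
  w <- fv_init_weights(mc, seed = 4)
  adam <- fewvessel:::fv_adam_init(w)
  s1 <- fewvessel:::fv_train_step(w, mc, ep, adam, 1e-4)
  s2 <- fewvessel:::fv_train_step(s1$weights, mc, ep, s1$adam, 1e-4)
  expect_lt(s2$loss, s1$loss)
})

test_that("training bookkeeping: history sizes, determinism, checkpoints", {
  lib <- fx_small_library(n_classes = 4L, seed = 1L)
  split <- list(train_ids = names(lib$classes)[1:2],
                valid_ids = names(lib$classes)[3:4])
  tc <- fv_train_config(learning_rate = 1e-3, epochs = 2L,
                        iterations_per_epoch = 3L, C = 2L, K = 1L,
                        seed = 5L, val_episodes = 1L)
  mc <- fv_model_config("baseline", channel_scale = 0.05)
  fit <- fsvs_fit(lib, "baseline", split, tc, mc)
  expect_s3_class(fit, "fsvs_model")
  expect_equal(nrow(fit$history), 6L)      # 2 epochs x 3 iterations
  expect_equal(nrow(fit$val_history), 2L)  # one validation row per epoch
  expect_true(all(fit$history$loss >= 0))
  # identical seed reproduces the loss history exactly
  fit2 <- fsvs_fit(lib, "baseline", split, tc, mc)
  expect_identical(fit$history$loss, fit2$history$loss)
  # checkpoint round trip restores weights bit-identically
  path <- tempfile(fileext = ".rds")
  fv_save_model(fit, path)
  back <- fv_load_model(path)
  expect_identical(back$weights, fit$weights)
  q <- lib$classes[[3]]$members[[1]]
  sup <- lib$classes[[4]]$members[1]
  expect_identical(
    fv_predict_patch(fit$weights, fit$model_config, q$patch, sup),
    fv_predict_patch(back$weights, back$model_config, q$patch, sup))
  # summary/print/plot run cleanly
  expect_output(print(fit), "baseline")
  expect_output(print(summary(fit)), "parameters")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("whole-plane prediction reassembles patch probabilities", {
  lib <- fx_small_library(n_classes = 4L, seed = 1L)
  mc <- fv_model_config("baseline", channel_scale = 0.05)
  fit <- structure(list(weights = fv_init_weights(mc, seed = 6),
                        model_config = mc,
                        config = fv_train_config(C = 2, K = 1)),
                   class = "fsvs_model")
  sup <- lib$classes[[1]]$members[1]
  pr <- predict(fit, plane = lib$classes[[2]]$plane, support = sup,
                grid = lib$grid)
  expect_equal(dim(pr), dim(lib$classes[[2]]$plane))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_error(predict(fit, plane = lib$classes[[2]]$plane), "support")
})
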