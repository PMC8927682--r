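with_tape <- function(expr) {
  fewvessel:::tp_begin()
  on.exit(fewvessel:::tp_end())
  expr
}

test_that("encoder produces the five-scale feature pyramid", {
  mc <- fv_model_config("baseline", channel_scale = 0.125)
  w <- fv_init_weights(mc, seed = 1)
  for (side in c(32L, 64L)) {
    feats <- with_tape({
      p <- fewvessel:::fv_param_nodes(w)
      x <- fewvessel:::tp_const(array(runif(side * side), c(side, side, 1)))
      lapply(fewvessel:::fv_encode_nodes(p, x), function(f) dim(f$v))
    })
    sides <- vapply(feats, `[`, 0L, 1)
    expect_equal(sides, as.integer(side / c(1, 2, 4, 8, 16)))
    expect_equal(vapply(feats, `[`, 0L, 3), mc$enc_widths)
  }
  expect_error(with_tape({
    p <- fewvessel:::fv_param_nodes(w)
    fewvessel:::fv_encode_nodes(
      p, fewvessel:::tp_const(array(0, c(24, 24, 1))))
  }), "divisible by 16")
})

test_that("full-width layer table matches the reference configuration", {
  tab <- fewvessel:::fv_layer_table(fv_model_config("baseline", 1))
  enc <- tab$cout[1:10]
  dec <- tab$cout[11:20]
  expect_equal(enc, c(64L, 64L, 128L, 128L, 256L, 256L, 256L,
                      512L, 512L, 512L))
  expect_equal(dec, c(512L, 256L, 256L, 128L, 128L, 64L, 64L, 32L, 3L, 1L))
  # upgraded variant only widens decoder inputs, never the outputs
  tab_u <- fewvessel:::fv_layer_table(fv_model_config("upgraded", 1))
  expect_equal(tab_u$cout, tab$cout)
  expect_true(all(tab_u$cin >= tab$cin))
})

test_that("mask average pooling matches the brute-force double loop", {
  set.seed(2)
  for (i in 1:20) {
    feat <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    mask <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    got <- with_tape(
      fewvessel:::ad_mask_avg_pool(fewvessel:::tp_const(feat), mask)$v)
    expect_equal(got, oracle_mask_avg_pool(feat, mask), tolerance = 1e-6)
  }
  # all-ones mask reduces to plain average pooling; all-zeros to zero
  feat <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_equal(
    with_tape(fewvessel:::ad_mask_avg_pool(fewvessel:::tp_const(feat),
                                           matrix(1, 8, 8))$v),
    apply(feat, 3, mean))
  expect_equal(
    with_tape(fewvessel:::ad_mask_avg_pool(fewvessel:::tp_const(feat),
                                           matrix(0, 8, 8))$v),
    numeric(3))
  # worked 2x2 example
  f <- array(c(1, 3, 2, 4), c(2, 2, 1))
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(
    with_tape(fewvessel:::ad_mask_avg_pool(fewvessel:::tp_const(f), m)$v),
    1.25)
})

test_that("multi-shot prototype merge is the element-wise mean", {
  with_tape({
    n1 <- fewvessel:::tp_const(c(0, 2))
    n2 <- fewvessel:::tp_const(c(2, 0))
    expect_equal(fewvessel:::ad_mean_nodes(list(n1, n2))$v, c(1, 1))
    expect_equal(fewvessel:::ad_mean_nodes(list(n1))$v, c(0, 2))
    expect_equal(fewvessel:::ad_mean_nodes(list(n2, n2))$v, c(2, 0))
  })
})

test_that("prototype guidance is the per-position inner product", {
  set.seed(3)
  feat <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  proto <- rnorm(3)
  got <- with_tape(
    fewvessel:::ad_proto_dot(fewvessel:::tp_const(feat),
                             fewvessel:::tp_const(proto))$v)
  brute <- matrix(0, 6, 6)
  for (h in 1:6) for (w in 1:6) brute[h, w] <- sum(feat[h, w, ] * proto)
  expect_lt(max(abs(got[, , 1] - brute)), 1e-6)
  # zero prototype gives a zero grid; one-hot selects a channel
  expect_equal(with_tape(
    fewvessel:::ad_proto_dot(fewvessel:::tp_const(feat),
                             fewvessel:::tp_const(c(0, 0, 0)))$v[, , 1]),
    matrix(0, 6, 6))
  expect_equal(with_tape(
    fewvessel:::ad_proto_dot(fewvessel:::tp_const(feat),
                             fewvessel:::tp_const(c(0, 1, 0)))$v[, , 1]),
    feat[, , 2])
})

test_that("non-local attention normalises affinities and keeps shape", {
  mc <- fv_model_config("upgraded", channel_scale = 0.125)
  w <- fv_init_weights(mc, seed = 4)
  side <- 8L
  f5 <- array(runif(side * side * mc$enc_widths[5]),
              c(side, side, mc$enc_widths[5]))
  out <- with_tape({
    p <- fewvessel:::fv_param_nodes(w)
    fewvessel:::fv_msa_nodes(p, mc, fewvessel:::tp_const(f5))$v
  })
  expect_equal(dim(out), dim(f5))
  expect_true(all(is.finite(out)))
  # constant input stays spatially constant (uniform attention + residual)
  cf <- array(rep(seq_len(mc$enc_widths[5]), each = side * side),
              c(side, side, mc$enc_widths[5]))
  outc <- with_tape({
    p <- fewvessel:::fv_param_nodes(w)
    fewvessel:::fv_msa_nodes(p, mc, fewvessel:::tp_const(cf))$v
  })
  sp_var <- apply(outc, 3, function(m) diff(range(m)))
  expect_lt(max(sp_var), 1e-8)
  # softmax rows sum to one
  set.seed(5)
  a <- matrix(rnorm(30), 5, 6)
  s <- with_tape(fewvessel:::ad_softmax_rows(fewvessel:::tp_const(a))$v)
  expect_equal(rowSums(s), rep(1, 5))
  expect_error(with_tape({
    p <- fewvessel:::fv_param_nodes(w)
    fewvessel:::fv_msa_nodes(p, mc, fewvessel:::tp_const(array(0, c(1, 1, mc$enc_widths[5]))))
  }), "attention scale")
})

test_that("forward passes give probabilities, determinism and zero-mask logic", {
  ep <- fx_tiny_episode(side = 32L, C = 1L, K = 2L)
  sup <- ep$classes[[1]]$support
  q <- ep$classes[[1]]$query[[1]]$patch
  for (variant in c("baseline", "upgraded")) {
    mc <- fv_model_config(variant, channel_scale = 0.06)
    w <- fv_init_weights(mc, seed = 5)
    pr <- fv_predict_patch(w, mc, q, sup)
    expect_equal(dim(pr), dim(q))
    expect_true(all(pr >= 0 & pr <= 1))
    expect_identical(pr, fv_predict_patch(w, mc, q, sup))
    # permutation-invariance to support order (prototype merge is a mean)
    expect_equal(fv_predict_patch(w, mc, q, rev(sup)), pr, tolerance = 1e-12)
    # all-zero support masks give zero prototypes -> guidance grid zero
    sup0 <- lapply(sup, function(s) { s$mask <- s$mask * 0; s })
    pr0 <- fv_predict_patch(w, mc, q, sup0)
    expect_true(all(is.finite(pr0)))
  }
})

test_that("zero support masks yield an exactly zero deep prototype", {
  mc <- fv_model_config("baseline", channel_scale = 0.06)
  w <- fv_init_weights(mc, seed = 6)
  sup <- fx_tiny_episode(side = 32L)$classes[[1]]$support
  sup[[1]]$mask <- sup[[1]]$mask * 0
  protos <- with_tape({
    p <- fewvessel:::fv_param_nodes(w)
    fewvessel:::fv_support_prototypes(p, mc, sup, 5L)
  })
  expect_equal(protos[[5]]$v, numeric(mc$enc_widths[5]))
})

test_that("upgraded pass exposes the guidance-ablation hook", {
  mc <- fv_model_config("upgraded", channel_scale = 0.06)
  w <- fv_init_weights(mc, seed = 7)
  ep <- fx_tiny_episode(side = 32L)
  sup <- ep$classes[[1]]$support
  q <- ep$classes[[1]]$query[[1]]$patch
  full <- fv_predict_patch(w, mc, q, sup)
  ablated <- fv_predict_patch(w, mc, q, sup, ablate_guidance = TRUE)
  expect_equal(dim(ablated), dim(q))
  expect_false(identical(full, ablated))
})

test_that("backpropagated gradients match central finite differences", {
  ep <- fx_tiny_episode(side = 16L, C = 1L, K = 1L, seed = 9L)
  mc <- fv_model_config("baseline", channel_scale = 0.05)
  w <- fv_init_weights(mc, seed = 8)
  lossfn <- function(weights) with_tape({
    p <- fewvessel:::fv_param_nodes(weights)
    fewvessel:::fv_episode_loss(p, mc, ep)$v
  })
  grads <- with_tape({
    p <- fewvessel:::fv_param_nodes(w)
    L <- fewvessel:::fv_episode_loss(p, mc, ep)
    fewvessel:::tp_backward(L)
    lapply(p, function(nd) nd$g)
  })
  set.seed(10)
  h <- 1e-5
  for (nm in c("e1_1.k", "e4_3.k", "d1.k", "d10.k", "d10.b")) {
    i <- sample(length(w[[nm]]), 1)
    wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
    wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
    num <- (lossfn(wp) - lossfn(wm)) / (2 * h)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("all forward outputs are finite for random inputs", {
  set.seed(12)
  for (variant in c("baseline", "upgraded")) {
    mc <- fv_model_config(variant, channel_scale = 0.06)
    w <- fv_init_weights(mc, seed = 13)
    ep <- fx_tiny_episode(side = 32L, seed = 14L)
    pr <- fv_predict_patch(w, mc, ep$classes[[1]]$query[[1]]$patch,
                           ep$classes[[1]]$support)
    expect_true(all(is.finite(pr)))
  }
})
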