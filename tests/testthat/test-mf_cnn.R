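test_that("closed-form counts match network introspection over the grid", {
  for (nc in 3:5) {
    for (nk in c(32L, 64L)) {
      for (trainable in c(TRUE, FALSE)) {
        spec <- mf_model_spec(nc, nk,
          conv_init = "default",
          conv_trainable = trainable
        )
        pc <- count_params(spec)
        ic <- model_param_count(build_model(spec))
        expect_identical(pc$total, as.integer(ic$total))
        expect_identical(pc$trainable, as.integer(ic$trainable))
        expect_identical(pc$non_trainable, as.integer(ic$non_trainable))
        expect_identical(pc$total, pc$trainable + pc$non_trainable)
      }
    }
  }
  # two-channel input doubles the correlator weights only
  pc_both <- count_params(mf_model_spec(3, 32, input_feature = "both"))
  pc_one <- count_params(mf_model_spec(3, 32))
  expect_identical(
    pc_both$total - pc_one$total,
    unname(pc_one$layers["conv"]) - 11L # extra NK*NF weights, same biases
  )
})

test_that("forward pass emits valid probabilities on any spec", {
  segs <- small_sets()$train
  one <- subset_segments(segs, 1:5)
  for (feat in c("signal", "derivative", "both")) {
    spec <- mf_model_spec(3, 32,
      input_feature = feat, conv_init = "default",
      seed = 3
    )
    m <- build_model(spec)
    pr <- predict_mf(m, one)
    expect_equal(dim(pr), c(5L, 3L))
    expect_true(all(pr > 0))
    expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-6)
  }
})

test_that("the frozen correlator layer computes correlate() plus bias", {
  segs <- small_sets()$train
  bank <- small_bank("derivative", 32L)
  spec <- mf_model_spec(3, 32,
    nf = length(bank$labels),
    conv_trainable = FALSE, seed = 5
  )
  m <- build_model(spec, bank)
  m$params$conv_b <- runif(length(bank$labels)) # nonzero bias on purpose
  X <- segs$windows[1:3, , drop = FALSE]
  xcol <- mfbeat:::conv_im2col(mfbeat:::model_input_channels(m, X), 32L)
  wmat <- matrix(m$params$conv_w, nrow = 32L)
  conv <- sweep(xcol %*% wmat, 2, m$params$conv_b, `+`)
  feats <- mfbeat:::feature_windows(X, "derivative")
  for (b in 1:3) {
    for (t in seq_along(bank$labels)) {
      expected <- correlate(feats[b, ], bank$kernels[, t]) + m$params$conv_b[t]
      got <- conv[(seq_len(64) - 1) * 3 + b, t]
      expect_lt(max(abs(got - expected)), 1e-5)
    }
  }
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(42)
  B <- 6L
  X <- matrix(rnorm(B * 64), B)
  R <- matrix(abs(rnorm(B * 4, 1, 0.2)), B)
  y <- sample.int(3, B, replace = TRUE)
  w <- runif(B, 0.5, 2)
  m <- build_model(mf_model_spec(3, 32,
    nf = 4, conv_init = "default",
    conv_trainable = TRUE, seed = 9
  ))
  fw <- mfbeat:::model_forward(m, X, R, training = TRUE, keep_cache = TRUE)
  fw$cache$probs <- fw$probs
  g <- mfbeat:::model_backward(m, fw$cache, y, w)
  loss <- function(model) {
    p <- mfbeat:::model_forward(model, X, R, training = TRUE)$probs
    sum(w * -log(p[cbind(seq_len(B), y)])) / B
  }
  set.seed(1)
  for (nm in c("conv_w", "bn_gamma", "bn_beta", "out_w", "out_b")) {
    a <- g[[nm]]
    for (i in sample(length(a), min(4, length(a)))) {
      m1 <- m
      m2 <- m
      m1$params[[nm]][i] <- m1$params[[nm]][i] + 1e-6
      m2$params[[nm]][i] <- m2$params[[nm]][i] - 1e-6
      expect_equal(unname(a[i]), (loss(m1) - loss(m2)) / 2e-6, tolerance = 1e-4)
    }
  }
  a <- g$rr[[2]]$W
  for (i in sample(length(a), 4)) {
    m1 <- m
    m2 <- m
    m1$params$rr[[2]]$W[i] <- m1$params$rr[[2]]$W[i] + 1e-6
    m2$params$rr[[2]]$W[i] <- m2$params$rr[[2]]$W[i] - 1e-6
    expect_equal(unname(a[i]), (loss(m1) - loss(m2)) / 2e-6, tolerance = 1e-4)
  }
})

test_that("class weights follow the inverse-frequency formula", {
  w <- class_weights(
    rep(c("N", "SVEB", "VEB"), c(90, 5, 5)), c("N", "SVEB", "VEB")
  )
  expect_equal(unname(w), c(100 / 270, 100 / 15, 100 / 15))
  expect_error(
    class_weights(rep("N", 10), c("N", "SVEB", "VEB")),
    "absent from training data: SVEB, VEB"
  )
})

test_that("training errors before starting when a class is missing", {
  sets <- small_sets()
  only_n <- subset_segments(sets$train, sets$train$super_label == "N")
  m <- build_model(mf_model_spec(3, 32, conv_init = "default", nf = 3))
  expect_error(train_mf(m, only_n, sets$val, epochs = 1), "absent from training data")
})

test_that("frozen kernels are bit-identical after training", {
  sets <- small_sets()
  bank <- small_bank("derivative", 32L)
  spec <- mf_model_spec(3, 32,
    nf = length(bank$labels),
    conv_trainable = FALSE, seed = 2
  )
  m0 <- build_model(spec, bank)
  m1 <- train_mf(m0, sets$train, sets$val, epochs = 3)
  expect_identical(m1$params$conv_w, m0$params$conv_w)
  expect_identical(m1$params$conv_b, m0$params$conv_b)
  expect_false(identical(m1$params$out_w, m0$params$out_w))
  expect_equal(nrow(m1$history), 3)
})

test_that("training is deterministic given the spec seed", {
  sets <- small_sets()
  bank <- small_bank("derivative", 32L)
  spec <- mf_model_spec(3, 32, nf = length(bank$labels), seed = 7)
  m1 <- train_mf(build_model(spec, bank), sets$train, sets$val, epochs = 3)
  m2 <- train_mf(build_model(spec, bank), sets$train, sets$val, epochs = 3)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("bank/spec mismatches are rejected with names", {
  bank <- small_bank("derivative", 32L)
  expect_error(
    build_model(mf_model_spec(3, 64, nf = 3), bank),
    "expected NK=64, NF=3"
  )
  expect_error(
    build_model(mf_model_spec(3, 32, nf = 3, conv_init = "default"), bank),
    "omitted"
  )
  expect_error(
    build_model(mf_model_spec(3, 32, nf = 3, input_feature = "signal"), bank),
    "does not match"
  )
  expect_error(build_model(mf_model_spec(3, 32, nf = 3)), "requires a template bank")
})

test_that("models round-trip through JSON with identical predictions", {
  sets <- small_sets()
  bank <- small_bank("derivative", 32L)
  spec <- mf_model_spec(3, 32, nf = length(bank$labels), seed = 4)
  m <- train_mf(build_model(spec, bank), sets$train, sets$val, epochs = 3)
  path <- file.path(withr::local_tempdir(), "model.json")
  save_model(m, path)
  m2 <- load_model(path)
  p1 <- predict_mf(m, sets$test)
  p2 <- predict_mf(m2, sets$test)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the derivative input is front-padded to the window length", {
  X <- matrix(1:128, nrow = 2, byrow = TRUE)
  f <- mfbeat:::feature_windows(X, "derivative")
  expect_equal(dim(f), c(2L, 64L))
  expect_equal(f[, 1], f[, 2]) # repeated edge value
  expect_equal(f[1, -1], rep(1, 63))
})
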