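test_that("first_derivative is the discrete difference", {
  expect_equal(first_derivative(c(0, 1, 3, 6)), c(1, 2, 3))
  expect_equal(first_derivative(rep(4, 10)), rep(0, 9))
  # ramp + step: symbolic difference is slope + impulse at the step
  x <- 0.5 * (0:19) + c(rep(0, 10), rep(2, 10))
  expect_equal(first_derivative(x), rep(0.5, 19) + c(rep(0, 9), 2, rep(0, 9)))
  m <- rbind(c(1, 2, 4), c(0, -1, -3))
  expect_equal(first_derivative(m), rbind(c(1, 2), c(-1, -2)))
  expect_error(first_derivative(1), "at least 2")
})

test_that("templates are group means with the documented central crop", {
  w <- matrix(rep(sin(1:64 / 4), 5), nrow = 5, byrow = TRUE)
  segs <- mfbeat:::new_beat_segments(
    w, rep("r1", 5), 1:5 * 100L, rep("N", 5), rep("N", 5),
    fs = 128
  )
  b64 <- extract_templates(segs, "sub_class", "signal", 64)
  expect_equal(unname(b64$kernels[, "N"]), sin(1:64 / 4))
  b32 <- extract_templates(segs, "sub_class", "signal", 32)
  expect_equal(unname(b32$kernels[, "N"]), sin(17:48 / 4)) # central [16, 48)
  # derivative feature: front-padded difference; crop equals the
  # unpadded derivative's samples [15, 47) (0-based), frozen by contract
  bd <- extract_templates(segs, "sub_class", "derivative", 32)
  d <- diff(sin(1:64 / 4))
  expect_equal(unname(bd$kernels[, "N"]), d[16:47])
  expect_error(extract_templates(segs, "sub_class", "signal", 65), "exceeds")
})

test_that("template extraction is order-invariant and conserves groups", {
  segs <- small_sets()$train
  b1 <- extract_templates(segs, "sub_class", "derivative", 32)
  set.seed(2)
  b2 <- extract_templates(
    subset_segments(segs, sample(n_beats(segs))), "sub_class", "derivative", 32
  )
  expect_equal(b1$kernels, b2$kernels)
  expect_identical(b1$labels, sort(unique(segs$sub_label)))
  b_super <- extract_templates(segs, "super_class", "signal", 32)
  expect_identical(b_super$labels, sort(unique(segs$super_label)))
  b_rec <- extract_templates(segs, "per_record_sub_class", "signal", 32)
  expect_identical(
    b_rec$labels,
    sort(unique(paste(segs$record_id, segs$sub_label, sep = ":")))
  )
  expect_equal(sum(b1$group_sizes), n_beats(segs))
})

test_that("averaging and differencing commute for derivative templates", {
  segs <- small_sets()$train
  bd <- extract_templates(segs, "sub_class", "derivative", 64)
  bs <- extract_templates(segs, "sub_class", "signal", 64)
  for (lab in bd$labels) {
    d_of_mean <- diff(bs$kernels[, lab])
    expect_equal(unname(bd$kernels[-1, lab]), unname(d_of_mean), tolerance = 1e-12)
  }
})

brute_correlate <- function(x, h) {
  n <- length(x)
  k <- length(h)
  pad <- (k - 1) %/% 2
  vapply(seq_len(n), function(t) {
    s <- 0
    for (j in seq_len(k)) {
      p <- t + j - 1 - pad
      if (p >= 1 && p <= n) s <- s + x[p] * h[j]
    }
    s
  }, numeric(1))
}

test_that("correlate matches the double-loop oracle and known identities", {
  # impulse template reproduces the input up to the padding alignment
  x <- rnorm(40)
  h <- c(1, numeric(7))
  expect_equal(correlate(x, h)[4:40], x[1:37]) # pad_left = 3
  # unit-energy autocorrelation peaks at the template energy
  h2 <- sin(1:16 / 3)
  h2 <- h2 / sqrt(sum(h2^2))
  y <- correlate(c(numeric(20), h2, numeric(20)), h2)
  expect_equal(max(y), 1, tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:80, 1)
    k <- sample(2:n, 1)
    x <- rnorm(n)
    h <- rnorm(k)
    expect_lt(max(abs(correlate(x, h) - brute_correlate(x, h))), 1e-9)
  }
  expect_error(correlate(rnorm(4), rnorm(9)), "longer than input")
})

test_that("correlate is linear in both arguments", {
  set.seed(4)
  x1 <- rnorm(50)
  x2 <- rnorm(50)
  h1 <- rnorm(16)
  h2 <- rnorm(16)
  a <- 2.5
  b <- -1.25
  expect_equal(
    correlate(a * x1 + b * x2, h1),
    a * correlate(x1, h1) + b * correlate(x2, h1)
  )
  expect_equal(
    correlate(x1, a * h1 + b * h2),
    a * correlate(x1, h1) + b * correlate(x1, h2)
  )
})

test_that("mf_classify picks the matching template and breaks ties low", {
  kernels <- cbind(
    A = c(1, numeric(15)), B = c(numeric(15), 1),
    C = sin(1:16) / 10
  )
  bank <- structure(
    list(
      labels = colnames(kernels), kernels = kernels, nk = 16L,
      granularity = "sub_class", feature_kind = "signal",
      group_sizes = c(1L, 1L, 1L)
    ),
    class = "template_bank"
  )
  d <- mf_classify(c(numeric(10), 5, numeric(21)), bank)
  expect_equal(d$best_label, "A") # same max for A and B -> lexicographic
  expect_equal(unname(d$scores["A"]), unname(d$scores["B"]))
  d0 <- mf_classify(numeric(32), bank)
  expect_equal(unname(d0$scores), c(0, 0, 0))
  expect_equal(d0$best_label, "A")
})

test_that("the matched-filter bank separates clean synthetic classes", {
  segs <- small_sets()$train
  bank <- extract_templates(segs, "sub_class", "signal", 32)
  test_clean <- memo("small_clean", prep_synth(14, 240, noise_percent = 0))
  pred <- mf_classify_segments(test_clean, bank)
  expect_gt(mean(pred == test_clean$sub_label), 0.9)
})
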