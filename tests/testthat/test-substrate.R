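test_that("net input aggregates scaled projections and handles edge cases", {
  l_in <- layer_spec("a", 3, clamped = TRUE)
  l_out <- layer_spec("b", 3)
  net <- network_spec(list(l_in, l_out),
                      list(projection_spec("a", "b", diag(1, 3))))
  acts <- list(a = c(1, 0, 0), b = numeric(3))
  expect_equal(compute_net_input(net, "b", acts), c(1, 0, 0))
  # no incoming projections -> zero vector
  expect_equal(compute_net_input(net, "a", acts), numeric(3))

  # two projections with scales 1 and 2: hand-computed weighted sum
  W1 <- matrix(c(0.5, 1, 0.25, 0), 2, 2)
  W2 <- matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)
  net2 <- network_spec(
    list(layer_spec("s1", 2, clamped = TRUE), layer_spec("s2", 2, clamped = TRUE),
         layer_spec("d", 2)),
    list(projection_spec("s1", "d", W1, scale = 1),
         projection_spec("s2", "d", W2, scale = 2)))
  a1 <- c(1, 0.5)
  a2 <- c(0.5, 1)
  expected <- (as.numeric(W1 %*% a1) + 2 * as.numeric(W2 %*% a2)) / 2
  got <- compute_net_input(net2, "d", list(s1 = a1, s2 = a2, d = numeric(2)))
  expect_equal(got, expected)

  # dimension mismatch is a configuration error
  expect_error(compute_net_input(net, "b", list(a = c(1, 0), b = numeric(3))),
               "mismatch")
})

test_that("kWTA threshold sits at the midpoint and matches a sort oracle", {
  expect_equal(kwta_threshold(c(0.9, 0.5, 0.1), 1), 0.7)
  # k = n suppresses nothing
  expect_lt(kwta_threshold(c(0.3, 0.2), 2), 0.2)
  expect_error(kwta_threshold(c(1, 2), 0), "k must")
  expect_error(kwta_threshold(c(1, 2), 3), "k must")

  set.seed(42)
  for (rep in 1:50) {
    nvec <- stats::runif(10)
    k <- sample(1:9, 1)
    thr <- kwta_threshold(nvec, k)
    srt <- sort(nvec, decreasing = TRUE)
    if (srt[k] > srt[k + 1]) {
      expect_identical(which(nvec > thr), which(rank(-nvec) <= k))
    }
  }
})

test_that("activation function is a logistic with the documented anchors", {
  expect_equal(activation_fn(0), 0.5)
  expect_equal(activation_fn(100), 1, tolerance = 1e-6)
  expect_equal(activation_fn(-100), 0, tolerance = 1e-6)
  expect_equal(activation_fn(0.2, gain = 5), 1 / (1 + exp(-1)))
  drives <- seq(-2, 2, by = 0.1)
  expect_true(all(diff(activation_fn(drives)) >= 0))
})

test_that("settling respects clamps, converges, and finds fixed points", {
  # all layers clamped: converges immediately to the clamp patterns
  net <- network_spec(list(layer_spec("a", 2, clamped = TRUE),
                           layer_spec("b", 2, clamped = TRUE)), list())
  r <- settle(net, clamps = list(a = c(1, 0), b = c(0, 1)))
  expect_equal(r$cycles_run, 1L)
  expect_true(r$converged)
  expect_equal(r$final_act$a, c(1, 0))

  # one clamped source driving a 2-unit layer: fixed point is the logistic
  # of the drive left after midpoint inhibition
  net2 <- network_spec(
    list(layer_spec("src", 2, clamped = TRUE), layer_spec("dst", 2, k = 1)),
    list(projection_spec("src", "dst", diag(1, 2), scale = 1)))
  r2 <- settle(net2, clamps = list(src = c(1, 0)))
  expect_true(r2$converged)
  expect_equal(r2$final_act$dst[1], 1 / (1 + exp(-5 * 0.5)), tolerance = 0.02)

  # zero weights everywhere: everything relaxes to the no-drive activation
  net3 <- network_spec(
    list(layer_spec("src", 2, clamped = TRUE), layer_spec("dst", 3, k = 3)),
    list(projection_spec("src", "dst", matrix(0, 3, 2))))
  r3 <- settle(net3, clamps = list(src = c(1, 1)))
  expect_true(all(abs(r3$final_act$dst - 0.5) < 0.02))
})

test_that("activations stay in [0, 1] on random networks and settling is deterministic", {
  set.seed(7)
  for (rep in 1:10) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    net <- network_spec(
      list(layer_spec("x", n1, clamped = TRUE),
           layer_spec("y", n2, k = sample(n2, 1)),
           layer_spec("z", n1, k = 1)),
      list(projection_spec("x", "y", init_weights(n2, n1), scale = runif(1, 0, 2)),
           projection_spec("y", "z", init_weights(n1, n2)),
           projection_spec("z", "y", init_weights(n2, n1))))
    clamp <- as.numeric(runif(n1) > 0.5)
    r <- settle(net, clamps = list(x = clamp), trace = TRUE)
    expect_true(all(r$trace$act >= 0 & r$trace$act <= 1))
    r2 <- settle(net, clamps = list(x = clamp), trace = TRUE)
    expect_identical(r$final_act, r2$final_act)
    expect_identical(r$trace, r2$trace)
  }
})

test_that("Hebbian updates converge weights onto the presynaptic pattern", {
  # fixed point when pre equals the weight
  W <- matrix(0.3, 1, 1)
  expect_equal(hebbian_update(0.3, 1, W, lr = 0.1), W)
  # direct arithmetic
  expect_equal(hebbian_update(1, 1, matrix(0, 1, 1), lr = 0.1)[1, 1], 0.1)
  # repeated pairing: monotone geometric convergence to pre
  pre <- c(1, 0.6, 0)
  post <- c(1, 0.5)
  W <- matrix(0, 2, 3)
  prev_gap <- Inf
  for (i in 1:300) {
    W <- hebbian_update(pre, post, W, lr = 0.04)
    gap <- max(abs(W[1, ] - pre))
    expect_lte(gap, prev_gap + 1e-12)
    prev_gap <- gap
  }
  expect_equal(W[1, ], pre, tolerance = 0.01)
  # closed form for the active row: w_t = pre * (1 - (1 - lr)^t)
  expect_equal(W[2, 1], 1 - (1 - 0.04 * 0.5)^300, tolerance = 1e-6)
})

test_that("contrastive error-driven rule has the documented local structure", {
  W <- matrix(0.5, 1, 1)
  expect_equal(error_driven_update(1, 1, 1, 1, W, lr = 0.1), W)
  expect_equal(error_driven_update(1, 0, 1, 1, matrix(0, 1, 1), lr = 0.1)[1, 1],
               0.1)
  expect_error(error_driven_update(c(1, 0), 1, 1, 1, W), "mismatched")
})

test_that("a two-layer net learns any bijective localist mapping to criterion", {
  set.seed(11)
  perm <- sample(0:9)
  W <- init_weights(10, 10)
  learned <- FALSE
  for (ep in 1:100) {
    correct <- 0
    for (j in 1:10) {
      pre <- replace(numeric(10), j, 1)
      target <- replace(numeric(10), perm[j] + 1, 1)
      nin <- as.numeric(W %*% pre)
      thr <- kwta_threshold(nin, 1)
      minus <- as.numeric(activation_fn(nin - thr) > 0.5)
      if (which.max(nin) == perm[j] + 1) correct <- correct + 1
      W <- error_driven_update(pre, minus, pre, target, W, lr = 0.04)
    }
    if (correct == 10) {
      learned <- TRUE
      break
    }
  }
  expect_true(learned)
})

test_that("three-factor updates follow dopamine sign and cancel over balanced sequences", {
  W <- matrix(0.5, 2, 2)
  expect_equal(three_factor_update(c(1, 0), c(1, 0), 0, W), W)
  up <- three_factor_update(1, 1, 1, matrix(0, 1, 1), lr = 0.1, pathway_sign = 1)
  dn <- three_factor_update(1, 1, 1, matrix(0.5, 1, 1), lr = 0.1, pathway_sign = -1)
  expect_equal(up[1, 1], 0.1)
  expect_equal(dn[1, 1], 0.4)
  # alternating +/- dopamine of equal size nets out to zero change
  W <- matrix(0.5, 2, 2)
  for (i in 1:20) {
    W <- three_factor_update(c(1, 1), c(1, 0), +0.5, W, lr = 0.1)
    W <- three_factor_update(c(1, 1), c(1, 0), -0.5, W, lr = 0.1)
  }
  expect_equal(W, matrix(0.5, 2, 2))
})
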