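test_that("valid convolution lengths follow floor((n - k)/s) + 1", {
  expect_equal(conv_output_length(200, 11, 3), 64)
  expect_equal(conv_output_length(64, 3, 2), 31)
  for (n in c(1, 5, 17)) expect_equal(conv_output_length(n, 1, 1), n)
  expect_error(conv_output_length(10, 11, 1), "shorter")
})

test_that("the shape trace reproduces the published architecture table", {
  sh <- architecture_shapes()
  expect_equal(sh$shape,
               c("200 x 1",
                 "64 x 16", "64 x 16", "64 x 16", "31 x 16",
                 "27 x 32", "27 x 32", "27 x 32", "13 x 32",
                 "11 x 64", "11 x 64", "11 x 64", "5 x 64",
                 "320", "4", "324", "64", "4"))
})

test_that("the parameter trace reproduces the published counts", {
  pc <- count_parameters()
  expect_equal(pc$trainable[pc$trainable > 0],
               c(192, 32, 2592, 64, 6208, 128, 20800, 260))
  expect_equal(pc$non_trainable[pc$non_trainable > 0], c(32, 64, 128))
  expect_equal(sum(pc$trainable), 30276)
  expect_equal(sum(pc$non_trainable), 224)
})

test_that("shape-inconsistent architectures are rejected by name", {
  bad <- hb_architecture(input_len = 8)  # first conv kernel 11 cannot fit
  expect_error(count_parameters(bad), "layer 1")
})

test_that("builds are seeded and the built model matches the accounting", {
  m1 <- build_model(seed = 5)
  m2 <- build_model(seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(seed = 6)
  expect_false(identical(m1$params, m3$params))
  n_actual <- sum(vapply(m1$params, length, numeric(1)))
  expect_equal(n_actual, sum(count_parameters()$trainable))
  n_running <- sum(vapply(m1$bn, function(b) length(b$mean) + length(b$var),
                          numeric(1)))
  expect_equal(n_running, sum(count_parameters()$non_trainable))
})

test_that("forward output rows are probability vectors", {
  m <- build_model(seed = 2)
  p <- forward(m, matrix(0, 3, 200), matrix(0, 3, 4))
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_equal(colnames(p), aami_classes)
})

test_that("inference is batch-independent and permutation-equivariant", {
  m <- build_model(seed = 2)
  set.seed(10)
  X <- matrix(rnorm(6 * 200), 6, 200)
  R <- matrix(rnorm(6 * 4), 6, 4)
  p_all <- forward(m, X, R)
  p_one <- forward(m, X[4, , drop = FALSE], R[4, , drop = FALSE])
  expect_equal(p_all[4, ], p_one[1, ], tolerance = 1e-12)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(forward(m, X[perm, ], R[perm, ]), p_all[perm, ],
               tolerance = 1e-12)
})

test_that("shape mismatches are reported with expected dimensions", {
  m <- build_model(seed = 2)
  expect_error(forward(m, matrix(0, 2, 150), matrix(0, 2, 4)), "200")
  expect_error(forward(m, matrix(0, 2, 200), matrix(0, 3, 4)), "matching")
})

test_that("backpropagated gradients match finite differences", {
  m <- build_model(seed = 3)
  set.seed(9)
  X <- matrix(rnorm(4 * 200), 4, 200)
  R <- matrix(rnorm(4 * 4), 4, 4)
  y <- c(1L, 2L, 3L, 4L)
  lc <- loss_config("focal", gamma = 2)
  fw <- ecgbeats:::nn_forward(m, X, R, training = TRUE)
  lg <- ecgbeats:::loss_grad_logits(lc, fw$probs, y)
  bk <- ecgbeats:::nn_backward(m, fw$cache, lg$dlogits)
  loss_at <- function(model) {
    f <- ecgbeats:::nn_forward(model, X, R, training = TRUE)
    ecgbeats:::loss_grad_logits(lc, f$probs, y)$loss
  }
  eps <- 1e-5
  for (pn in c("L01_W", "L02_gamma", "L06_beta", "L09_W", "L16_W", "L17_b")) {
    for (k in 1:3) {
      i <- sample(length(m$params[[pn]]), 1)
      up <- m; up$params[[pn]][i] <- up$params[[pn]][i] + eps
      dn <- m; dn$params[[pn]][i] <- dn$params[[pn]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(bk$grads[[pn]][i], num, tolerance = 1e-4)
    }
  }
})
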