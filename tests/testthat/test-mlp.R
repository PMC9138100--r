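test_that("pooled R2 follows its definition", {
  y <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(pooled_r2(y, y)$pooled_r2, 1)
  expect_equal(pooled_r2(y, matrix(mean(y), 3, 1))$pooled_r2, 0)
  expect_equal(pooled_r2(y, matrix(c(0, 1, 1), 3, 1))$pooled_r2, 0.5)
  m <- pooled_r2(cbind(y, y * 2), cbind(y, y * 2))
  expect_equal(unname(m$per_output_r2), c(1, 1))
  expect_equal(m$sos, 0)
  expect_error(pooled_r2(matrix(1, 3, 1), matrix(1, 3, 1)), "zero total")
  expect_error(pooled_r2(matrix(1:4, 2), matrix(1:6, 3)), "same shape")
})

test_that("an identity-activation network reduces to least squares", {
  set.seed(21)
  X <- matrix(runif(60, 1, 5), 20, 3)
  Y <- X %*% matrix(c(1, -2, 0.5, 0.3, 1, 2), 3, 2) + 4
  fit <- fit_mlp(X, Y, hidden = 3, hidden_activation = "identity",
                 restarts = 3, maxit = 500, seed = 1)
  expect_gte(fit$metrics$pooled_r2, 1 - 1e-8)
})

test_that("a teacher network is recovered from its own noise-free data", {
  tch <- gen_teacher_network(3, 4, 2, n_samples = 150, seed = 7)
  fit <- fit_mlp(tch$X, tch$Y, hidden = 4, restarts = 10, maxit = 3000,
                 seed = 3, normalize = FALSE)
  expect_lt(fit$metrics$sos, 1e-6)
  # weight-path importances match the teacher (hidden-unit permutation and
  # tanh sign symmetry leave the importance matrix invariant)
  expect_lt(max(abs(yoon_ri(fit$params) - yoon_ri(tch$params))), 5)
  # predictions reproduce the teacher on fresh inputs
  set.seed(99)
  Xf <- matrix(runif(30), 10, 3)
  expect_equal(predict(fit$params, Xf),
               predict(tch$params, Xf), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("training is reproducible and validates its inputs", {
  tch <- gen_teacher_network(2, 3, 1, n_samples = 25, seed = 1)
  f1 <- fit_mlp(tch$X, tch$Y, hidden = 2, restarts = 2, maxit = 50, seed = 5)
  f2 <- fit_mlp(tch$X, tch$Y, hidden = 2, restarts = 2, maxit = 50, seed = 5)
  expect_identical(f1$params$W1, f2$params$W1)
  expect_identical(f1$metrics$sos, f2$metrics$sos)
  Xb <- tch$X; Xb[1, 1] <- NA
  expect_error(fit_mlp(Xb, tch$Y), "non-finite")
  expect_error(fit_mlp(tch$X, tch$Y, hidden = 0), ">= 1")
  expect_error(mlp_parameters(matrix(1, 2, 3), rep(0, 2), matrix(1, 3, 1), 0),
               "dimensions")
  expect_error(mlp_parameters(matrix(1, 2, 3), rep(0, 3), matrix(1, 3, 1), 0,
                              hidden_activation = "relu"), "activation")
})

test_that("topology screening selects the row-wise minimum of its table", {
  tch <- gen_teacher_network(3, 3, 1, n_samples = 30, seed = 2)
  cfg <- training_config(hidden = 2:4, activations = "tanh", restarts = 2,
                         maxit = 200, validation_fraction = 0.2, seed = 11)
  scr <- screen_topologies(tch$X, tch$Y, cfg)
  expect_equal(nrow(scr$table), 3L)
  expect_equal(scr$selected, which.min(scr$table$sos_val))
  # determinism: same configuration, same selection and weights
  scr2 <- screen_topologies(tch$X, tch$Y, cfg)
  expect_identical(scr$selected, scr2$selected)
  expect_identical(scr$best$params$W1, scr2$best$params$W1)
  # degenerate screen returns its only candidate
  one <- screen_topologies(tch$X, tch$Y,
                           training_config(hidden = 3, restarts = 1,
                                           maxit = 100, seed = 1))
  expect_equal(nrow(one$table), 1L)
  expect_equal(one$selected, 1L)
  expect_error(training_config(hidden = 0), "\\[1, 64\\]")
  expect_error(training_config(validation_fraction = 1), "validation")
})

test_that("weight-path importance is normalized, signed and exact", {
  # one input: importance is +/-100 whatever the hidden layer
  p1 <- mlp_parameters(matrix(c(0.3, -0.2), 1, 2), c(0, 0),
                       matrix(c(0.5, 0.4), 2, 1), 0)
  expect_equal(unname(yoon_ri(p1)[1, 1]), 100 * sign(0.3 * 0.5 - 0.2 * 0.4))
  # mirror-image inputs split +50 / -50
  pm <- mlp_parameters(matrix(c(1, -1, 2, -2), 2, 2), c(0, 0),
                       matrix(c(0.7, 0.1), 2, 1), 0)
  expect_equal(unname(yoon_ri(pm)[, 1]), c(50, -50))
  # brute-force path enumeration oracle on random weights
  set.seed(31)
  W1 <- matrix(rnorm(15), 5, 3); W2 <- matrix(rnorm(6), 3, 2)
  p <- mlp_parameters(W1, rnorm(3), W2, rnorm(2))
  ri <- yoon_ri(p)
  expect_equal(unname(ri), yoon_bruteforce(W1, W2), tolerance = 1e-10)
  expect_equal(unname(colSums(abs(ri))), c(100, 100), tolerance = 1e-9)
  # biases are excluded: changing them never moves the importances
  p_b <- mlp_parameters(W1, rnorm(3, 10), W2, rnorm(2, -5))
  expect_equal(yoon_ri(p_b), ri)
  # literal (signed-denominator) reading as documented alternative
  P <- W1 %*% W2
  expect_equal(unname(yoon_ri(p, literal = TRUE)),
               sweep(P, 2, colSums(P), "/") * 100, tolerance = 1e-12)
})

test_that("importance is invariant to hidden-unit permutation and tracks weight scale", {
  set.seed(41)
  W1 <- matrix(rnorm(12), 4, 3); W2 <- matrix(rnorm(6), 3, 2)
  B1 <- rnorm(3)
  ri <- yoon_ri(mlp_parameters(W1, B1, W2, rnorm(2)))
  perm <- c(3, 1, 2)
  ri_p <- yoon_ri(mlp_parameters(W1[, perm], B1[perm], W2[perm, ], rnorm(2)))
  expect_equal(ri_p, ri, tolerance = 1e-12)
  # scaling one input's weights scales its unnormalized path sum linearly
  lam <- 3.7
  W1s <- W1; W1s[2, ] <- lam * W1s[2, ]
  expect_equal((W1s %*% W2)[2, ], lam * (W1 %*% W2)[2, ], tolerance = 1e-12)
  # an output whose path sums all vanish has undefined importance
  expect_error(yoon_ri(mlp_parameters(matrix(0, 2, 2), c(0, 0),
                                      matrix(c(0, 0, 1, 1), 2, 2), c(0, 0))),
               "undefined importance")
})
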