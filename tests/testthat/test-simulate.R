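test_that("the study-shaped generator stamps the ND block deterministically", {
  m <- gen_extract_matrix(sim_config_beetroot(seed = 123))
  expect_equal(dim(m), c(20L, 17L))
  expect_equal(n_nd(m), 88L)
  expect_true(all(m$nd[13:20, 1:11]))
  expect_true(all(m$values[!m$nd] >= 0))
  # same seed, identical matrix; different seed, different draws
  m2 <- gen_extract_matrix(sim_config_beetroot(seed = 123))
  expect_identical(m$values, m2$values)
  m3 <- gen_extract_matrix(sim_config_beetroot(seed = 124))
  expect_false(identical(m$values, m3$values))
  # byte-identical CSV under the same seed
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_matrix(m, p1); write_matrix(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("simulated marginals and block correlations match the configuration", {
  vars <- data.frame(name = c("a", "b", "c", "d"),
                     mean = c(100, 80, 60, 40), sd = c(10, 8, 6, 4))
  cfg <- matrix_sim_config(10000, vars,
                           blocks = list(list(vars = c("a", "b", "c"),
                                              rho = 0.9)),
                           seed = 77)
  x <- gen_extract_matrix(cfg)$values
  expect_equal(unname(colMeans(x)), vars$mean, tolerance = 0.02)
  expect_equal(unname(apply(x, 2, sd)), vars$sd, tolerance = 0.02)
  cc <- cor(x)
  expect_equal(cc["a", "b"], 0.9, tolerance = 0.02)
  expect_equal(cc["b", "c"], 0.9, tolerance = 0.02)
  expect_lt(abs(cc["a", "d"]), 0.05)
})

test_that("impossible configurations fail at validation time", {
  vars <- data.frame(name = c("a", "b", "c"), mean = 1, sd = 0.1)
  # rho = -0.9 on three variables is not a valid correlation structure
  expect_error(matrix_sim_config(5, vars,
                                 blocks = list(list(vars = c("a", "b", "c"),
                                                    rho = -0.9))),
               "non-PSD")
  expect_error(matrix_sim_config(5, vars,
                                 blocks = list(list(vars = "zz", rho = 0.5))),
               "unknown variable")
  expect_error(matrix_sim_config(5, vars,
                                 nd_block = list(rows = 9, cols = "a")),
               "out of range")
  vars$sd[1] <- -1
  expect_error(matrix_sim_config(5, vars), "sds")
})

test_that("absorbance panels invert exactly to their generating pigments", {
  sim <- gen_absorbance_panel(conc_bc = c(9.5, 2, 0.4),
                              conc_bx = c(3.2, 1.5, 0.1),
                              impurity = 0.05, F_dilution = 25, noise_sd = 0)
  out <- reduce_absorbance_panel(sim$panel)
  expect_equal(out$betacyanin, sim$truth$betacyanin, tolerance = 1e-9)
  expect_equal(out$betaxanthin, sim$truth$betaxanthin, tolerance = 1e-9)
  # zero pigments, zero impurity: dark wells
  z <- gen_absorbance_panel(0, 0, impurity = 0, noise_sd = 0)
  expect_equal(z$panel$a538, 0)
  expect_equal(z$panel$a476, 0)
  expect_error(gen_absorbance_panel(-1, 0), ">= 0")
})

test_that("noisy reduction is unbiased around the generating concentration", {
  n <- 1000
  sim <- gen_absorbance_panel(rep(9.5, n), rep(3.2, n), impurity = 0.05,
                              noise_sd = 0.005, seed = 42)
  out <- reduce_absorbance_panel(sim$panel)
  for (ch in c("betacyanin", "betaxanthin")) {
    err <- out[[ch]] - sim$truth[[ch]]
    se <- sd(err) / sqrt(n)
    expect_lt(abs(mean(err)), 3 * se)
  }
})

test_that("teacher networks are self-consistent and seed-reproducible", {
  t1 <- gen_teacher_network(4, 3, 2, n_samples = 20, seed = 9)
  expect_equal(unname(predict(t1$params, t1$X)), unname(t1$Y),
               tolerance = 1e-12)
  t2 <- gen_teacher_network(4, 3, 2, n_samples = 20, seed = 9)
  expect_identical(t1$params$W1, t2$params$W1)
  expect_identical(t1$Y, t2$Y)
  expect_equal(yoon_ri(t1$params),
               yoon_ri(t2$params))
})

test_that("simulated matrices flow through the whole ranking stage", {
  m <- gen_extract_matrix(sim_config_beetroot(seed = 5))
  ss <- standard_score(minmax_normalize(m, nd = "zero"))
  expect_equal(sort(ss$rank), 1:20)
  expect_true(all(ss$ss >= 0 & ss$ss <= 1))
  ord <- rank_extracts(ss)
  expect_length(ord, 20L)
})
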