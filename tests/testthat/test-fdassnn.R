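test_that("Nguyen-Widrow initialization spreads weights at the NW norm", {
  net <- nguyen_widrow_init(c(930, 75, 65, 3), seed = 1)
  expect_equal(unname(sqrt(rowSums(net$W1^2))),
               rep(0.7 * 75^(1 / 930), 75))
  expect_equal(unname(sqrt(rowSums(net$W2^2))),
               rep(0.7 * 65^(1 / 75), 65))
  expect_equal(net$b3, rep(0, 3))
  net2 <- nguyen_widrow_init(c(930, 75, 65, 3), seed = 1)
  expect_identical(net, net2)
  net3 <- nguyen_widrow_init(c(930, 75, 65, 3), seed = 2)
  expect_false(identical(net$W1, net3$W1))
  expect_error(nguyen_widrow_init(c(930, 0, 65, 3)), "positive")
})

test_that("forward pass equals the scalar-loop oracle", {
  net <- toy_net(c(4, 2, 2, 3), seed = 7)
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(4)
    expect_equal(as.vector(nn_forward(net, x)), forward_oracle(net, x),
                 tolerance = 1e-12)
  }
  # zero weights give sigmoid(0) = 0.5 everywhere
  z <- net
  z$W1[] <- 0; z$W2[] <- 0; z$W3[] <- 0; z$b3[] <- 0
  expect_equal(as.vector(nn_forward(z, rnorm(4))), rep(0.5, 3))
  # outputs bounded in (0,1) for random parameters
  for (seed in 1:5) {
    n <- toy_net(c(6, 3, 3, 3), seed = seed)
    y <- nn_forward(n, matrix(rnorm(60, sd = 5), 6, 10))
    expect_true(all(y > 0 & y < 1))
  }
  expect_error(nn_forward(net, rnorm(5)), "expected 4")
})

test_that("AARE matches hand-evaluated cases", {
  expect_equal(aare(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(aare(estimated = 0.5, desired = 0.6), 0.2)
  expect_equal(aare(c(0.5, 0.5), c(0.4, 0.6)), 0.2)
  # clamp guards small estimates
  expect_equal(aare(estimated = 0.01, desired = 0.06, eps = 0.05), 1)
  expect_error(aare(numeric(0), numeric(0)), "length")
})

test_that("analytic gradient matches central finite differences", {
  net <- toy_net(c(4, 2, 2, 3), seed = 3)
  set.seed(4)
  X <- matrix(rnorm(4 * 6), 4, 6)
  T_ <- matrix(runif(18, 0.1, 0.9), 3, 6)
  g <- analytic_gradient(net, X, T_)
  for (block in c("W1", "W2", "W3", "b3")) {
    fd <- fd_gradient(net, block, X, T_)
    expect_lt(max(abs(fd - g[[block]]) / (abs(fd) + 1e-10)), 1e-6)
  }
})

test_that("training descends, stops by rule, and is reproducible", {
  d <- generate_training_windows(40, seed = 5)
  cfg <- train_config(max_epochs = 60, seed = 5)
  net <- nguyen_widrow_init(c(930, 12, 8, 3), seed = 5)
  tr <- nn_train(net, d$windows, d$targets, cfg)
  expect_lte(tail(tr$history$train_aare, 1), tr$history$train_aare[1])
  expect_equal(tr$trained$stop, "epoch-cap")
  expect_equal(nrow(tr$history), 60)
  # validation curve is populated under the 80:20 split
  expect_true(all(is.finite(tr$history$val_aare)))
  # bit-reproducible under the same seed
  tr2 <- nn_train(net, d$windows, d$targets, cfg)
  expect_identical(tr$W1, tr2$W1)
  expect_identical(tr$history, tr2$history)
  # hidden biases never appear; only the output bias trains
  expect_false(identical(tr$b3, net$b3))
  expect_error(nn_train(net, d$windows, d$targets * 0, cfg), "\\(0, 1\\]")
})

test_that("activation banding follows the threshold convention", {
  expect_equal(band_activation(0.45), "Moderate")
  expect_equal(band_activation(0.85), "ExtremelySevere")
  expect_equal(band_activation(0.15), "Mild")
  expect_equal(band_activation(0), "Normal")
  expect_equal(band_activation(0.3), "Moderate")
  expect_equal(band_activation(0.6), "Severe")
  expect_equal(band_activation(0.8), "Severe")   # "over 0.8" is strict
  expect_equal(band_activation(0.8 + 1e-9), "ExtremelySevere")
  expect_equal(band_activation(1), "ExtremelySevere")
  expect_error(band_activation(1.2), "\\[0, 1\\]")
  # monotone in activation
  a <- seq(0, 1, by = 0.01)
  expect_true(all(diff(band_rank(band_activation(a))) >= 0))
  # band midpoints re-band to their own band
  expect_equal(unname(band_activation(band_midpoints())), severity_bands())
})

test_that("prediction is deterministic and banding-consistent", {
  d <- generate_training_windows(6, seed = 6)
  net <- nguyen_widrow_init(c(930, 12, 8, 3), seed = 6)
  p1 <- predict(net, d$windows)
  p2 <- predict(net, d$windows)
  expect_identical(p1, p2)
  for (i in seq_along(dass_scales())) {
    s <- dass_scales()[i]
    expect_equal(p1[[s]], band_activation(p1[[paste0("act_", s)]]))
  }
})

test_that("disorder variant thresholds outputs at 0.5", {
  net <- nguyen_widrow_init(c(930, 30, 25, 3), seed = 1)
  w <- generate_training_windows(4, seed = 2)$windows
  flags <- predict_disorders(net, w)
  expect_true(all(flags %in% c(0L, 1L)))
  expect_equal(rownames(flags), c("MDD", "GAD", "PTSD"))
  # a zero network sits exactly at 0.5, which resolves to 0
  z <- net; z$W1[] <- 0; z$W2[] <- 0; z$W3[] <- 0; z$b3[] <- 0
  expect_equal(unname(predict_disorders(z, w[[1]])[, 1]), rep(0L, 3))
  wrong <- nguyen_widrow_init(c(930, 75, 65, 3), seed = 1)
  expect_error(predict_disorders(wrong, w[[1]]), "30")
})

test_that("disorder variant recovers a separable disorder signature", {
  # windows from subjects with vs without MDD-grade depression signal
  mk <- function(dep_band, n, offset) {
    lapply(seq_len(n), function(i) {
      b <- c(depression = dep_band, anxiety = "Normal", stress = "Normal")
      s <- generate_au_stream(b, NULL, generator_config(duration = 1),
                              seed = offset + i)
      stream_windows(s)[[1]]
    })
  }
  pos <- mk("ExtremelySevere", 30, 1000)
  neg <- mk("Normal", 30, 2000)
  X <- vapply(c(pos, neg), flatten_window, numeric(930))
  T_ <- rbind(rep(c(0.9, 0.1), each = 30),
              matrix(0.1, 2, 60))
  net <- nguyen_widrow_init(c(930, 30, 25, 3), seed = 3)
  net <- nn_train(net, X, T_, train_config(seed = 3))
  expect_equal(net$trained$stop, "error-target")
  test_pos <- mk("ExtremelySevere", 10, 3000)
  test_neg <- mk("Normal", 10, 4000)
  fp <- predict_disorders(net, vapply(test_pos, flatten_window,
                                      numeric(930)))
  fn <- predict_disorders(net, vapply(test_neg, flatten_window,
                                      numeric(930)))
  expect_gte(mean(fp["MDD", ]), 0.8)
  expect_lte(mean(fn["MDD", ]), 0.2)
})
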