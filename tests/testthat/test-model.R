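test_that("analytic gradients match finite differences for both variants", {
  set.seed(17)
  X <- matrix(rnorm(2 * 15, sd = 0.1), 2, 15)
  y <- matrix(rbinom(2 * 15, 1, 0.3), 2, 15)
  eps <- 1e-6
  for (variant in c("bidirectional", "unidirectional")) {
    m <- swrnet_init(variant, conv_filters = c(3, 2), kernel_size = 3,
                     lstm_units = 2, seed = 42)
    g <- swrnet:::.net_gradients(m$params, X, y)
    worst <- 0
    for (nm in names(m$params)) {
      if (grepl("_(mean|var)$", nm)) next
      for (i in seq_len(min(length(m$params[[nm]]), 5))) {
        pp <- m$params
        pp[[nm]][i] <- pp[[nm]][i] + eps
        lp <- swrnet:::.net_loss(pp, X, y)
        pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
        lm <- swrnet:::.net_loss(pp, X, y)
        num <- (lp - lm) / (2 * eps)
        worst <- max(worst, abs(num - g[[nm]][i]) /
                       max(1e-3, abs(num), abs(g[[nm]][i])))
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("the network is length-agnostic with sigmoid-bounded outputs", {
  m <- swrnet_init(seed = 3)
  for (N in c(625, 1250, 12500)) {
    yh <- predict(m, matrix(rnorm(N, sd = 0.05), 1, N))
    expect_identical(dim(yh), c(1L, as.integer(N)))
    expect_true(all(yh > 0 & yh < 1))
  }
  # inference is deterministic and batch elements are independent
  X2 <- matrix(rnorm(2 * 400, sd = 0.05), 2, 400)
  X2[2, ] <- X2[1, ]
  yh2 <- predict(m, X2)
  expect_equal(yh2[1, ], yh2[2, ], tolerance = 1e-12)
  expect_identical(predict(m, X2), predict(m, X2))
})

test_that("loss and metric match their closed forms", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(0, 0.9), -log(0.1), tolerance = 1e-9)
  expect_lt(bce_loss(c(0, 1), c(1e-7, 1 - 1e-7)), 1.1e-7)
  expect_message(v <- bce_loss(c(0, 1), c(0, 1)), "clipping")
  expect_lt(v, 1e-6)
  # independent elementwise oracle
  set.seed(9)
  y <- rbinom(50, 1, 0.5); p <- runif(50, 0.01, 0.99)
  oracle <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(bce_loss(y, p), oracle, tolerance = 1e-9)
  expect_equal(mse_metric(y, p), mean((y - p)^2), tolerance = 1e-12)
  expect_equal(mse_metric(c(1, 0), c(0.5, 0.5)), 0.25)
  expect_equal(mse_metric(p, p), 0)
})

test_that("unidirectional default keeps about twice the trainable parameters", {
  nb <- n_parameters(swrnet_init("bidirectional", seed = 1))
  nu <- n_parameters(swrnet_init("unidirectional", seed = 1))
  ratio <- nu[["trainable"]] / nb[["trainable"]]
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("training reduces the loss, is seed-deterministic, and validates inputs", {
  ss <- make_toy_sampleset(n = 40, T = 200, seed = 23)
  drops <- vapply(1:3, function(s) {
    m <- swrnet(ss, variant = "bidirectional", epochs = 6, seed = s,
                lstm_units = 4, conv_filters = c(8, 4))
    m$history$loss[1] - tail(m$history$loss, 1)
  }, 1)
  expect_gte(sum(drops > 0), 2)            # learning sanity across seeds
  m1 <- swrnet(ss, epochs = 2, seed = 7, lstm_units = 3, conv_filters = c(4, 3))
  m2 <- swrnet(ss, epochs = 2, seed = 7, lstm_units = 3, conv_filters = c(4, 3))
  expect_identical(m1$params, m2$params)   # bitwise training determinism
  expect_identical(m1$history, m2$history)
  expect_error(swrnet(ss, epochs = 0), class = "swrnet_validation_error")
  empty <- sample_set(array(numeric(0), c(0, 10, 1)),
                      array(numeric(0), c(0, 10, 1)), fs = 1250)
  expect_error(swrnet(empty, epochs = 1), class = "swrnet_validation_error")
})

test_that("models round-trip through disk and remain trainable", {
  ss <- make_toy_sampleset(n = 10, T = 120, seed = 29)
  m <- swrnet(ss, epochs = 1, seed = 5, lstm_units = 3, conv_filters = c(4, 3))
  X <- matrix(rnorm(300, sd = 0.05), 2, 150)
  path <- withr::local_tempfile(fileext = ".rds")
  save_swrnet(m, path)
  back <- load_swrnet(path)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-6)
  more <- swrnet_train(back, ss, epochs = 1)
  expect_identical(more$epochs_trained, 2L)
  expect_error(load_swrnet(file.path(tempdir(), "nope.rds")),
               class = "swrnet_format_error")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_swrnet(bad), class = "swrnet_format_error")
})

test_that("print, summary, coef and plot methods work on fitted models", {
  ss <- make_toy_sampleset(n = 10, T = 120, seed = 31)
  m <- swrnet(ss, val = ss, epochs = 1, seed = 5, lstm_units = 3,
              conv_filters = c(4, 3))
  expect_output(print(m), "swrnet bidirectional")
  expect_output(summary(m), "history")
  expect_named(coef(m)["conv1_W"], "conv1_W")
  pdf(NULL)
  expect_silent(plot(m))
  dev.off()
})
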