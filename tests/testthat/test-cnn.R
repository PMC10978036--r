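test_that("architecture matches the 40/20-channel GAP design", {
  m <- build_cnn(cnn_config(input_size = 32), seed = 1)
  expect_equal(n_parameters(m), 3 * 3 * 1 * 40 + 3 * 3 * 40 * 20 + 20)
  expect_identical(n_parameters(m), 7580L)
  x <- matrix(runif(32 * 32), 32)
  expect_length(feature_maps(m, x, layer = 1), 40L)
  expect_length(feature_maps(m, x, layer = 2), 20L)
  expect_length(m$weights$wd, 20L)

  small <- build_cnn(cnn_config(conv1_channels = 8, conv2_channels = 4),
                     seed = 1)
  expect_identical(n_parameters(small), 9L * 8L + 9L * 8L * 4L + 4L)
  with_bias <- build_cnn(cnn_config(conv1_channels = 8, conv2_channels = 4,
                                    use_bias = TRUE), seed = 1)
  expect_identical(n_parameters(with_bias),
                   9L * 8L + 9L * 8L * 4L + 4L + 8L + 4L + 1L)
})

test_that("zero weights give probability 1/2, score 0 and zero gradient", {
  m <- build_cnn(cnn_config(input_size = 16), seed = 1)
  m$weights <- lapply(m$weights, function(w) w * 0)
  x <- matrix(runif(256), 16)
  expect_identical(cnn_score(m, x), 0)
  expect_identical(cnn_predict(m, x), 0.5)
  expect_true(all(cnn_score_gradient(m, x) == 0))
  expect_true(all(vapply(feature_maps(m, x, 2),
                         function(fm) all(fm == 0), logical(1))))
})

test_that("classifier output is the sigmoid of the score", {
  m <- build_cnn(cnn_config(input_size = 16), seed = 3)
  set.seed(4)
  for (rep in 1:20) {
    x <- matrix(rnorm(256), 16)
    s <- cnn_score(m, x)
    expect_lt(abs(cnn_predict(m, x) - 1 / (1 + exp(-s))), 1e-12)
  }
})

test_that("bias-free score is positively homogeneous of degree 1", {
  m <- build_cnn(cnn_config(input_size = 16), seed = 5)
  set.seed(6)
  x <- matrix(rnorm(256), 16)
  s <- cnn_score(m, x)
  for (c in c(0.5, 2)) {
    expect_equal(cnn_score(m, c * x), c * s, tolerance = 1e-12)
  }
  # consequence: the gradient is invariant to positive scaling
  g <- cnn_score_gradient(m, x)
  expect_equal(cnn_score_gradient(m, 2 * x), g, tolerance = 1e-12)
  # and the all-zero image scores exactly 0
  expect_identical(cnn_score(m, matrix(0, 16, 16)), 0)
})

test_that("score gradient matches central finite differences", {
  m <- build_cnn(cnn_config(input_size = 24), seed = 7)
  set.seed(8)
  x <- matrix(runif(24 * 24), 24)
  g <- cnn_score_gradient(m, x)
  expect_identical(dim(g), dim(x))
  h <- 1e-3
  for (rep in 1:20) {
    i <- sample(24, 1); j <- sample(24, 1)
    xp <- x; xp[i, j] <- xp[i, j] + h
    xm <- x; xm[i, j] <- xm[i, j] - h
    num <- (cnn_score(m, xp) - cnn_score(m, xm)) / (2 * h)
    expect_lt(abs(g[i, j] - num), 1e-4 * (1 + abs(num)))
  }
})

test_that("feature maps are post-ReLU images of the right multiplicity", {
  m <- build_cnn(cnn_config(input_size = 32), seed = 9)
  x <- tiny_corpus()$images[2, , ]
  fm <- feature_maps(m, x, layer = 2)
  expect_length(fm, 20L)
  for (f in fm) {
    expect_identical(dim(f), c(32L, 32L))
    expect_true(all(f >= 0))
  }
  expect_error(feature_maps(m, x, layer = 3), "layer")
})

test_that("invalid inputs to the network are rejected", {
  m <- build_cnn(cnn_config(input_size = 16), seed = 1)
  expect_error(cnn_score(m, matrix(0, 2, 2)), "smaller than")
  expect_error(cnn_score(m, matrix(c(NA, rep(0, 255)), 16)), "non-finite")
  expect_error(cnn_score(m, matrix(0, 16, 8)), "square")
  expect_error(cnn_config(kernel_size = 4), "kernel_size")
})

test_that("training reduces the loss and separates the classes", {
  tr <- tiny_trained()
  r <- tr$report
  expect_identical(nrow(r), 40L)
  expect_lt(r$train_loss[40], r$train_loss[1])

  test <- tiny_test_corpus()
  acc <- classifier_accuracy(tr$model, test)
  expect_gte(acc, 0.9)

  s <- vapply(seq_along(test$labels),
              function(i) cnn_score(tr$model, test$images[i, , ]), numeric(1))
  expect_gt(mean(s[test$labels == 1L]), mean(s[test$labels == 0L]))
})

test_that("the trained model's top channel responds more to streaked images", {
  tr <- tiny_trained()
  test <- tiny_test_corpus()
  top <- which.max(abs(tr$model$weights$wd))
  m_few <- mean(vapply(which(test$labels == 1L), function(i) {
    mean(feature_maps(tr$model, test$images[i, , ], 2)[[top]])
  }, numeric(1)))
  m_full <- mean(vapply(which(test$labels == 0L), function(i) {
    mean(feature_maps(tr$model, test$images[i, , ], 2)[[top]])
  }, numeric(1)))
  if (tr$model$weights$wd[top] > 0) expect_gt(m_few, m_full)
  else expect_gt(m_full, m_few)
})

test_that("label inversion is learned symmetrically", {
  inverted <- tiny_corpus()
  inverted$labels <- 1L - inverted$labels
  m <- build_cnn(cnn_config(input_size = 32), seed = 101L)
  tr <- train_classifier(m, inverted,
                         train_config(epochs = 60, learning_rate = 1e-2,
                                      batch_size = 16, seed = 202L))
  # accuracy measured against the ORIGINAL labels collapses
  orig <- tiny_test_corpus()
  expect_lte(classifier_accuracy(tr$model, orig), 0.1)
})

test_that("training is reproducible for a fixed seed", {
  corpus <- build_corpus(tiny_phantom_config(), 6, tiny_few(), tiny_full())
  run <- function() {
    m <- build_cnn(cnn_config(input_size = 32), seed = 11L)
    train_classifier(m, corpus, train_config(epochs = 2, seed = 33L))
  }
  a <- run(); b <- run()
  expect_identical(a$model$weights, b$model$weights)
  expect_identical(a$report, b$report)
})

test_that("degenerate corpora are rejected by the trainer", {
  corpus <- build_corpus(tiny_phantom_config(), 2, tiny_few(), tiny_full())
  corpus$labels[] <- 1L
  m <- build_cnn(cnn_config(input_size = 32), seed = 1)
  expect_error(train_classifier(m, corpus, train_config(epochs = 1)),
               "both labels")
})
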