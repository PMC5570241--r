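test_that("featurize windows are method-major with 0.5 boundary imputation", {
  ws <- ws_small()
  tab <- local_score_table(ws$native, ws$bundle, ws$ensemble)
  X <- featurize(tab)
  expect_equal(ncol(X), 30L)
  expect_true(all(X >= 0 & X <= 1))
  # interior position: first block is CDA at offsets -2..+2
  i <- 10L
  expected <- tab[(i - 2):(i + 2), "CDA"]
  expected[is.na(expected)] <- 0.5
  expect_equal(unname(X[as.character(i), 1:5]), unname(expected))
  # position 1: offsets -2 and -1 imputed for every method (columns 1,2 of
  # each 5-wide block)
  x1 <- X["1", ]
  expect_true(all(x1[c(1, 2, 6, 7, 11, 12, 16, 17, 21, 22, 26, 27)] == 0.5))
})

test_that("a globally absent channel is imputed at 0.5 everywhere", {
  ws <- ws_small()
  tab <- local_score_table(ws$native, ws$bundle, ws$ensemble,
                           external_local = NULL)
  X <- featurize(tab)
  expect_true(all(X[, 11:15] == 0.5))   # ProQ2 block
})

test_that("the forward pass has the sigmoid closed form and determinism", {
  zero <- combiner_network(matrix(0, 30, 15), rep(0, 15), rep(0, 15), 0)
  ws <- ws_small()
  tab <- local_score_table(ws$native, ws$bundle, ws$ensemble)
  out <- predict_local(zero, tab)
  expect_true(all(out == 0.5))
  net <- frozen_net()
  o1 <- predict_local(net, tab)
  expect_true(all(o1 > 0 & o1 < 1))
  expect_identical(predict_local(net, tab), o1)
})

test_that("training is seed-reproducible and fits a constant target", {
  set.seed(3)
  X <- matrix(runif(1500 * 30), 1500, 30)
  n1 <- train_combiner(X, rep(0.7, 1500), seed = 5, epochs = 300)
  n2 <- train_combiner(X, rep(0.7, 1500), seed = 5, epochs = 300)
  expect_identical(n1$weights_in, n2$weights_in)
  expect_identical(n1$weights_out, n2$weights_out)
  pred <- modqa6:::nn_forward(n1, matrix(runif(200 * 30), 200, 30))
  expect_true(all(abs(pred - 0.7) < 0.02))
})

test_that("a student network recovers a frozen random teacher", {
  teacher <- modqa6:::random_network(seed = 9, scale = 1)
  set.seed(10)
  X <- matrix(runif(1200 * 30), 1200, 30)
  y <- modqa6:::nn_forward(teacher, X)
  student <- train_combiner(X[1:1000, ], y[1:1000], seed = 11, epochs = 300)
  held <- modqa6:::nn_forward(student, X[1001:1200, ])
  expect_lt(rmse(held, y[1001:1200]), 0.05)
})

test_that("training refuses tiny example sets", {
  X <- matrix(runif(50 * 30), 50, 30)
  expect_error(train_combiner(X, runif(50)), "at least 100")
})

test_that("similarity/distance transforms are exact inverses", {
  expect_equal(similarity_to_distance(1), 0)
  expect_equal(similarity_to_distance(0.5), 3.9)
  expect_equal(distance_to_similarity(3.9), 0.5)
  s <- seq(0.01, 1, length.out = 200)
  expect_equal(distance_to_similarity(similarity_to_distance(s)), s,
               tolerance = 1e-12)
  # strictly decreasing on (0,1]
  d <- similarity_to_distance(s)
  expect_true(all(diff(d) < 0))
  expect_error(similarity_to_distance(0), "\\(0, 1\\]")
  expect_error(similarity_to_distance(-0.2), "\\(0, 1\\]")
  # floor caps the reported error
  expect_equal(similarity_to_distance(1e-9), 3.9 * sqrt(99))
})

test_that("weight files round-trip bit-exactly", {
  net <- modqa6:::random_network(seed = 13)
  path <- tempfile(fileext = ".txt")
  write_weights(net, path)
  net2 <- read_weights(path)
  expect_identical(net2$weights_in, net$weights_in)
  expect_identical(net2$bias_hidden, net$bias_hidden)
  expect_identical(net2$weights_out, net$weights_out)
  expect_identical(net2$bias_out, net$bias_out)
  # corrupt header is rejected
  writeLines(c("bogus"), path)
  expect_error(read_weights(path), "not a combiner weight file")
})
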