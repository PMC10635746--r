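# shared tiny fixture: three well-separated 2-D clusters, 50 per class
make_cluster_fixture <- function(n = 50, seed = 42) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5)),
             cbind(rnorm(n, 4, 0.5), rnorm(n, 0, 0.5)),
             cbind(rnorm(n, 2, 0.5), rnorm(n, 4, 0.5)))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(mass_classes(), each = n))
}

test_that("one-hot encoding uses the canonical class order and round-trips", {
  expect_equal(one_hot_encode("benign")[1, ], c(benign = 1L, malignant = 0L,
                                                ignorant = 0L))
  expect_equal(unname(one_hot_encode("malignant")[1, ]), c(0L, 1L, 0L))
  expect_equal(unname(one_hot_encode("ignorant")[1, ]), c(0L, 0L, 1L))
  for (lab in mass_classes())
    expect_identical(one_hot_decode(one_hot_encode(lab)), lab)
  expect_error(one_hot_encode("weird"), "unknown label")
  expect_error(one_hot_decode(c(0, 1, 1)), "exactly one 1")
})

test_that("the MLP learns separable data and exposes normalized probabilities", {
  fx <- make_cluster_fixture()
  m <- train_mlp(fx$x, fx$y, mlp_config(2, seed = 3))
  p <- predict_proba(m, fx$x)
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(mean(mass_classes()[max.col(p)] == fx$y), 0.95)
  # aggregate loss decrease
  expect_lt(m$loss_history[length(m$loss_history)], m$loss_history[1])
  # determinism
  m2 <- train_mlp(fx$x, fx$y, mlp_config(2, seed = 3))
  expect_identical(m$params, m2$params)
  # inference determinism + empty input
  expect_identical(p, predict_proba(m, fx$x))
  expect_identical(nrow(predict_proba(m, fx$x[0, , drop = FALSE])), 0L)
})

test_that("a tiny training set is memorized and degenerate input errors", {
  set.seed(8)
  x <- matrix(rnorm(12), 6, 2)
  y <- rep(mass_classes(), 2)
  m <- train_mlp(x, y, mlp_config(2, epochs = 3000, seed = 1))
  p <- predict_proba(m, x)
  expect_equal(mean(mass_classes()[max.col(p)] == y), 1.0)
  expect_error(train_mlp(x, rep("benign", 6), mlp_config(2)), "single class")
  expect_error(predict_proba(list(), x), "not a trained")
})

test_that("backprop matches finite-difference gradients", {
  set.seed(5)
  x <- matrix(rnorm(10), 5, 2)
  y <- one_hot_encode(c("benign", "malignant", "ignorant", "benign",
                        "malignant"))
  cfg <- mlp_config(2, hidden_layers = c(4, 3), seed = 9)
  set.seed(cfg$seed)
  params <- dsmammo:::mlp_init(cfg)
  g <- dsmammo:::mlp_grad(params, x, y)
  eps <- 1e-6
  for (l in seq_along(params$W)) {
    for (i in seq_len(min(length(params$W[[l]]), 8L))) {
      p1 <- params; p1$W[[l]][i] <- p1$W[[l]][i] + eps
      p2 <- params; p2$W[[l]][i] <- p2$W[[l]][i] - eps
      num <- (dsmammo:::mlp_loss(p1, x, y) -
                dsmammo:::mlp_loss(p2, x, y)) / (2 * eps)
      ana <- g$W[[l]][i]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-8), 1e-4)
    }
    b1 <- params; b1$b[[l]][1] <- b1$b[[l]][1] + eps
    b2 <- params; b2$b[[l]][1] <- b2$b[[l]][1] - eps
    num <- (dsmammo:::mlp_loss(b1, x, y) -
              dsmammo:::mlp_loss(b2, x, y)) / (2 * eps)
    expect_lt(abs(num - g$b[[l]][1]) / max(abs(num) + abs(g$b[[l]][1]), 1e-8),
              1e-4)
  }
})

test_that("the CNN architecture walk matches the four-block design", {
  arch <- cnn_architecture(cnn_config())
  convs <- arch[arch$layer == "convolution", ]
  expect_identical(convs$filters, c(16L, 32L, 32L, 64L))
  expect_identical(convs$kernel, c(28L, 14L, 7L, 4L))
  expect_identical(sum(arch$layer == "batch_normalization"), 4L)
  expect_identical(sum(grepl("pooling", arch$layer)), 4L)
  expect_identical(arch$layer[arch$layer %in% c("max_pooling",
                                                "mean_pooling")],
                   c("max_pooling", "max_pooling", "max_pooling",
                     "mean_pooling"))
  expect_identical(arch$filters[arch$layer == "fully_connected"], 100L)
  expect_identical(arch$filters[arch$layer == "output"], 3L)
  # 20 nominal layers plus the explicit 3-logit output a 3-class softmax needs
  expect_identical(nrow(arch), 21L)
  expect_error(cnn_config(input_size = 24), "multiple of 16")
})

test_that("the CNN trains deterministically and overfits a small phantom set", {
  ds <- generate_phantom_dataset(10, phantom_spec("benign", image_size = 64),
                                 seed = 5)
  # memorization check: augmentation off so the training set is fixed
  cfg <- cnn_config(input_size = 32, epochs = 12, augment = FALSE, seed = 2)
  m <- train_cnn(ds$images, ds$labels, cfg)
  p <- predict_proba(m, ds$images[1:5])
  expect_identical(dim(p), c(5L, 3L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_identical(p, predict_proba(m, ds$images[1:5]))
  expect_identical(nrow(predict_proba(m, list())), 0L)

  acc <- mean(mass_classes()[max.col(predict_proba(m, ds$images))] ==
                as.character(ds$labels))
  expect_gte(acc, 0.9)

  cfg2 <- cnn_config(input_size = 32, epochs = 2, seed = 2)  # augment on
  expect_identical(train_cnn(ds$images, ds$labels, cfg2)$params,
                   train_cnn(ds$images, ds$labels, cfg2)$params)
  expect_error(train_cnn(ds$images, rep("benign", 30), cfg2), "single class")
})
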