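test_that("initialization has the stated shapes and seeded reproducibility", {
  m <- ann_init(30, 5, seed = 1)
  expect_identical(dim(m$W1), c(5L, 30L))
  expect_identical(dim(m$W2), c(1L, 5L))
  expect_identical(m$b1, rep(0, 5))
  expect_identical(m$b2, 0)
  expect_true(all(abs(m$W1) <= 0.5))
  expect_identical(ann_init(30, 5, seed = 1)$W1, m$W1)
  expect_false(identical(ann_init(30, 5, seed = 2)$W1, m$W1))
  expect_error(ann_init(0, 5), ">= 1")
})

test_that("analytic gradients match central finite differences", {
  set.seed(77)
  X <- matrix(rbinom(12, 1, 0.5), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  y <- c(0, 1, 1, 0)
  for (loss in c("cross_entropy", "sse")) {
    model <- ann_init(3, 4, seed = 5)
    g <- sigscoreann:::ann_loss_grad(model, X, y, loss)
    analytic <- c(g$gW1, g$gb1, g$gW2, g$gb2)
    fd <- oracle_fd_gradient(model, X, y, loss)
    expect_lt(max(abs(analytic - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("training is deterministic and separates a separable score matrix", {
  set.seed(4)
  X <- rbind(matrix(rbinom(50, 1, 0.15), 10),   # controls: mostly 0
             matrix(rbinom(50, 1, 0.85), 10))   # cases: mostly 1
  dimnames(X) <- list(sprintf("s%02d", 1:20), sprintf("g%d", 1:5))
  y <- rep(c(0L, 1L), each = 10)
  m1 <- ann_train(ann_init(5, 5, seed = 1), X, y)
  m2 <- ann_train(ann_init(5, 5, seed = 1), X, y)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$meta$epochs, m2$meta$epochs)

  p <- predict(m1, X)
  expect_identical(as.integer(p > 0.5), y)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(p[y == 1] > 0.5) && all(p[y == 0] < 0.5))
})

test_that("identical rows with mixed labels bottom out at the label entropy", {
  X <- matrix(1L, 10, 3, dimnames = list(paste0("s", 1:10), paste0("g", 1:3)))
  y <- rep(c(0L, 1L), c(3, 7))
  m <- ann_train(ann_init(3, 5, seed = 2), X, y, max_epochs = 20000)
  p <- predict(m, X)
  expect_equal(accuracy(as.integer(p > 0.5), y), 0.7)  # majority class
  entropy <- -mean(c(rep(log(0.3), 3), rep(log(0.7), 7)))
  expect_gte(m$meta$final_loss, entropy - 1e-9)
  expect_lt(m$meta$final_loss, entropy + 1e-3)
})

test_that("loss is nonincreasing across epochs at the default learning rate", {
  set.seed(8)
  X <- matrix(rbinom(40, 1, 0.5), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("g", 1:5)))
  y <- rep(c(0, 1), 4)
  model <- ann_init(5, 5, seed = 3)
  losses <- numeric(200)
  for (i in 1:200) {
    g <- sigscoreann:::ann_loss_grad(model, X, y, "cross_entropy")
    losses[i] <- g$value
    model$W1 <- model$W1 - 0.1 * g$gW1
    model$b1 <- model$b1 - 0.1 * g$gb1
    model$W2 <- model$W2 - 0.1 * g$gW2
    model$b2 <- model$b2 - 0.1 * g$gb2
  }
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("an untrained zero-weight model predicts exactly 0.5 everywhere", {
  m <- ann_init(4, 3, seed = 1)
  m$W1[] <- 0; m$W2[] <- 0
  X <- matrix(rbinom(20, 1, 0.5), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:4)))
  expect_equal(unname(predict(m, X)), rep(0.5, 5))
})

test_that("prediction is row-permutation equivariant and feature-order safe", {
  set.seed(10)
  X <- matrix(rbinom(30, 1, 0.5), 6, 5,
              dimnames = list(paste0("s", 1:6), paste0("g", 1:5)))
  y <- rep(c(0L, 1L), 3)
  m <- ann_train(ann_init(5, 4, seed = 6), X, y, max_epochs = 200)
  p <- predict(m, X)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(predict(m, X[perm, ]), p[perm])
  shuffled <- X[, c(3, 1, 5, 2, 4)]
  expect_equal(predict(m, shuffled), p)          # reordered to model features
  colnames(shuffled)[1] <- "other"
  expect_error(predict(m, shuffled), "feature mismatch.*g3|feature mismatch.*other")
})

test_that("label and shape validation, and divergence reporting", {
  X <- matrix(0L, 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b")))
  expect_error(ann_train(ann_init(2, 2, seed = 1), X, c(0, 2, 1, 0)),
               "binary")
  expect_error(ann_train(ann_init(2, 2, seed = 1), X, c(0, 1, 1)), "labels")
  expect_error(ann_train(ann_init(3, 2, seed = 1), X, c(0, 1, 1, 0)),
               "input features")
})

test_that("models round-trip through JSON serialization", {
  set.seed(21)
  X <- matrix(rbinom(24, 1, 0.5), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("g", 1:4)))
  y <- rep(c(0L, 1L), 3)
  m <- ann_train(ann_init(4, 3, seed = 9), X, y, max_epochs = 500)
  path <- withr::local_tempfile(fileext = ".json")
  write_ann_model(m, path)
  back <- read_ann_model(path)
  expect_equal(back$W1, m$W1)
  expect_equal(back$b2, m$b2)
  expect_identical(back$feature_names, m$feature_names)
  expect_equal(predict(back, X), predict(m, X))
})
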