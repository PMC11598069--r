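well_separated <- function(n_per_class = 10, seed = 1) {
  # two Gaussian clouds 10 standard deviations apart in both features
  set.seed(seed)
  train <- cbind(matrix(rnorm(2 * n_per_class, 0, 1), 2),
                 matrix(rnorm(2 * n_per_class, 10, 1), 2))
  labels <- rep(c("L", "R"), each = n_per_class)
  list(x = train, labels = labels)
}

test_that("all three classifiers separate distant Gaussian clouds", {
  tr <- well_separated(seed = 1)
  te <- well_separated(seed = 2)
  for (m in c("svm", "bayes", "nn")) {
    pred <- fit_predict(m, tr$x, tr$labels, te$x, seed = 5)
    expect_identical(pred, te$labels)
  }
  expect_error(fit_predict("svm", tr$x[, 1:5], rep("L", 5), te$x), "single class")
})

test_that("untrained zero network outputs (0.5, 0.5) and ln 2 loss", {
  net <- two_layer_net(3, S1 = 10, init = "zero")
  P <- matrix(rnorm(30), 3)
  probs <- predict(net, P, type = "prob")
  expect_equal(unname(probs), matrix(0.5, 2, 10))
  expect_equal(colSums(probs), rep(1, 10), tolerance = 1e-12, ignore_attr = TRUE)
  target <- rbind(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                  c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))
  expect_equal(accsym:::nn_loss(probs, target), log(2))
})

test_that("NN training fits separable data with a non-increasing loss", {
  tr <- well_separated(seed = 3)
  z <- accsym:::standardize_rows(tr$x, tr$x)
  target <- rbind(L = as.numeric(tr$labels == "L"),
                  R = as.numeric(tr$labels == "R"))
  net <- train_nn(z$train, target, S1 = 10, seed = 4)
  expect_identical(predict(net, z$train), tr$labels)
  expect_lt(net$loss, log(2))
  expect_error(train_nn(z$train, target[, 1:3]), "target")
  expect_error(train_nn(z$train, matrix(0.5, 2, 20)), "one-hot")
})

test_that("analytic NN gradients match central finite differences", {
  set.seed(9)
  P <- matrix(rnorm(10), 2, 5)
  target <- rbind(c(1, 0, 1, 0, 1), c(0, 1, 0, 1, 0))
  net <- two_layer_net(2, S1 = 4, seed = 3)
  fwd <- accsym:::nn_forward(net, P)
  analytic <- accsym:::nn_gradients(net, P, target, fwd)
  loss_at <- function(n) accsym:::nn_loss(accsym:::nn_forward(n, P)$A2, target)
  h <- 1e-6
  for (field in c("W1", "b1", "W2", "b2")) {
    numeric_grad <- analytic[[field]]
    for (i in seq_along(numeric_grad)) {
      up <- net; up[[field]][i] <- up[[field]][i] + h
      down <- net; down[[field]][i] <- down[[field]][i] - h
      numeric_grad[i] <- (loss_at(up) - loss_at(down)) / (2 * h)
    }
    rel <- abs(analytic[[field]] - numeric_grad) /
      pmax(abs(numeric_grad), 1e-8)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("confusion metrics satisfy their defining identities", {
  m <- classification_metrics(TP = 90, FN = 10, TN = 85, FP = 15)
  expect_equal(m$TPR, 0.9)
  expect_equal(m$TNR, 0.85)
  expect_equal(m$AC, 0.875)
  expect_equal(m$TP + m$TN + m$FP + m$FN, 200)
})

test_that("LOOCV reports are deterministic and internally consistent", {
  fset <- synth_fs(asym_amp = 0.3, noise_sd = 0.25, seed = 12)
  psi <- c("std", "bandpower[0.5,3)")
  for (m in c("svm", "bayes", "nn")) {
    r1 <- loocv(m, fset, seed = 7, psi = psi)
    r2 <- loocv(m, fset, seed = 7, psi = psi)
    expect_identical(r1$predictions, r2$predictions)
    expect_equal(r1$TPR, r1$TP / (r1$TP + r1$FN))
    expect_equal(r1$TNR, r1$TN / (r1$TN + r1$FP))
    expect_equal(r1$AC, (r1$TP + r1$TN) / 20)
    expect_equal(r1$TP + r1$TN + r1$FP + r1$FN, 20)
    expect_equal(r1$CV, 1 - r1$AC)  # two balanced classes, L positive
  }
  expect_error(loocv("svm", synth_fs(M = 1)), "at least 4")
})

test_that("perfectly separable synthetic data give zero LOOCV error", {
  fset <- synth_fs(asym_amp = 0.6, noise_sd = 0.05, seed = 3)
  for (m in c("svm", "bayes", "nn")) {
    r <- loocv(m, fset, seed = 2, psi = c("std", "bandpower[0.5,3)"))
    expect_equal(r$CV, 0)
    expect_equal(r$AC, 1)
  }
})

test_that("equal-prior Gaussian Bayes agrees with the e1071 reference", {
  # balanced training data, so e1071's empirical priors are also equal
  tr <- well_separated(n_per_class = 25, seed = 6)
  tr$x <- tr$x + matrix(rnorm(length(tr$x), 0, 4), nrow = 2)  # overlap clouds
  te <- well_separated(n_per_class = 25, seed = 7)
  mine <- accsym:::predict_gauss_bayes(
    accsym:::fit_gauss_bayes(tr$x, tr$labels), te$x)
  ref_fit <- e1071::naiveBayes(x = t(tr$x), y = factor(tr$labels))
  ref <- as.character(predict(ref_fit, t(te$x)))
  expect_identical(mine, ref)
})
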