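sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_cols <- function(z) {
  m <- if (nrow(z) == 2L) pmax(z[1L, ], z[2L, ]) else apply(z, 2L, max)
  e <- exp(z - rep(m, each = nrow(z)))
  e / rep(colSums(e), each = nrow(z))
}

#' Construct a two-layer neural network
#'
#' A fully connected network with `S1` hidden units, sigmoid hidden
#' activation and a 2-class softmax output:
#' `A1 = sigmoid(W1 P + b1)`, `A2 = softmax(W2 A1 + b2)`.
#' Weights use a Glorot-style uniform initialization scaled by fan-in and
#' fan-out, drawn reproducibly from `seed`; `init = "zero"` gives the
#' all-zero network, whose softmax output is (0.5, 0.5) for any input.
#'
#' @param n_features number of input features (rows of the pattern matrix).
#' @param S1 hidden units (default 10).
#' @param S2 output classes (default 2).
#' @param seed RNG seed for the initialization.
#' @param init `"glorot"` or `"zero"`.
#' @return An object of class `two_layer_net`.
#' @export
two_layer_net <- function(n_features, S1 = 10, S2 = 2, seed = 1,
                          init = c("glorot", "zero")) {
  init <- match.arg(init)
  if (init == "zero") {
    W1 <- matrix(0, S1, n_features); W2 <- matrix(0, S2, S1)
  } else {
    with_seed(seed, {
      l1 <- sqrt(6 / (n_features + S1))
      l2 <- sqrt(6 / (S1 + S2))
      W1 <- matrix(runif(S1 * n_features, -l1, l1), S1, n_features)
      W2 <- matrix(runif(S2 * S1, -l2, l2), S2, S1)
    })
  }
  structure(list(W1 = W1, b1 = numeric(S1), W2 = W2, b2 = numeric(S2),
                 S1 = S1, S2 = S2, epochs = 0L, loss = NA_real_),
            class = "two_layer_net")
}

#' @export
print.two_layer_net <- function(x, ...) {
  cat(sprintf("<two_layer_net> %d -> %d (sigmoid) -> %d (softmax); %d epoch(s), loss %.6g\n",
              ncol(x$W1), x$S1, x$S2, x$epochs, x$loss))
  invisible(x)
}

nn_forward <- function(net, P) {
  A1 <- sigmoid(net$W1 %*% P + net$b1)
  A2 <- softmax_cols(net$W2 %*% A1 + net$b2)
  list(A1 = A1, A2 = A2)
}

# Mean cross-entropy over columns; eps guards log(0) at extreme logits.
nn_loss <- function(A2, target) {
  -sum(target * log(pmax(A2, 1e-300))) / ncol(target)
}

nn_gradients <- function(net, P, target, fwd = nn_forward(net, P)) {
  Q <- ncol(P)
  dZ2 <- (fwd$A2 - target) / Q
  dZ1 <- crossprod(net$W2, dZ2) * fwd$A1 * (1 - fwd$A1)
  list(W1 = tcrossprod(dZ1, P), b1 = rowSums(dZ1),
       W2 = tcrossprod(dZ2, fwd$A1), b2 = rowSums(dZ2))
}

#' Train the two-layer network by full-batch gradient descent
#'
#' Minimizes the mean softmax cross-entropy with full-batch gradient
#' descent. A step that would increase the loss is rejected and retried with
#' a halved learning rate, so the recorded loss is non-increasing across
#' accepted steps; training stops when the loss improves by less than `tol`
#' or after `max_epochs` epochs.
#'
#' @param P pattern matrix, features x segments.
#' @param target one-hot target matrix, 2 x segments (row 1 = class L).
#' @param S1 hidden units.
#' @param seed RNG seed for the weight initialization.
#' @param max_epochs epoch cap (default 2000).
#' @param lr initial learning rate (default 0.1).
#' @param tol stop when the loss decrease falls below this (default 1e-6).
#' @return A trained `two_layer_net` with `epochs` and final `loss` set.
#' @export
train_nn <- function(P, target, S1 = 10, seed = 1, max_epochs = 2000,
                     lr = 0.1, tol = 1e-6) {
  P <- as.matrix(P)
  target <- as.matrix(target)
  if (ncol(P) != ncol(target)) stop_field("target", "column count must match P")
  if (!all(target %in% c(0, 1)) || !all(colSums(target) == 1)) {
    stop_field("target", "columns must be one-hot")
  }
  net <- two_layer_net(nrow(P), S1 = S1, S2 = nrow(target), seed = seed)
  W1 <- net$W1; b1 <- net$b1; W2 <- net$W2; b2 <- net$b2
  Q <- ncol(P)
  S2 <- nrow(target)
  forward <- function(W1, b1, W2, b2) {
    A1 <- 1 / (1 + exp(-(W1 %*% P + b1)))
    A2 <- softmax_cols(W2 %*% A1 + b2)
    list(A1 = A1, A2 = A2, loss = -sum(target * log(pmax(A2, 1e-300))) / Q)
  }
  fwd <- forward(W1, b1, W2, b2)
  loss <- fwd$loss
  step <- lr
  epochs_run <- 0L
  for (epoch in seq_len(max_epochs)) {
    dZ2 <- (fwd$A2 - target) / Q
    dZ1 <- crossprod(W2, dZ2) * fwd$A1 * (1 - fwd$A1)
    gW1 <- tcrossprod(dZ1, P); gb1 <- rowSums(dZ1)
    gW2 <- tcrossprod(dZ2, fwd$A1); gb2 <- rowSums(dZ2)
    repeat {
      cand <- forward(W1 - step * gW1, b1 - step * gb1,
                      W2 - step * gW2, b2 - step * gb2)
      if (!is.finite(cand$loss)) {
        stop(sprintf("non-finite training loss at epoch %d", epoch), call. = FALSE)
      }
      if (cand$loss <= loss || step < 1e-14) break
      step <- step / 2
    }
    W1 <- W1 - step * gW1; b1 <- b1 - step * gb1
    W2 <- W2 - step * gW2; b2 <- b2 - step * gb2
    improved <- loss - cand$loss
    fwd <- cand; loss <- cand$loss
    epochs_run <- epoch
    if (improved >= 0 && improved < tol) break
    step <- min(step * 1.1, lr)  # cautiously recover after halvings
  }
  net$W1 <- W1; net$b1 <- b1; net$W2 <- W2; net$b2 <- b2
  net$epochs <- epochs_run; net$loss <- loss
  net
}

#' @export
predict.two_layer_net <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  probs <- nn_forward(object, as.matrix(newdata))$A2
  if (type == "prob") return(probs)
  c("L", "R")[max.col(t(probs))]
}

# Gaussian naive Bayes with equal class priors: per-class, per-feature
# Gaussian likelihoods. sd is floored to avoid degenerate zero-variance
# features on tiny training folds.
fit_gauss_bayes <- function(train, labels) {
  classes <- sort(unique(labels))
  stats_by_class <- lapply(classes, function(cl) {
    X <- train[, labels == cl, drop = FALSE]
    m <- rowMeans(X)
    s <- apply(X, 1L, sd)
    s[!is.finite(s) | s < 1e-9] <- 1e-9
    list(mean = m, sd = s)
  })
  names(stats_by_class) <- classes
  structure(list(classes = classes, stats = stats_by_class), class = "gauss_bayes")
}

predict_gauss_bayes <- function(model, test) {
  ll <- vapply(model$classes, function(cl) {
    st <- model$stats[[cl]]
    colSums(dnorm(test, mean = st$mean, sd = st$sd, log = TRUE))
  }, numeric(ncol(test)))
  ll <- matrix(ll, ncol = length(model$classes))
  model$classes[max.col(ll)]
}

standardize_rows <- function(train, test) {
  m <- rowMeans(train)
  s <- apply(train, 1L, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(train = (train - m) / s, test = (test - m) / s)
}

#' Classify test segments as left or right
#'
#' Trains the requested classifier on the training columns and predicts a
#' side label for each test column. Features are z-scored per row using
#' training-fold statistics only (the SVM and NN need comparable feature
#' scales). Methods: `"svm"` — radial-basis SVM ([e1071::svm()]) with cost 1
#' and kernel width `1 / (R * var)`; `"bayes"` — Gaussian naive Bayes with
#' equal class priors; `"nn"` — the two-layer network of [train_nn()].
#'
#' @param method `"svm"`, `"bayes"`, or `"nn"`.
#' @param train features x segments training matrix.
#' @param train_labels character vector of `"L"`/`"R"` per training column.
#' @param test features x segments matrix to classify.
#' @param seed RNG seed (used by the NN initialization).
#' @param S1 hidden units for the NN.
#' @return Character vector of predicted labels, one per test column.
#' @export
fit_predict <- function(method = c("svm", "bayes", "nn"), train, train_labels,
                        test, seed = 1, S1 = 10) {
  method <- match.arg(method)
  train <- as.matrix(train); test <- as.matrix(test)
  if (length(unique(train_labels)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  z <- standardize_rows(train, test)
  if (method == "svm") {
    gamma <- 1 / (nrow(z$train) * max(var(as.vector(z$train)), 1e-12))
    fit <- e1071::svm(x = t(z$train), y = factor(train_labels, levels = c("L", "R")),
                      kernel = "radial", cost = 1, gamma = gamma, scale = FALSE)
    as.character(predict(fit, t(z$test)))
  } else if (method == "bayes") {
    predict_gauss_bayes(fit_gauss_bayes(z$train, train_labels), z$test)
  } else {
    target <- rbind(L = as.numeric(train_labels == "L"),
                    R = as.numeric(train_labels == "R"))
    net <- train_nn(z$train, target, S1 = S1, seed = seed)
    predict(net, z$test)
  }
}

#' Confusion metrics for a two-class report
#'
#' Sensitivity `TPR = TP / (TP + FN)`, specificity `TNR = TN / (TN + FP)`
#' and accuracy `AC = (TP + TN) / (TP + TN + FP + FN)`, with class L as
#' positive.
#'
#' @param TP,FN,TN,FP confusion counts.
#' @return Named list with the counts and `TPR`, `TNR`, `AC`.
#' @export
classification_metrics <- function(TP, FN, TN, FP) {
  list(TP = TP, FN = FN, TN = TN, FP = FP,
       TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       TNR = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       AC = (TP + TN) / (TP + TN + FP + FN))
}

#' Leave-one-out cross-validation of a side classifier
#'
#' Runs as many folds as there are segments: fold `i` trains on all columns
#' but `i` and predicts column `i`. Confusion counts are accumulated over
#' folds with class L as positive; `CV` is the misclassified fraction. A
#' fold whose training set degenerates to a single class is predicted by the
#' training-set majority class, with a warning.
#'
#' @param method `"svm"`, `"bayes"`, or `"nn"`.
#' @param fset a `feature_set` (requires `Q >= 4`).
#' @param seed RNG seed; per-fold NN seeds are derived from it, so the
#'   whole report is reproducible.
#' @param psi optional subset of feature names to classify on (default all
#'   rows of the pattern matrix).
#' @param S1 hidden units for the NN.
#' @return An object of class `classification_report` with confusion
#'   counts, `TPR`, `TNR`, `AC`, `CV`, `method`, `seed` and per-segment
#'   `predictions`.
#' @export
loocv <- function(method = c("svm", "bayes", "nn"), fset, seed = 1,
                  psi = NULL, S1 = 10) {
  method <- match.arg(method)
  stopifnot(inherits(fset, "feature_set"))
  P <- fset$P
  if (!is.null(psi)) P <- P[psi, , drop = FALSE]
  labels <- fset$side
  Q <- ncol(P)
  if (Q < 4L) stop("leave-one-out CV needs at least 4 segments", call. = FALSE)
  preds <- character(Q)
  for (i in seq_len(Q)) {
    train <- P[, -i, drop = FALSE]
    tr_labels <- labels[-i]
    if (length(unique(tr_labels)) < 2L) {
      tab <- table(tr_labels)
      preds[i] <- names(tab)[which.max(tab)]
      warning(sprintf("fold %d has a single-class training set; predicted by majority class", i))
      next
    }
    preds[i] <- fit_predict(method, train, tr_labels, P[, i, drop = FALSE],
                            seed = (seed + i) %% 2147483647, S1 = S1)
  }
  TP <- sum(labels == "L" & preds == "L")
  FN <- sum(labels == "L" & preds == "R")
  TN <- sum(labels == "R" & preds == "R")
  FP <- sum(labels == "R" & preds == "L")
  metrics <- classification_metrics(TP, FN, TN, FP)
  structure(c(list(method = method, seed = seed, CV = mean(preds != labels),
                   predictions = preds), metrics),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s: AC %.1f%%, TPR %.2f, TNR %.2f, CV %.2f (n = %d)\n",
              x$method, 100 * x$AC, x$TPR, x$TNR, x$CV,
              x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Write classification reports as CSV or JSON
#'
#' CSV mirrors the usual summary layout: one row per (individual, method)
#' with AC in percent (1 decimal) and CV (2 decimals); JSON stores the full
#' reports at full precision.
#'
#' @param reports named list (typically individual -> method ->
#'   `classification_report`), or a flat list of reports.
#' @param path output path.
#' @param format `"csv"` or `"json"` (default from extension).
#' @param provenance optional named list embedded in JSON output.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, format = NULL, provenance = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "csv"
  flat <- flatten_reports(reports)
  if (format == "json") {
    payload <- lapply(flat, function(r) {
      r$report$predictions <- NULL
      c(list(individual_id = r$individual_id, exercise_id = r$exercise_id),
        unclass(r$report))
    })
    if (!is.null(provenance)) payload <- list(provenance = provenance, reports = payload)
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  } else {
    df <- do.call(rbind, lapply(flat, function(r) {
      data.frame(individual = r$individual_id %||% NA, exercise = r$exercise_id %||% NA,
                 method = r$report$method, AC_pct = round(100 * r$report$AC, 1),
                 CV = round(r$report$CV, 2), stringsAsFactors = FALSE)
    }))
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

flatten_reports <- function(reports) {
  out <- list()
  walk <- function(x, ind = NULL, ex = NULL) {
    if (inherits(x, "classification_report")) {
      out[[length(out) + 1L]] <<- list(individual_id = ind, exercise_id = ex, report = x)
    } else if (is.list(x)) {
      nm <- names(x) %||% rep(NA_character_, length(x))
      for (i in seq_along(x)) {
        label <- nm[[i]]
        if (is.null(ind)) walk(x[[i]], ind = label, ex = ex)
        else walk(x[[i]], ind = ind, ex = if (is.null(ex)) label else ex)
      }
    }
  }
  walk(reports)
  out
}
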