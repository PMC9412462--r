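# Binary motion-sickness classifiers at the fixed, reported
# hyperparameters: pooled-covariance LDA, 28-nearest-neighbours
# (Euclidean), a deviance-reduction decision tree with at most 2 splits,
# and a linear soft-margin SVM at C = 0.0706 (dual coordinate descent).
# No external ML package is used; each model exposes a continuous score
# oriented towards the positive class for ROC construction.

#' Classifier specification
#'
#' @param kind One of `"LDA"`, `"KNN"`, `"DT"`, `"LSVM"`.
#' @param knn_k Number of neighbours for KNN (default 28, half of the
#'   56-observation design).
#' @param dt_max_splits Maximum number of internal splits for the tree
#'   (default 2, i.e. at most 3 leaves).
#' @param svm_cost Soft-margin box constraint C for the linear SVM
#'   (default 0.0706, on standardized features).
#' @param standardize Standardize features with training-set parameters
#'   (default `TRUE`; applied inside each CV fold).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("LDA", "KNN", "DT", "LSVM"),
                            knn_k = 28, dt_max_splits = 2,
                            svm_cost = 0.0706, standardize = TRUE) {
  kind <- match.arg(kind)
  stopifnot(knn_k >= 1, dt_max_splits >= 1, svm_cost > 0)
  structure(list(kind = kind, knn_k = as.integer(knn_k),
                 dt_max_splits = as.integer(dt_max_splits),
                 svm_cost = svm_cost, standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

#' Default battery of the four classifiers
#' @return Named list of [classifier_spec()] objects.
#' @export
default_classifiers <- function() {
  kinds <- c("LDA", "KNN", "DT", "LSVM")
  stats::setNames(lapply(kinds, classifier_spec), kinds)
}

#' Standardize features with training-set parameters
#'
#' Per-feature `(x - mean_train) / sd_train`, with the training
#' parameters applied to both sets (leakage-safe).
#'
#' @param train_features,test_features Numeric matrices (test may be
#'   `NULL`).
#' @return List with `train`, `test`, `center`, `scale`.
#' @export
standardize_fit_apply <- function(train_features, test_features = NULL) {
  train_features <- as.matrix(train_features)
  if (nrow(train_features) < 2L) stop_vims("need >= 2 training rows")
  center <- colMeans(train_features)
  scale <- apply(train_features, 2, stats::sd)
  if (any(scale == 0)) {
    stop_vims("constant training feature(s): ",
              paste(colnames(train_features)[scale == 0], collapse = ", "))
  }
  std <- function(m) sweep(sweep(as.matrix(m), 2, center), 2, scale, "/")
  list(train = std(train_features),
       test = if (!is.null(test_features)) std(test_features),
       center = center, scale = scale)
}

# ---- model fitting (internal; X already standardized if requested) ----

# y01: integer vector, 1 = positive class
fit_model <- function(spec, X, y01) {
  switch(spec$kind,
    LDA = fit_lda(X, y01),
    KNN = fit_knn(X, y01, spec$knn_k),
    DT = fit_dt(X, y01, spec$dt_max_splits),
    LSVM = fit_lsvm(X, y01, spec$svm_cost)
  )
}

predict_model <- function(spec, model, X) {
  switch(spec$kind,
    LDA = predict_lda(model, X),
    KNN = predict_knn(model, X),
    DT = predict_dt(model, X),
    LSVM = predict_lsvm(model, X)
  )
}

fit_lda <- function(X, y01) {
  mu0 <- colMeans(X[y01 == 0, , drop = FALSE])
  mu1 <- colMeans(X[y01 == 1, , drop = FALSE])
  n0 <- sum(y01 == 0); n1 <- sum(y01 == 1)
  c0 <- stats::cov(X[y01 == 0, , drop = FALSE])
  c1 <- stats::cov(X[y01 == 1, , drop = FALSE])
  Sp <- ((n0 - 1) * c0 + (n1 - 1) * c1) / (n0 + n1 - 2)
  w <- solve(Sp, mu1 - mu0)
  b <- -sum(w * (mu0 + mu1)) / 2 + log(n1 / n0)
  list(w = w, b = b)
}
predict_lda <- function(m, X) {
  s <- drop(as.matrix(X) %*% m$w) + m$b
  list(score = s, label = as.integer(s > 0))
}

fit_knn <- function(X, y01, k) {
  if (nrow(X) < k) {
    stop_vims("KNN requires at least k = ", k, " training rows (got ",
              nrow(X), ")")
  }
  list(X = as.matrix(X), y = y01, k = k)
}
predict_knn <- function(m, X) {
  X <- as.matrix(X)
  # squared Euclidean distances train x test
  d2 <- outer(rowSums(m$X^2), rep(1, nrow(X))) +
    outer(rep(1, nrow(m$X)), rowSums(X^2)) - 2 * m$X %*% t(X)
  score <- numeric(nrow(X))
  label <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    ord <- order(d2[, i])
    nb <- ord[seq_len(m$k)]
    pos <- sum(m$y[nb])
    score[i] <- pos / m$k
    label[i] <- if (2 * pos == m$k) m$y[ord[1]]  # tie: nearest neighbour decides
                else as.integer(2 * pos > m$k)
  }
  list(score = score, label = label)
}

# Binary tree grown greedily by deviance reduction, best-first, at most
# `max_splits` internal nodes. Node deviance: -2 sum n_k log(n_k / n).
node_deviance <- function(y01) {
  n <- length(y01); n1 <- sum(y01); n0 <- n - n1
  d <- 0
  if (n1 > 0) d <- d - 2 * n1 * log(n1 / n)
  if (n0 > 0) d <- d - 2 * n0 * log(n0 / n)
  d
}

best_split <- function(X, y01, rows) {
  n <- length(rows)
  if (n < 2L) return(NULL)
  d0 <- node_deviance(y01[rows])
  if (d0 <= 1e-12) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[rows, j]
    o <- order(v)
    vs <- v[o]; ys <- y01[rows][o]
    cut_at <- which(diff(vs) > 0)
    if (!length(cut_at)) next
    c1 <- cumsum(ys)
    cn <- seq_len(n)
    for (ci in cut_at) {
      nl <- cn[ci]; n1l <- c1[ci]
      nr <- n - nl; n1r <- c1[n] - n1l
      dev <- dev_counts(n1l, nl) + dev_counts(n1r, nr)
      red <- d0 - dev
      if (is.null(best) || red > best$reduction + 1e-12) {
        best <- list(feature = j, threshold = (vs[ci] + vs[ci + 1]) / 2,
                     reduction = red)
      }
    }
  }
  best
}

dev_counts <- function(n1, n) {
  n0 <- n - n1
  d <- 0
  if (n1 > 0) d <- d - 2 * n1 * log(n1 / n)
  if (n0 > 0) d <- d - 2 * n0 * log(n0 / n)
  d
}

fit_dt <- function(X, y01, max_splits) {
  X <- as.matrix(X)
  # nodes: list(rows, is_leaf, feature, threshold, left, right, prob)
  nodes <- list(list(rows = seq_len(nrow(X)), leaf = TRUE))
  open <- c(1L)
  n_splits <- 0L
  while (n_splits < max_splits && length(open)) {
    cands <- lapply(open, function(id) best_split(X, y01, nodes[[id]]$rows))
    ok <- !vapply(cands, is.null, logical(1))
    if (!any(ok)) break
    reds <- vapply(cands[ok], `[[`, numeric(1), "reduction")
    pick <- open[ok][which.max(reds)]
    sp <- cands[ok][[which.max(reds)]]
    rows <- nodes[[pick]]$rows
    left_rows <- rows[X[rows, sp$feature] <= sp$threshold]
    right_rows <- setdiff(rows, left_rows)
    li <- length(nodes) + 1L
    ri <- length(nodes) + 2L
    nodes[[li]] <- list(rows = left_rows, leaf = TRUE)
    nodes[[ri]] <- list(rows = right_rows, leaf = TRUE)
    nodes[[pick]] <- list(rows = rows, leaf = FALSE, feature = sp$feature,
                          threshold = sp$threshold, left = li, right = ri)
    open <- c(setdiff(open, pick), li, ri)
    n_splits <- n_splits + 1L
  }
  for (i in seq_along(nodes)) {
    if (isTRUE(nodes[[i]]$leaf)) {
      nodes[[i]]$prob <- mean(y01[nodes[[i]]$rows])
    }
    nodes[[i]]$rows <- NULL
  }
  list(nodes = nodes, n_splits = n_splits)
}
predict_dt <- function(m, X) {
  X <- as.matrix(X)
  score <- vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    while (!isTRUE(m$nodes[[id]]$leaf)) {
      nd <- m$nodes[[id]]
      id <- if (X[i, nd$feature] <= nd$threshold) nd$left else nd$right
    }
    m$nodes[[id]]$prob
  }, numeric(1))
  list(score = score, label = as.integer(score >= 0.5))
}

# L1-loss linear SVM solved by dual coordinate descent (deterministic
# sweep order); bias handled by feature augmentation.
fit_lsvm <- function(X, y01, cost, max_epochs = 1000, tol = 1e-10) {
  X <- cbind(as.matrix(X), bias = 1)
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X)
  q <- rowSums(X^2)
  alpha <- numeric(n)
  w <- numeric(ncol(X))
  for (ep in seq_len(max_epochs)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      g <- y[i] * sum(w * X[i, ]) - 1
      a_new <- min(max(alpha[i] - g / q[i], 0), cost)
      d <- a_new - alpha[i]
      if (d != 0) {
        w <- w + d * y[i] * X[i, ]
        alpha[i] <- a_new
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
  }
  list(w = w[-length(w)], b = w[length(w)])
}
predict_lsvm <- function(m, X) {
  s <- drop(as.matrix(X) %*% m$w) + m$b
  list(score = s, label = as.integer(s > 0))
}

# ---- user-facing training / prediction ----

#' Train a classifier on a labelled feature matrix
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @param positive Label of the positive (motion-sickness) class; default
#'   `"VR"` if present, else the second factor level.
#' @return A `vims_classifier` model usable with [predict()] and
#'   [monitor()].
#' @export
train_classifier <- function(spec, X, y, positive = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) stop_vims("labels must be binary")
  positive <- positive %||% (if ("VR" %in% levels(y)) "VR" else levels(y)[2])
  if (!positive %in% levels(y)) stop_vims("positive class not among labels")
  y01 <- as.integer(y == positive)
  std <- NULL
  if (spec$standardize) {
    std <- standardize_fit_apply(X)
    X <- std$train
  }
  structure(list(spec = spec, model = fit_model(spec, X, y01),
                 center = std$center, scale = std$scale,
                 levels = levels(y), positive = positive),
            class = "vims_classifier")
}

#' @export
predict.vims_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  }
  pr <- predict_model(object$spec, object$model, X)
  neg <- setdiff(object$levels, object$positive)
  list(label = ifelse(pr$label == 1, object$positive, neg), score = pr$score)
}

#' Fit on training data and predict test data
#'
#' One-shot train/predict honouring the spec's standardization flag
#' (training parameters only are used to transform the test set).
#'
#' @param spec A [classifier_spec()].
#' @param train_x,train_y Training features and binary labels.
#' @param test_x Test features.
#' @param positive Positive-class label (see [train_classifier()]).
#' @return List with `label` (predicted labels) and `score` (continuous
#'   scores oriented towards the positive class).
#' @export
fit_predict <- function(spec, train_x, train_y, test_x, positive = NULL) {
  fit <- train_classifier(spec, train_x, train_y, positive)
  predict(fit, test_x)
}
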