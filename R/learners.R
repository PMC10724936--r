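#' Base-learner registry
#'
#' The 12 base-learner configurations used in the univariate accuracy
#' study: three SVM kernels (linear, polynomial degree 3, RBF with
#' scale-style gamma), a decision tree, k-nearest neighbors (k = 5), random
#' forests with 20/40/60/100 trees, discrete AdaBoost over decision stumps,
#' Gaussian naive Bayes, and logistic regression. Each fit is seeded so the
#' study is bit-reproducible.
#'
#' @return Data frame with columns `id`, `label`.
#' @export
learner_registry <- function() {
  data.frame(
    id = c("svm_linear", "svm_poly", "svm_rbf", "tree", "knn5",
           "rf20", "rf40", "rf60", "rf100", "adaboost", "nbayes",
           "logistic"),
    label = c("Linear SVM", "Poly SVM", "Scale SVM", "Decision Tree",
              "K-nearest neighbors", "Random Forest 20", "Random Forest 40",
              "Random Forest 60", "Random Forest 100", "AdaBoost",
              "Naive Bayes", "Logistic Regression"),
    stringsAsFactors = FALSE
  )
}

#' Fit one base learner
#'
#' @param algorithm Registry id (see [learner_registry()]).
#' @param x Numeric feature matrix (rows = lesions).
#' @param y Binary labels (0/1), both classes present.
#' @param seed Integer seed applied before the fit (stochastic learners and
#'   SVM probability calibration).
#' @return Object of class `base_learner`; score new rows with
#'   [predict_prob()].
#' @export
fit_learner <- function(algorithm, x, y, seed = 0L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(algorithm %in% learner_registry()$id,
            all(y %in% c(0L, 1L)), nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("training labels are single-class")
  set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(
    algorithm,
    svm_linear = svm_fit(x, yf, kernel = "linear"),
    svm_poly = svm_fit(x, yf, kernel = "polynomial", degree = 3),
    svm_rbf = svm_fit(x, yf, kernel = "radial"),
    tree = rpart::rpart(y ~ ., data = data.frame(x, y = yf),
                        method = "class",
                        control = rpart::rpart.control(minsplit = 10, cp = 0.01)),
    knn5 = list(x = x, y = y, k = 5L),
    rf20 = randomForest::randomForest(x, yf, ntree = 20),
    rf40 = randomForest::randomForest(x, yf, ntree = 40),
    rf60 = randomForest::randomForest(x, yf, ntree = 60),
    rf100 = randomForest::randomForest(x, yf, ntree = 100),
    adaboost = adaboost_fit(x, y, n_rounds = 50L),
    nbayes = e1071::naiveBayes(data.frame(x), yf),
    logistic = suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, x),
                                        y, family = binomial()))
  )
  structure(list(algorithm = algorithm, fit = fit,
                 columns = colnames(x), seed = seed),
            class = "base_learner")
}

# features are standardized inside the fit; gamma then defaults to
# 1/n_features, the "scale" convention evaluated on unit-variance columns
svm_fit <- function(x, yf, ...) {
  scale <- apply(x, 2, function(col) var(col) > 0)
  e1071::svm(x, yf, probability = TRUE, cost = 1, scale = scale, ...)
}

#' Positive-class probability from a fitted base learner
#'
#' Returns each learner's native class probability for class 1 (Platt
#' scaling for SVMs, vote fractions for forests, neighbor fractions for
#' kNN, Gaussian posteriors for naive Bayes, the link-inverse for logistic
#' regression, the logistic transform of the boosted margin for AdaBoost).
#'
#' @param object A `base_learner`.
#' @param newx Numeric matrix of rows to score.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_prob <- function(object, newx) {
  stopifnot(inherits(object, "base_learner"))
  newx <- as.matrix(newx)
  colnames(newx) <- object$columns
  fit <- object$fit
  p <- switch(
    object$algorithm,
    svm_linear = ,
    svm_poly = ,
    svm_rbf = svm_prob(fit, newx),
    tree = predict(fit, data.frame(newx), type = "prob")[, "1"],
    knn5 = knn_prob(fit$x, fit$y, newx, fit$k),
    rf20 = ,
    rf40 = ,
    rf60 = ,
    rf100 = predict(fit, newx, type = "prob")[, "1"],
    adaboost = adaboost_prob(fit, newx),
    nbayes = predict(fit, data.frame(newx), type = "raw")[, "1"],
    logistic = {
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0  # aliased columns drop out of the fit
      plogis(as.numeric(cbind(1, newx) %*% beta))
    }
  )
  as.numeric(p)
}

svm_prob <- function(fit, newx) {
  pred <- predict(fit, newx, probability = TRUE)
  pr <- attr(pred, "probabilities")
  if (!is.null(pr) && "1" %in% colnames(pr)) return(pr[, "1"])
  # Platt calibration can fail on degenerate folds; fall back to a
  # sigmoid of the decision value oriented toward class "1"
  dec <- attr(predict(fit, newx, decision.values = TRUE), "decision.values")
  s <- if (grepl("^1", colnames(dec)[1])) 1 else -1
  plogis(s * as.numeric(dec))
}

#' Brute-force k-nearest-neighbor probability
#'
#' Fraction of the k nearest training rows (Euclidean distance; ties broken
#' by training-row order) that are positive.
#'
#' @param x,y Training features and 0/1 labels.
#' @param newx Rows to score.
#' @param k Neighborhood size.
#' @return Probability vector.
#' @export
knn_prob <- function(x, y, newx, k = 5L) {
  k <- min(k, nrow(x))
  apply(newx, 1, function(row) {
    d <- sqrt(colSums((t(x) - row)^2))
    nn <- order(d)[seq_len(k)]   # order() is stable: distance, then index
    mean(y[nn] == 1)
  })
}

# ---- discrete AdaBoost over decision stumps ------------------------------
# No boosting package in the dependency set implements AdaBoost.M1, so the
# classical algorithm is written out: T rounds of weighted stump fitting
# with weight alpha = 0.5 log((1 - err) / err).

adaboost_fit <- function(x, y, n_rounds = 50L) {
  yy <- ifelse(y == 1, 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  for (t in seq_len(n_rounds)) {
    stump <- best_stump(x, yy, w)
    pred <- stump_predict(stump, x)
    err <- sum(w[pred != yy])
    if (err >= 0.5 - 1e-10) {
      stumps <- stumps[seq_len(t - 1)]
      break
    }
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stump$alpha <- alpha
    stumps[[t]] <- stump
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err < 1e-9) {
      stumps <- stumps[seq_len(t)]
      break
    }
  }
  stumps[!vapply(stumps, is.null, logical(1))]
}

best_stump <- function(x, yy, w) {
  total_w <- sum(w)
  best <- list(score = -Inf)
  for (j in seq_len(ncol(x))) {
    xs <- x[, j]
    u <- sort(unique(xs))
    if (length(u) > 1) {
      cuts <- (u[-1] + u[-length(u)]) / 2
      # prefix weights of each class below every cut (no score ties a cut)
      w1 <- vapply(u, function(v) sum(w[yy == 1 & xs == v]), numeric(1))
      w0 <- vapply(u, function(v) sum(w[yy == -1 & xs == v]), numeric(1))
      cum1 <- cumsum(w1)[-length(u)]
      cum0 <- cumsum(w0)[-length(u)]
      # dir +1 predicts +1 at x >= cut: correct weight above for class 1,
      # below for class -1; dir -1 is the complement
      score_pos <- (sum(w1) - cum1) + cum0
    } else {
      cuts <- u
      score_pos <- sum(w[yy == 1])
    }
    # dir -1 flips the call everywhere except the degenerate single-value
    # cut, where x <= cut and x >= cut coincide
    score_neg <- if (length(u) > 1) total_w - score_pos else score_pos
    # interleave (cut, +1), (cut, -1) to keep the scan order deterministic
    scores <- as.vector(rbind(score_pos, score_neg))
    k <- which.max(scores)
    if (scores[k] > best$score) {
      best <- list(feature = j, cut = cuts[ceiling(k / 2)],
                   dir = if (k %% 2 == 1) 1 else -1, score = scores[k])
    }
  }
  best[c("feature", "cut", "dir")]
}

stump_predict <- function(stump, x) {
  ifelse(stump$dir * (x[, stump$feature] - stump$cut) >= 0, 1, -1)
}

adaboost_prob <- function(stumps, newx) {
  if (length(stumps) == 0) return(rep(0.5, nrow(newx)))
  f <- Reduce(`+`, lapply(stumps, function(s)
    s$alpha * stump_predict(s, newx)))
  plogis(2 * f)
}
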