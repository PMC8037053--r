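# Classifiers: Fisher LDA (shrinkage-regularized, one-vs-one for
# multiclass), linear SVM, kNN and Gaussian Naive Bayes, behind a common
# train/predict surface.

#' Classifier specification
#'
#' @param method One of "flda", "svm_linear", "knn", "naive_bayes".
#' @param C SVM cost parameter (linear kernel).
#' @param k kNN neighbor count.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(method = c("flda", "svm_linear", "knn",
                                       "naive_bayes"),
                            C = 1, k = 5) {
  method <- match.arg(method)
  structure(list(method = method, C = C, k = k), class = "classifier_spec")
}

# Fisher direction for two classes with shrinkage-ridge regularized pooled
# within-class scatter (inevitable at p >> n); threshold at the midpoint of
# the projected class means (equal priors).
flda_binary <- function(x, y01, shrink = 1e-3) {
  m0 <- colMeans(x[y01 == 0, , drop = FALSE])
  m1 <- colMeans(x[y01 == 1, , drop = FALSE])
  S <- ((sum(y01 == 0) - 1) * stats::cov(x[y01 == 0, , drop = FALSE]) +
          (sum(y01 == 1) - 1) * stats::cov(x[y01 == 1, , drop = FALSE])) /
    (nrow(x) - 2)
  regularized <- FALSE
  d <- tryCatch(solve(S, m1 - m0), error = function(e) NULL)
  if (is.null(d) || any(!is.finite(d)) || kappa(S) > 1e10) {
    S <- S + diag(shrink * mean(diag(S)) + 1e-12, ncol(S))
    d <- solve(S, m1 - m0)
    regularized <- TRUE
  }
  thr <- sum(d * (m0 + m1)) / 2
  list(w = d, thr = thr, regularized = regularized)
}

#' Train a classifier
#'
#' Fits the requested classifier on a numeric feature matrix. FLDA and the
#' linear SVM handle multiclass problems one-vs-one (majority vote, ties
#' broken by total decision margin); kNN stores the training set; Naive
#' Bayes uses Gaussian class conditionals.
#'
#' @param x Samples x features matrix.
#' @param labels Class labels (>= 2 classes present).
#' @param spec A [classifier_spec()].
#' @return Object of class `cl_model` with a [predict.cl_model()] method.
#' @export
train_classifier <- function(x, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  g <- factor(labels)
  if (nlevels(g) < 2) stop_cogload("training data has a single class")
  x <- as.matrix(x)
  fit <- switch(
    spec$method,
    svm_linear = e1071::svm(x, g, kernel = "linear", cost = spec$C,
                            scale = FALSE),
    naive_bayes = e1071::naiveBayes(x, g),
    knn = list(x = x, g = g, k = spec$k),
    flda = {
      lv <- levels(g)
      pairs <- utils::combn(lv, 2)
      machines <- lapply(seq_len(ncol(pairs)), function(j) {
        a <- pairs[1, j]; b <- pairs[2, j]
        sel <- g %in% c(a, b)
        c(list(a = a, b = b),
          flda_binary(x[sel, , drop = FALSE], as.integer(g[sel] == b)))
      })
      list(machines = machines, levels = lv)
    })
  structure(list(method = spec$method, fit = fit, levels = levels(g),
                 spec = spec),
            class = "cl_model")
}

#' Predict class labels
#'
#' @param object A `cl_model` from [train_classifier()].
#' @param newdata Samples x features matrix.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.cl_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  switch(
    object$method,
    svm_linear = stats::predict(object$fit, newdata),
    naive_bayes = stats::predict(object$fit, newdata),
    knn = class::knn(object$fit$x, newdata, object$fit$g, k = object$fit$k),
    flda = {
      lv <- object$fit$levels
      votes <- matrix(0, nrow(newdata), length(lv),
                      dimnames = list(NULL, lv))
      margin <- votes
      for (mch in object$fit$machines) {
        sc <- drop(newdata %*% mch$w) - mch$thr
        pick_b <- sc > 0
        votes[, mch$b] <- votes[, mch$b] + pick_b
        votes[, mch$a] <- votes[, mch$a] + !pick_b
        margin[, mch$b] <- margin[, mch$b] + sc
        margin[, mch$a] <- margin[, mch$a] - sc
      }
      idx <- vapply(seq_len(nrow(votes)), function(i) {
        best <- which(votes[i, ] == max(votes[i, ]))
        if (length(best) > 1) best <- best[which.max(margin[i, best])]
        best[1]
      }, integer(1))
      factor(lv[idx], levels = lv)
    })
}

#' Per-class evaluation metrics
#'
#' One-vs-rest confusion per class: recall, precision, specificity and
#' F-measure (2PR/(P+R)), plus overall accuracy, all in percent. Metrics
#' undefined for a class absent from `truth` (or with a zero denominator)
#' are returned as NA.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return List `per_class` (data.frame class, recall, precision,
#'   specificity, f_measure) and `accuracy`.
#' @export
evaluate <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop_cogload("prediction/label length mismatch")
  lv <- sort(unique(c(as.character(predicted), as.character(truth))))
  predicted <- factor(predicted, levels = lv)
  truth <- factor(truth, levels = lv)
  per <- do.call(rbind, lapply(lv, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fn <- sum(predicted != cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    tn <- sum(predicted != cl & truth != cl)
    rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    pre <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    spe <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    f <- if (!is.na(rec) && !is.na(pre) && rec + pre > 0)
      2 * pre * rec / (pre + rec) else NA_real_
    data.frame(class = cl, recall = rec, precision = pre, specificity = spe,
               f_measure = f, stringsAsFactors = FALSE)
  }))
  list(per_class = per,
       accuracy = 100 * mean(as.character(predicted) == as.character(truth)))
}
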