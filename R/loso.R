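# Leave-one-subject-out cross-validation with nested hyperparameter
# search, pairwise model comparison and discriminant-feature summaries.

#' Selector specification
#'
#' Exactly one sizing parameter applies per method: `n_feat` for the
#' rank-based selectors (kruskal, mannwhitney, relieff, nmi), `cev` for
#' PCA; "none" passes features through.
#'
#' @param method One of "none", "kruskal", "mannwhitney", "relieff",
#'   "nmi", "pca".
#' @param n_feat Number of features kept by rank-based selection.
#' @param cev Cumulative explained variance fraction for PCA.
#' @param prune_r Pearson correlation pruning threshold (kruskal /
#'   mannwhitney).
#' @return List of class `selector_spec`.
#' @export
selector_spec <- function(method = c("none", "kruskal", "mannwhitney",
                                     "relieff", "nmi", "pca"),
                          n_feat = 100, cev = 0.95, prune_r = 0.95) {
  method <- match.arg(method)
  structure(list(method = method, n_feat = n_feat, cev = cev,
                 prune_r = prune_r),
            class = "selector_spec")
}

# Fit the selector on the training block only and project both blocks.
# Returns train/test matrices plus the fold's ranked feature list (for
# rank-based selectors).
apply_selector <- function(train_x, train_labels, test_x, sel) {
  ranking <- NULL
  if (sel$method == "none") {
    out <- list(train = train_x, test = test_x)
  } else if (sel$method == "pca") {
    pr <- pca_reduce(train_x, test_x, cev = sel$cev)
    out <- list(train = pr$train, test = pr$test)
  } else if (sel$method %in% c("kruskal", "mannwhitney")) {
    keep <- rank_univariate(train_x, train_labels, method = sel$method,
                            prune_r = sel$prune_r, n_keep = sel$n_feat)
    ranking <- as.character(keep)
    out <- list(train = train_x[, ranking, drop = FALSE],
                test = if (!is.null(test_x)) test_x[, ranking, drop = FALSE])
  } else if (sel$method == "relieff") {
    w <- relieff_rank(train_x, train_labels)
    ranking <- attr(w, "order")[seq_len(min(sel$n_feat, length(w)))]
    out <- list(train = train_x[, ranking, drop = FALSE],
                test = if (!is.null(test_x)) test_x[, ranking, drop = FALSE])
  } else {
    ranking <- nmi_select(train_x, train_labels,
                          k = min(sel$n_feat, ncol(train_x)))
    ranking <- as.character(ranking)
    out <- list(train = train_x[, ranking, drop = FALSE],
                test = if (!is.null(test_x)) test_x[, ranking, drop = FALSE])
  }
  out$ranking <- ranking
  out
}

apply_grid_row <- function(sel, cls, row) {
  if (!is.null(row$cev)) sel$cev <- row$cev
  if (!is.null(row$n_feat)) sel$n_feat <- row$n_feat
  if (!is.null(row$C)) cls$C <- row$C
  if (!is.null(row$k)) cls$k <- row$k
  list(sel = sel, cls = cls)
}

# one scaled/selected/fitted/predicted split; returns factor predictions
fit_predict_split <- function(train_x, train_y, test_x, sel, cls) {
  sc <- zscore_fit_apply(train_x, test_x)
  pr <- apply_selector(sc$train, train_y, sc$test, sel)
  mod <- train_classifier(pr$train, train_y, cls)
  list(pred = predict(mod, pr$test), ranking = pr$ranking)
}

#' Leave-one-subject-out cross-validation
#'
#' Outer loop over subjects: the classifier is trained on all other
#' subjects' samples and tested on the held-out subject. Z-scoring,
#' feature selection/reduction and fitting all happen inside the training
#' fold only (no leakage; asserted structurally). When `grid` has more
#' than one row, hyperparameters are chosen per outer fold by a nested
#' leave-one-subject-out over the training subjects, maximizing mean inner
#' accuracy.
#'
#' @param table A `sample_table`.
#' @param selector A [selector_spec()].
#' @param classifier A [classifier_spec()].
#' @param grid Optional data.frame of hyperparameter candidates (columns
#'   among `C`, `k`, `cev`, `n_feat`); NULL or a single row skips the
#'   inner search.
#' @param verbose Print per-fold progress.
#' @return Object of class `loso_result`: `predictions` (subject, truth,
#'   predicted), `fold_accuracy`, `metrics` (per-class mean and sd across
#'   folds), `accuracy` (mean), `accuracy_sd`, `chosen` (per-fold
#'   hyperparameters), `rankings` (per-fold ranked features, rank-based
#'   selectors only), `n_folds`.
#' @export
loso_cv <- function(table, selector = selector_spec("pca"),
                    classifier = classifier_spec("svm_linear"),
                    grid = NULL, verbose = FALSE) {
  stopifnot(inherits(table, "sample_table"))
  subjects <- unique(table$meta$subject)
  if (length(subjects) < 3) stop_cogload("need >= 3 subjects for LOSO")
  one_class <- vapply(subjects, function(s)
    length(unique(table$meta$label[table$meta$subject == s])) < 2, logical(1))
  if (any(one_class))
    warn_cogload("subject(s) with a single class: %s",
                 paste(subjects[one_class], collapse = ", "))
  preds <- list(); fold_acc <- numeric(0); chosen <- list(); rankings <- list()
  fold_eval <- list()
  for (s in subjects) {
    te <- table$meta$subject == s
    tr <- !te
    stopifnot(!any(table$meta$subject[tr] == s))   # leakage guard
    train_x <- table$x[tr, , drop = FALSE]
    train_y <- table$meta$label[tr]
    best <- list(sel = selector, cls = classifier, row = NULL)
    if (!is.null(grid) && nrow(grid) > 1) {
      inner_subj <- unique(table$meta$subject[tr])
      inner_acc <- numeric(nrow(grid))
      for (gi in seq_len(nrow(grid))) {
        cfg <- apply_grid_row(selector, classifier, grid[gi, , drop = FALSE])
        accs <- vapply(inner_subj, function(v) {
          vi <- table$meta$subject[tr] == v
          fp <- fit_predict_split(train_x[!vi, , drop = FALSE], train_y[!vi],
                                  train_x[vi, , drop = FALSE],
                                  cfg$sel, cfg$cls)
          mean(as.character(fp$pred) == train_y[vi])
        }, numeric(1))
        inner_acc[gi] <- mean(accs)
      }
      gi <- which.max(inner_acc)
      best <- apply_grid_row(selector, classifier, grid[gi, , drop = FALSE])
      best$row <- grid[gi, , drop = FALSE]
    } else if (!is.null(grid) && nrow(grid) == 1) {
      best <- apply_grid_row(selector, classifier, grid[1, , drop = FALSE])
      best$row <- grid[1, , drop = FALSE]
    }
    fp <- fit_predict_split(train_x, train_y, table$x[te, , drop = FALSE],
                            best$sel, best$cls)
    truth <- table$meta$label[te]
    ev <- evaluate(fp$pred, truth)
    fold_eval[[as.character(s)]] <- ev
    fold_acc <- c(fold_acc, stats::setNames(ev$accuracy, s))
    preds[[length(preds) + 1L]] <- data.frame(
      subject = s, truth = truth, predicted = as.character(fp$pred),
      stringsAsFactors = FALSE)
    if (!is.null(fp$ranking)) rankings[[as.character(s)]] <- fp$ranking
    chosen[[as.character(s)]] <- best$row
    if (verbose)
      message(sprintf("fold %s: accuracy %.1f%%", s, ev$accuracy))
  }
  classes <- sort(unique(table$meta$label))
  metr <- c("recall", "precision", "specificity", "f_measure")
  metrics <- do.call(rbind, lapply(classes, function(cl) {
    vals <- vapply(fold_eval, function(ev) {
      r <- ev$per_class[ev$per_class$class == cl, metr]
      if (nrow(r)) unlist(r) else rep(NA_real_, 4)
    }, numeric(4))
    data.frame(class = cl,
               metric = metr,
               mean = rowMeans(vals, na.rm = TRUE),
               sd = apply(vals, 1, stats::sd, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(metrics) <- NULL
  structure(list(predictions = do.call(rbind, preds),
                 fold_accuracy = fold_acc,
                 metrics = metrics,
                 accuracy = mean(fold_acc),
                 accuracy_sd = stats::sd(fold_acc),
                 chosen = chosen,
                 rankings = rankings,
                 n_folds = length(subjects),
                 selector = selector, classifier = classifier),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %s + %s, %d folds\n",
              x$selector$method, x$classifier$method, x$n_folds))
  cat(sprintf("accuracy: %.2f +/- %.2f %%\n", x$accuracy, x$accuracy_sd))
  invisible(x)
}

#' @export
summary.loso_result <- function(object, ...) {
  cat(sprintf("Leave-one-subject-out: %s selector, %s classifier (%d folds)\n",
              object$selector$method, object$classifier$method,
              object$n_folds))
  cat(sprintf("Overall accuracy: %.2f +/- %.2f %%\n\n",
              object$accuracy, object$accuracy_sd))
  m <- object$metrics
  for (cl in unique(m$class)) {
    r <- m[m$class == cl, ]
    cat(sprintf("  %-10s %s\n", cl,
                paste(sprintf("%s %.1f±%.1f", r$metric, r$mean, r$sd),
                      collapse = "  ")))
  }
  invisible(object)
}

#' Pairwise model comparison by Mann-Whitney tests
#'
#' Two-sided Mann-Whitney U test between every pair of models' per-fold
#' accuracy vectors, Bonferroni-corrected by the number of pairs (capped
#' at 1). The matrix is symmetric with unit diagonal.
#'
#' @param acc_list Named list of equal-length per-fold accuracy vectors
#'   (>= 2 models).
#' @return Numeric matrix of corrected p-values.
#' @export
compare_models <- function(acc_list) {
  if (length(acc_list) < 2) stop_cogload("need >= 2 models")
  lens <- lengths(acc_list)
  if (length(unique(lens)) != 1) stop_cogload("fold counts differ")
  nm <- names(acc_list) %||% paste0("model", seq_along(acc_list))
  n <- length(acc_list)
  npairs <- n * (n - 1) / 2
  P <- matrix(1, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- min(mw_u_test(acc_list[[i]], acc_list[[j]])$p * npairs, 1)
    P[i, j] <- p; P[j, i] <- p
  }
  P
}

# strip the second-order suffix from sample-table feature names
strip_second_order <- function(nm) {
  sub("__(max|min|mean|std|median)$", "", nm)
}

# electrodes referenced by a base feature name ("F3_F4__dasym__Theta" ->
# F3, F4; "FZ__abspow__Theta" -> FZ)
feature_electrodes <- function(nm) {
  head_tok <- sub("__.*$", "", nm)
  strsplit(head_tok, "_", fixed = TRUE)
}

# feature kind/band: the name without its channel prefix
feature_type <- function(nm) sub("^[^_]+(_[^_]+)?__", "", nm)

#' Summarize the most frequently selected features
#'
#' Aggregates the first `k` features of every fold's ranked list into
#' per-electrode and per-feature-type frequency tables, as percentages of
#' all counted top-k slots (asymmetry features count toward both
#' electrodes of the pair).
#'
#' @param rankings A `loso_result` (with a rank-based selector) or a list
#'   of per-fold ranked feature-name vectors.
#' @param k Features counted per fold (default 100; capped, with a
#'   warning, at the available list length).
#' @return List `by_electrode` and `by_type`: data.frames with columns
#'   `name`, `count`, `percent`, sorted decreasing.
#' @export
top_feature_summary <- function(rankings, k = 100) {
  if (inherits(rankings, "loso_result")) rankings <- rankings$rankings
  if (!length(rankings)) stop_cogload("no fold rankings available (rank-based selector required)")
  elec <- character(0); typ <- character(0)
  for (r in rankings) {
    kk <- min(k, length(r))
    if (kk < k) warn_cogload("only %d ranked features available (k = %d)",
                             length(r), k)
    top <- strip_second_order(r[seq_len(kk)])
    elec <- c(elec, unlist(feature_electrodes(top)))
    typ <- c(typ, feature_type(top))
  }
  mk <- function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    data.frame(name = names(tb), count = as.integer(tb),
               percent = 100 * as.integer(tb) / sum(tb),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(by_electrode = mk(elec), by_type = mk(typ))
}
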