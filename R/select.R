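# Feature selection and dimensionality reduction: Kruskal-Wallis /
# Mann-Whitney ranking with Pearson pruning, ReliefF, normalized mutual
# information, and PCA by cumulative explained variance.

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The exact null
#' distribution is used when both groups have at most 50 observations and
#' there are no ties; otherwise the normal approximation with mid-rank tie
#' correction and continuity correction is used. This mirrors the base R
#' convention and is cross-checked against `stats::wilcox.test` (and, for
#' small n, against exhaustive enumeration of label assignments) in the
#' package tests.
#'
#' @param x,y Numeric samples of the two groups.
#' @return List `u` (U statistic of `x`), `p` (two-sided p-value),
#'   `exact` (logical).
#' @export
mw_u_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop_cogload("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  exact <- !has_ties && nx <= 50 && ny <= 50
  if (exact) {
    # pwilcox gives P(U <= q) of the exact null distribution
    p <- if (u > nx * ny / 2) {
      2 * stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, nx, ny)
    }
  } else {
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))
    sigma <- sqrt(nx * ny / 12 * (nx + ny + 1 - tie_term))
    if (sigma == 0) return(list(u = u, p = 1, exact = FALSE))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sigma   # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(u = u, p = min(p, 1), exact = exact)
}

# Vectorized column-wise Kruskal-Wallis H (with tie correction) over a
# matrix; returns the p-value per column. Constant columns get p = 1.
kruskal_p_columns <- function(x, g) {
  g <- as.factor(g)
  n <- nrow(x)
  k <- nlevels(g)
  R <- apply(x, 2, rank)
  sum_r2 <- rowsum(R, g)^2                    # per-group squared rank sums
  ng <- as.vector(table(g))
  H <- 12 / (n * (n + 1)) * colSums(sum_r2 / ng) - 3 * (n + 1)
  # tie correction (only columns that actually contain ties)
  C <- rep(1, ncol(x))
  tied <- which(apply(x, 2, anyDuplicated) > 0)
  for (j in tied) {
    t <- table(x[, j])
    C[j] <- 1 - sum(t^3 - t) / (n^3 - n)
  }
  ok <- C > 0
  H[ok] <- H[ok] / C[ok]
  p <- rep(1, ncol(x))
  p[ok] <- stats::pchisq(H[ok], df = k - 1, lower.tail = FALSE)
  p
}

# Vectorized column-wise two-sided Mann-Whitney p (normal approximation
# with tie and continuity correction), for ranking many features.
mannwhitney_p_columns <- function(x, g) {
  g <- as.factor(g)
  if (nlevels(g) != 2) stop_cogload("Mann-Whitney ranking needs exactly 2 classes")
  a <- g == levels(g)[1]
  nx <- sum(a); ny <- sum(!a)
  R <- apply(x, 2, rank)
  u <- colSums(R[a, , drop = FALSE]) - nx * (nx + 1) / 2
  tie_term <- numeric(ncol(x))
  tied <- which(apply(x, 2, anyDuplicated) > 0)
  for (j in tied) {
    t <- table(x[, j])
    tie_term[j] <- sum(t^3 - t)
  }
  tie_term <- tie_term / ((nx + ny) * (nx + ny - 1))
  sigma <- sqrt(nx * ny / 12 * (nx + ny + 1 - tie_term))
  z <- u - nx * ny / 2
  z <- (z - sign(z) * 0.5) / pmax(sigma, 1e-300)
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma == 0] <- 1
  pmin(p, 1)
}

#' Rank features by a univariate non-parametric test, pruning correlates
#'
#' Features are ordered by ascending p-value of the Kruskal-Wallis H test
#' (multiclass) or the Mann-Whitney U test (binary), then greedily pruned:
#' walking down the ranking, a feature is dropped if its absolute Pearson
#' correlation with any higher-ranked kept feature exceeds `prune_r`.
#' Constant features rank last.
#'
#' @param x Samples x features matrix with column names.
#' @param labels Class labels (>= 2 classes, >= 2 samples per class).
#' @param method "kruskal" or "mannwhitney".
#' @param prune_r Pearson correlation threshold (default 0.95).
#' @param n_keep Stop after this many features survive pruning.
#' @return Character vector of kept feature names, best first, with the
#'   full p-value ranking in attribute `ranking`.
#' @export
rank_univariate <- function(x, labels, method = c("kruskal", "mannwhitney"),
                            prune_r = 0.95, n_keep = ncol(x)) {
  method <- match.arg(method)
  g <- as.factor(labels)
  if (nlevels(g) < 2) stop_cogload("need >= 2 classes")
  if (any(table(g) < 2)) stop_cogload("need >= 2 samples per class")
  p <- switch(method,
              kruskal = kruskal_p_columns(x, g),
              mannwhitney = mannwhitney_p_columns(x, g))
  sds <- apply(x, 2, stats::sd)
  p[sds < 1e-12] <- 1 + 1e-9        # constant features strictly last
  ord <- order(p)
  nm <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  kept_idx <- integer(0)
  for (j in ord) {
    if (sds[j] < 1e-12 && length(kept_idx) >= 1) next
    if (length(kept_idx)) {
      r <- abs(stats::cor(x[, j], x[, kept_idx, drop = FALSE]))
      if (any(r > prune_r, na.rm = TRUE)) next
    }
    kept_idx <- c(kept_idx, j)
    if (length(kept_idx) >= n_keep) break
  }
  out <- nm[kept_idx]
  attr(out, "ranking") <- nm[ord]
  attr(out, "p") <- p[kept_idx]
  out
}

#' ReliefF feature weights
#'
#' Multi-class ReliefF with all instances used (deterministic, no
#' sampling): for each instance, the `n_neighbors` nearest hits and, per
#' other class, the nearest misses (weighted by class prior) update the
#' weights with range-normalized Manhattan feature differences.
#'
#' @param x Samples x features matrix.
#' @param labels Class labels (>= 2 per class).
#' @param n_neighbors Neighbors per class (default 10, capped by class
#'   sizes).
#' @return Named numeric weight vector sorted decreasing, with attribute
#'   `order` (feature names best first).
#' @export
relieff_rank <- function(x, labels, n_neighbors = 10) {
  g <- as.factor(labels)
  if (any(table(g) < 2)) stop_cogload("need >= 2 samples per class")
  n <- nrow(x); pfe <- ncol(x)
  rng <- apply(x, 2, max) - apply(x, 2, min)
  rng[rng < 1e-300] <- 1
  xs <- sweep(x, 2, rng, "/")
  D <- as.matrix(stats::dist(xs, method = "manhattan"))
  diag(D) <- Inf
  prior <- table(g) / n
  w <- numeric(pfe)
  for (i in seq_len(n)) {
    same <- g == g[i]
    k_hit <- min(n_neighbors, sum(same) - 1)
    hits <- order(D[i, same & seq_len(n) != i])  # indices within subset
    hit_idx <- which(same & seq_len(n) != i)[hits[seq_len(k_hit)]]
    if (k_hit > 0)
      w <- w - colSums(abs(xs[hit_idx, , drop = FALSE] -
                             matrix(xs[i, ], k_hit, pfe, byrow = TRUE))) / (k_hit * n)
    for (cl in levels(g)[levels(g) != g[i]]) {
      other <- g == cl
      k_miss <- min(n_neighbors, sum(other))
      miss <- order(D[i, other])
      miss_idx <- which(other)[miss[seq_len(k_miss)]]
      pw <- prior[[cl]] / (1 - prior[[as.character(g[i])]])
      w <- w + pw * colSums(abs(xs[miss_idx, , drop = FALSE] -
                                  matrix(xs[i, ], k_miss, pfe, byrow = TRUE))) / (k_miss * n)
    }
  }
  names(w) <- colnames(x) %||% paste0("f", seq_len(pfe))
  ord <- order(w, decreasing = TRUE)
  out <- w[ord]
  attr(out, "order") <- names(w)[ord]
  out
}

# plug-in normalized mutual information between two discrete vectors,
# normalization sqrt(H(X) H(Y)); 0 when either entropy is 0
nmi_discrete <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx <= 0 || hy <= 0) return(0)
  mi / sqrt(hx * hy)
}

equal_width_bins <- function(v, n_bins) {
  r <- range(v)
  if (diff(r) < 1e-300) return(rep(1L, length(v)))
  findInterval(v, seq(r[1], r[2], length.out = n_bins + 1),
               rightmost.closed = TRUE, all.inside = TRUE)
}

#' Greedy NMI feature selection (relevance minus redundancy)
#'
#' Features are discretized into equal-width bins; selection greedily
#' maximizes NMI(feature; label) minus the mean NMI between the candidate
#' and the already-selected features, so relevant but redundant features
#' (e.g. exact duplicates) are not selected twice.
#'
#' @param x Samples x features matrix.
#' @param labels Class labels.
#' @param k Number of features to select (<= ncol(x)).
#' @param n_bins Equal-width bins for discretization (default 10).
#' @return Character vector of selected feature names, in selection order,
#'   with attribute `scores`.
#' @export
nmi_select <- function(x, labels, k, n_bins = 10) {
  if (k > ncol(x)) stop_cogload("k = %d exceeds feature count %d", k, ncol(x))
  nm <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  disc <- apply(x, 2, equal_width_bins, n_bins = n_bins)
  rel <- apply(disc, 2, nmi_discrete, b = labels)
  sel <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(x)), sel)
    score <- rel[cand]
    if (length(sel)) {
      red_mat <- vapply(cand, function(j)
        vapply(sel, function(s) nmi_discrete(disc[, j], disc[, s]),
               numeric(1)), numeric(length(sel)))
      red_mat <- matrix(red_mat, nrow = length(sel))
      score <- score - colMeans(red_mat)
      # near-duplicates of an already-selected feature are excluded
      # outright unless nothing else remains
      dup <- apply(red_mat, 2, max) > 0.95
      if (any(!dup)) score[dup] <- -Inf
    }
    best <- cand[which.max(score)]
    sel <- c(sel, best)
    scores <- c(scores, max(score))
  }
  out <- nm[sel]
  attr(out, "scores") <- scores
  out
}

#' PCA by cumulative explained variance, fitted on training data only
#'
#' Principal components are fitted on the (centred) training matrix; the
#' smallest number of components whose cumulative explained variance
#' reaches `cev` is retained and both tables are projected. For p >> n the
#' eigendecomposition is done on the n x n Gram matrix (identical
#' subspace, cross-checked against `prcomp` in the tests).
#'
#' @param train,test Numeric matrices with identical columns (`test` may
#'   be NULL).
#' @param cev Cumulative explained variance fraction in (0, 1].
#' @return List `train`, `test` (projected scores), `rotation`, `center`,
#'   `m` (components kept), `explained` (per-component variance fractions).
#' @export
pca_reduce <- function(train, test = NULL, cev = 0.95) {
  if (!(cev > 0 && cev <= 1)) stop_cogload("cev must be in (0, 1]")
  if (nrow(train) < 2) stop_cogload("need >= 2 training rows")
  ctr <- colMeans(train)
  Xc <- sweep(train, 2, ctr)
  n <- nrow(Xc); p <- ncol(Xc)
  if (p > n) {
    G <- tcrossprod(Xc)                     # n x n
    eg <- eigen(G, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-12
    lam <- eg$values[pos] / (n - 1)
    rot <- crossprod(Xc, eg$vectors[, pos, drop = FALSE]) %*%
      diag(1 / sqrt(eg$values[pos]), sum(pos))
  } else {
    eg <- eigen(stats::cov(Xc), symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-12
    lam <- eg$values[pos]
    rot <- eg$vectors[, pos, drop = FALSE]
  }
  explained <- lam / sum(lam)
  m <- which(cumsum(explained) >= cev - 1e-12)[1]
  if (is.na(m)) m <- length(lam)
  rot <- rot[, seq_len(m), drop = FALSE]
  out_train <- Xc %*% rot
  out_test <- if (!is.null(test)) sweep(test, 2, ctr) %*% rot else NULL
  list(train = out_train, test = out_test, rotation = rot, center = ctr,
       m = m, explained = explained)
}
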