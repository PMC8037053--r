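# Feature selection: rank tests, ReliefF, NMI and PCA.

test_that("mw_u_test agrees with wilcox.test and exhaustive enumeration", {
  with_seed_test(101, {
    for (i in 1:8) {
      nx <- sample(3:10, 1); ny <- sample(3:10, 1)
      x <- rnorm(nx); y <- rnorm(ny, mean = runif(1, -1, 1))
      ours <- mw_u_test(x, y)
      ref <- wilcox.test(x, y, exact = TRUE)
      expect_equal(ours$u, unname(ref$statistic))
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
      enum <- mw_exact_enum(x, y)
      expect_equal(ours$u, enum$u)
      expect_equal(ours$p, enum$p, tolerance = 1e-12)
    }
    # ties: mid-ranks + normal approximation with continuity correction
    x <- c(1, 2, 2, 3, 5, 5, 8); y <- c(2, 4, 4, 5, 9, 10)
    ours <- mw_u_test(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
    expect_false(ours$exact)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    # large samples switch to the normal path and stay calibrated
    big <- mw_u_test(rnorm(60), rnorm(60))
    expect_false(big$exact)
    expect_gt(big$p, 0.001)
  })
})

test_that("column-wise rank statistics agree with kruskal.test / wilcox.test", {
  with_seed_test(102, {
    x <- cbind(rnorm(30), rep(1:3, 10), rnorm(30, sd = 4))
    g3 <- rep(c("a", "b", "c"), each = 10)
    ours <- cogload:::kruskal_p_columns(x, g3)
    ref <- apply(x, 2, function(col) kruskal.test(col, factor(g3))$p.value)
    expect_equal(ours, unname(ref), tolerance = 1e-9)
    g2 <- rep(c("a", "b"), each = 15)
    ours2 <- cogload:::mannwhitney_p_columns(x, g2)
    ref2 <- apply(x, 2, function(col)
      suppressWarnings(wilcox.test(col[g2 == "a"], col[g2 == "b"],
                                   exact = FALSE, correct = TRUE))$p.value)
    expect_equal(ours2, unname(ref2), tolerance = 1e-9)
  })
})

test_that("univariate ranking puts discriminative features first and prunes duplicates", {
  with_seed_test(103, {
    g <- rep(c("a", "b"), each = 10)
    disc <- c(rnorm(10, 0, 0.2), rnorm(10, 5, 0.2))    # disjoint classes
    x <- cbind(sig = disc, noise = rnorm(20), copy = disc)
    kept <- rank_univariate(x, g, method = "mannwhitney", prune_r = 0.99)
    expect_equal(kept[1], "sig")
    expect_false("copy" %in% kept)                     # r = 1 with sig
    kept3 <- rank_univariate(x, g, method = "mannwhitney", prune_r = 1.01)
    expect_length(kept3, 3)
    # multiclass path
    g3 <- rep(c("a", "b", "c"), times = c(7, 7, 6))
    x3 <- cbind(sig = c(rnorm(7, 0, .2), rnorm(7, 3, .2), rnorm(6, 6, .2)),
                noise = rnorm(20))
    expect_equal(rank_univariate(x3, g3, "kruskal")[1], "sig")
    # constant features rank last
    xc <- cbind(const = rep(1, 20), sig = disc)
    expect_equal(rank_univariate(xc, g, "mannwhitney")[1], "sig")
    expect_error(rank_univariate(x, rep("a", 20), "mannwhitney"), "classes")
  })
})

test_that("under permuted labels no feature is systematically ranked first", {
  with_seed_test(104, {
    x <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, paste0("f", 1:4)))
    firsts <- replicate(60, {
      g <- sample(rep(c("a", "b"), each = 10))
      rank_univariate(x, g, "mannwhitney")[1]
    })
    f <- mean(firsts == "f1")          # expect ~ 1/4
    expect_gt(f, 0.02); expect_lt(f, 0.6)
  })
})

test_that("ReliefF rewards informative and interacting features", {
  with_seed_test(105, {
    # margin feature vs pure noise
    g <- rep(c("a", "b"), each = 15)
    x <- cbind(inf = c(rnorm(15, 0, .3), rnorm(15, 3, .3)), noise = rnorm(30))
    w <- relieff_rank(x, g, n_neighbors = 5)
    expect_gt(w[["inf"]], 0)
    expect_gt(w[["inf"]], w[["noise"]] + 0.05)
    expect_equal(attr(w, "order")[1], "inf")
    # XOR pair: individually useless, jointly separating
    xa <- rep(c(0, 0, 1, 1), each = 2)
    xb <- rep(c(0, 1, 0, 1), each = 2)
    gx <- ifelse(xor(xa > 0, xb > 0), "p", "q")
    xx <- cbind(a = xa, b = xb, n1 = runif(8), n2 = runif(8))
    wx <- relieff_rank(xx, gx, n_neighbors = 1)
    expect_true(all(match(c("a", "b"), attr(wx, "order")) <
                      match(c("n1", "n2"), attr(wx, "order"))))
    # identical features share identical weights
    xi <- cbind(u = x[, 1], v = x[, 1])
    wi <- relieff_rank(xi, g, n_neighbors = 3)
    expect_equal(wi[["u"]], wi[["v"]])
  })
})

test_that("NMI selection is relevance-driven and redundancy-averse", {
  with_seed_test(106, {
    g <- rep(c("a", "b"), each = 30)
    ident <- as.numeric(g == "a")                   # NMI = 1 with the label
    x <- cbind(ident = ident, dup = ident, noise = runif(60))
    sel <- nmi_select(x, g, k = 2)
    expect_equal(sel[1], "ident")
    expect_equal(sel[2], "noise")                   # duplicate penalized away
    # independent feature: NMI ~ 0 at n = 1000
    gg <- rep(c("a", "b"), each = 500)
    v <- cogload:::nmi_discrete(cogload:::equal_width_bins(runif(1000), 10), gg)
    expect_lt(v, 0.05)
    expect_error(nmi_select(x, g, k = 9), "exceeds")
  })
})

test_that("PCA keeps the smallest component set reaching the requested CEV", {
  with_seed_test(107, {
    # exact 1-D structure in 3-D
    t <- rnorm(40)
    line <- cbind(t, 2 * t, -t) + matrix(rnorm(120, 0, 1e-8), 40)
    pr <- pca_reduce(line, cev = 0.99)
    expect_equal(pr$m, 1)
    # cev = 1 retains the full rank
    x <- matrix(rnorm(20 * 5), 20, 5)
    expect_equal(pca_reduce(x, cev = 1)$m, 5)
    # agreement with prcomp up to component sign
    ref <- prcomp(x, center = TRUE)
    ours <- pca_reduce(x, x[1:3, , drop = FALSE], cev = 1)
    for (j in 1:5) {
      agree <- max(abs(ours$train[, j] - ref$x[, j]),
                   abs(ours$train[, j] + ref$x[, j]))
      expect_lt(min(max(abs(ours$train[, j] - ref$x[, j])),
                    max(abs(ours$train[, j] + ref$x[, j]))), 1e-8)
    }
    expect_equal(abs(unname(ours$test[1, ])), abs(unname(ref$x[1, ])),
                 tolerance = 1e-8)
    # the p >> n Gram route matches the covariance route
    wide <- matrix(rnorm(10 * 50), 10, 50)
    pw <- pca_reduce(wide, cev = 0.9)
    refw <- prcomp(wide, center = TRUE)
    cum <- cumsum(refw$sdev^2) / sum(refw$sdev^2)
    expect_equal(pw$m, which(cum >= 0.9)[1])
    expect_lt(min(max(abs(pw$train[, 1] - refw$x[, 1])),
                  max(abs(pw$train[, 1] + refw$x[, 1]))), 1e-8)
    # isotropic Gaussian: component count scales with cev
    iso <- matrix(rnorm(4000 * 10), 4000, 10)
    expect_lt(abs(pca_reduce(iso, cev = 0.5)$m - 5), 2.1)
    expect_error(pca_reduce(x, cev = 0), "cev")
  })
})
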