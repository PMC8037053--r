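# Baseline normalization, segmentation, second-order features and table
# assembly.

test_that("baseline normalization is the relative variation against the preceding cross", {
  sched <- data.frame(onset = c(0, 4, 10, 14), duration = c(4, 6, 4, 8),
                      kind = c("cross", "reading", "cross", "code"),
                      label = c("", "Control-1", "", "C1"),
                      trial = 1, load = 0)
  vals <- rbind(c(1, 10), c(3, 10),          # cross 1 windows: means 2, 10
                c(4, 20), c(2, 5),           # reading windows
                c(2, 1), c(2, 1),            # cross 2: means 2, 1
                c(4, 1))                     # code window
  meta <- data.frame(event = c(1, 1, 2, 2, 3, 3, 4),
                     kind = c("cross", "cross", "reading", "reading",
                              "cross", "cross", "code"),
                     label = c("", "", "Control-1", "Control-1", "", "", "C1"),
                     trial = 1, t_mid = 1:7)
  fm <- fake_feature_matrix(vals, meta)
  out <- baseline_normalize(fm, sched)
  expect_equal(nrow(out$values), 3)          # cross windows consumed
  # hand computation of the relative variation
  expect_equal(out$values[1, ], c((4 - 2) / 2, (20 - 10) / 10))
  expect_equal(out$values[2, ], c(0, (5 - 10) / 10))
  # code normalized by the *second* cross
  expect_equal(out$values[3, ], c((4 - 2) / 2, 0))
  # doubling a feature's value over the baseline always gives exactly 1
  expect_equal(out$values[3, 1], 1.0)
})

test_that("near-zero baselines are guarded and flagged", {
  sched <- data.frame(onset = c(0, 4), duration = c(4, 6),
                      kind = c("cross", "reading"),
                      label = c("", "Control-1"), trial = 1, load = 0)
  vals <- rbind(c(0, 5), c(0, 7), c(3, 6))
  meta <- data.frame(event = c(1, 1, 2), kind = c("cross", "cross", "reading"),
                     label = c("", "", "Control-1"), trial = 1, t_mid = 1:3)
  out <- baseline_normalize(fake_feature_matrix(vals, meta), sched)
  expect_equal(out$values[1, 1], 0)
  expect_true(out$guard_flags[1, 1])
  expect_false(out$guard_flags[1, 2])
})

test_that("normalization equals brute-force recomputation under affine changes", {
  with_seed_test(81, {
    sched <- data.frame(onset = c(0, 4), duration = c(4, 6),
                        kind = c("cross", "reading"),
                        label = c("", "Control-1"), trial = 1, load = 0)
    base <- matrix(runif(6, 1, 2), 3, 2)
    task <- matrix(runif(8, 1, 2), 4, 2)
    meta <- data.frame(event = rep(1:2, c(3, 4)),
                       kind = rep(c("cross", "reading"), c(3, 4)),
                       label = rep(c("", "Control-1"), c(3, 4)),
                       trial = 1, t_mid = 1:7)
    for (a in c(1, 2.5)) for (b in c(0, 3)) {
      fm <- fake_feature_matrix(rbind(base * a + b, task * a + b), meta)
      out <- baseline_normalize(fm, sched)
      bm <- colMeans(base * a + b)
      oracle <- sweep(sweep(task * a + b, 2, bm), 2, bm, "/")
      expect_equal(out$values, oracle, tolerance = 1e-12)
    }
  })
})

test_that("tasks split into 4 near-equal contiguous segments, remainder first", {
  expect_equal(table(segment_task(296)), table(rep(1:4, each = 74)))
  expect_equal(segment_task(5), c(1, 1, 2, 3, 4))
  expect_equal(segment_task(4), 1:4)
  expect_error(segment_task(3), ">= 4")
  for (n in c(7, 9, 50, 101)) {
    s <- segment_task(n)
    sizes <- as.integer(table(s))
    expect_equal(sum(sizes), n)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_true(all(diff(s) >= 0))             # contiguous
    expect_true(all(diff(sizes) <= 0))         # remainder to earliest
  }
})

test_that("second-order features are the five statistics per input feature", {
  v <- second_order(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f")))
  expect_equal(unname(v), c(3, 1, 2, 1, 2))    # max min mean sd(n-1) median
  expect_equal(names(v), c("f__max", "f__min", "f__mean", "f__std", "f__median"))
  one <- second_order(matrix(5, 1, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(one), c(5, 5, 5, 0, 5, 5, 5, 5, 0, 5))
  wide <- second_order(matrix(rnorm(2 * 3007), 2, 3007))
  expect_length(wide, 15035)
})

test_that("table shapes follow subjects x tasks x segments for any cohort size", {
  for (ns in c(1, 2, 3)) {
    feats <- fake_cohort_features(n_subjects = ns, seed = ns)
    b <- assemble_binary(feats)
    m <- assemble_multiclass(feats)
    expect_equal(nrow(b$x), ns * 6 * 4)
    expect_equal(nrow(m$x), ns * 4 * 4)
    expect_equal(ncol(b$x), 5 * 3)
    expect_setequal(unique(b$meta$label),
                    c("C1", "C2", "C3", "Control-1", "Control-2", "Control-3"))
    expect_setequal(unique(m$meta$label), c("C1", "C2", "C3", "Control"))
    # every (subject, label) cell has exactly 4 segments
    expect_true(all(table(m$meta$subject, m$meta$label) == 4))
  }
})

test_that("pooled control concatenates trials in time order before splitting", {
  feats <- fake_cohort_features(n_subjects = 1, windows_per_event = 4, seed = 5)
  m <- assemble_multiclass(feats)
  ctl <- m$meta$label == "Control"
  expect_equal(sum(ctl), 4)
  # oracle: pooled control = all reading windows in time order
  fm <- feats[[1]]$fm
  rd <- fm$meta$kind == "reading"
  V <- fm$values[rd, ][order(fm$meta$t_mid[rd]), ]
  seg <- segment_task(nrow(V))
  oracle <- t(vapply(1:4, function(s) second_order(V[seg == s, , drop = FALSE]),
                     numeric(15)))
  expect_equal(unname(m$x[ctl, ]), unname(oracle))
})

test_that("missing tasks are reported with the offending subject", {
  feats <- fake_cohort_features(n_subjects = 1)
  drop <- feats[[1]]$fm$meta$kind == "code" & feats[[1]]$fm$meta$trial == 2
  feats[[1]]$fm$values <- feats[[1]]$fm$values[!drop, , drop = FALSE]
  feats[[1]]$fm$meta <- feats[[1]]$fm$meta[!drop, , drop = FALSE]
  expect_error(assemble_binary(feats), "trial 2")
  expect_error(assemble_multiclass(feats), "trial 2")
})

test_that("NASA relabeling merges C2/C3 and conserves rows", {
  feats <- fake_cohort_features(n_subjects = 2)
  m <- assemble_multiclass(feats)
  n23 <- sum(m$meta$label %in% c("C2", "C3"))
  r <- relabel_nasa(m)
  expect_setequal(unique(r$meta$label), c("C1", "C2/C3", "Control"))
  expect_equal(nrow(r$x), nrow(m$x))
  expect_equal(sum(r$meta$label == "C2/C3"), n23)
  # a table with no C2/C3 rows is unchanged
  keep <- !(m$meta$label %in% c("C2", "C3"))
  m2 <- cogload:::new_sample_table(m$x[keep, ], m$meta[keep, ], "multiclass")
  expect_equal(relabel_nasa(m2)$meta$label, m2$meta$label)
  # saturation check refuses to merge clearly distinct scores
  tlx <- data.frame(task = rep(c("C2", "C3"), each = 4), score = rep(c(2, 5), each = 4))
  expect_warning(r3 <- relabel_nasa(m, tlx), "not merging")
  expect_setequal(unique(r3$meta$label), c("C1", "C2", "C3", "Control"))
})

test_that("z-scoring fits on the training rows only", {
  with_seed_test(91, {
    tr <- matrix(rnorm(60, 5, 2), 20, 3)
    te <- matrix(rnorm(15, 5, 2), 5, 3)
    te[1, ] <- colMeans(tr)
    sc <- zscore_fit_apply(tr, te)
    expect_lt(max(abs(colMeans(sc$train))), 1e-9)
    expect_lt(max(abs(apply(sc$train, 2, sd) - 1)), 1e-9)
    expect_equal(unname(sc$test[1, ]), c(0, 0, 0))
    tr2 <- cbind(tr, 7)                      # constant column
    sc2 <- zscore_fit_apply(tr2, cbind(te, 9))
    expect_true(all(sc2$train[, 4] == 0))
    expect_true(sc2$flags[4])
  })
})
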