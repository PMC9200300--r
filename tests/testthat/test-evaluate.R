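test_that("confusion counts conserve pixels and match a per-pixel oracle", {
  set.seed(61)
  for (i in 1:10) {
    p <- random_mask(12, 9); t <- random_mask(12, 9)
    cf <- confusion(p, t)
    expect_equal(cf$tp + cf$fp + cf$tn + cf$fn, 12L * 9L)
    # naive double loop
    tp <- fp <- tn <- fn <- 0L
    for (a in 1:12) for (b in 1:9) {
      if (p[a, b] == 1 && t[a, b] == 1) tp <- tp + 1L
      if (p[a, b] == 1 && t[a, b] == 0) fp <- fp + 1L
      if (p[a, b] == 0 && t[a, b] == 0) tn <- tn + 1L
      if (p[a, b] == 0 && t[a, b] == 1) fn <- fn + 1L
    }
    expect_equal(unlist(cf), c(tp = tp, fp = fp, tn = tn, fn = fn))
  }
  m <- random_mask(5, 5)
  perfect <- confusion(m, m)
  expect_equal(perfect$fp + perfect$fn, 0L)
  inverted <- confusion(mp_mask(1L - unclass(m)), m)
  expect_equal(inverted$tp + inverted$tn, 0L)
  expect_error(confusion(random_mask(3, 3), random_mask(4, 4)), "shapes")
})

test_that("metrics follow their standard formulas", {
  m <- random_mask(6, 6, 0.4)
  perfect <- seg_metrics(confusion(m, m))
  expect_equal(unlist(perfect[1:5]), c(balanced_accuracy = 1, recall = 1,
                                       precision = 1, f1 = 1, iou = 1))
  hand <- seg_metrics(list(tp = 50, fp = 10, tn = 930, fn = 10))
  expect_equal(hand$recall, 5 / 6, tolerance = 1e-12)
  expect_equal(hand$precision, 5 / 6, tolerance = 1e-12)
  expect_equal(hand$f1, 5 / 6, tolerance = 1e-12)
  expect_equal(hand$iou, 50 / 70, tolerance = 1e-12)
  expect_equal(hand$balanced_accuracy, (5 / 6 + 930 / 940) / 2,
               tolerance = 1e-12)
  # all-background prediction: zero recall/iou, flagged
  t <- mp_mask(matrix(c(1L, rep(0L, 15)), 4, 4))
  zero <- seg_metrics(confusion(mp_mask(matrix(0L, 4, 4)), t))
  expect_equal(zero$recall, 0); expect_equal(zero$iou, 0)
  expect_match(zero$undefined, "precision")
  # iou <= f1 whenever both defined
  set.seed(67)
  for (i in 1:10) {
    r <- seg_metrics(confusion(random_mask(8, 8), random_mask(8, 8)))
    expect_lte(r$iou, r$f1 + 1e-12)
  }
})

test_that("mean-of-fold-means differs from the pooled mean as expected", {
  rows <- do.call(rbind, lapply(c(0.2, 0.4, 0.9), function(v)
    data.frame(balanced_accuracy = v, recall = v, precision = v, f1 = v,
               iou = v, undefined = "")))
  expect_equal(mean_metrics(rows)$mean$iou, 0.5)
  folded <- mean_metrics(rows, folds = c("a", "a", "b"))
  expect_equal(folded$mean$iou, mean(c(0.3, 0.9)))
  expect_false(isTRUE(all.equal(folded$mean$iou, 0.5)))
  expect_equal(nrow(folded$fold_means), 2L)
  # identical rows: mean equals the row
  same <- rows[c(1, 1, 1), ]
  expect_equal(mean_metrics(same)$mean$f1, 0.2)
})

test_that("majority voting is a per-pixel count, idempotent and symmetric", {
  set.seed(71)
  masks <- lapply(1:3, function(i) random_mask(10, 8))
  mv <- majority_vote(masks)
  votes <- Reduce(`+`, lapply(masks, unclass))
  expect_identical(unclass(mv), (votes >= 2L) * 1L)
  expect_identical(unclass(majority_vote(masks[c(3, 1, 2)])), unclass(mv))
  expect_identical(unclass(majority_vote(list(mv, mv, mv))), unclass(mv))
  # even count: ties go to background
  two <- majority_vote(list(mp_mask(matrix(1L, 2, 2)),
                            mp_mask(matrix(0L, 2, 2))))
  expect_true(all(two == 0L))
  expect_error(majority_vote(list(random_mask(3, 3), random_mask(2, 2))),
               "shape")
})

test_that("percentage recovery rounds half away from zero", {
  expect_equal(recovery(175, 170), 103L)
  expect_equal(recovery(64, 2), 3200L)
  expect_equal(recovery(11, 8), 138L)   # 137.5 -> 138
  expect_equal(recovery(42, 26), 162L)  # 161.53.. -> 162
  expect_equal(recovery(7, 7), 100L)
  expect_equal(recovery(3 * 17, 17), 300L)
  expect_error(recovery(5, 0), "ground truth")
})

test_that("recovery reports aggregate with a sample SD", {
  rep5 <- recovery_report(c(170, 91, 132, 53, 131), c(175, 100, 135, 65, 132))
  expect_equal(rep5$samples$recovery_pct, c(103L, 110L, 102L, 123L, 101L))
  expect_equal(rep5$mean_pct, 107.8)
  expect_equal(rep5$sd_pct, 9.2)
  same <- recovery_report(c(10, 10), c(10, 10))
  expect_equal(same$sd_pct, 0)
  single <- recovery_report(5, 6)
  expect_true(is.na(single$sd_pct))
})

test_that("estimation tallies partition the samples", {
  gt <- c(5, 5, 5, 10, 10)
  pred <- c(5, 7, 3, 10, 20)
  tal <- estimation_tally(gt, pred)
  expect_equal(tal, c(under = 1L, exact = 2L, over = 2L))
  expect_equal(sum(tal), 5L)
  all_exact <- estimation_tally(1:4, 1:4)
  expect_equal(all_exact, c(under = 0L, exact = 4L, over = 0L))
  set.seed(73)
  g <- sample(1:50, 20, TRUE); p <- sample(1:50, 20, TRUE)
  tal2 <- estimation_tally(g, p)
  expect_equal(unname(tal2), c(sum(p < g), sum(p == g), sum(p > g)))
})
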