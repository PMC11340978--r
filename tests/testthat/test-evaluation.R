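test_that("AUC matches the hand example and edge cases", {
  curve <- roc_and_auc(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 1, 0, 0))
  expect_equal(curve$auc, 8 / 9, tolerance = 1e-12)
  expect_equal(roc_and_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_and_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("labels independent of scores give AUC near one half", {
  set.seed(31)
  s <- runif(1000)
  l <- rbinom(1000, 1, 0.5)
  expect_equal(roc_and_auc(s, l)$auc, 0.5, tolerance = 0.05)
})

test_that("AUC equals the concordant-pair oracle on random instances", {
  set.seed(32)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_and_auc(scores, labels)$auc,
                 auc_by_pairs(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.4)
  expect_equal(roc_and_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
  set.seed(34)
  curve <- roc_and_auc(runif(50), rbinom(50, 1, 0.5))
  expect_equal(curve$points$fpr[1], 0)
  expect_equal(curve$points$tpr[1], 0)
  expect_equal(tail(curve$points$fpr, 1), 1)
  expect_equal(tail(curve$points$tpr, 1), 1)
  expect_true(all(diff(curve$points$fpr) >= 0))
  expect_true(all(diff(curve$points$tpr) >= 0))
})

test_that("vertical averaging interpolates TPR at fixed FPR", {
  set.seed(35)
  curve <- roc_and_auc(runif(30), rbinom(30, 1, 0.5))
  # averaging one curve (or identical copies) returns that curve
  avg1 <- vertical_average(list(curve))
  avg3 <- vertical_average(list(curve, curve, curve))
  expect_equal(avg1$tpr_mean, avg3$tpr_mean)
  expect_true(all(avg3$tpr_sd == 0))
  on_grid <- avg1[avg1$fpr %in% curve$points$fpr, ]
  for (i in seq_len(nrow(on_grid))) {
    expect_equal(on_grid$tpr_mean[i],
                 max(curve$points$tpr[curve$points$fpr == on_grid$fpr[i]]))
  }
  # two synthetic curves: mean of 0.2 and 0.4 at FPR 0.1 is 0.3
  c1 <- structure(list(points = data.frame(threshold = c(Inf, 1, 0),
                                           fpr = c(0, 0.1, 1),
                                           tpr = c(0, 0.2, 1))),
                  class = "roc_curve")
  c2 <- structure(list(points = data.frame(threshold = c(Inf, 1, 0),
                                           fpr = c(0, 0.1, 1),
                                           tpr = c(0, 0.4, 1))),
                  class = "roc_curve")
  avg <- vertical_average(list(c1, c2), fpr_grid = c(0, 0.1, 1))
  expect_equal(avg$tpr_mean[avg$fpr == 0.1], 0.3)
  expect_error(vertical_average(list()), "no curves")
})

test_that("averaged AUC matches the mean of individual AUCs on a dense grid", {
  set.seed(36)
  curves <- lapply(1:5, function(i) {
    n <- 200
    s <- runif(n)
    l <- as.integer(s + rnorm(n, sd = 0.3) > 0.5)
    if (length(unique(l)) < 2) l[1:2] <- c(0L, 1L)
    roc_and_auc(s, l)
  })
  avg <- vertical_average(curves, fpr_grid = seq(0, 1, by = 1e-3))
  expect_equal(attr(avg, "auc_mean"),
               mean(vapply(curves, `[[`, numeric(1), "auc")),
               tolerance = 1e-3)
})

test_that("operating points follow their selection rules", {
  perfect <- roc_and_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  op <- operating_point(perfect, "youden")
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)

  # hand example: exhaustive enumeration over the curve's own points
  curve <- roc_and_auc(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 1, 0, 0))
  op2 <- operating_point(curve, "youden")
  best <- max(curve$points$tpr + 1 - curve$points$fpr)
  expect_equal(op2$sensitivity + op2$specificity, best)

  hs <- operating_point(curve, "high_sensitivity", sensitivity_floor = 0.8)
  ok <- curve$points$tpr >= 0.8
  expect_equal(hs$specificity, max(1 - curve$points$fpr[ok]))
  expect_gte(hs$sensitivity, 0.8)
})

test_that("the Youden point is never dominated by another curve point", {
  set.seed(37)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    s <- runif(n)
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    curve <- roc_and_auc(s, l)
    op <- operating_point(curve, "youden")
    dominated <- any(curve$points$tpr > op$sensitivity &
                     (1 - curve$points$fpr) > op$specificity)
    expect_false(dominated)
  }
})

test_that("per-class metrics match a hand-computed confusion case", {
  # truth:      0 0 1 1 1 2 2 2 2
  # predicted:  0 1 1 1 2 2 2 1 0
  truth <- c(0, 0, 1, 1, 1, 2, 2, 2, 2)
  pred <- c(0, 1, 1, 1, 2, 2, 2, 1, 0)
  m <- per_class_metrics(pred, truth)
  expect_equal(m$support, c(2L, 3L, 4L, 0L))
  expect_equal(m$precision[1], 100 * 1 / 2)   # grade 0: 1 of 2 predictions
  expect_equal(m$recall[1], 100 * 1 / 2)
  expect_equal(m$precision[2], 100 * 2 / 4)
  expect_equal(m$recall[2], 100 * 2 / 3)
  expect_equal(m$f1[2], 100 * 2 * (1 / 2) * (2 / 3) / (1 / 2 + 2 / 3))
  expect_true(m$undefined[4])                 # no grade-3 truth or predictions
  expect_equal(m$f1[4], 0)
})

test_that("perfect and constant predictors hit the expected extremes", {
  truth <- c(0, 1, 1, 2, 3, 3)
  perfect <- per_class_metrics(truth, truth)
  expect_true(all(perfect$precision == 100))
  expect_true(all(perfect$recall == 100))

  all_one <- per_class_metrics(rep(1, 10), c(rep(1, 3), rep(2, 7)))
  expect_equal(all_one$recall[2], 100)
  expect_equal(all_one$precision[2], 100 * 3 / 10)  # prevalence of grade 1
})

test_that("per-class run summaries average metric-wise", {
  runs <- list(per_class_metrics(c(0, 1), c(0, 1)),
               per_class_metrics(c(1, 1), c(0, 1)))
  s <- summarise_per_class(runs)
  expect_equal(s$precision_mean[1], mean(c(100, 0)))
  expect_equal(s$support_mean[2], 1)
})

test_that("post-operative encounters drop from test metrics only", {
  df <- data.frame(encounter_id = c("a", "b", "c"),
                   post_op = c(FALSE, TRUE, FALSE))
  expect_equal(nrow(exclude_post_op(df)), 2L)
  none <- df[df$post_op == FALSE, ]
  expect_identical(exclude_post_op(none), none)
  expect_warning(out <- exclude_post_op(df[df$post_op, ]), "post-operative")
  expect_equal(nrow(out), 0L)
})
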