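# Diagnostic core: confusion metrics, ROC/AUC, cut-points, paired AUC tests,
# precision-recall, joint threshold grids -- all against independent oracles.

roc_of <- function(scores, labels) {
  roc_curve(tibble::tibble(y = labels, x = scores), y, x)
}

test_that("confusion metrics match hand-computed clinical table values", {
  m <- confusion_metrics(tp = 41, fp = 21, tn = 16, fn = 4)
  expect_identical(m$sensitivity_pct, 91)
  expect_identical(m$specificity_pct, 43)
  expect_identical(m$ppv_pct, 66)
  expect_identical(m$npv_pct, 80)
  expect_identical(m$accuracy_pct, 70)
  expect_identical(m$f1_pct, 77)
  expect_equal(m$youden_j, 41 / 45 + 16 / 37 - 1)
  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_true(all(perfect[paste0(c("sensitivity", "specificity", "ppv",
                                   "npv", "accuracy", "f1"), "_pct")] == 100))
  expect_equal(perfect$youden_j, 1)
  # F1 as the rounded harmonic mean of integer-percent sens and PPV
  expect_identical(round_half_away(2 * 84 * 66 / (84 + 66)), 74)
  # undefined ratios are NA, never zero
  none_pred <- confusion_metrics(0, 0, 5, 5)
  expect_true(is.na(none_pred$ppv))
  expect_error(confusion_metrics(-1, 0, 0, 0), class = "vatmets_domain_error")
})

test_that("ROC handles the worked separable and crossed examples", {
  sep <- roc_of(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  expect_equal(sep$youden$cutpoint, 3)
  expect_equal(sep$youden$youden_j, 1)
  crossed <- roc_of(c(1, 3, 2, 4), c(1, 1, 0, 0))
  expect_equal(crossed$auc, 0.25)
  mixed <- roc_of(c(5, 6, 7, 1, 2, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(mixed$youden$cutpoint, 5)
  expect_equal(mixed$youden$youden_j, 1 + 2 / 3 - 1, tolerance = 1e-12)
  expect_error(roc_of(1:4, c(1, 1, 1, 1)), class = "vatmets_domain_error")
})

# independent check of the placement-value AUC used for the variance
placements_check <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
}

test_that("AUC equals the concordant-pair fraction on random instances", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(4:120, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:2, 1)) # coarse rounding forces ties
    r <- roc_of(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(r$auc, mean(placements_check(scores, labels)),
                 tolerance = 1e-12)
  }
})

test_that("Youden and product cut-points match exhaustive scans", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(6:80, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n, 0, 10), 1)
    r <- roc_of(scores, labels)
    oy <- oracle_cutpoint(scores, labels, "youden")
    op <- oracle_cutpoint(scores, labels, "product")
    expect_equal(r$youden$cutpoint, oy$threshold)
    expect_equal(r$youden$youden_j, oy$value, tolerance = 1e-12)
    expect_equal(r$product$cutpoint, op$threshold)
  }
})

test_that("ROC output is invariant to shifting all scores", {
  set.seed(7)
  labels <- sample(0:1, 60, replace = TRUE, prob = c(0.5, 0.5))
  labels[1:2] <- 0:1
  scores <- rnorm(60)
  a <- roc_of(scores, labels)
  b <- roc_of(scores + 100, labels)
  expect_equal(a$auc, b$auc)
  expect_equal(a$ci_low, b$ci_low)
  expect_equal(a$youden$cutpoint + 100, b$youden$cutpoint)
  expect_equal(a$points$sensitivity, b$points$sensitivity)
})

test_that("ROC curves are monotone and AUC agrees with pROC", {
  set.seed(55)
  labels <- c(rep(1, 40), rep(0, 40))
  scores <- rnorm(80, mean = labels)
  r <- roc_of(scores, labels)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$sensitivity) >= 0))
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(r$ci_low, max(0, ci[1]), tolerance = 1e-9)
  expect_equal(r$ci_high, min(1, ci[3]), tolerance = 1e-9)
})

test_that("paired AUC comparison behaves under identity, swap and pROC", {
  set.seed(66)
  labels <- c(rep(1, 25), rep(0, 25))
  a <- rnorm(50, mean = 0.8 * labels)
  b <- 0.5 * a + rnorm(50, mean = 0.3 * labels)
  same <- compare_auc_paired(a, a, labels)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  ab <- compare_auc_paired(a, b, labels)
  ba <- compare_auc_paired(b, a, labels)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$p_value, ba$p_value)
  ref <- pROC::roc.test(
    pROC::roc(labels, a, quiet = TRUE, direction = "<"),
    pROC::roc(labels, b, quiet = TRUE, direction = "<"),
    method = "delong", paired = TRUE
  )
  expect_equal(ab$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(compare_auc_paired(a[1:10], b, labels),
               class = "vatmets_domain_error")
})

test_that("the DeLong p-value tracks a label-permutation oracle at small n", {
  set.seed(77)
  labels <- rep(c(1, 0), each = 6)
  a <- rnorm(12, mean = labels)
  b <- rnorm(12, mean = 0.4 * labels)
  obs <- compare_auc_paired(a, b, labels)
  perm <- replicate(4000, {
    pl <- sample(labels)
    oracle_auc(a, pl) - oracle_auc(b, pl)
  })
  p_perm <- mean(abs(perm) >= abs(obs$delta_auc))
  expect_lt(abs(obs$p_value - p_perm), 0.15)
})

test_that("precision-recall area matches enumeration and its limits", {
  sep <- pr_curve(tibble::tibble(y = c(1, 1, 0, 0), x = c(3, 4, 1, 2)), y, x)
  expect_equal(sep$pr_area, 1)
  crossed <- pr_curve(tibble::tibble(y = c(1, 1, 0, 0), x = c(1, 3, 2, 4)), y, x)
  expect_equal(crossed$pr_area, oracle_pr_area(c(1, 3, 2, 4), c(1, 1, 0, 0)),
               tolerance = 1e-12)
  set.seed(88)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    labels <- c(1, sample(0:1, n - 1, replace = TRUE))
    scores <- round(runif(n, 0, 5), 1)
    got <- pr_curve(tibble::tibble(y = labels, x = scores), y, x)
    expect_equal(got$pr_area, oracle_pr_area(scores, labels),
                 tolerance = 1e-12)
  }
  # random scores, balanced classes: area near the prevalence baseline
  set.seed(99)
  labels <- rep(0:1, each = 1500)
  scores <- rnorm(3000)
  base <- pr_curve(tibble::tibble(y = labels, x = scores), y, x)
  expect_lt(abs(base$pr_area - 0.5), 0.05)
  expect_error(pr_curve(tibble::tibble(y = c(0, 0), x = 1:2), y, x),
               class = "vatmets_domain_error")
})

test_that("the joint threshold grid matches brute force and degenerates", {
  set.seed(111)
  d <- tibble::tibble(
    y = sample(0:1, 40, replace = TRUE),
    x1 = round(rnorm(40, 2 * y), 1),
    x2 = round(rnorm(40, y), 1)
  )
  d$y[1:2] <- 0:1
  gs <- joint_threshold_grid(d, y, x1, x2)
  brute <- oracle_joint_accuracy(d$x1, d$x2, d$y,
                                 sort(unique(d$x1)), sort(unique(d$x2)))
  expect_equal(gs$best$accuracy, brute, tolerance = 1e-12)
  expect_equal(max(gs$accuracy), gs$best$accuracy)
  prev <- mean(d$y)
  # thresholds below all observations: everyone positive
  low <- joint_threshold_grid(d, y, x1, x2, grid1 = min(d$x1) - 1,
                              grid2 = min(d$x2) - 1)
  expect_equal(low$best$accuracy, prev)
  # thresholds above all observations: everyone negative
  high <- joint_threshold_grid(d, y, x1, x2, grid1 = max(d$x1) + 1,
                               grid2 = max(d$x2) + 1)
  expect_equal(high$best$accuracy, 1 - prev)
  # pairing a marker with itself reduces to the single-marker scan
  self <- joint_threshold_grid(d, y, x1, x1)
  single <- vapply(sort(unique(d$x1)), function(t) {
    mean((d$x1 >= t) == (d$y == 1))
  }, numeric(1))
  expect_equal(self$best$accuracy, max(single), tolerance = 1e-12)
  # complete-case exclusion and empty-data error
  d2 <- d
  d2$x1[1:5] <- NA
  gs2 <- joint_threshold_grid(d2, y, x1, x2)
  expect_equal(gs2$n_pos + gs2$n_neg, 35)
  d3 <- d
  d3$x1 <- NA_real_
  expect_error(joint_threshold_grid(d3, y, x1, x2),
               class = "vatmets_missing_error")
})

test_that("grid-search tie-breaking prefers higher F1 then lower thresholds", {
  # constructed so that two pairs share the top accuracy
  d <- tibble::tibble(
    y = c(1, 1, 1, 0, 0, 0),
    x1 = c(3, 4, 5, 1, 2, 5),
    x2 = c(3, 4, 5, 1, 2, 5)
  )
  gs <- joint_threshold_grid(d, y, x1, x2)
  # best accuracy is unique in value but check invariants of the choice
  acc <- gs$accuracy
  top <- which(acc == max(acc), arr.ind = TRUE)
  chosen <- c(gs$best$threshold1, gs$best$threshold2)
  f1_of <- function(i, j) {
    t1 <- gs$grid1[i]; t2 <- gs$grid2[j]
    pred <- d$x1 >= t1 & d$x2 >= t2
    tp <- sum(pred & d$y == 1)
    if (tp == 0) return(0)
    s <- tp / sum(d$y == 1)
    p <- tp / sum(pred)
    2 * s * p / (s + p)
  }
  best_f1 <- max(apply(top, 1, function(ij) f1_of(ij[1], ij[2])))
  expect_equal(f1_of(which(gs$grid1 == chosen[1]), which(gs$grid2 == chosen[2])),
               best_f1, tolerance = 1e-12)
})
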