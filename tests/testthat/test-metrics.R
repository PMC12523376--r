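# Confusion matrices, the metric suite, binomial inference, PR curves.

test_that("confusion matrix counts match a brute-force tally and validate
           labels", {
  set.seed(41)
  k <- 4L
  truth <- sample(k, 10000, replace = TRUE)
  pred <- sample(k, 10000, replace = TRUE)
  cm <- confusion_matrix(truth, pred, letters[1:k])
  for (i in 1:k) for (j in 1:k)
    expect_identical(cm[i, j], sum(truth == i & pred == j))
  expect_identical(sum(cm), 10000L)
  perfect <- confusion_matrix(1:3, 1:3, letters[1:3])
  expect_true(all(perfect == diag(3)))
  expect_error(confusion_matrix(c(1, 5), c(1, 1), letters[1:4]),
               "out of range")
})

test_that("every metric is 100% for perfect predictions and the macro
           identities hold on random matrices", {
  m <- classification_metrics(confusion_matrix(rep(1:2, 5), rep(1:2, 5),
                                               c("pos", "neg")))
  expect_equal(m$accuracy, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$g_mean, 100)
  expect_equal(m$macro_f1, 100)
  set.seed(42)
  for (trial in 1:200) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 20) + 1L, k, k,
                 dimnames = list(letters[1:k], letters[1:k]))
    class(cm) <- c("tnv2_confusion", class(cm))
    m <- classification_metrics(cm)
    # balanced accuracy is macro recall by definition
    expect_equal(m$balanced_accuracy, m$macro_recall, tolerance = 1e-12)
    expect_true(all(unlist(m$per_class[2:4]) >= 0) &&
                  all(unlist(m$per_class[2:4]) <= 100))
    if (k == 2) {
      # AM-GM: the geometric mean never exceeds balanced accuracy
      expect_lte(m$g_mean, m$balanced_accuracy + 1e-12)
    }
  }
})

test_that("binary metrics agree with an independent scalar implementation
           to 1e-10", {
  set.seed(43)
  for (trial in 1:200) {
    cnt <- rpois(4, 50) + 1L
    cm <- confusion_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    m <- classification_metrics(cm)
    r <- ref_metrics_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(m$accuracy, r$accuracy, tolerance = 1e-10)
    expect_equal(m$per_class$precision, r$precision, tolerance = 1e-10)
    expect_equal(m$per_class$recall, r$recall, tolerance = 1e-10)
    expect_equal(m$per_class$f1, r$f1, tolerance = 1e-10)
    expect_equal(m$macro_f1, r$macro_f1, tolerance = 1e-10)
    expect_equal(m$g_mean, r$g_mean, tolerance = 1e-10)
    expect_equal(m$balanced_accuracy, r$balanced_accuracy, tolerance = 1e-10)
  }
})

test_that("a never-predicted class yields precision 0 with a warning", {
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 1, 1, 1), c("a", "b"))
  expect_warning(m <- classification_metrics(cm), "zero predicted")
  expect_equal(m$per_class$precision[2], 0)
})

test_that("binomial tail is exact: closed form at correct = n, pmf
           summation oracle, and the strong-baseline bound", {
  inf <- accuracy_inference(20, 20, 0.85)
  expect_equal(inf$p_value, 0.85^20, tolerance = 1e-12)
  set.seed(44)
  for (trial in 1:20) {
    n <- sample(10:1000, 1)
    correct <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    ref <- sum(dbinom(correct:n, n, p0))
    expect_equal(accuracy_inference(correct, n, p0)$p_value, ref,
                 tolerance = 1e-10)
  }
  expect_lt(accuracy_inference(481, 515, 0.85)$p_value, 0.001)
})

test_that("Wilson interval brackets the point estimate and is inside [0,1]", {
  inf <- accuracy_inference(481, 515, 0.5)
  phat <- 481 / 515
  expect_lt(inf$ci_wilson[1], phat)
  expect_gt(inf$ci_wilson[2], phat)
  expect_true(all(inf$ci_wilson >= 0 & inf$ci_wilson <= 1))
  expect_true(all(inf$ci_normal >= 0 & inf$ci_normal <= 1))
})

test_that("PR curves: separation pins precision at 1, ties collapse to the
           prevalence point, and points match threshold enumeration", {
  probs <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.9))
  pr <- pr_curves(probs, c(1L, 1L, 2L, 2L), c("a", "b"))
  expect_true(all(pr$a$precision == 1))
  expect_true(all(diff(pr$a$recall) >= 0))    # thresholds sweep downwards
  same <- matrix(0.5, 4, 2)
  pr2 <- pr_curves(same, c(1L, 2L, 2L, 2L), c("a", "b"))
  expect_equal(nrow(pr2$a), 1L)
  expect_equal(pr2$a$precision, 0.25)
  expect_equal(pr2$a$recall, 1)
  set.seed(45)
  sc <- runif(200)
  truth <- sample(1:2, 200, replace = TRUE)
  pr3 <- pr_curves(cbind(sc, 1 - sc), truth, c("a", "b"))$a
  for (i in sample(nrow(pr3), 25)) {
    th <- pr3$threshold[i]
    called <- sc >= th
    expect_equal(pr3$precision[i], sum(called & truth == 1) / sum(called))
    expect_equal(pr3$recall[i], sum(called & truth == 1) / sum(truth == 1))
  }
  expect_error(pr_curves(probs, rep(1L, 4)), "two classes")
})
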