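hl_labels <- rep(c("HC", "LHL", "RHL"), c(20, 15, 14))

test_that("stratified fold plans balance classes and fold sizes", {
  plan <- make_folds(hl_labels, 10, seed = 3)
  sizes <- tabulate(plan$assignments, 10)
  expect_identical(sort(sizes), c(4L, rep(5L, 9)))
  # every fold holds at least one HC (20 across 10 folds -> exactly 2)
  per_class <- table(hl_labels, plan$assignments)
  expect_true(all(per_class["HC", ] == 2))
  expect_true(all(per_class["LHL", ] %in% 1:2))
  expect_true(all(per_class["RHL", ] %in% 1:2))
  # determinism and seed sensitivity
  expect_identical(make_folds(hl_labels, 10, seed = 3)$assignments,
                   plan$assignments)
  expect_false(identical(make_folds(hl_labels, 10, seed = 4)$assignments,
                         plan$assignments))
})

test_that("leave-one-out and invalid fold counts behave", {
  y <- rep(c("a", "b"), 4)
  expect_identical(sort(make_folds(y, 8, seed = 1)$assignments), 1:8)
  expect_error(make_folds(y, 9, seed = 1), "exceeds")
  expect_error(make_folds(y, 1, seed = 1), ">= 2")
})

test_that("overall accuracy and per-class metrics follow the definitions", {
  cm <- as_confusion_matrix(rbind(a = c(10, 0, 0), b = c(0, 7, 0),
                                  c = c(0, 0, 3)))
  expect_equal(overall_accuracy(cm), 100)
  m <- class_metrics(cm)
  expect_true(all(unlist(m[, -1]) == 100))
  # two-class identity: sensitivity of one class = specificity of the other
  cm2 <- as_confusion_matrix(rbind(p = c(8, 2), n = c(1, 9)))
  m2 <- class_metrics(cm2)
  expect_equal(m2$sensitivity[1], m2$specificity[2])
  expect_equal(m2$sensitivity[2], m2$specificity[1])
  # overall accuracy equals sum of one-vs-rest true positives over total
  expect_equal(overall_accuracy(cm2), 100 * (8 + 9) / 20)
  expect_error(overall_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("undefined metrics surface as NA, never as 0 or 100", {
  cm <- as_confusion_matrix(rbind(a = c(0, 5), b = c(0, 7)))
  m <- class_metrics(cm, "a")
  expect_true(is.na(m$precision))  # empty predicted column
  expect_equal(m$sensitivity, 0)
})

test_that("the printed reference confusion matrix reproduces its metrics", {
  cm <- reference_confusion()
  expect_equal(sum(cm), 490)
  expect_equal(round(overall_accuracy(cm), 2), 95.10)
  m <- class_metrics(cm)
  m[, -1] <- round(m[, -1], 2)
  expect_equal(m$sensitivity, c(97.00, 94.00, 93.57))
  expect_equal(m$specificity, c(96.55, 97.35, 98.57))
  expect_equal(m$precision,   c(95.10, 94.00, 96.32))
  expect_equal(m$accuracy,    c(96.73, 96.33, 97.14))
})

test_that("repeated k-fold CV conserves counts and is reproducible", {
  cl <- make_clusters(rbind(HC = c(0, 0), LHL = c(4, 0), RHL = c(0, 4)),
                      n_each = 8, seed = 80)
  cv <- cv_dag_svm(cl$x, cl$y, k = 4, runs = 3, cost = 1, seed = 7)
  S <- nrow(cl$x)
  expect_equal(sum(cv$confusion), 3 * S)
  expect_true(all(rowSums(cv$fold_total) == S))
  # row sums of the aggregate matrix equal runs x class size
  expect_equal(unname(rowSums(cv$confusion)),
               3 * as.vector(table(factor(cl$y, levels = rownames(cv$confusion)))))
  # per-run accuracy identity against the stored per-fold records
  expect_equal(cv$per_run_accuracy,
               100 * rowSums(cv$fold_correct) / rowSums(cv$fold_total))
  expect_equal(cv$mean_accuracy, mean(cv$per_run_accuracy))
  # aggregate trace/total equals the mean accuracy when runs cover all samples
  expect_equal(overall_accuracy(cv$confusion), cv$mean_accuracy,
               tolerance = 1e-9)
  cv2 <- cv_dag_svm(cl$x, cl$y, k = 4, runs = 3, cost = 1, seed = 7)
  expect_identical(cv2$confusion, cv$confusion)
})

test_that("trivially separable data scores 100% under leave-one-out", {
  cl <- make_clusters(rbind(A = c(0, 0), B = c(10, 0)), n_each = 6,
                      sd = 0.2, seed = 81)
  cv <- cv_dag_svm(cl$x, cl$y, k = 12, runs = 1, cost = 10, seed = 2)
  expect_equal(cv$mean_accuracy, 100)
})

test_that("a 49-sample 10x10 protocol accumulates 490 validation counts", {
  set.seed(90)
  x <- matrix(rnorm(49 * 4), 49, 4) +
    outer(as.integer(factor(hl_labels)), rep(2, 4))
  cv <- cv_dag_svm(x, hl_labels, k = 10, runs = 10, cost = 0.05, seed = 1)
  expect_equal(sum(cv$confusion), 490)
  expect_identical(dim(cv$fold_correct), c(10L, 10L))
  expect_true(all(sort(unique(as.vector(cv$fold_total))) %in% 4:5))
})

test_that("level sweep reports 3n+1 features per level and sane accuracy", {
  set.seed(91)
  mk <- function(gain) {
    img <- matrix(rnorm(64 * 64), 64)
    img + gain * matrix(rep(sin(seq_len(64) / 2), 64), 64)
  }
  images <- c(replicate(6, mk(0), simplify = FALSE),
              replicate(6, mk(3), simplify = FALSE))
  labels <- rep(c("A", "B"), each = 6)
  tab <- level_sweep(images, labels, levels = 1:2, k = 3, runs = 2,
                     cost = 1, seed = 5)
  expect_identical(tab$n_features, c(4L, 7L))
  expect_identical(tab$level, 1:2)
  expect_true(all(tab$mean_accuracy >= 100 / 3))
  single <- level_sweep(images, labels, levels = 3, k = 3, runs = 1,
                        cost = 1, seed = 5)
  expect_identical(nrow(single), 1L)
})

test_that("training folds missing a class raise an explicit error", {
  x <- matrix(rnorm(12), 6, 2)
  y <- c("a", "a", "a", "a", "a", "b")
  expect_error(cv_dag_svm(x, y, k = 3, runs = 1, seed = 1, stratified = FALSE),
               "lack class")
})
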