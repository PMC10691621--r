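# Splitting, KNN vs brute force, SVM properties, sweep determinism.

test_that("split_lists sizes, determinism and validation", {
  co <- generate_cohort_features(cohort_spec(seed = 1))
  s <- split_lists(co, 0.1, seed = 3)
  expect_equal(nrow(s$test), 67)                 # floor(0.1 * 671)
  expect_equal(nrow(s$train), 671 - 67)
  s2 <- split_lists(co, 0.1, seed = 3)
  expect_identical(s$test$patient_id, s2$test$patient_id)
  expect_identical(s$test$bin_dose, s2$test$bin_dose)
  # 0.9 test size leaves 10% for learning
  s9 <- split_lists(co, 0.9, seed = 1)
  expect_equal(nrow(s9$test), floor(0.9 * 671))
  # patient-level split keeps the 11 sibling lists together
  sp <- split_lists(co, 0.5, seed = 2, level = "patient")
  expect_true(all(table(sp$test$patient_id) == 11))
  expect_length(intersect(sp$test$patient_id, sp$train$patient_id), 0)
  expect_error(split_lists(co, 1.2, seed = 1), "test_size")
  # the global RNG stream is untouched by splitting
  set.seed(42); r1 <- runif(1)
  set.seed(42); invisible(split_lists(co, 0.3, seed = 9)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("knn_classify equals the exhaustive distance-sort oracle", {
  set.seed(23)
  for (rep in 1:5) {
    train_x <- matrix(rnorm(40 * 5), 40)
    train_y <- sample(c(-1, 1), 40, replace = TRUE)
    test_x <- matrix(rnorm(20 * 5), 20)
    for (k in c(1, 3, 5)) {
      got <- knn_classify(train_x, train_y, test_x, k = k)
      expect_equal(got, unname(brute_knn(train_x, train_y, test_x, k)))
    }
  }
  # k = 1 on a training point returns its own label (zero distance)
  expect_equal(knn_classify(matrix(c(0, 0, 5, 5), 2, byrow = TRUE),
                            c(-1, 1), matrix(c(0, 0), 1), k = 1), -1)
  # two well-separated 2-point classes, k = 1: perfect labels
  tr <- matrix(c(0, 0, 0.1, 0, 10, 10, 10.1, 10), 4, byrow = TRUE)
  expect_equal(knn_classify(tr, c(-1, -1, 1, 1),
                            matrix(c(0.05, 0, 10.05, 10), 2, byrow = TRUE),
                            k = 1), c(-1, 1))
  expect_error(knn_classify(tr, c(-1, -1, 1, 1), tr, k = 9), "k exceeds")
})

test_that("svm_rbf separates toy data and satisfies the dual KKT conditions", {
  set.seed(91)
  x <- rbind(matrix(rnorm(60, 0, .5), ncol = 2),
             matrix(rnorm(60, 4, .5), ncol = 2))
  y <- rep(c(-1, 1), each = 30)
  fit <- svm_rbf(x, y, gamma = 0.5, c = 10)
  expect_equal(predict(fit, x), y)              # separable -> perfect
  # KKT: box constraints, and margin conditions at tolerance
  K <- artpredict:::.rbf_kernel(x, x, 0.5)
  smo <- artpredict:::smo_train(K, y, C = 10, eps = 1e-4)
  alpha <- smo$alpha
  expect_true(all(alpha >= -1e-12 & alpha <= 10 + 1e-12))
  expect_lt(abs(sum(alpha * y)), 1e-9)          # equality constraint
  f <- drop(K %*% (alpha * y)) + smo$b
  margins <- y * f
  expect_true(all(margins[alpha < 1e-8] >= 1 - 1e-3))   # non-SVs outside
  free <- alpha > 1e-8 & alpha < 10 - 1e-8
  if (any(free)) expect_true(all(abs(margins[free] - 1) < 1e-3))
  expect_true(all(margins[alpha > 10 - 1e-8] <= 1 + 1e-3))
  # analytic 2-point check: symmetric points, RBF; decision boundary at 0
  x2 <- matrix(c(-1, 0, 1, 0), 2, byrow = TRUE)
  fit2 <- svm_rbf(x2, c(-1, 1), gamma = 0.1, c = 100)
  expect_equal(unname(predict(fit2, matrix(c(-3, 0, 3, 0), 2, byrow = TRUE))),
               c(-1, 1))
  expect_equal(fit2$b, 0, tolerance = 1e-6)     # symmetric -> zero bias
  expect_error(svm_rbf(x, rep(1, 60)), "both classes")
})

test_that("fit_predict scales on the training partition and validates labels", {
  co <- toy_cohort()
  parts <- split_lists(co, 0.3, seed = 1)
  for (kind in c("svm_rbf", "knn")) {
    pred <- fit_predict(classifier_spec(kind), parts$train, parts$test)
    expect_equal(accuracy(pred, parts$test$label), 1)  # well-separated toy
  }
  bad <- parts$train[parts$train$label == 1, ]
  expect_error(fit_predict(classifier_spec("knn"), bad, parts$test),
               "single-class")
})

test_that("accuracy is the fraction of agreeing labels", {
  expect_equal(accuracy(c(1, 1, -1), c(1, 1, -1)), 1)
  expect_equal(accuracy(c(1, 1), c(-1, -1)), 0)
  expect_equal(accuracy(c(rep(1, 9), -1), rep(1, 10)), 0.9)
  expect_error(accuracy(1, c(1, 1)), "length")
})

test_that("sweep_accuracy is reproducible and perfect on separable data", {
  co <- toy_cohort()
  spec <- classifier_spec("knn")
  s1 <- sweep_accuracy(co, spec, sizes = c(0.3, 0.5), seeds = 1:5)
  s2 <- sweep_accuracy(co, spec, sizes = c(0.3, 0.5), seeds = 1:5)
  expect_identical(s1$matrix, s2$matrix)
  expect_true(all(s1$matrix == 1))
  expect_equal(s1$mean, 1)
  expect_equal(s1$cv, 0)
  expect_true(all(s1$matrix >= 0 & s1$matrix <= 1))
})

test_that("list-level splits leak sibling information relative to patient-level", {
  # directional property over 10 generator seeds: duplicated per-patient
  # fields make list-level KNN at least as accurate as patient-level
  spec <- classifier_spec("knn")
  wins <- 0L
  for (s in 1:10) {
    co <- generate_cohort_features(cohort_spec(n_non_art = 15, n_art = 8,
                                               seed = 100 + s))
    a_list <- sweep_accuracy(co, spec, sizes = 0.5, seeds = 1:5)$mean
    a_pat <- sweep_accuracy(co, spec, sizes = 0.5, seeds = 1:5,
                            level = "patient")$mean
    wins <- wins + (a_list >= a_pat)
  }
  expect_gte(wins, 8)
})
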