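# Classification of five-dimensional feature lists: RBF-kernel soft-margin
# SVM (SMO solver in src/smo.cpp) and k-nearest-neighbor majority vote, plus
# the train/test split and the test-size x random-seed accuracy sweep.

FEATURE_COLS <- c("eqif_size", "bin_dose", "ctv_high_per_bmi",
                  "total_mu", "oral_mean_dose")

#' Classifier specification
#'
#' Defaults are the study settings: RBF-kernel SVM with `gamma = 0.05`,
#' `c = 10`; KNN with `k = 5`. `scaling` controls feature standardization:
#' with raw units (MU ~ 640, doses in Gy, sizes 3-20) an RBF with fixed
#' gamma effectively sees only the largest-scale feature, so the default is
#' z-score scaling fit on the training partition; `"none"` reproduces raw
#' Euclidean geometry.
#'
#' @param kind `"svm_rbf"` or `"knn"`.
#' @param gamma RBF kernel width.
#' @param c Soft-margin penalty.
#' @param k Neighbor count (odd recommended).
#' @param scaling `"zscore"` (default) or `"none"`.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "knn"), gamma = 0.05,
                            c = 10, k = 5L, scaling = c("zscore", "none")) {
  kind <- match.arg(kind)
  scaling <- match.arg(scaling)
  stopifnot_scalar_pos(gamma, "gamma")
  stopifnot_scalar_pos(c, "c")
  if (k < 1L) stop("k must be >= 1")
  structure(list(kind = kind, gamma = gamma, c = c, k = as.integer(k),
                 scaling = scaling), class = "classifier_spec")
}

.feature_matrix <- function(cohort) {
  as.matrix(cohort[, FEATURE_COLS, drop = FALSE])
}

# z-score parameters fit on the training matrix; zero-variance columns are
# centered but not scaled.
.fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(center = mu, scale = sd)
}
.apply_scaler <- function(x, s) {
  sweep(sweep(x, 2L, s$center, "-"), 2L, s$scale, "/")
}

.rbf_kernel <- function(x, z, gamma) {
  d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * tcrossprod(x, z)
  exp(-gamma * pmax(d2, 0))
}

#' Fit an RBF-kernel soft-margin SVM
#'
#' Solves the dual problem with sequential minimal optimization (maximal
#' violating pair selection). Training is deterministic.
#'
#' @param x Numeric feature matrix.
#' @param y Labels in \{-1, +1\}.
#' @param gamma RBF width; `c` soft-margin penalty.
#' @param c Penalty parameter.
#' @param eps KKT stopping tolerance.
#' @return An `svm_rbf_fit` with support vectors, dual coefficients and bias.
#' @export
svm_rbf <- function(x, y, gamma = 0.05, c = 10, eps = 1e-3) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  K <- .rbf_kernel(x, x, gamma)
  fit <- smo_train(K, as.numeric(y), C = c, eps = eps)
  sv <- fit$alpha > 1e-8
  structure(list(sv_x = x[sv, , drop = FALSE],
                 sv_coef = (fit$alpha * y)[sv],
                 b = fit$b, gamma = gamma, c = c,
                 iterations = fit$iterations, gap = fit$gap),
            class = "svm_rbf_fit")
}

#' @rdname svm_rbf
#' @param object An `svm_rbf_fit`.
#' @param newdata Matrix of points to classify.
#' @param decision Return the decision values instead of labels.
#' @param ... Unused.
#' @export
predict.svm_rbf_fit <- function(object, newdata, decision = FALSE, ...) {
  K <- .rbf_kernel(as.matrix(newdata), object$sv_x, object$gamma)
  f <- drop(K %*% object$sv_coef) + object$b
  if (decision) f else ifelse(f >= 0, 1, -1)
}

#' K-nearest-neighbor classification
#'
#' Majority label of the `k` Euclidean-nearest training points. Distance
#' ties are broken by training-set order (first occurrence wins), and a tied
#' vote falls back to the nearer class (sum of inverse distances).
#'
#' @param train_x,train_y Training features and -1/+1 labels.
#' @param test_x Points to classify.
#' @param k Neighbor count.
#' @return Predicted -1/+1 labels.
#' @export
knn_classify <- function(train_x, train_y, test_x, k = 5L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  n <- nrow(train_x)
  if (k > n) stop("k exceeds the number of training points")
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  d2 <- pmax(d2, 0)
  apply_row <- function(i) {
    ord <- order(d2[i, ])[seq_len(k)]
    votes <- train_y[ord]
    s <- sum(votes)
    if (s != 0) return(sign(s))
    w <- 1 / (sqrt(d2[i, ord]) + 1e-12)   # tie: nearer class wins
    if (sum(w[votes == 1]) >= sum(w[votes == -1])) 1 else -1
  }
  vapply(seq_len(nrow(test_x)), apply_row, numeric(1))
}

#' Split a cohort table into learning and test partitions
#'
#' List-level splitting draws `floor(test_size * N)` (minimum 1) of the N
#' feature lists uniformly at random without replacement — the protocol under
#' which sibling lists of one patient can straddle the boundary. The
#' `"patient"` level instead assigns whole patients (all 11 lists) to the
#' test side, as a leakage control. Deterministic given `seed`; the caller's
#' RNG state is untouched.
#'
#' @param cohort A `cohort_table`.
#' @param test_size Fraction in (0, 1).
#' @param seed Integer seed.
#' @param level `"list"` (default) or `"patient"`.
#' @return List with `train` and `test` cohort tables.
#' @export
split_lists <- function(cohort, test_size, seed, level = c("list", "patient")) {
  level <- match.arg(level)
  if (test_size <= 0 || test_size >= 1) stop("test_size must be in (0, 1)")
  n <- nrow(cohort)
  idx <- with_seed(seed, {
    if (level == "list") {
      sample.int(n, max(1L, floor(test_size * n)))
    } else {
      ids <- unique(cohort$patient_id)
      take <- sample(ids, max(1L, floor(test_size * length(ids))))
      which(cohort$patient_id %in% take)
    }
  })
  if (length(idx) == 0L || length(idx) == n)
    stop("empty train or test partition")
  list(train = cohort[-idx, , drop = FALSE],
       test = cohort[idx, , drop = FALSE])
}

#' Fit a classifier on the training lists and predict the test lists
#'
#' Applies the spec's scaling (fit on the training partition only), trains
#' the SVM or KNN, and returns predicted -1/+1 labels for the test lists.
#'
#' @param spec A `classifier_spec`.
#' @param train,test `cohort_table` partitions from [split_lists()].
#' @return Predicted labels for `test`.
#' @export
fit_predict <- function(spec, train, test) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (length(unique(train$label)) < 2L)
    stop("single-class training set")
  xtr <- .feature_matrix(train)
  xte <- .feature_matrix(test)
  if (spec$scaling == "zscore") {
    s <- .fit_scaler(xtr)
    xtr <- .apply_scaler(xtr, s)
    xte <- .apply_scaler(xte, s)
  }
  if (spec$kind == "svm_rbf") {
    fit <- svm_rbf(xtr, train$label, gamma = spec$gamma, c = spec$c)
    predict(fit, xte)
  } else {
    knn_classify(xtr, train$label, xte, k = spec$k)
  }
}

#' Classification accuracy
#'
#' @param predicted,actual Label vectors of equal length.
#' @return Fraction of agreeing labels, in `[0, 1]`.
#' @export
accuracy <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  mean(predicted == actual)
}

#' Test-size by random-seed accuracy sweep
#'
#' For every test size and every seed, splits the cohort, trains the
#' classifier on the learning partition and scores the test partition. The
#' summary reports the per-size mean accuracy over seeds, and the overall
#' mean, SD and coefficient of variation over the per-size means (the
#' structure of the published sweep table).
#'
#' @param cohort A `cohort_table`.
#' @param spec A `classifier_spec`.
#' @param sizes Test sizes (default 0.1 to 0.9 by 0.1).
#' @param seeds Split seeds (default 1:100).
#' @param level Split level, see [split_lists()].
#' @return A `sweep_result`: `matrix` (sizes x seeds accuracies),
#'   `per_size_mean`, `mean`, `sd`, `cv`.
#' @export
sweep_accuracy <- function(cohort, spec, sizes = seq(0.1, 0.9, by = 0.1),
                           seeds = 1:100, level = "list") {
  acc <- matrix(NA_real_, length(sizes), length(seeds),
                dimnames = list(format(sizes), NULL))
  for (i in seq_along(sizes)) {
    for (j in seq_along(seeds)) {
      parts <- split_lists(cohort, sizes[i], seeds[j], level = level)
      pred <- fit_predict(spec, parts$train, parts$test)
      acc[i, j] <- accuracy(pred, parts$test$label)
    }
  }
  per_size <- rowMeans(acc)
  structure(list(matrix = acc, sizes = sizes, seeds = seeds,
                 per_size_mean = per_size,
                 mean = mean(per_size), sd = stats::sd(per_size),
                 cv = stats::sd(per_size) / mean(per_size)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Accuracy sweep (", length(x$seeds), " seeds per size)\n", sep = "")
  print(round(x$per_size_mean, 3))
  cat(sprintf("mean %.3f  sd %.3f  cv %.3f\n", x$mean, x$sd, x$cv))
  invisible(x)
}
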