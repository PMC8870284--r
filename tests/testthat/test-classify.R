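# Normalisation, KNN tie rules, confusion-matrix measures, the PUK kernel,
# and cross-validation behaviour on separable and label-permuted data.

sep_features <- function(n_per_class = 20, p = 6, gap = 30, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, gap), n_per_class))
  y <- rep(c("middle_aged", "elderly"), each = n_per_class)
  list(x = x, y = y)
}

test_that("min-max normalisation maps training ranges to [0, 1]", {
  tr <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  nm <- min_max_normalize(tr)
  expect_equal(unname(nm$scaled[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(nm$scaled[, "b"]), c(0, 0, 0))  # constant column
  # test data scaled by training ranges may leave [0, 1], unclipped
  out <- min_max_normalize(tr, cbind(a = c(0, 8), b = c(1, 9)))
  expect_equal(unname(out$scaled[, "a"]), c(-0.5, 1.5))
  expect_error(min_max_normalize(tr[0, , drop = FALSE]), "empty")
})

test_that("KNN votes by Euclidean neighbourhood with stated tie rules", {
  train <- rbind(c(0, 0), c(1, 0), c(10, 10))
  labs <- c("elderly", "elderly", "middle_aged")
  expect_equal(knn_predict(train[1, , drop = FALSE], labs[1], c(5, 5), k = 1)$label,
               "elderly")
  # two of class A nearer than one of class B
  res <- knn_predict(train, labs, c(0.4, 0), k = 3)
  expect_equal(res$label, "elderly")
  expect_equal(res$score, 2 / 3)
  # a training point queried with k = 1 returns its own label
  expect_equal(knn_predict(train, labs, train[3, ], k = 1)$label, "middle_aged")
  # vote tie with even k breaks toward the positive (elderly) class
  train2 <- rbind(c(-1, 0), c(1, 0))
  expect_equal(knn_predict(train2, c("middle_aged", "elderly"), c(0, 0), k = 2)$label,
               "elderly")
  # distance tie broken by training order
  expect_equal(knn_predict(train2, c("middle_aged", "elderly"), c(0, 0), k = 1)$label,
               "middle_aged")
  expect_error(knn_predict(train, labs, c(0, 0), k = 9), "exceeds")
  expect_error(knn_predict(train[0, , drop = FALSE], character(0), c(0, 0)),
               "empty")
})

test_that("confusion measures reproduce the printed formulas", {
  perfect <- score_confusion(tp = 45, tn = 45, fp = 0, fn = 0)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$f_score, 1)
  expect_equal(perfect$precision, 1)

  m <- score_confusion(tp = 40, tn = 35, fp = 10, fn = 5)
  expect_equal(m$accuracy, 100 * 75 / 90, tolerance = 1e-12)
  expect_equal(m$sensitivity, 8 / 9, tolerance = 1e-12)
  expect_equal(m$specificity, 7 / 9, tolerance = 1e-12)
  expect_equal(m$precision, 0.8, tolerance = 1e-12)
  expect_equal(m$f_score, 80 / 95, tolerance = 1e-12)
  # P_b = (45*50 + 45*40) / 90^2 = 0.5 -> kappa = (75/90 - 0.5)/0.5
  expect_equal(m$kappa, 2 / 3, tolerance = 1e-12)

  # all predictions positive on a balanced set: P_a = P_b = 0.5 -> kappa 0
  allpos <- score_confusion(tp = 45, tn = 0, fp = 45, fn = 0)
  expect_equal(allpos$kappa, 0)
  w <- capture_warnings(score_confusion(tp = 0, tn = 90, fp = 0, fn = 0))
  expect_match(w, "undefined", all = TRUE)
  expect_error(score_confusion(tp = 0, tn = 0, fp = 0, fn = 0), "empty")
})

test_that("PUK kernel has unit peak and monotone radial decay", {
  k <- puk_kernel(omega = 1, sigma = 1)
  x <- c(1, 2)
  expect_equal(k(x, x), 1)
  # omega = 1, sigma = 1: K = 1 / (1 + 4 ||x-y||^2) since 2 sqrt(2^1-1) = 2
  expect_equal(k(c(0, 0), c(1, 0)), 1 / 5)
  d <- seq(0, 3, 0.5)
  vals <- vapply(d, function(dd) k(0, dd), 0)
  expect_true(all(diff(vals) < 0))
  expect_error(puk_kernel(omega = 0), "positive")
})

test_that("stratified folds are balanced and CV is deterministic", {
  sf <- sep_features(25, seed = 3)
  rep1 <- cross_validate(sf$x, sf$y, list(classifier = "knn", k = 3),
                         folds = 10, seed = 7)
  rep2 <- cross_validate(sf$x, sf$y, list(classifier = "knn", k = 3),
                         folds = 10, seed = 7)
  expect_identical(rep1$prediction, rep2$prediction)
  expect_identical(rep1$fold, rep2$fold)
  # per-fold class counts differ from perfect balance by at most one
  for (f in 1:10) {
    tab <- table(sf$y[rep1$fold == f])
    expect_lte(max(abs(tab - 2.5)), 0.5)
  }
})

test_that("separable clusters classify perfectly; permuted labels do not", {
  sf <- sep_features(20)
  for (mod in list(list(classifier = "knn", k = 1),
                   list(classifier = "svm"),
                   list(classifier = "rf", ntree = 50))) {
    rep <- cross_validate(sf$x, sf$y, mod, folds = 10, seed = 2)
    expect_equal(rep$accuracy, 100, label = mod$classifier)
    expect_equal(rep$kappa, 1, label = mod$classifier)
    expect_equal(rep$auc, 1, label = mod$classifier)
    # report internal consistency: measures recompute from the confusion
    rec <- score_confusion(rep$confusion)
    for (f in c("accuracy", "sensitivity", "specificity", "kappa",
                "f_score", "precision"))
      expect_equal(rep[[f]], rec[[f]], tolerance = 1e-12)
  }

  set.seed(42)
  yperm <- sample(sf$y)
  accs <- vapply(1:5, function(s)
    cross_validate(sf$x, yperm, list(classifier = "knn", k = 3),
                   folds = 10, seed = s)$accuracy, 0)
  # binomial null around 50% for 40 instances
  expect_gt(mean(accs), 25)
  expect_lt(mean(accs), 75)
})

test_that("cross_validate validates inputs", {
  sf <- sep_features(4)
  expect_error(cross_validate(sf$x, sf$y, folds = 10), "at least 10")
  expect_error(cross_validate(sf$x, rep("old", 8)), "labels")
  expect_error(cross_validate(sf$x[1:4, ], sf$y), "disagree")
})
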