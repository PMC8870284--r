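# Classification of middle-aged-like vs elderly-like feature vectors:
# KNN (Euclidean), SVM with the Pearson VII universal kernel (PUK), and
# random forest, under stratified k-fold cross-validation with per-fold
# min-max normalisation. The elderly group is the positive class throughout.

POSITIVE <- "elderly"
NEGATIVE <- "middle_aged"

#' Min-max normalisation fitted on training data
#'
#' Scales each feature to [0, 1] using the training minima/maxima; constant
#' features map to 0. Data scaled by a fitted range may fall outside [0, 1]
#' (no clipping).
#'
#' @param train numeric matrix (rows = instances) used to fit the ranges.
#' @param apply_to matrix to scale (defaults to \code{train}).
#' @return list with \code{scaled} matrix and the fitted \code{min}/\code{max}
#'   vectors.
#' @export
min_max_normalize <- function(train, apply_to = train) {
  if (!nrow(train)) stop_input("empty training set")
  mins <- apply(train, 2L, min)
  maxs <- apply(train, 2L, max)
  rng <- maxs - mins
  scaled <- sweep(apply_to, 2L, mins, "-")
  pos <- rng > 0
  scaled[, pos] <- sweep(scaled[, pos, drop = FALSE], 2L, rng[pos], "/")
  scaled[, !pos] <- 0
  list(scaled = scaled, min = mins, max = maxs)
}

#' K-nearest-neighbour prediction
#'
#' Majority label among the k training instances nearest in Euclidean
#' distance. Distance ties are broken by training-set order; vote ties
#' (possible for even k) are broken toward the positive class (elderly).
#'
#' @param train numeric matrix of training instances.
#' @param labels factor/character labels for \code{train} rows.
#' @param query numeric matrix (or single vector) of query instances.
#' @param k neighbour count, \code{k <= nrow(train)}.
#' @return list with \code{label} (predicted labels) and \code{score}
#'   (fraction of the k neighbours in the positive class).
#' @export
knn_predict <- function(train, labels, query, k = 3) {
  if (!NROW(train)) stop_input("empty training set")
  if (k > nrow(train)) stop_input("k = ", k, " exceeds training size ", nrow(train))
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  labels <- as.character(labels)
  # squared Euclidean distances, queries x train
  d2 <- outer(rowSums(query^2), rowSums(train^2), "+") -
    2 * tcrossprod(query, train)
  pred <- character(nrow(query)); score <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    nn <- order(d2[i, ])[seq_len(k)]  # order() is stable: ties by train order
    votes_pos <- sum(labels[nn] == POSITIVE)
    score[i] <- votes_pos / k
    pred[i] <- if (votes_pos * 2 >= k) POSITIVE else NEGATIVE
  }
  list(label = pred, score = score)
}

#' Pearson VII universal kernel (PUK)
#'
#' K(x, y) = 1 / (1 + (2 sqrt(2^(1/omega) - 1) ||x - y|| / sigma)^2)^omega.
#' With the defaults omega = 1, sigma = 1 this is a Cauchy-shaped radial
#' kernel. Returned as a \pkg{kernlab} kernel object usable in
#' \code{\link[kernlab]{ksvm}}.
#'
#' @param omega peak-shape (tailing) parameter, > 0.
#' @param sigma half-width parameter, > 0.
#' @return a function of class \code{"kernel"}.
#' @export
puk_kernel <- function(omega = 1, sigma = 1) {
  if (omega <= 0 || sigma <= 0) stop_input("omega and sigma must be positive")
  const <- 2 * sqrt(2^(1 / omega) - 1) / sigma
  k <- function(x, y) {
    1 / (1 + (const * sqrt(sum((x - y)^2)))^2)^omega
  }
  class(k) <- "kernel"
  k
}

# Deterministic stratified fold assignment: within each class, instances are
# shuffled by the seeded RNG and dealt to folds round-robin, so per-fold class
# proportions differ from the global ones by at most one instance.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

# Grouped variant: whole groups (e.g. all epochs of one subject) are assigned
# to a single fold, stratified by the group label, so no instance shares its
# source subject with a training instance.
grouped_stratified_folds <- function(labels, group_ids, folds, seed) {
  gid <- as.character(group_ids)
  first <- !duplicated(gid)
  glab <- labels[first]
  names(glab) <- gid[first]
  if (any(tapply(labels, gid, function(v) length(unique(v))) > 1L))
    stop_input("a grouping unit carries more than one class label")
  gfold <- stratified_folds(glab, folds, seed)
  names(gfold) <- names(glab)
  unname(gfold[gid])
}

#' Performance measures from a confusion matrix
#'
#' Accuracy (percent), sensitivity, specificity, precision and F-score as the
#' usual TP/TN/FP/FN ratios, and Cohen's kappa = (P_a - P_b)/(1 - P_b) with
#' P_a the observed agreement and P_b the chance agreement from the confusion
#' margins. Zero-denominator ratios are NaN with a warning.
#'
#' @param tp,tn,fp,fn confusion counts (elderly = positive class), or a single
#'   list/vector with those names passed as \code{tp}.
#' @return named list: accuracy (percent), sensitivity, specificity,
#'   precision, f_score, kappa, and the counts.
#' @export
score_confusion <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && (is.list(tp) || length(tp) == 4L)) {
    cc <- as.list(tp); tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  }
  total <- tp + tn + fp + fn
  if (total <= 0) stop_input("confusion matrix is empty")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); NaN", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  p_a <- (tp + tn) / total
  p_b <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- if (abs(1 - p_b) < 1e-15) {
    warning("kappa undefined (chance agreement = 1); NaN", call. = FALSE)
    NaN
  } else (p_a - p_b) / (1 - p_b)
  list(accuracy = 100 * p_a,
       sensitivity = ratio(tp, tp + fn, "sensitivity"),
       specificity = ratio(tn, tn + fp, "specificity"),
       precision = ratio(tp, tp + fp, "precision"),
       f_score = ratio(2 * tp, 2 * tp + fp + fn, "F-score"),
       kappa = kappa,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

train_predict <- function(model, train_x, train_y, test_x) {
  cls <- model$classifier
  if (cls == "knn") {
    res <- knn_predict(train_x, train_y, test_x, k = model$k)
    return(res)
  }
  if (cls == "svm") {
    y <- factor(train_y, levels = c(NEGATIVE, POSITIVE))
    kern <- if (identical(model$kernel, "rbf"))
      kernlab::rbfdot(sigma = model$sigma_rbf %||% 1)
    else puk_kernel(model$omega %||% 1, model$sigma %||% 1)
    fit <- kernlab::ksvm(as.matrix(train_x), y, type = "C-svc",
                         kernel = kern, C = model$C %||% 1, scaled = FALSE)
    pred <- as.character(kernlab::predict(fit, as.matrix(test_x)))
    dec <- as.numeric(kernlab::predict(fit, as.matrix(test_x),
                                       type = "decision"))
    # orient decision values so larger = positive class, using the
    # predicted labels (sign convention of ksvm depends on level order)
    if (any(pred == POSITIVE) && any(pred == NEGATIVE)) {
      if (mean(dec[pred == POSITIVE]) < mean(dec[pred == NEGATIVE])) dec <- -dec
    }
    return(list(label = pred, score = dec))
  }
  if (cls == "rf") {
    y <- factor(train_y, levels = c(NEGATIVE, POSITIVE))
    fit <- with_seed(model$tree_seed %||% 1L,
                     randomForest::randomForest(as.matrix(train_x), y,
                                                ntree = model$ntree %||% 100))
    prob <- stats::predict(fit, as.matrix(test_x), type = "prob")[, POSITIVE]
    lab <- ifelse(prob >= 0.5, POSITIVE, NEGATIVE)
    return(list(label = lab, score = as.numeric(prob)))
  }
  stop_input("unknown classifier '", cls, "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified k-fold cross-validated classification
#'
#' Splits instances into stratified folds (deterministically from
#' \code{seed}), fits min-max normalisation inside each training fold, trains
#' the requested classifier, and pools out-of-fold predictions into one
#' confusion matrix scored by \code{\link{score_confusion}} plus AUC from the
#' out-of-fold scores (KNN: positive-vote fraction; SVM: decision value;
#' RF: positive-tree fraction).
#'
#' @param x numeric feature matrix (rows = instances).
#' @param y labels (\code{"middle_aged"} / \code{"elderly"}).
#' @param model list describing the classifier:
#'   \code{list(classifier = "knn", k = 3)},
#'   \code{list(classifier = "svm", omega = 1, sigma = 1, C = 1)} (or
#'   \code{kernel = "rbf"}), or
#'   \code{list(classifier = "rf", ntree = 100)}.
#' @param folds fold count (default 10); every class must have at least
#'   \code{folds} instances so each fold's training split contains both.
#' @param seed integer seed controlling fold assignment (and RF tree growth).
#' @param group_ids optional vector of grouping units (e.g. subject ids when
#'   instances are epochs): all instances of a unit are assigned to the same
#'   fold, preventing within-subject leakage between training and test folds.
#' @return object of class \code{classification_report}: the measures of
#'   \code{\link{score_confusion}}, \code{auc}, \code{confusion}, per-instance
#'   \code{fold}, \code{prediction}, \code{score}, and the resolved
#'   \code{model}, \code{folds}, \code{seed}.
#' @export
cross_validate <- function(x, y, model = list(classifier = "knn", k = 3),
                           folds = 10, seed = 1L, group_ids = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop_input("x and y sizes disagree")
  if (!all(y %in% c(POSITIVE, NEGATIVE)))
    stop_input("labels must be '", NEGATIVE, "' or '", POSITIVE, "'")
  if (min(table(y)) < folds)
    stop_input("need at least ", folds, " instances per class for ", folds,
               "-fold stratified CV")
  model$tree_seed <- derive_seed(seed, "rf_trees")
  fold_of <- if (is.null(group_ids))
    stratified_folds(y, folds, derive_seed(seed, "folds"))
  else grouped_stratified_folds(y, group_ids, folds, derive_seed(seed, "folds"))
  pred <- character(length(y)); score <- numeric(length(y))
  for (f in seq_len(folds)) {
    test <- fold_of == f
    if (length(unique(y[!test])) < 2L)
      stop_input("a class is absent from the training split of fold ", f)
    nm <- min_max_normalize(x[!test, , drop = FALSE])
    test_scaled <- min_max_normalize(x[!test, , drop = FALSE],
                                     x[test, , drop = FALSE])$scaled
    res <- train_predict(model, nm$scaled, y[!test], test_scaled)
    pred[test] <- res$label
    score[test] <- res$score
  }
  conf <- list(tp = sum(pred == POSITIVE & y == POSITIVE),
               tn = sum(pred == NEGATIVE & y == NEGATIVE),
               fp = sum(pred == POSITIVE & y == NEGATIVE),
               fn = sum(pred == NEGATIVE & y == POSITIVE))
  measures <- score_confusion(conf)
  auc <- if (length(unique(score)) > 1L) {
    as.numeric(pROC::auc(pROC::roc(response = factor(y, c(NEGATIVE, POSITIVE)),
                                   predictor = score, direction = "<",
                                   quiet = TRUE)))
  } else if (measures$accuracy == 100) 1 else 0.5
  structure(c(measures, list(auc = auc, confusion = conf, fold = fold_of,
                             prediction = pred, score = score, truth = y,
                             model = model, folds = folds, seed = seed)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s, %d-fold CV (seed %d)\n",
              x$model$classifier, x$folds, x$seed))
  cat(sprintf("  accuracy %.2f%% | sens %.3f | spec %.3f | kappa %.3f | F %.3f | precision %.3f | AUC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$kappa, x$f_score,
              x$precision, x$auc))
  cat(sprintf("  confusion: TP %d  FN %d  FP %d  TN %d (positive = %s)\n",
              x$confusion$tp, x$confusion$fn, x$confusion$fp, x$confusion$tn,
              POSITIVE))
  invisible(x)
}
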