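#' Train a subject identifier on connectivity features
#'
#' Fits a one-against-one multiclass support-vector machine with a radial
#' basis kernel on per-epoch connectivity feature vectors: one binary
#' classifier per subject pair, predictions by majority vote. Features are
#' z-scored per column with parameters learned on the training rows only
#' (constant columns get scale 1, so they contribute nothing after
#' centering); the same scaler is applied at prediction time, so no
#' information leaks from test data.
#'
#' The kernel width defaults to `1 / (n_features * mean feature variance)`
#' of the scaled training matrix. If `cost` has several values, the value is
#' chosen by an internal stratified 3-fold cross-validation on the training
#' rows only.
#'
#' @param features An `fc_features` object (training rows).
#' @param cost SVM regularization constant C (default 1); a vector triggers
#'   the internal grid search.
#' @param gamma RBF kernel width; default as above.
#' @param seed Seed for the internal grid-search folds (the SVM fit itself
#'   is deterministic).
#' @return Object of class `fc_identifier`: the fitted `e1071::svm` model
#'   plus `center`, `scale`, `classes`, `cost`, `gamma`, `kind`.
#' @export
train_identifier <- function(features, cost = 1, gamma = NULL, seed = 1L) {
  x <- features$values
  y <- factor(features$subject_id)
  if (nlevels(y) < 2) stop("need >= 2 subjects to train an identifier")
  if (min(table(y)) < 2) stop("need >= 2 epochs per subject")

  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = center, scale = scl)
  if (is.null(gamma)) {
    v <- mean(apply(xs, 2, stats::var))
    gamma <- 1 / (ncol(xs) * max(v, .Machine$double.eps))
  }
  if (length(cost) > 1) {
    cost <- pick_cost(xs, y, cost, gamma, seed)
  }
  fit <- e1071::svm(x = xs, y = y, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  structure(
    list(svm = fit, center = center, scale = scl,
         classes = levels(y), cost = cost, gamma = gamma,
         kind = features$kind),
    class = "fc_identifier"
  )
}

# choose C by stratified 3-fold CV on the (already scaled) training matrix
pick_cost <- function(xs, y, costs, gamma, seed) {
  fold <- stratified_folds(y, 3L, seed)
  acc <- vapply(costs, function(cc) {
    correct <- 0L
    for (f in 1:3) {
      fit <- e1071::svm(x = xs[fold != f, , drop = FALSE], y = y[fold != f],
                        kernel = "radial", cost = cc, gamma = gamma,
                        scale = FALSE)
      pred <- stats::predict(fit, xs[fold == f, , drop = FALSE])
      correct <- correct + sum(pred == y[fold == f])
    }
    correct / length(y)
  }, numeric(1))
  costs[which.max(acc)]
}

#' @rdname train_identifier
#' @param model A fitted `fc_identifier`.
#' @param newdata An `fc_features` object (or plain feature matrix) to
#'   classify.
#' @return `predict_identifier` returns a factor of predicted subject
#'   labels.
#' @export
predict_identifier <- function(model, newdata) {
  x <- if (inherits(newdata, "fc_features")) newdata$values else newdata
  xs <- scale(x, center = model$center, scale = model$scale)
  stats::predict(model$svm, xs)
}

# subject-stratified fold labels: each subject's epochs are shuffled with
# the given seed and dealt round-robin over folds
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  seeds <- derive_seeds(seed, nlevels(factor(y)))
  lv <- levels(factor(y))
  for (s in seq_along(lv)) {
    idx <- which(y == lv[s])
    idx <- run_seeded(seeds[s], sample(idx))
    fold[idx] <- rep_len(1:k, length(idx))
  }
  fold
}

#' Intra-session identification accuracy by stratified k-fold CV
#'
#' Splits one session's epochs into `k` subject-stratified folds, trains the
#' identifier on k-1 folds and scores the held-out fold, and pools the
#' held-out predictions: accuracy = correct epochs / total epochs. With the
#' default k = 10, 9/10 of the session trains and 1/10 tests in each round.
#' This accuracy measures how subject-specific the connectivity patterns are
#' within a single session.
#'
#' @param features An `fc_features` object from one session.
#' @param k Number of folds (default 10).
#' @param cost,gamma Passed to [train_identifier()].
#' @param seed Seed for fold assignment.
#' @return Pooled accuracy in `[0, 1]`, with attributes `confusion` (table)
#'   and `n` (epoch count).
#' @export
intra_session_cv <- function(features, k = 10L, cost = 1, gamma = NULL,
                             seed = 1L) {
  y <- factor(features$subject_id)
  if (length(unique(features$session_id)) > 1) {
    stop("intra_session_cv expects features from a single session; got ",
         paste(unique(features$session_id), collapse = ","))
  }
  if (min(table(y)) < k) {
    stop("every subject needs >= k = ", k, " epochs in the session")
  }
  fold <- stratified_folds(y, k, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    tr <- features_subset(features, fold != f)
    model <- train_identifier(tr, cost = cost, gamma = gamma, seed = seed)
    pred[fold == f] <- predict_identifier(model, features_subset(features, fold == f))
  }
  acc <- mean(pred == y)
  structure(acc, confusion = table(truth = y, predicted = pred),
            n = length(y))
}

#' Cross-session permanence evaluation
#'
#' Trains one identifier on all epochs of the training session and scores
#' every other session with it, in nominal-day order: the decay of accuracy
#' with the day gap measures how permanent the subject-specific connectivity
#' is. The feature scaler comes from the training session only.
#'
#' @param features Pooled `fc_features` covering the training session and
#'   the test sessions, with the same subject set in every session.
#' @param train_session Label of the training session (default `"A"`).
#' @param sessions Optional [session_specs()] data.frame fixing the session
#'   order (default: order of first appearance in `features`).
#' @param cost,gamma,seed Passed to [train_identifier()].
#' @return Object of class `permanence_result`: `train_session`,
#'   `per_session_accuracy` (named numeric, test sessions in nominal-day
#'   order), `confusion` (list of tables), `index_kind`, `n_subjects`,
#'   `seed`.
#' @export
cross_session_eval <- function(features, train_session = "A",
                               sessions = NULL, cost = 1, gamma = NULL,
                               seed = 1L) {
  sess_ids <- if (is.null(sessions)) unique(features$session_id) else sessions$session_id
  if (!train_session %in% features$session_id) {
    stop("training session ", train_session, " not present in features")
  }
  train <- features_subset(features, features$session_id == train_session)
  test_ids <- setdiff(sess_ids, train_session)
  subj <- sort(unique(train$subject_id))
  for (sid in test_ids) {
    ts <- sort(unique(features$subject_id[features$session_id == sid]))
    if (!identical(ts, subj)) {
      stop("subject set of session ", sid, " differs from training session")
    }
  }
  model <- train_identifier(train, cost = cost, gamma = gamma, seed = seed)
  acc <- numeric(length(test_ids))
  names(acc) <- test_ids
  conf <- vector("list", length(test_ids))
  names(conf) <- test_ids
  for (sid in test_ids) {
    te <- features_subset(features, features$session_id == sid)
    pred <- predict_identifier(model, te)
    truth <- factor(te$subject_id, levels = model$classes)
    acc[sid] <- mean(pred == truth)
    conf[[sid]] <- table(truth = truth, predicted = pred)
  }
  structure(
    list(train_session = train_session, per_session_accuracy = acc,
         confusion = conf, index_kind = features$kind,
         n_subjects = length(subj), seed = as.integer(seed)),
    class = "permanence_result"
  )
}

#' @export
print.permanence_result <- function(x, ...) {
  cat("<permanence_result> ", x$index_kind, ", trained on session ",
      x$train_session, " (", x$n_subjects, " subjects)\n", sep = "")
  print(round(x$per_session_accuracy, 3))
  invisible(x)
}
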