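# Machine-learning re-ranking harness: pluggable estimators behind a uniform
# fit/score contract, repeated stratified k-fold cross-validation, and a grid
# search maximizing the mean of weighted and unweighted AUC.
#
# The estimators themselves are delegated to established libraries (e1071,
# randomForest, glmnet, class); the contribution here is the evaluation
# protocol and the objective.

#' Construct a pluggable estimator
#'
#' Supported names: `"svc"` (support-vector classifier), `"knn"`
#' (k-nearest-neighbor classifier), `"rf_classifier"`, `"svr"`
#' (support-vector regressor), `"ridge"`, `"rf_regressor"`.  Classifiers
#' score by class probability of the stabilizing class, regressors by the
#' predicted melting-temperature change.
#'
#' @param name estimator name.
#' @param params named list of hyperparameters (estimator specific, e.g.
#'   `cost`, `gamma` for SVMs; `k` for knn; `ntree`, `mtry` for forests;
#'   `lambda` for ridge).
#' @return list with `name`, `params`, `task`, `fit(X, y)`,
#'   `score(model, X)`.
#' @export
make_estimator <- function(name = c("svc", "knn", "rf_classifier",
                                    "svr", "ridge", "rf_regressor"),
                           params = list()) {
  name <- match.arg(name)
  p <- function(key, default) params[[key]] %||% default
  est <- switch(name,
    svc = list(task = "classify",
      fit = function(X, y) e1071::svm(X, factor(y, levels = c(FALSE, TRUE)),
                                      probability = TRUE,
                                      cost = p("cost", 1),
                                      gamma = p("gamma", 1 / ncol(X)),
                                      kernel = p("kernel", "radial")),
      score = function(m, X) {
        pr <- attr(stats::predict(m, X, probability = TRUE), "probabilities")
        pr[, "TRUE"]
      }),
    knn = list(task = "classify",
      fit = function(X, y) list(X = X, y = factor(y, levels = c(FALSE, TRUE)),
                                k = p("k", 5)),
      score = function(m, X) {
        pred <- class::knn(m$X, X, m$y, k = m$k, prob = TRUE)
        pr <- attr(pred, "prob")
        ifelse(pred == "TRUE", pr, 1 - pr)
      }),
    rf_classifier = list(task = "classify",
      fit = function(X, y) randomForest::randomForest(
        X, factor(y, levels = c(FALSE, TRUE)),
        ntree = p("ntree", 500), mtry = p("mtry", max(1, floor(sqrt(ncol(X)))))),
      score = function(m, X) stats::predict(m, X, type = "prob")[, "TRUE"]),
    svr = list(task = "regress",
      fit = function(X, y) e1071::svm(X, y, cost = p("cost", 1),
                                      gamma = p("gamma", 1 / ncol(X)),
                                      kernel = p("kernel", "radial")),
      score = function(m, X) as.numeric(stats::predict(m, X))),
    ridge = list(task = "regress",
      fit = function(X, y) glmnet::glmnet(as.matrix(X), y, alpha = 0,
                                          lambda = p("lambda", 1)),
      score = function(m, X) as.numeric(stats::predict(m, as.matrix(X)))),
    rf_regressor = list(task = "regress",
      fit = function(X, y) randomForest::randomForest(
        X, y, ntree = p("ntree", 500),
        mtry = p("mtry", max(1, floor(ncol(X) / 3)))),
      score = function(m, X) as.numeric(stats::predict(m, X))))
  c(list(name = name, params = params), est)
}

#' Repeated stratified k-fold cross-validation of a ranking model
#'
#' Fold assignment is stratified on the class labels (for regression, on the
#' stabilizing/non-stabilizing binning of `y`) and depends only on the
#' labels, the seed, and the fold layout — never on the feature values.  Per
#' repeat, out-of-fold scores are pooled and the (weighted) ROC AUC
#' computed; means across repeats are reported.
#'
#' @param X feature matrix/data.frame (rows = mutations, columns = scaled
#'   metrics; no missing values).
#' @param y labels: logical/0-1 stabilizing class (classification) or dtm in
#'   degrees C (regression).
#' @param estimator from [make_estimator()].
#' @param dtm optional per-mutation dtm for the weighted AUC (regression
#'   defaults to `y`).
#' @param n_splits folds per repeat (default 4).
#' @param n_repeats repeats (default 10).
#' @param seed integer seed.
#' @return list with `auc`, `weighted_auc` (means), `per_repeat`
#'   (data.frame), `estimator`.
#' @export
cross_validate <- function(X, y, estimator, dtm = NULL, n_splits = 4,
                           n_repeats = 10, seed = 1L) {
  X <- as.data.frame(X)
  if (anyNA(X)) stop("feature matrix must not contain missing values")
  if (estimator$task == "regress" && is.null(dtm)) dtm <- y
  strata <- if (estimator$task == "classify") as.logical(y) else y > 0
  is_pos <- strata
  counts <- table(strata)
  if (length(counts) < 2 || any(counts < n_splits))
    stop(sprintf("infeasible stratification: class counts %s for %d splits",
                 paste(counts, collapse = "/"), n_splits))
  set.seed(seed)
  folds <- caret::createMultiFolds(factor(strata), k = n_splits,
                                   times = n_repeats)
  rep_of <- sub("^Fold[0-9]+\\.", "", names(folds))
  per_rep <- lapply(unique(rep_of), function(rp) {
    scores <- rep(NA_real_, nrow(X))
    for (fold in which(rep_of == rp)) {
      train <- folds[[fold]]
      test <- setdiff(seq_len(nrow(X)), train)
      m <- estimator$fit(X[train, , drop = FALSE],
                         if (estimator$task == "classify") strata[train]
                         else y[train])
      scores[test] <- estimator$score(m, X[test, , drop = FALSE])
    }
    rk_plain <- labeled_ranking(seq_along(scores), scores,
                                ifelse(is_pos, 1, -1))
    w <- NA_real_
    if (!is.null(dtm) && !any(is.na(dtm[is_pos]))) {
      rk_w <- labeled_ranking(seq_along(scores), scores,
                              ifelse(is_pos, pmax(dtm, 1e-9), -1))
      w <- weighted_roc(rk_w)$auc
    }
    data.frame(repeat_id = rp, auc = roc(rk_plain)$auc, weighted_auc = w)
  })
  per_rep <- do.call(rbind, per_rep)
  list(auc = mean(per_rep$auc),
       weighted_auc = if (all(is.na(per_rep$weighted_auc))) NA_real_
                      else mean(per_rep$weighted_auc),
       per_repeat = per_rep, estimator = estimator$name)
}

#' Exhaustive hyperparameter grid search
#'
#' Every grid point is evaluated with [cross_validate()]; the objective is
#' the mean of the unweighted and weighted AUC (the unweighted AUC alone
#' when no dtm is available).  Ties keep the first grid entry.
#'
#' @param X,y,dtm,n_splits,n_repeats,seed as in [cross_validate()].
#' @param name estimator name for [make_estimator()].
#' @param grid list of named parameter lists.
#' @return list with `best_params`, `objective`, `results` (data.frame of
#'   every grid point).
#' @export
grid_search <- function(X, y, name, grid, dtm = NULL, n_splits = 4,
                        n_repeats = 10, seed = 1L) {
  if (length(grid) == 0) stop("empty hyperparameter grid")
  rows <- lapply(seq_along(grid), function(i) {
    cv <- cross_validate(X, y, make_estimator(name, grid[[i]]), dtm = dtm,
                         n_splits = n_splits, n_repeats = n_repeats,
                         seed = seed)
    obj <- if (is.na(cv$weighted_auc)) cv$auc
           else (cv$auc + cv$weighted_auc) / 2
    data.frame(grid_index = i, auc = cv$auc, weighted_auc = cv$weighted_auc,
               objective = obj)
  })
  res <- do.call(rbind, rows)
  best <- which.max(res$objective)   # which.max keeps the first maximum
  list(best_params = grid[[best]], objective = res$objective[best],
       results = res)
}
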