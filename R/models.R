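#' Classifier harness
#'
#' Six classifiers are benchmarked: penalized (elastic-net) logistic
#' regression (PR), random forest (RF), extreme gradient boosting (XGBoost),
#' logistic stepwise regression (LSR), k-nearest neighbours (KNN) and an
#' RBF support vector machine (SVM). [tune_and_fit()] selects hyperparameters
#' by stratified cross-validated AUC over a small grid, refits on the full
#' training fold, and returns a fitted model handle; [predict_scores()]
#' yields class-1 probabilities and [extract_importance()] a ranked feature
#' list for the classifiers that expose one (PR, RF, XGBoost, LSR).
#'
#' @name model_bench
NULL

#' All classifier names
#' @return character vector of the six classifiers.
#' @export
classifiers <- function() {
  c("PR", "RF", "XGBoost", "LSR", "KNN", "SVM")
}

# Stratified fold assignment, deterministic under seed
make_folds <- function(outcome, k, seed) {
  set.seed(seed)
  fold <- integer(length(outcome))
  for (cl in unique(outcome)) {
    idx <- which(outcome == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Median-heuristic RBF kernel width on standardized features
median_gamma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 200) seq(1, n, length.out = 200) else seq_len(n)
  d <- stats::dist(x[round(idx), , drop = FALSE])
  med <- stats::median(d)
  if (!is.finite(med) || med <= 0) med <- 1
  1 / (2 * med^2)
}

#' Default hyperparameter grids
#'
#' @param classifier classifier name.
#' @param p number of features.
#' @param fast if `TRUE`, a single sensible point per classifier (no
#'   cross-validation needed), used for large benchmark sweeps.
#' @return data frame, one row per grid point.
#' @export
default_grid <- function(classifier, p, fast = FALSE) {
  switch(classifier,
    PR = if (fast) data.frame(alpha = 1)
         else data.frame(alpha = c(0.5, 1)),
    RF = {
      mtry <- unique(pmax(1, floor(c(sqrt(p), p / 3, p / 10))))
      if (fast) mtry <- mtry[1]
      data.frame(mtry = mtry, num_trees = 500)
    },
    XGBoost = if (fast) data.frame(max_depth = 4, eta = 0.3, nrounds = 60)
              else expand.grid(max_depth = c(2, 4, 6), eta = c(0.05, 0.3),
                               nrounds = 200),
    LSR = data.frame(dummy = 0),
    KNN = data.frame(k = if (fast) 11 else seq(3, 21, by = 2)),
    SVM = if (fast) data.frame(cost = 1, gamma_mult = 1)
          else expand.grid(cost = c(0.25, 1, 4), gamma_mult = c(0.5, 1, 2)),
    stop("unknown classifier: ", classifier, call. = FALSE))
}

# Fit one classifier at fixed hyperparameters on (x, y); returns an opaque
# handle used by score_state. x is already standardized where applicable.
fit_state <- function(classifier, x, y, hp, seed) {
  set.seed(seed)
  switch(classifier,
    PR = if (ncol(x) < 2) {
      # glmnet needs >= 2 columns; a single selected feature gets a plain
      # logistic fit (equivalent to zero penalty)
      structure(list(fit = stats::glm.fit(cbind(1, x), y,
                                          family = stats::binomial())),
                class = "pr_single")
    } else {
      glmnet::glmnet(x, y, family = "binomial", alpha = hp$alpha,
                     standardize = FALSE, nlambda = 50)
    },
    RF = ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        num.trees = hp$num_trees, mtry = hp$mtry,
                        probability = TRUE, importance = "impurity",
                        seed = seed, num.threads = 1),
    XGBoost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = hp$nrounds,
      verbose = 0),
    LSR = {
      df <- data.frame(y = y, x, check.names = FALSE)
      null_fit <- stats::glm(y ~ 1, family = stats::binomial(), data = df)
      full_scope <- stats::as.formula(paste(
        "~", paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
      suppressWarnings(MASS::stepAIC(null_fit, direction = "both",
                                     scope = list(lower = ~1,
                                                  upper = full_scope),
                                     trace = 0))
    },
    KNN = list(x = x, y = y, k = hp$k), # lazy learner: store the fold
    SVM = e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                     cost = hp$cost, gamma = hp$gamma, scale = FALSE),
    stop("unknown classifier: ", classifier, call. = FALSE))
}

# Class-1 scores from a fitted handle on standardized newdata
score_state <- function(classifier, state, newx, hp) {
  switch(classifier,
    PR = if (inherits(state, "pr_single")) {
      as.numeric(stats::plogis(cbind(1, newx) %*% state$fit$coefficients))
    } else {
      s <- utils::tail(state$lambda, 1)
      lam <- if (!is.null(hp$lambda)) hp$lambda else s
      as.numeric(stats::predict(state, newx, s = lam, type = "response"))
    },
    RF = stats::predict(state, data = newx,
                        num.threads = 1)$predictions[, "1"],
    XGBoost = as.numeric(stats::predict(state,
                                        xgboost::xgb.DMatrix(newx))),
    LSR = as.numeric(stats::predict(
      state, newdata = data.frame(newx, check.names = FALSE),
      type = "response")),
    KNN = {
      pred <- class::knn(state$x, newx, factor(state$y, levels = c(0, 1)),
                         k = state$k, prob = TRUE)
      prob <- attr(pred, "prob")
      ifelse(pred == "1", prob, 1 - prob)
    },
    SVM = {
      dv <- attr(stats::predict(state, newx, decision.values = TRUE),
                 "decision.values")
      # orient decision values toward class "1", then squash monotonically;
      # a monotone map leaves AUC unchanged and keeps 0.5 at the margin
      flip <- if (startsWith(colnames(dv)[1], "1")) 1 else -1
      stats::plogis(flip * dv[, 1])
    })
}

#' Tune and fit one classifier
#'
#' Grid search maximizing mean stratified cross-validated AUC, followed by a
#' refit on the full training fold. Features are standardized (training
#' center/scale) for PR, KNN, SVM and LSR. A single-point grid skips the
#' cross-validation. Deterministic under `seed`.
#'
#' LSR refuses feature sets that are too large for stepwise selection
#' (p >= 50 or p >= n/2); in the benchmark it is only run after a feature
#' selection step.
#'
#' @param classifier one of [classifiers()].
#' @param train_features numeric matrix.
#' @param train_outcome 0/1 vector.
#' @param cv_folds stratified CV folds (default 5).
#' @param grid hyperparameter data frame; `NULL` for [default_grid()],
#'   `"fast"` for the single-point fast grid.
#' @param seed integer seed.
#' @return a `radbench_model`.
#' @export
tune_and_fit <- function(classifier, train_features, train_outcome,
                         cv_folds = 5, grid = NULL, seed = 1) {
  stopifnot(classifier %in% classifiers())
  y <- as.integer(train_outcome)
  if (length(unique(y)) < 2) {
    stop("training outcome must contain both classes", call. = FALSE)
  }
  p <- ncol(train_features)
  n <- nrow(train_features)
  if (classifier == "LSR" && (p >= 50 || p >= n / 2)) {
    stop("LSR (stepwise regression) refused with ", p, " features and ", n,
         " samples: stepwise selection on wide feature sets is unstable; ",
         "apply a feature selection step first", call. = FALSE)
  }
  fast <- identical(grid, "fast")
  if (is.null(grid) || fast) grid <- default_grid(classifier, p, fast = fast)
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)

  standardized <- classifier %in% c("PR", "KNN", "SVM", "LSR")
  center <- scale_ <- NULL
  x <- train_features
  if (standardized) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    x <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")
  }
  if (classifier == "SVM") {
    g0 <- median_gamma(x)
    grid$gamma <- g0 * grid$gamma_mult
  }

  if (classifier == "PR" && p < 2) {
    grid <- data.frame(alpha = 1, lambda = 0) # unpenalized single feature
  }
  cv_auc <- rep(NA_real_, nrow(grid))
  best <- 1L
  if ((nrow(grid) > 1 || classifier == "PR") && !(classifier == "PR" && p < 2)) {
    fold <- make_folds(y, cv_folds, derive_seed(seed, "folds"))
    for (g in seq_len(nrow(grid))) {
      hp <- grid[g, , drop = FALSE]
      aucs <- numeric(cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
          stop("single-class CV fold; use fewer folds", call. = FALSE)
        }
        state <- fit_state(classifier, x[tr, , drop = FALSE], y[tr], hp,
                           derive_seed(seed, sprintf("cv/%d/%d", g, f)))
        if (classifier == "PR") {
          # evaluate the whole lambda path on the held-out fold at once
          pr <- stats::predict(state, x[!tr, , drop = FALSE],
                               type = "response")
          path_auc <- apply(pr, 2, roc_auc, labels = y[!tr])
          aucs[f] <- max(path_auc)
          attr(aucs, sprintf("lam%d", f)) <- state$lambda[which.max(path_auc)]
        } else {
          sc <- score_state(classifier, state, x[!tr, , drop = FALSE], hp)
          aucs[f] <- roc_auc(sc, y[!tr])
        }
      }
      cv_auc[g] <- mean(aucs)
      if (classifier == "PR") {
        lam <- vapply(seq_len(cv_folds),
                      function(f) attr(aucs, sprintf("lam%d", f)),
                      numeric(1))
        grid$lambda[g] <- exp(mean(log(lam)))
      }
    }
    best <- order(-cv_auc, seq_len(nrow(grid)))[1]
  }
  hp <- grid[best, , drop = FALSE]
  if (classifier == "PR" && is.null(hp$lambda)) {
    # fast path: pick lambda by a single internal CV on the default grid
    fold <- make_folds(y, cv_folds, derive_seed(seed, "folds"))
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = hp$alpha,
                               foldid = fold, type.measure = "auc",
                               standardize = FALSE)
    hp$lambda <- cvfit$lambda.min
  }
  state <- fit_state(classifier, x, y, hp, derive_seed(seed, "refit"))
  structure(list(classifier = classifier, hyperparameters = hp,
                 fitted_state = state, cv_auc = cv_auc[best],
                 features = colnames(train_features),
                 center = center, scale = scale_, seed = seed),
            class = "radbench_model")
}

#' @exportS3Method base::print
print.radbench_model <- function(x, ...) {
  hp <- paste(sprintf("%s=%s", names(x$hyperparameters),
                      vapply(x$hyperparameters, format, character(1))),
              collapse = ", ")
  cat(sprintf("radbench_model [%s] on %d features (%s)\n", x$classifier,
              length(x$features), hp))
  invisible(x)
}

#' Predict class-1 probabilities
#'
#' @param model a `radbench_model`.
#' @param validation_features matrix containing at least the training
#'   features (matched by name).
#' @return probability vector in [0, 1].
#' @export
predict_scores <- function(model, validation_features) {
  stopifnot(inherits(model, "radbench_model"))
  missing <- setdiff(model$features, colnames(validation_features))
  if (length(missing) > 0) {
    stop("validation data lacks feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- validation_features[, model$features, drop = FALSE]
  if (!is.null(model$center)) {
    x <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  }
  sc <- score_state(model$classifier, model$fitted_state, x,
                    model$hyperparameters)
  pmin(1, pmax(0, as.numeric(sc)))
}

#' Ranked feature importance
#'
#' Available for PR (|standardized coefficient|), RF (impurity importance),
#' XGBoost (gain) and LSR (|z statistic| of retained terms); KNN and SVM do
#' not expose an importance measure and raise an error. Descending order,
#' ties broken by feature order.
#'
#' @param model a `radbench_model`.
#' @return data frame with columns `feature` and `importance`, best first.
#' @export
extract_importance <- function(model) {
  stopifnot(inherits(model, "radbench_model"))
  cl <- model$classifier
  if (!cl %in% c("PR", "RF", "XGBoost", "LSR")) {
    stop(cl, " does not expose a feature importance measure", call. = FALSE)
  }
  imp <- switch(cl,
    PR = if (inherits(model$fitted_state, "pr_single")) {
      stats::setNames(abs(model$fitted_state$fit$coefficients[-1]),
                      model$features)
    } else {
      beta <- stats::coef(model$fitted_state,
                          s = model$hyperparameters$lambda)[-1, 1]
      abs(beta) # features were standardized, so |coef| is standardized
    },
    RF = model$fitted_state$variable.importance,
    XGBoost = if (length(model$features) < 2) {
      stats::setNames(1, model$features) # sole feature carries all the gain
    } else {
      tab <- xgboost::xgb.importance(model = model$fitted_state)
      v <- stats::setNames(rep(0, length(model$features)), model$features)
      v[tab$Feature] <- tab$Gain
      v
    },
    LSR = {
      z <- summary(model$fitted_state)$coefficients
      z <- z[rownames(z) != "(Intercept)", 3]
      names(z) <- gsub("`", "", names(z))
      v <- stats::setNames(rep(0, length(model$features)), model$features)
      v[names(z)] <- abs(z)
      v
    })
  full <- stats::setNames(rep(0, length(model$features)), model$features)
  full[names(imp)] <- imp
  ord <- order(-full, seq_along(full))
  data.frame(feature = names(full)[ord], importance = unname(full[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}
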