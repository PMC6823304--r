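#' Train a cross-validated tachycardia risk model
#'
#' Fits either an L1-regularized (lasso) logistic regression or a random
#' forest to a labeled feature table under k-fold cross-validation. Folds
#' are stratified by class and, by default, grouped by subject so no
#' subject contributes windows to both the training and test side of a
#' fold. Every window receives a pooled out-of-fold risk score in [0, 1]
#' from the one fold model that never saw it. Missing feature values are
#' median-imputed per fold, using training-fold medians only.
#'
#' The lasso penalty is chosen by nested 5-fold cross-validation inside
#' each training fold (`glmnet::cv.glmnet`, `lambda.min`). The forest uses
#' 500 trees, `floor(sqrt(p))` candidate features per split, and no depth
#' cap. All randomness derives from `cfg$rng_seed`, so identical seeds give
#' identical fold assignments, models, and scores.
#'
#' @param features Feature table from [featurize_windows()] (the 42 feature
#'   columns plus, ideally, a `subject` column for fold grouping).
#' @param labels Binary labels: 0/1, logical, or `"case"`/`"control"`.
#' @param algorithm `"random_forest"` or `"lasso_logistic"`.
#' @param cfg A [pipeline_config()] (supplies `n_folds`, `group_folds`,
#'   `rng_seed`).
#' @param fold_id Optional explicit fold assignment (integer vector in
#'   `1:n_folds`, one entry per window); overrides the internal assignment.
#' @return A `risk_model_cv` object: fold models, fold assignment, pooled
#'   out-of-fold `scores`, labels, and the training configuration.
#' @export
crossval_train <- function(features, labels,
                           algorithm = c("random_forest", "lasso_logistic"),
                           cfg = pipeline_config(), fold_id = NULL) {
  algorithm <- match.arg(algorithm)
  y <- normalize_labels_(labels)
  fn <- feature_names()
  missing_cols <- setdiff(fn, names(features))
  if (length(missing_cols))
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(features[, fn])
  k <- cfg$n_folds
  if (min(table(y)) < k)
    stop("need at least n_folds = ", k, " windows per class; ",
         "use fewer folds for this cohort")
  if (is.null(fold_id)) {
    subj <- if (cfg$group_folds && "subject" %in% names(features))
      as.character(features$subject) else as.character(seq_along(y))
    fold_id <- assign_folds_(subj, y, k, cfg$rng_seed)
  }
  stopifnot(length(fold_id) == length(y))
  for (f in seq_len(k)) {
    if (length(unique(y[fold_id != f])) < 2)
      stop("a class is absent from the training split of fold ", f,
           "; use fewer folds")
  }
  scores <- rep(NA_real_, length(y))
  fold_models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    fm <- fit_fold_(x[tr, , drop = FALSE], y[tr], algorithm,
                    derive_seed(cfg$rng_seed, 1000 + f))
    fold_models[[f]] <- fm
    if (any(!tr))
      scores[!tr] <- score_fold_(fm, x[!tr, , drop = FALSE])
  }
  structure(list(algorithm = algorithm, fold_models = fold_models,
                 fold_id = fold_id, scores = scores, labels = y,
                 feature_names = fn, cfg = cfg),
            class = "risk_model_cv")
}

normalize_labels_ <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("case", "control")))
    return(as.integer(labels == "case"))
  }
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)))
  y
}

# Stratified, optionally subject-grouped fold assignment: subjects that own
# at least one case window and control-only subjects are dealt round-robin
# into folds after a seeded shuffle, so class balance holds at subject level.
assign_folds_ <- function(subject, y, k, seed) {
  with_seed(derive_seed(seed, 555), {
    has_case <- tapply(y, subject, max)
    strata <- split(names(has_case), has_case)
    fold_of <- integer(0)
    for (s in strata) {
      s <- sample(s)
      fold_of[s] <- rep_len(sample(seq_len(k)), length(s))
    }
    unname(fold_of[subject])
  })
}

fit_fold_ <- function(x_tr, y_tr, algorithm, seed) {
  medians <- apply(x_tr, 2, stats::median, na.rm = TRUE)
  medians[!is.finite(medians)] <- 0
  x_tr <- impute_(x_tr, medians)
  sds <- apply(x_tr, 2, stats::sd)
  if (algorithm == "lasso_logistic") {
    cnt <- table(factor(y_tr, levels = c(0, 1)))
    k_in <- min(5, floor(min(cnt) / 2))
    if (k_in >= 2) {
      # nested, class-stratified CV chooses the penalty inside the fold
      fit <- with_seed(seed, {
        foldid <- integer(length(y_tr))
        for (cl in c(0, 1)) {
          idx <- sample(which(y_tr == cl))
          foldid[idx] <- rep_len(seq_len(k_in), length(idx))
        }
        glmnet::cv.glmnet(x_tr, y_tr, family = "binomial", alpha = 1,
                          foldid = foldid)
      })
      lambda <- fit$lambda.min
    } else {
      # fold too small to cross-validate the penalty: fit the path and take
      # its midpoint, deterministically
      fit <- glmnet::glmnet(x_tr, y_tr, family = "binomial", alpha = 1)
      lambda <- fit$lambda[ceiling(length(fit$lambda) / 2)]
    }
    list(algorithm = algorithm, fit = fit, lambda = lambda,
         medians = medians, sds = sds)
  } else {
    fit <- ranger::ranger(
      x = as.data.frame(x_tr), y = factor(y_tr, levels = c(0, 1)),
      num.trees = 500, mtry = floor(sqrt(ncol(x_tr))),
      min.node.size = 1,
      probability = TRUE, importance = "impurity",
      seed = seed, num.threads = 1)
    list(algorithm = algorithm, fit = fit, medians = medians, sds = sds)
  }
}

impute_ <- function(x, medians) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- medians[j]
  }
  x
}

score_fold_ <- function(fm, x) {
  x <- impute_(x, fm$medians)
  if (fm$algorithm == "lasso_logistic") {
    as.numeric(stats::predict(fm$fit, newx = x, s = fm$lambda,
                              type = "response"))
  } else {
    stats::predict(fm$fit, data = as.data.frame(x),
                   num.threads = 1)$predictions[, "1"]
  }
}

#' Score new windows with a trained model
#'
#' The risk of a new window is the mean of the k fold models' predicted
#' probabilities (each fold imputing with its own training medians).
#'
#' @param object A `risk_model_cv` from [crossval_train()].
#' @param newdata Feature table or matrix containing the 42 feature columns.
#' @param ... Unused.
#' @return Numeric vector of risk scores in [0, 1].
#' @export
predict.risk_model_cv <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$feature_names])
  storage.mode(x) <- "double"
  sc <- vapply(object$fold_models, score_fold_, numeric(nrow(x)), x = x)
  if (nrow(x) == 1) mean(sc) else rowMeans(sc)
}

#' @method print risk_model_cv
#' @export
print.risk_model_cv <- function(x, ...) {
  cat(sprintf("<risk_model_cv> %s, %d folds, %d windows (%d cases)\n",
              x$algorithm, length(x$fold_models), length(x$labels),
              sum(x$labels)))
  invisible(x)
}

#' Evaluate pooled cross-validated scores
#'
#' Computes the empirical ROC curve of the pooled out-of-fold scores, the
#' area under it by the trapezoidal rule, and the accuracy at the 0.5
#' threshold.
#'
#' @param bundle A `risk_model_cv`, or a numeric vector of scores.
#' @param labels Binary labels; defaults to the bundle's stored labels.
#' @return List with `auc`, `accuracy`, and `roc` (data frame
#'   `threshold`, `fpr`, `tpr`).
#' @export
evaluate <- function(bundle, labels = NULL) {
  if (inherits(bundle, "risk_model_cv")) {
    scores <- bundle$scores
    labels <- labels %||% bundle$labels
  } else scores <- as.numeric(bundle)
  y <- normalize_labels_(labels)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yy <- y[o]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(yy)[keep] / sum(yy))
  fpr <- c(0, cumsum(1 - yy)[keep] / sum(1 - yy))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc,
       accuracy = mean((scores >= 0.5) == (y == 1)),
       roc = data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr))
}

#' Rank features by model importance
#'
#' Random forests are ranked by mean impurity (Gini) importance across the
#' fold models; lasso models by the mean absolute standardized coefficient
#' (|coefficient| times the training-fold feature SD). Ties break
#' alphabetically.
#'
#' @param bundle A `risk_model_cv`.
#' @param top_k Number of features to return (capped at 42).
#' @return Data frame `feature`, `importance`, ordered by decreasing
#'   importance.
#' @export
feature_ranking <- function(bundle, top_k = 15) {
  stopifnot(inherits(bundle, "risk_model_cv"))
  fn <- bundle$feature_names
  imp <- vapply(bundle$fold_models, function(fm) {
    if (fm$algorithm == "random_forest") {
      fm$fit$variable.importance[fn]
    } else {
      beta <- as.numeric(stats::coef(fm$fit, s = fm$lambda))[-1]
      abs(beta) * fm$sds
    }
  }, numeric(length(fn)))
  m <- rowMeans(imp)
  ord <- order(-m, fn)
  utils::head(data.frame(feature = fn[ord], importance = unname(m[ord])),
              min(top_k, length(fn)))
}
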