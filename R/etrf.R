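#' Fit the hybrid probability-feature transformer
#'
#' Stacks class-probability outputs of an extra-trees and a random-forest
#' model, each fitted twice (once per target: the 3-class disorder and the
#' 9-class subclass), into a 24-column hybrid feature set used as input to
#' downstream learners. In `out_of_fold` mode (default) every training row's
#' features come from models fitted with that row's fold held out, so the
#' stacked features carry no leakage; `in_sample` mode uses the full models
#' for training rows as well.
#'
#' @param X_train Encoded numeric feature matrix.
#' @param y_train Labels data.frame (`disorder` 0--2, `subclass` 0--8); every
#'   class of both targets must occur.
#' @param mode `"out_of_fold"` or `"in_sample"`.
#' @param n_folds Folds for out-of-fold construction (>= 2).
#' @param seed Integer seed.
#' @param append_raw Also append the raw feature columns on transform.
#' @param et_spec,rf_spec Base-model specs (default: the registered ETC and
#'   RFC configurations; override to scale tests).
#' @return An `etrf_transformer`.
#' @export
fit_etrf <- function(X_train, y_train, mode = c("out_of_fold", "in_sample"),
                     n_folds = 5L, seed = 0L, append_raw = FALSE,
                     et_spec = learner_spec("ETC"),
                     rf_spec = learner_spec("RFC")) {
  mode <- match.arg(mode)
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  stopifnot(n == nrow(y_train), n_folds >= 2L)

  for (tgt in c("disorder", "subclass")) {
    K <- if (tgt == "disorder") 3L else 9L
    classes <- if (tgt == "disorder") disorder_classes() else subclass_classes()
    missing <- setdiff(0:(K - 1L), unique(y_train[[tgt]]))
    if (length(missing)) {
      stop(sprintf("target class absent from training set: %s '%s'",
                   tgt, classes[missing[1] + 1L]))
    }
  }

  specs <- list(ET = et_spec, RF = rf_spec)
  fit4 <- function(X, y, seed0) {
    list(ET_disorder = fit_learner(specs$ET, X, y$disorder, 3L, seed0 + 1L),
         ET_subclass = fit_learner(specs$ET, X, y$subclass, 9L, seed0 + 2L),
         RF_disorder = fit_learner(specs$RF, X, y$disorder, 3L, seed0 + 3L),
         RF_subclass = fit_learner(specs$RF, X, y$subclass, 9L, seed0 + 4L))
  }
  full <- fit4(X_train, y_train, as.integer(seed))

  fold_of <- NULL
  fold_models <- NULL
  train_features <- NULL
  if (mode == "out_of_fold") {
    fold_of <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
    fold_models <- vector("list", n_folds)
    train_features <- matrix(NA_real_, n, 24L)
    for (f in seq_len(n_folds)) {
      in_fold <- fold_of == f
      # fold models never see the fold's rows; guard against a class
      # vanishing from the complement in tiny data
      ytr <- y_train[!in_fold, , drop = FALSE]
      if (length(unique(ytr$disorder)) < 3L ||
          length(unique(ytr$subclass)) < 9L) {
        stop("a target class is confined to a single fold; ",
             "use fewer folds or more data")
      }
      m <- fit4(X_train[!in_fold, , drop = FALSE], ytr,
                as.integer(seed) + 10L * f)
      fold_models[[f]] <- m
      train_features[in_fold, ] <-
        etrf_predict_blocks(m, X_train[in_fold, , drop = FALSE])
    }
  } else {
    train_features <- etrf_predict_blocks(full, X_train)
  }
  colnames(train_features) <- etrf_block_names()

  structure(list(mode = mode, n_folds = if (mode == "out_of_fold") n_folds,
                 seed = as.integer(seed), append_raw = append_raw,
                 models = full, fold_of = fold_of,
                 fold_models = fold_models,
                 train_features = train_features,
                 n_train = n, feature_names = colnames(X_train)),
            class = "etrf_transformer")
}

etrf_block_names <- function() {
  c(paste0("ET_disorder_", 0:2), paste0("ET_subclass_", 0:8),
    paste0("RF_disorder_", 0:2), paste0("RF_subclass_", 0:8))
}

etrf_predict_blocks <- function(models, X) {
  cbind(predict_proba(models$ET_disorder, X),
        predict_proba(models$ET_subclass, X),
        predict_proba(models$RF_disorder, X),
        predict_proba(models$RF_subclass, X))
}

#' Transform rows into the hybrid probability feature set
#'
#' Test rows always receive full-model probabilities; in out-of-fold mode,
#' training rows (`is_training_set = TRUE`, X must be the fit input) receive
#' the probabilities produced by their held-out-fold models.
#'
#' @param t An `etrf_transformer`.
#' @param X Feature matrix with the same columns as at fit time.
#' @param is_training_set Is `X` the training matrix passed to [fit_etrf()]?
#' @return n x 24 matrix (24 + raw width when `append_raw`), block order
#'   ET-disorder, ET-subclass, RF-disorder, RF-subclass.
#' @export
etrf_transform <- function(t, X, is_training_set = FALSE) {
  stopifnot(inherits(t, "etrf_transformer"))
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !is.null(t$feature_names) &&
      !identical(colnames(X), t$feature_names)) {
    stop("feature-name mismatch with the fitted transformer")
  }
  if (is_training_set) {
    if (nrow(X) != t$n_train) {
      stop("is_training_set = TRUE but row count differs from the fit input")
    }
    H <- t$train_features
  } else {
    H <- etrf_predict_blocks(t$models, X)
    colnames(H) <- etrf_block_names()
  }
  if (isTRUE(t$append_raw)) H <- cbind(H, X)
  H
}

#' Block layout of the hybrid feature set
#'
#' @param t A fitted `etrf_transformer`.
#' @return data.frame of 24 ordered descriptors: `model` (ET/RF), `target`,
#'   `class_index`, `class_name`.
#' @export
describe_blocks <- function(t) {
  stopifnot(inherits(t, "etrf_transformer"))
  blocks <- data.frame(
    model = rep(c("ET", "ET", "RF", "RF"), times = c(3, 9, 3, 9)),
    target = rep(c("disorder", "subclass", "disorder", "subclass"),
                 times = c(3, 9, 3, 9)),
    class_index = c(0:2, 0:8, 0:2, 0:8),
    stringsAsFactors = FALSE
  )
  blocks$class_name <- ifelse(blocks$target == "disorder",
                              disorder_classes()[blocks$class_index + 1L],
                              subclass_classes()[blocks$class_index + 1L])
  blocks
}
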