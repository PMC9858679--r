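# Learner registry: named base learners with their published configurations.
# Tree ensembles use the package's compiled CART implementation; LR is ridge
# logistic regression (glmnet); KNN uses exact neighbour search (FNN).

forest_defaults <- list(
  DTC = list(n_trees = 1L, mtry = NA, max_depth = 300L, bootstrap = FALSE,
             random_splits = FALSE),
  RFC = list(n_trees = 100L, mtry = "sqrt", max_depth = 300L,
             bootstrap = TRUE, random_splits = FALSE),
  ETC = list(n_trees = 300L, mtry = "sqrt", max_depth = 300L,
             bootstrap = FALSE, random_splits = TRUE)
)

#' Registered base learners
#'
#' @return Character vector of registered learner names: decision tree
#'   (`DTC`), random forest (`RFC`), extra trees (`ETC`), l2 logistic
#'   regression (`LR`), and k-nearest neighbours (`KNN`, k = 5, uniform
#'   votes, Euclidean distance).
#' @export
registered_learners <- function() c("LR", "DTC", "RFC", "ETC", "KNN")

#' Describe a base learner
#'
#' @param name One of [registered_learners()].
#' @param ... Configuration overrides (e.g. `n_trees` for the tree
#'   ensembles, `k` for KNN, `lambda` for LR) used mainly to scale tests.
#' @return A `learner_spec` object consumed by [fit_learner()].
#' @export
learner_spec <- function(name, ...) {
  name <- match.arg(name, registered_learners())
  params <- switch(name,
    LR = list(lambda = NULL),
    KNN = list(k = 5L),
    forest_defaults[[name]]
  )
  over <- list(...)
  params[names(over)] <- over
  structure(list(name = name, params = params), class = "learner_spec")
}

resolve_mtry <- function(mtry, p) {
  if (is.na(mtry) || is.null(mtry)) return(as.integer(p))
  if (identical(mtry, "sqrt")) return(max(1L, as.integer(floor(sqrt(p)))))
  as.integer(mtry)
}

#' Fit a registered learner
#'
#' @param spec A [learner_spec()].
#' @param X Numeric feature matrix.
#' @param y Integer class codes in `0:(n_classes - 1)`.
#' @param n_classes Number of classes (codes need not all occur for tree
#'   learners; LR requires every class present).
#' @param seed Integer seed for stochastic learners.
#' @return A fitted model answering [predict_proba()].
#' @export
fit_learner <- function(spec, X, y, n_classes, seed = 0L) {
  stopifnot(inherits(spec, "learner_spec"), nrow(X) == length(y))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (any(y < 0L | y >= n_classes)) stop("class code out of range")
  model <- switch(spec$name,
    DTC = ,
    RFC = ,
    ETC = {
      p <- spec$params
      trees <- cpp_forest_fit(X, y, n_classes,
                              as.integer(p$n_trees),
                              resolve_mtry(p$mtry, ncol(X)),
                              as.integer(p$max_depth), 2L,
                              isTRUE(p$bootstrap),
                              isTRUE(p$random_splits),
                              as.integer(seed))
      list(trees = trees)
    },
    LR = {
      present <- sort(unique(y))
      if (length(present) < n_classes) {
        stop("LR requires every class in the training set; missing code(s): ",
             paste(setdiff(0:(n_classes - 1L), present), collapse = ", "))
      }
      Xg <- if (ncol(X) == 1L) cbind(X, `..pad` = 0) else X
      lambda <- spec$params$lambda
      if (is.null(lambda)) lambda <- max(1 / nrow(X), 1e-4)
      # pathwise warm starts down to the target penalty (a single small
      # lambda can fail to converge in the multinomial solver)
      path <- exp(seq(log(1), log(lambda), length.out = 8L))
      fam <- if (n_classes == 2L) "binomial" else "multinomial"
      fit <- glmnet::glmnet(Xg, factor(y, levels = 0:(n_classes - 1L)),
                            family = fam, alpha = 0, lambda = path,
                            standardize = TRUE)
      list(fit = fit, lambda = lambda, pad = ncol(X) == 1L)
    },
    KNN = list(X = X, y = y, k = as.integer(spec$params$k))
  )
  structure(c(model, list(name = spec$name, n_classes = n_classes,
                          n_features = ncol(X))),
            class = c(paste0("gc_", tolower(spec$name)), "gc_model"))
}

#' Class-probability predictions from a fitted learner
#'
#' @param model A model from [fit_learner()].
#' @param X Feature matrix with the same width as at fit time.
#' @return An n x n_classes matrix of class probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, X) UseMethod("predict_proba")

#' @export
predict_proba.gc_model <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop("feature width mismatch: model expects ", model$n_features,
         ", got ", ncol(X))
  }
  K <- model$n_classes
  out <- switch(model$name,
    DTC = ,
    RFC = ,
    ETC = cpp_forest_predict(model$trees, X, K),
    LR = {
      Xg <- if (isTRUE(model$pad)) cbind(X, `..pad` = 0) else X
      pr <- stats::predict(model$fit, Xg, type = "response",
                           s = model$lambda)
      if (K == 2L) cbind(1 - pr[, 1], pr[, 1]) else pr[, , 1]
    },
    KNN = {
      k <- min(model$k, nrow(model$X))
      nn <- FNN::get.knnx(model$X, X, k = k)$nn.index
      votes <- matrix(0, nrow(X), K)
      for (j in seq_len(k)) {
        lab <- model$y[nn[, j]] + 1L
        votes[cbind(seq_len(nrow(X)), lab)] <-
          votes[cbind(seq_len(nrow(X)), lab)] + 1
      }
      votes / k
    }
  )
  out <- as.matrix(out)
  dimnames(out) <- list(NULL, paste0("class_", 0:(K - 1L)))
  out
}
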