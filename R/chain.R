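# Classifier chain over the 12 binarized classes (3 disorder + 9 subclass):
# member k is a binary classifier trained on the input features plus the true
# indicators of all preceding classes in the chain order, and at inference
# consumes the preceding members' *predicted* indicators.

#' Fit a classifier chain
#'
#' @param X Numeric feature matrix (width d).
#' @param Y n x 12 binary indicator matrix ([labels_to_indicator()] layout:
#'   disorder block columns 1--3, subclass block columns 4--12).
#' @param base_learner_spec A [learner_spec()] used for every member.
#' @param order Permutation of `1:12` giving the chain order over indicator
#'   columns; default disorder classes first, then subclasses.
#' @param seed Integer seed (member k uses `seed + k`).
#' @return A `chain_model` with 12 fitted members; a constant indicator
#'   column yields a constant member with a warning.
#' @export
fit_chain <- function(X, Y, base_learner_spec = learner_spec("DTC"),
                      order = 1:12, seed = 0L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(Y) == 12L,
            all(Y %in% c(0L, 1L)))
  if (!identical(sort(as.integer(order)), 1:12)) {
    stop("order must be a permutation of 1:12")
  }
  order <- as.integer(order)
  members <- vector("list", 12L)
  for (k in seq_len(12L)) {
    feats <- cbind(X, Y[, order[seq_len(k - 1L)], drop = FALSE])
    yk <- Y[, order[k]]
    if (length(unique(yk)) == 1L) {
      warning(sprintf("indicator column %d is constant; using a constant %d",
                      order[k], yk[1]))
      members[[k]] <- list(type = "const", value = as.numeric(yk[1]),
                           input_width = ncol(feats))
    } else {
      m <- fit_learner(base_learner_spec, feats, as.integer(yk), 2L,
                       as.integer(seed) + k)
      members[[k]] <- list(type = "model", model = m,
                           input_width = ncol(feats))
    }
  }
  structure(list(members = members, order = order, d = ncol(X),
                 base_learner = base_learner_spec, seed = as.integer(seed)),
            class = "chain_model")
}

#' Predict with a classifier chain
#'
#' Sequential inference: member k consumes the hard 0/1 predictions of the
#' preceding members (threshold 0.5 on their scores).
#'
#' @param m A `chain_model`.
#' @param X Feature matrix of the training width.
#' @return A `chain_prediction`: `raw_indicator` and `scores` are n x 12 in
#'   the indicator column layout (not chain order).
#' @export
predict_chain <- function(m, X) {
  stopifnot(inherits(m, "chain_model"))
  X <- as.matrix(X)
  if (ncol(X) != m$d) stop("feature width mismatch: expected ", m$d)
  n <- nrow(X)
  raw <- matrix(0L, n, 12L, dimnames = list(NULL, indicator_colnames()))
  scores <- matrix(0, n, 12L, dimnames = list(NULL, indicator_colnames()))
  if (n == 0L) {
    return(structure(list(raw_indicator = raw, scores = scores),
                     class = "chain_prediction"))
  }
  for (k in seq_len(12L)) {
    feats <- cbind(X, raw[, m$order[seq_len(k - 1L)], drop = FALSE])
    mem <- m$members[[k]]
    sc <- if (mem$type == "const") rep(mem$value, n)
          else predict_proba(mem$model, feats)[, 2L]
    j <- m$order[k]
    scores[, j] <- sc
    raw[, j] <- as.integer(sc >= 0.5)
  }
  structure(list(raw_indicator = raw, scores = scores),
            class = "chain_prediction")
}

indicator_colnames <- function() {
  c(paste0("disorder_", 0:2), paste0("subclass_", 0:8))
}

#' Decode a prediction to one class per label block
#'
#' Within each block (disorder columns 1--3, subclass columns 4--12) the
#' decoded class is the argmax of the member scores, ties broken by the
#' lowest class index; an all-zero block therefore decodes to class 0. Raw
#' indicators with zero or multiple positives in a block are always resolved
#' to exactly one class.
#'
#' @param p A `chain_prediction`, or an n x 12 score matrix.
#' @return data.frame with integer `disorder` (0--2) and `subclass` (0--8).
#' @export
decode_labels <- function(p) {
  scores <- if (inherits(p, "chain_prediction")) p$scores else as.matrix(p)
  stopifnot(ncol(scores) == 12L)
  if (nrow(scores) == 0L) {
    return(data.frame(disorder = integer(0), subclass = integer(0)))
  }
  data.frame(
    disorder = max.col(scores[, 1:3, drop = FALSE],
                       ties.method = "first") - 1L,
    subclass = max.col(scores[, 4:12, drop = FALSE],
                       ties.method = "first") - 1L
  )
}

#' Fit independent per-label baseline models
#'
#' Control condition for chain-benefit comparisons: one multiclass learner
#' per label variable, no conditioning between labels.
#'
#' @param X Feature matrix.
#' @param y Labels data.frame (`disorder`, `subclass`).
#' @param base_learner_spec A [learner_spec()].
#' @param seed Integer seed.
#' @return An `independent_model` with two members.
#' @export
fit_independent <- function(X, y, base_learner_spec = learner_spec("DTC"),
                            seed = 0L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(y))
  structure(list(
    disorder = fit_learner(base_learner_spec, X, y$disorder, 3L,
                           as.integer(seed) + 1L),
    subclass = fit_learner(base_learner_spec, X, y$subclass, 9L,
                           as.integer(seed) + 2L),
    d = ncol(X)
  ), class = "independent_model")
}

#' Predict with the independent baseline
#'
#' @param m An `independent_model`.
#' @param X Feature matrix.
#' @return A `chain_prediction` (scores = class probabilities per block, raw
#'   indicator = one-hot of the per-block argmax) so [decode_labels()]
#'   applies unchanged.
#' @export
predict_independent <- function(m, X) {
  stopifnot(inherits(m, "independent_model"))
  X <- as.matrix(X)
  if (ncol(X) != m$d) stop("feature width mismatch: expected ", m$d)
  scores <- cbind(predict_proba(m$disorder, X), predict_proba(m$subclass, X))
  colnames(scores) <- indicator_colnames()
  lab <- decode_labels(scores)
  structure(list(raw_indicator = labels_to_indicator(lab), scores = scores),
            class = "chain_prediction")
}

#' Two-stage categorical chain variant
#'
#' Alternative chain granularity over the two label variables instead of the
#' 12 binarized classes: a 3-class disorder learner on the input features,
#' then a 9-class subclass learner on the features plus the disorder's
#' one-hot (true labels at training time, predictions at inference).
#'
#' @inheritParams fit_independent
#' @return A `categorical_chain_model`.
#' @export
fit_categorical_chain <- function(X, y,
                                  base_learner_spec = learner_spec("DTC"),
                                  seed = 0L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(y))
  dis_ind <- labels_to_indicator(y)[, 1:3, drop = FALSE]
  structure(list(
    disorder = fit_learner(base_learner_spec, X, y$disorder, 3L,
                           as.integer(seed) + 1L),
    subclass = fit_learner(base_learner_spec, cbind(X, dis_ind), y$subclass,
                           9L, as.integer(seed) + 2L),
    d = ncol(X)
  ), class = "categorical_chain_model")
}

#' @rdname fit_categorical_chain
#' @param m A fitted `categorical_chain_model`.
#' @export
predict_categorical_chain <- function(m, X) {
  stopifnot(inherits(m, "categorical_chain_model"))
  X <- as.matrix(X)
  if (ncol(X) != m$d) stop("feature width mismatch: expected ", m$d)
  pd <- predict_proba(m$disorder, X)
  hard <- matrix(0L, nrow(X), 3L)
  if (nrow(X)) hard[cbind(seq_len(nrow(X)),
                          max.col(pd, ties.method = "first"))] <- 1L
  ps <- predict_proba(m$subclass, cbind(X, hard))
  scores <- cbind(pd, ps)
  colnames(scores) <- indicator_colnames()
  lab <- decode_labels(scores)
  structure(list(raw_indicator = labels_to_indicator(lab), scores = scores),
            class = "chain_prediction")
}

#' Disorder-to-subclass consistency rate of predicted label pairs
#'
#' Fraction of rows whose predicted subclass belongs to the predicted
#' disorder's group under a hierarchy map.
#'
#' @param labels data.frame (`disorder`, `subclass`) of predictions.
#' @param hierarchy A hierarchy map as from [default_hierarchy()].
#' @return Real in `[0, 1]` (NaN for zero rows).
#' @export
hierarchy_consistency <- function(labels, hierarchy = default_hierarchy()) {
  group_of <- subclass_group_codes(hierarchy)
  mean(group_of[labels$subclass + 1L] == labels$disorder)
}
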