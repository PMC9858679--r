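# Jaccard-family multi-label metrics over binary indicator matrices, plus
# the per-label multiclass report (accuracy, macro precision/recall/F1).

check_pair <- function(Y_true, Y_pred) {
  Y_true <- as.matrix(Y_true)
  Y_pred <- as.matrix(Y_pred)
  if (!identical(dim(Y_true), dim(Y_pred))) stop("shape mismatch")
  if (nrow(Y_true) < 1L) stop("need at least one row")
  if (!all(Y_true %in% c(0, 1)) || !all(Y_pred %in% c(0, 1))) {
    stop("indicator entries must be 0/1")
  }
  list(t = Y_true, p = Y_pred)
}

#' Hamming loss
#'
#' Fraction of wrong label-column decisions:
#' `(1/(nL)) * sum_i sum_j [y_ij != yhat_ij]`.
#'
#' @param Y_true,Y_pred n x L binary indicator matrices.
#' @return Real in `[0, 1]`.
#' @export
hamming_loss <- function(Y_true, Y_pred) {
  z <- check_pair(Y_true, Y_pred)
  mean(z$t != z$p)
}

#' Example-based Jaccard accuracy
#'
#' Mean over rows of `|y AND yhat| / |y OR yhat|`; a row with an empty union
#' scores 1 (perfectly predicted empty label set).
#'
#' @inheritParams hamming_loss
#' @return Real in `[0, 1]`.
#' @export
jaccard_row_accuracy <- function(Y_true, Y_pred) {
  z <- check_pair(Y_true, Y_pred)
  inter <- rowSums(z$t * z$p)
  uni <- rowSums(pmax(z$t, z$p))
  mean(ifelse(uni == 0, 1, inter / uni))
}

#' Label-based macro accuracy
#'
#' Per-column binary accuracy averaged over the L label columns.
#'
#' @inheritParams hamming_loss
#' @return Real in `[0, 1]`.
#' @export
label_macro_accuracy <- function(Y_true, Y_pred) {
  z <- check_pair(Y_true, Y_pred)
  mean(colMeans(z$t == z$p))
}

#' Configuration for the alpha-evaluation score
#'
#' @param alpha Strictness exponent, `alpha >= 0`.
#' @param beta,gamma Penalty weights in `[0, 1]` for missed true labels
#'   (false negatives) and false alarms (false positives).
#' @return An `alpha_score_config`.
#' @export
alpha_score_config <- function(alpha = 1, beta = 1, gamma = 1) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (beta < 0 || beta > 1 || gamma < 0 || gamma > 1) {
    stop("beta and gamma must lie in [0, 1]")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "alpha_score_config")
}

#' Alpha-evaluation score (generalized Jaccard similarity)
#'
#' Mean over rows of `(1 - (beta*|FN| + gamma*|FP|) / |union|)^alpha`, the
#' base clipped at 0 before exponentiation; rows with an empty union score 1.
#' With `alpha = beta = gamma = 1` this equals [jaccard_row_accuracy()].
#'
#' @inheritParams hamming_loss
#' @param config An [alpha_score_config()].
#' @return Real in `[0, 1]`.
#' @export
alpha_evaluation_score <- function(Y_true, Y_pred,
                                   config = alpha_score_config()) {
  stopifnot(inherits(config, "alpha_score_config"))
  z <- check_pair(Y_true, Y_pred)
  fn <- rowSums(z$t * (1 - z$p))
  fp <- rowSums((1 - z$t) * z$p)
  uni <- rowSums(pmax(z$t, z$p))
  base <- ifelse(uni == 0, 1,
                 pmax(0, 1 - (config$beta * fn + config$gamma * fp) / uni))
  mean(base ^ config$alpha)
}

#' Per-label multiclass report
#'
#' For each label variable: multiclass accuracy and one-vs-rest precision,
#' recall and F1 per class, averaged over classes (`macro`, default; `micro`
#' and support-`weighted` variants available). Zero-division cells score 0
#' with a warning.
#'
#' @param y_true,y_pred Labels data.frames (`disorder`, `subclass`) of equal
#'   length.
#' @param average One of `"macro"`, `"micro"`, `"weighted"`.
#' @return data.frame with one row per label variable and columns `label`,
#'   `accuracy`, `precision`, `recall`, `f1`.
#' @export
per_label_report <- function(y_true, y_pred, average = "macro") {
  average <- match.arg(average, c("macro", "micro", "weighted"))
  stopifnot(nrow(y_true) == nrow(y_pred), nrow(y_true) >= 1L)
  one <- function(truth, pred, K) {
    tp <- fp <- fn <- numeric(K)
    for (k in 0:(K - 1L)) {
      tp[k + 1] <- sum(truth == k & pred == k)
      fp[k + 1] <- sum(truth != k & pred == k)
      fn[k + 1] <- sum(truth == k & pred != k)
    }
    div0 <- function(num, den, what) {
      out <- ifelse(den == 0, 0, num / den)
      if (any(den == 0)) {
        warning("zero-division in ", what, " scored 0 for class(es) ",
                paste(which(den == 0) - 1L, collapse = ", "))
      }
      out
    }
    if (average == "micro") {
      prec <- if (sum(tp + fp) == 0) 0 else sum(tp) / sum(tp + fp)
      rec <- if (sum(tp + fn) == 0) 0 else sum(tp) / sum(tp + fn)
      f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    } else {
      p_k <- div0(tp, tp + fp, "precision")
      r_k <- div0(tp, tp + fn, "recall")
      f_k <- ifelse(p_k + r_k == 0, 0, 2 * p_k * r_k / (p_k + r_k))
      w <- if (average == "weighted") {
        supp <- tp + fn
        if (sum(supp) == 0) rep(1 / K, K) else supp / sum(supp)
      } else rep(1 / K, K)
      prec <- sum(w * p_k)
      rec <- sum(w * r_k)
      f1 <- sum(w * f_k)
    }
    c(accuracy = mean(truth == pred), precision = prec, recall = rec,
      f1 = f1)
  }
  rbind(
    data.frame(label = "disorder",
               t(one(y_true$disorder, y_pred$disorder, 3L))),
    data.frame(label = "subclass",
               t(one(y_true$subclass, y_pred$subclass, 9L)))
  )
}

#' Assemble a full evaluation report for one experiment arm
#'
#' Bundles the per-label multiclass metrics with the multi-label metrics
#' (example-based and label-based macro accuracy, Hamming loss,
#' alpha-evaluation score) computed on the 12-column indicator form.
#'
#' @param y_true,y_pred Labels data.frames on the same test partition.
#' @param arm Optional named list of arm descriptors (model, split, feature
#'   mode, balance mode) merged into the record.
#' @param alpha_config An [alpha_score_config()].
#' @param training_time_seconds Informational only.
#' @return A one-row data.frame (`evaluation_report`), serializable to CSV
#'   and JSON.
#' @export
assemble_report <- function(y_true, y_pred, arm = list(),
                            alpha_config = alpha_score_config(),
                            training_time_seconds = NA_real_) {
  Yt <- labels_to_indicator(y_true)
  Yp <- labels_to_indicator(y_pred)
  per <- per_label_report(y_true, y_pred)
  rec <- c(
    as.list(arm),
    list(
      disorder_accuracy = per$accuracy[1], disorder_precision = per$precision[1],
      disorder_recall = per$recall[1], disorder_f1 = per$f1[1],
      subclass_accuracy = per$accuracy[2], subclass_precision = per$precision[2],
      subclass_recall = per$recall[2], subclass_f1 = per$f1[2],
      macro_accuracy_label_based = label_macro_accuracy(Yt, Yp),
      macro_accuracy_example_based = jaccard_row_accuracy(Yt, Yp),
      hamming_loss = hamming_loss(Yt, Yp),
      alpha_score = alpha_evaluation_score(Yt, Yp, alpha_config),
      training_time_seconds = training_time_seconds
    )
  )
  out <- as.data.frame(rec, stringsAsFactors = FALSE)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Render reports in the percentage table layout
#'
#' Rates are shown as whole-number percentages (Hamming loss kept to two
#' decimals), one arm per row.
#'
#' @param reports An `evaluation_report` data.frame (one or more rows).
#' @return data.frame of formatted strings.
#' @export
format_report_table <- function(reports) {
  pct <- function(x) sprintf("%.0f", 100 * x)
  keep <- intersect(c("model", "split", "feature_mode", "balance_mode"),
                    names(reports))
  data.frame(
    reports[, keep, drop = FALSE],
    `Accuracy L1 (%)` = pct(reports$disorder_accuracy),
    `F1 L1 (%)` = pct(reports$disorder_f1),
    `Accuracy L2 (%)` = pct(reports$subclass_accuracy),
    `F1 L2 (%)` = pct(reports$subclass_f1),
    `Macro Accuracy (%)` = pct(reports$macro_accuracy_label_based),
    `Hamming Loss` = sprintf("%.2f", reports$hamming_loss),
    `Alpha Score (%)` = pct(reports$alpha_score),
    check.names = FALSE
  )
}
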