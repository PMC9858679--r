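# Independent brute-force oracles (set/count arithmetic, explicit loops) for
# the multi-label metrics, plus small fixture builders. These deliberately
# avoid the package's vectorized code paths.

oracle_hamming <- function(Yt, Yp) {
  bad <- 0L
  for (i in seq_len(nrow(Yt)))
    for (j in seq_len(ncol(Yt)))
      if (Yt[i, j] != Yp[i, j]) bad <- bad + 1L
  bad / (nrow(Yt) * ncol(Yt))
}

oracle_jaccard <- function(Yt, Yp) {
  vals <- numeric(nrow(Yt))
  for (i in seq_len(nrow(Yt))) {
    T_ <- which(Yt[i, ] == 1)
    P_ <- which(Yp[i, ] == 1)
    u <- union(T_, P_)
    vals[i] <- if (!length(u)) 1 else length(intersect(T_, P_)) / length(u)
  }
  mean(vals)
}

oracle_label_macro <- function(Yt, Yp) {
  accs <- numeric(ncol(Yt))
  for (j in seq_len(ncol(Yt))) {
    ok <- 0L
    for (i in seq_len(nrow(Yt))) if (Yt[i, j] == Yp[i, j]) ok <- ok + 1L
    accs[j] <- ok / nrow(Yt)
  }
  mean(accs)
}

oracle_alpha <- function(Yt, Yp, alpha = 1, beta = 1, gamma = 1) {
  vals <- numeric(nrow(Yt))
  for (i in seq_len(nrow(Yt))) {
    T_ <- which(Yt[i, ] == 1)
    P_ <- which(Yp[i, ] == 1)
    u <- union(T_, P_)
    if (!length(u)) {
      vals[i] <- 1
    } else {
      miss <- length(setdiff(T_, P_))   # FN
      false <- length(setdiff(P_, T_))  # FP
      vals[i] <- max(0, 1 - (beta * miss + gamma * false) / length(u))^alpha
    }
  }
  mean(vals)
}

# one-vs-rest confusion counts for a multiclass label
oracle_class_prf <- function(truth, pred, k) {
  tp <- sum(truth == k & pred == k)
  fp <- sum(truth != k & pred == k)
  fn <- sum(truth == k & pred != k)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

oracle_macro_prf <- function(truth, pred, K) {
  m <- t(vapply(0:(K - 1L), function(k) oracle_class_prf(truth, pred, k),
                c(precision = 0, recall = 0, f1 = 0)))
  colMeans(m)
}

rand_pair <- function(n, L = 12L, p = 0.3) {
  list(t = matrix(rbinom(n * L, 1, p), n, L),
       p = matrix(rbinom(n * L, 1, p), n, L))
}

# generated fixture table; separable by default so pipelines recover exactly
fixture_table <- function(n = 50, scenario = "separable", seed = 42, ...) {
  generate_patients(synthetic_config(n, scenario = scenario, seed = seed,
                                     ...))$table
}

# drop -> encode -> targets for a table, aligned on labelled rows
encode_pipeline <- function(tab) {
  tab <- suppressWarnings(drop_noncontributing(tab))
  X <- encode_features(tab)
  enc <- encode_targets(tab)
  list(X = X[enc$kept, , drop = FALSE], y = enc$labels,
       n_excluded = enc$n_excluded)
}

fast_et <- function(n_trees = 50L) learner_spec("ETC", n_trees = n_trees)
fast_rf <- function(n_trees = 30L) learner_spec("RFC", n_trees = n_trees)
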