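test_that("hamming loss: identity, complement, and counted mismatches", {
  Yt <- matrix(c(1, 0, 1,
                 0, 1, 0), 2, 3, byrow = TRUE)
  expect_equal(hamming_loss(Yt, Yt), 0)
  expect_equal(hamming_loss(Yt, 1 - Yt), 1)
  Yp <- matrix(c(1, 1, 1,
                 0, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(hamming_loss(Yt, Yp), 2 / 6)
  expect_error(hamming_loss(Yt, Yp[, 1:2]), "shape")
})

test_that("row-Jaccard accuracy follows set arithmetic with the empty-union
           convention", {
  expect_equal(jaccard_row_accuracy(matrix(c(1, 0, 1), 1),
                                    matrix(c(1, 1, 1), 1)), 2 / 3)
  expect_equal(jaccard_row_accuracy(matrix(0, 1, 3), matrix(0, 1, 3)), 1)
  Y <- matrix(rbinom(40, 1, 0.4), 8, 5)
  expect_equal(jaccard_row_accuracy(Y, Y), 1)
})

test_that("label macro accuracy averages per-column accuracies", {
  Yt <- matrix(1, 5, 4)
  Yp <- Yt
  Yp[, 2] <- 0 # one fully wrong column of four
  expect_equal(label_macro_accuracy(Yt, Yp), 0.75)
  set.seed(8)
  pr <- rand_pair(6, 12)
  expect_equal(label_macro_accuracy(pr$t, pr$p),
               oracle_label_macro(pr$t, pr$p))
})

test_that("alpha-evaluation score matches its closed form and constraints", {
  # perfect prediction -> 1 under any valid config
  Y <- matrix(rbinom(36, 1, 0.5), 3, 12)
  expect_equal(alpha_evaluation_score(Y, Y, alpha_score_config(3, 0.4, 0.9)),
               1)
  # disjoint non-empty sets at alpha=1, beta=gamma=1 -> 0
  expect_equal(alpha_evaluation_score(matrix(c(1, 0), 1),
                                      matrix(c(0, 1), 1)), 0)
  # hand-evaluated single row: Y={1,2}, P={1,3} of L=4
  Yt <- matrix(c(1, 1, 0, 0), 1)
  Yp <- matrix(c(1, 0, 1, 0), 1)
  expect_equal(alpha_evaluation_score(Yt, Yp), 1 / 3)
  expect_equal(alpha_evaluation_score(Yt, Yp, alpha_score_config(alpha = 2)),
               1 / 9)
  # config constraint set
  expect_error(alpha_score_config(alpha = -1), "alpha")
  expect_error(alpha_score_config(beta = 1.5), "beta")
})

test_that("metrics agree with brute-force oracles on random pairs", {
  set.seed(123)
  for (rep in 1:200) {
    pr <- rand_pair(sample(1:20, 1))
    expect_equal(hamming_loss(pr$t, pr$p), oracle_hamming(pr$t, pr$p),
                 tolerance = 1e-12)
    expect_equal(jaccard_row_accuracy(pr$t, pr$p),
                 oracle_jaccard(pr$t, pr$p), tolerance = 1e-12)
    expect_equal(label_macro_accuracy(pr$t, pr$p),
                 oracle_label_macro(pr$t, pr$p), tolerance = 1e-12)
    cfg <- alpha_score_config(runif(1, 0, 4), runif(1), runif(1))
    expect_equal(alpha_evaluation_score(pr$t, pr$p, cfg),
                 oracle_alpha(pr$t, pr$p, cfg$alpha, cfg$beta, cfg$gamma),
                 tolerance = 1e-12)
  }
})

test_that("metric identities and bounds hold on random pairs", {
  set.seed(77)
  for (rep in 1:50) {
    pr <- rand_pair(sample(1:15, 1))
    # alpha=1, beta=gamma=1 reduces to row-Jaccard
    expect_equal(alpha_evaluation_score(pr$t, pr$p),
                 jaccard_row_accuracy(pr$t, pr$p), tolerance = 1e-12)
    # complement of column-wise accuracy
    expect_equal(hamming_loss(pr$t, pr$p),
                 1 - label_macro_accuracy(pr$t, pr$p), tolerance = 1e-12)
    vals <- c(hamming_loss(pr$t, pr$p), jaccard_row_accuracy(pr$t, pr$p),
              label_macro_accuracy(pr$t, pr$p),
              alpha_evaluation_score(pr$t, pr$p))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("per-label report computes macro one-vs-rest scores", {
  # perfect predictions with all classes represented -> everything 1
  y <- data.frame(disorder = rep(0:2, 3L), subclass = 0:8)
  rep1 <- per_label_report(y, y)
  expect_true(all(unlist(rep1[, -1]) == 1))

  # crafted confusion: class 0 has tp=2, fp=1, fn=2 so precision=2/3,
  # recall=1/2, F1=4/7; report macro equals the oracle macro
  truth <- data.frame(disorder = c(0L, 0L, 0L, 0L, 1L, 1L, 2L),
                      subclass = rep(0L, 7))
  pred <- data.frame(disorder = c(0L, 0L, 1L, 2L, 0L, 1L, 2L),
                     subclass = rep(0L, 7))
  prf0 <- oracle_class_prf(truth$disorder, pred$disorder, 0L)
  expect_equal(unname(prf0), c(2 / 3, 1 / 2, 4 / 7))
  got <- suppressWarnings(per_label_report(truth, pred))
  want <- oracle_macro_prf(truth$disorder, pred$disorder, 3L)
  expect_equal(got$precision[1], unname(want["precision"]))
  expect_equal(got$recall[1], unname(want["recall"]))
  expect_equal(got$f1[1], unname(want["f1"]))
  expect_equal(got$accuracy[1], mean(truth$disorder == pred$disorder))

  # class absent from truth and prediction -> contributes 0 with a warning
  expect_warning(per_label_report(truth, pred), "zero-division")

  # micro and weighted variants stay in bounds
  for (avg in c("micro", "weighted")) {
    r <- suppressWarnings(per_label_report(truth, pred, average = avg))
    expect_true(all(r$precision >= 0 & r$precision <= 1))
  }
  expect_error(per_label_report(truth, pred[1:3, ]))
})

test_that("assembled reports serialize and format as percentages", {
  set.seed(5)
  y_true <- data.frame(disorder = sample(0:2, 30, TRUE),
                       subclass = sample(0:8, 30, TRUE))
  y_pred <- data.frame(disorder = sample(0:2, 30, TRUE),
                       subclass = sample(0:8, 30, TRUE))
  rep <- suppressWarnings(assemble_report(
    y_true, y_pred, arm = list(model = "DTC", split = 0.8,
                               feature_mode = "raw",
                               balance_mode = "imbalanced")))
  expect_s3_class(rep, "evaluation_report")
  need <- c("disorder_accuracy", "subclass_f1", "macro_accuracy_label_based",
            "macro_accuracy_example_based", "hamming_loss", "alpha_score")
  expect_true(all(need %in% names(rep)))

  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.list(rep), path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path)
  expect_equal(back$hamming_loss, rep$hamming_loss)
  expect_equal(back$alpha_score, rep$alpha_score)

  fmt <- format_report_table(rep)
  expect_match(fmt[["Macro Accuracy (%)"]], "^[0-9]+$")
  expect_match(fmt[["Hamming Loss"]], "^0\\.[0-9]{2}$")
})
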