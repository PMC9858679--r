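small_config <- function(..., n = 400, master_seed = 7) {
  experiment_config(
    data = synthetic_config(n, scenario = "noisy_linear", seed = 1),
    learners = c("DTC", "KNN"), splits = c(0.8, 0.7),
    feature_modes = "raw", balance_modes = "imbalanced",
    etrf_et_spec = fast_et(), etrf_rf_spec = fast_rf(),
    master_seed = master_seed, ...
  )
}

test_that("the grid emits one report row per arm", {
  cfg <- small_config()
  res <- run_experiment(cfg)
  expect_equal(nrow(res$ledger), 2 * 2) # learners x splits
  expect_equal(nrow(res$reports), 4L)
  expect_true(all(res$ledger$status == "ok"))
  expect_true(all(c("model", "split", "feature_mode", "balance_mode",
                    "hamming_loss", "alpha_score") %in%
                    names(res$reports)))
  # per-arm seeds are stable hashes of the descriptors
  expect_equal(res$reports$seed[1],
               genochain:::stable_hash(7, "DTC", 0.8, "raw", "imbalanced"))
})

test_that("arm failures are isolated and logged, the grid continues", {
  cfg <- experiment_config(
    data = synthetic_config(300, scenario = "noisy_linear",
                            disorder_priors = c(0.6, 0.4, 0), seed = 1),
    learners = "DTC", splits = 0.8, feature_modes = "raw",
    balance_modes = c("imbalanced", "balanced"),
    classifier = "independent", master_seed = 3
  )
  res <- suppressWarnings(suppressMessages(run_experiment(cfg)))
  expect_equal(sort(res$ledger$status), c("error", "ok"))
  expect_match(res$ledger$message[res$ledger$status == "error"],
               "zero samples")
  expect_equal(nrow(res$reports), 1L)
})

test_that("compare_modes pairs arms and reports hybrid-minus-raw deltas", {
  rep1 <- data.frame(model = c("LR", "LR"), split = 0.8,
                     balance_mode = "imbalanced",
                     feature_mode = c("raw", "etrf"),
                     macro_accuracy_label_based = c(0.70, 0.80),
                     hamming_loss = c(0.30, 0.20),
                     alpha_score = c(0.5, 0.6))
  cm <- compare_modes(rep1)
  expect_equal(nrow(cm$deltas), 1L)
  expect_equal(cm$deltas$d_macro_accuracy, 0.10)
  expect_equal(cm$summary$d_macro_accuracy, 0.10)

  # identical reports -> zero deltas; unpaired arms are skipped
  rep2 <- rep1
  rep2$macro_accuracy_label_based <- 0.7
  rep2$hamming_loss <- 0.3
  rep2$alpha_score <- 0.5
  expect_equal(compare_modes(rep2)$deltas$d_macro_accuracy, 0)
  expect_warning(compare_modes(rep1[1, ]), "unpaired")
})

test_that("balance-then-split and split-then-balance both equalize train
           classes", {
  for (ord in c("balance_then_split", "split_then_balance")) {
    cfg <- small_config(balance_order = ord)
    cfg$balance_modes <- "balanced"
    cfg$learners <- "DTC"
    cfg$splits <- 0.8
    res <- run_experiment(cfg)
    expect_equal(res$reports$balance_mode, "balanced")
    expect_equal(nrow(res$reports), 1L)
  }
})

test_that("CLI subcommands run end to end with the documented exit codes", {
  out <- withr::local_tempdir()
  expect_equal(genochain_cli(c("simulate", "--scenario", "separable",
                               "--n", "60", "--seed", "4",
                               "--out", out)), 0L)
  expect_true(file.exists(file.path(out, "patients.csv")))
  expect_true(file.exists(file.path(out, "ground_truth.csv")))

  enc_dir <- file.path(out, "enc")
  expect_equal(suppressWarnings(
    genochain_cli(c("preprocess", "--in", file.path(out, "patients.csv"),
                    "--out", enc_dir))), 0L)
  expect_true(file.exists(file.path(enc_dir, "features.csv")))
  expect_true(file.exists(file.path(enc_dir, "encoding_maps.tsv")))

  mod_dir <- file.path(out, "model")
  expect_equal(genochain_cli(c("train",
                               "--features", file.path(enc_dir,
                                                       "features.csv"),
                               "--labels", file.path(enc_dir, "labels.csv"),
                               "--seed", "1", "--out", mod_dir)), 0L)
  expect_true(file.exists(file.path(mod_dir, "chain_model.rds")))

  # evaluate: truth/pred CSVs of label codes
  truth <- file.path(out, "truth.csv")
  pred <- file.path(out, "pred.csv")
  lab <- utils::read.csv(file.path(enc_dir, "labels.csv"))
  utils::write.csv(lab, truth, row.names = FALSE)
  utils::write.csv(lab, pred, row.names = FALSE)
  rep_json <- file.path(out, "report.json")
  expect_equal(genochain_cli(c("evaluate", "--truth", truth, "--pred", pred,
                               "--out", rep_json)), 0L)
  expect_equal(jsonlite::read_json(rep_json)$hamming_loss, 0)

  # mismatched lengths -> data error (3)
  utils::write.csv(lab[1:5, ], pred, row.names = FALSE)
  expect_equal(suppressMessages(
    genochain_cli(c("evaluate", "--truth", truth, "--pred", pred,
                    "--out", rep_json))), 3L)

  # config errors -> 2
  expect_equal(suppressMessages(genochain_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(genochain_cli(c("simulate", "--n", "5"))),
               2L)
})

test_that("experiment CLI reads a plain-text config and writes the grid", {
  out <- withr::local_tempdir()
  cfg_path <- file.path(out, "grid.cfg")
  writeLines(c("scenario = noisy_linear", "n = 300",
               "learners = DTC", "splits = 0.8",
               "feature_modes = raw", "balance_modes = imbalanced",
               "classifier = independent"), cfg_path)
  expect_equal(suppressMessages(
    genochain_cli(c("experiment", "--config", cfg_path, "--seed", "2",
                    "--out", file.path(out, "run")))), 0L)
  got <- utils::read.csv(file.path(out, "run", "grid_reports.csv"))
  expect_equal(nrow(got), 1L)
  expect_true(file.exists(file.path(out, "run", "run_ledger.csv")))
})
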