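# Builds a small table covering every category string the encoder maps, so
# the full code alphabet {-1, 0, 1, 2} is exercised.
category_fixture <- function() {
  tab <- as.data.frame(fixture_table(8, seed = 5))
  tab[["Maternal gene"]] <- c("Yes", "No", "Yes", "No", "Yes", "No", "Yes",
                              "No")
  tab[["H/O radiation exposure (X-ray)"]] <-
    c("Yes", "No", "Not applicable", "Yes", "No", "Not applicable", "Yes",
      "No")
  tab[["H/O substance abuse"]] <-
    c("Not applicable", "Yes", "No", "Not applicable", "Yes", "No", "Yes",
      "No")
  tab[["Status"]] <- c("Deceased", "Alive", "Deceased", "Alive", "Deceased",
                       "Alive", "Deceased", "Alive")
  tab[["Respiratory Rate (breaths/min)"]] <-
    rep(c("Normal (30-60)", "Tachypnea"), 4)
  tab[["Heart Rate (rates/min"]] <- rep(c("Normal", "Tachypnea"), 4)
  tab[["Follow-up"]] <- rep(c("Low", "High"), 4)
  tab[["Gender"]] <- c("Male", "Female", "Ambiguous", "Male", "Female",
                       "Ambiguous", "Male", "Female")
  tab[["Birth asphyxia"]] <- c("No record", "Not available", "No", "Yes",
                               "No record", "Not available", "No", "Yes")
  tab[["Birth defects"]] <- rep(c("Singular", "Multiple"), 4)
  tab[["Blood test result"]] <- rep(c("normal", "abnormal"), 4)
  tab[["Mother's age"]][1] <- NA
  patient_table(tab)
}

test_that("drop list removes exactly the named columns and keeps Test 4", {
  tab <- fixture_table(5, seed = 3)
  expect_true(all(dropped_columns() %in% names(tab)))
  out <- drop_noncontributing(tab)
  expect_false(any(dropped_columns() %in% names(out)))
  expect_true("Test 4" %in% names(out))
  expect_false("Test 2" %in% names(out))
  expect_equal(ncol(tab) - ncol(out), 13L)

  # idempotent: absent columns are skipped with a warning
  expect_warning(out2 <- drop_noncontributing(out), "absent")
  expect_identical(as.data.frame(out2), as.data.frame(out))

  # a table already lacking one identifier behaves the same
  part <- patient_table(as.data.frame(tab)[, setdiff(names(tab),
                                                     "Parental consent")])
  expect_warning(out3 <- drop_noncontributing(part), "Parental consent")
  expect_identical(as.data.frame(out3), as.data.frame(out))
})

test_that("categorical encoding matches the printed integer codes", {
  tab <- drop_noncontributing(category_fixture())
  X <- encode_features(tab)
  expect_false(anyNA(X))
  expect_equal(unname(X[1:2, "Maternal gene"]), c(1, 0))
  expect_equal(unname(X[1:3, "H/O substance abuse"]), c(-1, 1, 0))
  expect_equal(unname(X[1:3, "Gender"]), c(0, 1, 2))
  expect_equal(unname(X[1:4, "Birth asphyxia"]), c(0, 0, 0, 1))
  expect_equal(unname(X[1:2, "Status"]), c(0, 1))
  expect_equal(unname(X[1:2, "Respiratory Rate (breaths/min)"]), c(0, 1))
  expect_equal(unname(X[1:2, "Heart Rate (rates/min"]), c(0, 1))
  expect_equal(unname(X[1:2, "Follow-up"]), c(0, 1))
  expect_equal(unname(X[1:2, "Birth defects"]), c(0, 1))
  expect_equal(unname(X[1:2, "Blood test result"]), c(0, 1))
  expect_equal(unname(X[1, "Mother's age"]), 0) # null -> zero fill
  # codes never leave the alphabet
  cats <- intersect(names(encoding_maps()), colnames(X))
  expect_true(all(X[, cats] %in% c(-1, 0, 1, 2)))
})

test_that("encoding is total, deterministic, and guards its contract", {
  tab <- drop_noncontributing(fixture_table(40, scenario = "noisy_linear",
                                            seed = 9))
  X1 <- encode_features(tab)
  X2 <- encode_features(tab)
  expect_identical(X1, X2)
  expect_equal(ncol(X1), ncol(tab) - 2L) # all non-target columns encoded

  # identifier columns present -> must drop first
  expect_error(encode_features(fixture_table(5, seed = 1)),
               "drop_noncontributing")

  # unseen category named in the error
  bad <- tab
  bad[["Maternal gene"]][1] <- "Perhaps"
  expect_error(encode_features(bad), "Maternal gene")

  # maps export/import round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_encoding_maps(path)
  maps <- read_encoding_maps(path)
  expect_equal(maps[order(names(maps))],
               encoding_maps()[order(names(encoding_maps()))])
})

test_that("target encoding yields codes, one-hot blocks, and exclusions", {
  tab <- fixture_table(20, seed = 13)
  tab[["Genetic Disorder"]][3] <- NA
  tab[["Disorder Subclass"]][5] <- NA
  enc <- encode_targets(tab)
  expect_equal(enc$n_excluded, 2L)
  expect_equal(nrow(enc$labels), 18L)
  expect_true(all(rowSums(enc$indicator) == 2))
  expect_true(all(enc$labels$disorder %in% 0:2))
  expect_true(all(enc$labels$subclass %in% 0:8))

  # code convention: mitochondrial disorder and its first subclass are code 0
  one <- as.data.frame(tab)[1, ]
  one[["Genetic Disorder"]] <- disorder_classes()[1]
  one[["Disorder Subclass"]] <- subclass_classes()[1]
  e1 <- encode_targets(patient_table(one))
  expect_equal(unlist(e1$labels, use.names = FALSE), c(0L, 0L))
  expect_equal(sum(e1$indicator), 2)
  expect_equal(which(e1$indicator[1, ] == 1), c(disorder_0 = 1L,
                                                subclass_0 = 4L))

  one[["Disorder Subclass"]] <- "mystery disease"
  expect_error(patient_table(one), "invalid Disorder Subclass")

  # indicator <-> labels inversion
  lab <- data.frame(disorder = c(0L, 2L, 1L), subclass = c(8L, 0L, 4L))
  expect_equal(indicator_to_labels(labels_to_indicator(lab)), lab)
})

test_that("undersampling equalizes disorder classes reproducibly", {
  g <- generate_patients(synthetic_config(3000, scenario = "noisy_linear",
                                          seed = 21))
  pp <- encode_pipeline(g$table)
  counts <- tabulate(pp$y$disorder + 1L, 3L)
  expect_true(min(counts) < max(counts))
  b1 <- balance_undersample(pp$X, pp$y, seed = 5)
  expect_equal(unname(tabulate(b1$y$disorder + 1L, 3L)),
               rep(min(counts), 3L))
  b2 <- balance_undersample(pp$X, pp$y, seed = 5)
  expect_identical(b1$idx, b2$idx)
  expect_false(identical(b1$idx, balance_undersample(pp$X, pp$y, 6)$idx))

  # already balanced -> unchanged up to row order
  b3 <- balance_undersample(b1$X, b1$y, seed = 1)
  expect_equal(nrow(b3$X), nrow(b1$X))
  expect_identical(b3$idx, seq_len(nrow(b1$X)))

  # empty class errors
  y0 <- pp$y[pp$y$disorder != 1L, , drop = FALSE]
  X0 <- pp$X[pp$y$disorder != 1L, , drop = FALSE]
  expect_error(balance_undersample(X0, y0, 1), "zero samples")
})

test_that("train/test split partitions exactly and stratifies within one", {
  g <- generate_patients(synthetic_config(100, scenario = "noisy_linear",
                                          seed = 31))
  pp <- encode_pipeline(g$table)
  n <- nrow(pp$X)
  sp <- train_test_split(pp$X, pp$y, 0.8, seed = 2, stratified = FALSE)
  expect_equal(nrow(sp$train$X), round(0.8 * n))
  expect_equal(sort(c(sp$train$idx, sp$test$idx)), seq_len(n))
  sp2 <- train_test_split(pp$X, pp$y, 0.8, seed = 2, stratified = FALSE)
  expect_identical(sp$train$idx, sp2$train$idx)

  g2 <- generate_patients(synthetic_config(900, scenario = "noisy_linear",
                                           seed = 32))
  pp2 <- encode_pipeline(g2$table)
  sp3 <- train_test_split(pp2$X, pp2$y, 0.8, seed = 3)
  cell <- interaction(pp2$y$disorder, pp2$y$subclass, drop = TRUE)
  for (k in levels(cell)) {
    rows <- which(cell == k)
    if (length(rows) < 2L) next
    got <- sum(rows %in% sp3$train$idx)
    expect_lte(abs(got - 0.8 * length(rows)), 1)
  }

  # singleton stratum falls back with a warning
  y1 <- data.frame(disorder = c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2),
                   subclass = c(0, 0, 0, 0, 1, 1, 1, 1, 2, 3))
  X1 <- matrix(rnorm(20), 10, 2)
  expect_warning(train_test_split(X1, y1, 0.8, seed = 1), "singleton")
})
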