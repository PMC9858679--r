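# Seed hygiene: every stochastic operation takes an explicit integer seed and
# leaves the caller's RNG state untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Columns dropped before modelling
#'
#' The 13 columns removed for their low or absent contribution to disorder
#' prediction: identifier/free-text fields, the laboratory columns
#' 'Test 1', 'Test 2', 'Test 3', 'Test 5' (note that 'Test 4' is retained),
#' and the autopsy indicator.
#'
#' @return Character vector of 13 column names.
#' @export
dropped_columns <- function() {
  c("Patient Id", "Patient First Name", "Family Name", "Father's name",
    "Institute Name", "Location of Institute", "Place of birth",
    "Parental consent", "Test 1", "Test 2", "Test 3", "Test 5",
    "Autopsy shows birth defect (if applicable)")
}

#' Drop non-contributing columns
#'
#' Removes exactly the [dropped_columns()] set; columns already absent are
#' skipped with a warning, so the operation is idempotent.
#'
#' @param table A `patient_table`.
#' @return The table without the dropped columns (class preserved).
#' @export
drop_noncontributing <- function(table) {
  drop <- dropped_columns()
  absent <- setdiff(drop, names(table))
  if (length(absent)) {
    warning("already absent, skipping: ", paste(absent, collapse = ", "))
  }
  out <- table[, setdiff(names(table), drop), drop = FALSE]
  class(out) <- class(table)
  out
}

#' Integer encoding maps for the categorical features
#'
#' The fixed category-to-integer dictionary applied by [encode_features()].
#' Codes are drawn from \{-1, 0, 1, 2\}: Yes/No -> 1/0 for the eight binary
#' history columns; Yes/No/'Not applicable' -> 1/0/-1 for the radiation and
#' substance-abuse columns; Deceased/Alive -> 0/1; 'Normal (30-60)' or
#' 'Normal' vs Tachypnea -> 0/1; Low/High follow-up -> 0/1;
#' Male/Female/Ambiguous -> 0/1/2; birth asphyxia 'No record'/'Not
#' available'/'No' -> 0 and 'Yes' -> 1; Singular/Multiple -> 0/1;
#' normal/abnormal blood test -> 0/1. Matching is case-insensitive.
#'
#' @return Named list: column name -> named integer vector (category -> code).
#' @export
encoding_maps <- function() {
  bin <- c(Yes = 1L, No = 0L)
  tri <- c(Yes = 1L, No = 0L, "Not applicable" = -1L)
  maps <- list(
    "Genes in mother's side" = bin,
    "Inherited from father" = bin,
    "Maternal gene" = bin,
    "Paternal gene" = bin,
    "Assisted conception IVF/ART" = bin,
    "History of anomalies in previous pregnancies" = bin,
    "Folic acid details (peri-conceptional)" = bin,
    "H/O serious maternal illness" = bin,
    "H/O radiation exposure (X-ray)" = tri,
    "H/O substance abuse" = tri,
    "Status" = c(Deceased = 0L, Alive = 1L),
    "Respiratory Rate (breaths/min)" = c("Normal (30-60)" = 0L,
                                         Tachypnea = 1L),
    "Heart Rate (rates/min" = c(Normal = 0L, Tachypnea = 1L),
    "Follow-up" = c(Low = 0L, High = 1L),
    "Gender" = c(Male = 0L, Female = 1L, Ambiguous = 2L),
    "Birth asphyxia" = c("No record" = 0L, "Not available" = 0L,
                         No = 0L, Yes = 1L),
    "Birth defects" = c(Singular = 0L, Multiple = 1L),
    "Blood test result" = c(normal = 0L, abnormal = 1L)
  )
  maps
}

#' Export / import the encoding maps as a plain-text config
#'
#' Tab-separated `column  category  code` lines, so the exact encoding
#' dialect is auditable outside R.
#'
#' @param path File path.
#' @param maps A map list as returned by [encoding_maps()].
#' @return `read_encoding_maps()` returns the map list.
#' @export
write_encoding_maps <- function(path, maps = encoding_maps()) {
  rows <- do.call(rbind, lapply(names(maps), function(col) {
    data.frame(column = col, category = names(maps[[col]]),
               code = unname(maps[[col]]), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_encoding_maps
#' @export
read_encoding_maps <- function(path) {
  rows <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE, fileEncoding = "UTF-8")
  maps <- split(rows, rows$column)
  lapply(maps, function(d) stats::setNames(as.integer(d$code), d$category))
}

#' Encode the feature columns to a numeric matrix
#'
#' Applies the fixed categorical maps, passes numeric columns through, and
#' finally replaces every remaining null with zero, so the result contains
#' no missing values. Expects [drop_noncontributing()] to have been applied
#' (identifier columns still present raise an error). Target columns, if
#' present, are ignored here; see [encode_targets()].
#'
#' @param table A `patient_table` after dropping.
#' @return Numeric matrix (rows = patients, columns = encoded features) with
#'   attributes `feature_names` and `provenance` (drop list + maps applied).
#' @export
encode_features <- function(table) {
  schema <- genome_schema()
  roles <- stats::setNames(schema$role, schema$name)
  idcols <- names(table)[roles[names(table)] == "identifier"]
  if (length(idcols)) {
    stop("identifier columns present; apply drop_noncontributing() first: ",
         paste(idcols, collapse = ", "))
  }
  feats <- names(table)[roles[names(table)] == "feature"]
  maps <- encoding_maps()
  cols <- lapply(feats, function(nm) {
    v <- table[[nm]]
    if (!is.null(maps[[nm]])) {
      m <- maps[[nm]]
      idx <- match(tolower(as.character(v)), tolower(names(m)))
      bad <- which(!is.na(v) & is.na(idx))
      if (length(bad)) {
        stop(sprintf("encoding error: column '%s' has unseen category '%s'",
                     nm, as.character(v[bad[1]])))
      }
      out <- as.numeric(m[idx])
    } else {
      out <- as.numeric(v)
    }
    out[is.na(out)] <- 0
    out
  })
  X <- do.call(cbind, cols)
  colnames(X) <- feats
  attr(X, "feature_names") <- feats
  attr(X, "provenance") <- list(dropped = setdiff(dropped_columns(),
                                                  names(table)),
                                maps = maps[intersect(names(maps), feats)])
  X
}

#' Encode the two targets to integer codes and a 12-column indicator
#'
#' Disorder codes are 0 = mitochondrial, 1 = multifactorial, 2 = single-gene;
#' subclass codes 0--8 follow [subclass_classes()] order. Rows with a null in
#' either target are excluded and counted. The indicator form is the
#' concatenated one-hot of the 3-class and 9-class blocks (every row sums
#' to 2).
#'
#' @param table A `patient_table` (targets present).
#' @return List with `labels` (data.frame of integer `disorder`, `subclass`),
#'   `indicator` (n x 12 binary matrix), `kept` (row indices into `table`),
#'   and `n_excluded`.
#' @export
encode_targets <- function(table) {
  d <- match(table[["Genetic Disorder"]], disorder_classes()) - 1L
  s <- match(table[["Disorder Subclass"]], subclass_classes()) - 1L
  bad_d <- !is.na(table[["Genetic Disorder"]]) & is.na(d)
  bad_s <- !is.na(table[["Disorder Subclass"]]) & is.na(s)
  if (any(bad_d) || any(bad_s)) {
    stop("unknown target class string")
  }
  keep <- which(!is.na(d) & !is.na(s))
  labels <- data.frame(disorder = d[keep], subclass = s[keep])
  list(labels = labels,
       indicator = labels_to_indicator(labels),
       kept = keep,
       n_excluded = nrow(table) - length(keep))
}

#' Convert label pairs to the 12-column indicator matrix and back
#'
#' @param labels data.frame with integer columns `disorder` (0--2) and
#'   `subclass` (0--8).
#' @return `labels_to_indicator()`: an n x 12 binary matrix, columns
#'   `disorder_0..2`, `subclass_0..8`. `indicator_to_labels()` inverts it for
#'   valid one-hot rows.
#' @export
labels_to_indicator <- function(labels) {
  n <- nrow(labels)
  ind <- matrix(0L, n, 12L,
                dimnames = list(NULL, c(paste0("disorder_", 0:2),
                                        paste0("subclass_", 0:8))))
  if (n) {
    ind[cbind(seq_len(n), labels$disorder + 1L)] <- 1L
    ind[cbind(seq_len(n), labels$subclass + 4L)] <- 1L
  }
  ind
}

#' @rdname labels_to_indicator
#' @param indicator An n x 12 binary matrix in the block layout above.
#' @export
indicator_to_labels <- function(indicator) {
  stopifnot(ncol(indicator) == 12L)
  data.frame(disorder = max.col(indicator[, 1:3, drop = FALSE],
                                ties.method = "first") - 1L,
             subclass = max.col(indicator[, 4:12, drop = FALSE],
                                ties.method = "first") - 1L)
}

#' Balance disorder classes by random undersampling
#'
#' Every disorder class is reduced to the minimum class count by uniform
#' sampling without replacement; the subclass distribution is whatever
#' survives. Row order of the result follows the original order.
#'
#' @param X Encoded feature matrix.
#' @param y Labels data.frame from [encode_targets()].
#' @param seed Integer seed.
#' @return List with balanced `X`, `y`, and the selected row indices `idx`.
#' @export
balance_undersample <- function(X, y, seed) {
  stopifnot(nrow(X) == nrow(y))
  counts <- tabulate(y$disorder + 1L, nbins = 3L)
  if (any(counts == 0L)) {
    stop("disorder class with zero samples: code ",
         paste(which(counts == 0L) - 1L, collapse = ", "))
  }
  m <- min(counts)
  idx <- with_seed(seed, {
    sel <- lapply(0:2, function(k) {
      rows <- which(y$disorder == k)
      if (length(rows) == m) rows else sample(rows, m)
    })
    sort(unlist(sel))
  })
  list(X = X[idx, , drop = FALSE], y = y[idx, , drop = FALSE], idx = idx)
}

#' Split into train and test sets
#'
#' Disjoint, exhaustive partition at `train_fraction`. With
#' `stratified = TRUE` (default) the split is stratified on the joint
#' (disorder, subclass) cell, keeping each cell's train fraction within one
#' sample of the target; singleton cells fall back to a global coin flip with
#' a warning.
#'
#' @param X Feature matrix.
#' @param y Labels data.frame.
#' @param train_fraction Real in (0, 1).
#' @param seed Integer seed.
#' @param stratified Stratify on the joint label (default TRUE).
#' @return List of `train` and `test`, each with `X`, `y`, `idx`.
#' @export
train_test_split <- function(X, y, train_fraction, seed, stratified = TRUE) {
  stopifnot(nrow(X) == nrow(y), nrow(X) >= 2L,
            train_fraction > 0, train_fraction < 1)
  n <- nrow(X)
  train_idx <- with_seed(seed, {
    if (!stratified) {
      sample(n, round(train_fraction * n))
    } else {
      cell <- interaction(y$disorder, y$subclass, drop = TRUE)
      singles <- names(which(table(cell) == 1L))
      if (length(singles)) {
        warning("singleton strata fall back to a global split: ",
                paste(singles, collapse = ", "))
      }
      unlist(lapply(split(seq_len(n), cell), function(rows) {
        if (length(rows) == 1L) {
          if (stats::runif(1) < train_fraction) rows else integer(0)
        } else {
          sample(rows, round(train_fraction * length(rows)))
        }
      }), use.names = FALSE)
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = list(X = X[train_idx, , drop = FALSE],
                    y = y[train_idx, , drop = FALSE], idx = train_idx),
       test = list(X = X[test_idx, , drop = FALSE],
                   y = y[test_idx, , drop = FALSE], idx = test_idx))
}
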