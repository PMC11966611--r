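# Cross-validation split plans for pair-input data. Random-pair folds model
# drug repurposing (only the combination must be unseen); drug-blind folds
# model virtual screening (a drug never spans train and test). Plans are
# seeded and serializable so a fixed split can be shared across experiments.

new_split_plan <- function(mode, k, fold_of_record, fold_of_drug, seed) {
  structure(list(mode = mode, k = as.integer(k),
                 fold_of_record = as.integer(fold_of_record),
                 fold_of_drug = fold_of_drug, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan: ", x$k, "-fold ", x$mode, ", ",
      length(x$fold_of_record), " records (seed ", x$seed, ")\n", sep = "")
  print(table(fold = x$fold_of_record))
  invisible(x)
}

#' Random-pair cross-validation folds
#'
#' Partitions records into `k` near-equal folds (sizes differ by at most 1)
#' by a seeded permutation. A pair may share its drug or its sample with the
#' training folds — only the combination is held out.
#'
#' @param table A `drug_response_table`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A `split_plan` with `mode = "random_pair"`.
#' @export
random_pair_folds <- function(table, k, seed) {
  n <- nrow(table)
  stopifnot(k >= 2)
  if (k > n) stop("random_pair_folds: k = ", k, " exceeds ", n, " records")
  perm <- withr::with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  new_split_plan("random_pair", k, fold, NULL, seed)
}

#' Drug-blind cross-validation folds
#'
#' Partitions drugs (not pairs) into `k` folds; every record inherits its
#' drug's fold, so no drug ever appears on both sides of a train/test
#' rotation. Fold pair-counts are balanced greedily: drugs are taken in
#' decreasing record-count order (ties broken by a seeded shuffle) and each
#' is assigned to the currently lightest fold.
#'
#' @param table A `drug_response_table`.
#' @param k Number of folds (>= 2, at most the number of drugs).
#' @param seed Integer seed.
#' @return A `split_plan` with `mode = "drug_blind"` and per-drug folds.
#' @export
drug_blind_folds <- function(table, k, seed) {
  stopifnot(k >= 2)
  drugs <- unique(table$drug_id)
  if (length(drugs) < k) {
    stop("drug_blind_folds: ", length(drugs), " drugs < k = ", k, " folds")
  }
  counts <- table(table$drug_id)[drugs]
  order_seeded <- withr::with_seed(seed, sample(seq_along(drugs)))
  drugs <- drugs[order_seeded]
  counts <- as.integer(counts[drugs])
  ord <- order(counts, decreasing = TRUE)  # stable: seeded order breaks ties
  fold_of_drug <- integer(length(drugs))
  names(fold_of_drug) <- drugs
  load <- numeric(k)
  for (i in ord) {
    f <- which.min(load)
    fold_of_drug[i] <- f
    load[f] <- load[f] + counts[i]
  }
  fold <- unname(fold_of_drug[table$drug_id])
  new_split_plan("drug_blind", k, fold, fold_of_drug, seed)
}

#' Record indices of the test and train portions of one fold rotation
#'
#' @param plan A `split_plan`.
#' @param fold Fold id in `1:k`.
#' @return List with integer vectors `train` and `test`.
#' @export
fold_indices <- function(plan, fold) {
  stopifnot(fold >= 1, fold <= plan$k)
  test <- which(plan$fold_of_record == fold)
  list(train = setdiff(seq_along(plan$fold_of_record), test), test = test)
}

#' Carve a validation holdout out of a fold's training portion
#'
#' Used to tune the regularization weight: within the training side of one
#' rotation, roughly `fraction` of it is held out. In drug-blind mode whole
#' drugs are held out, so the validation set is drug-disjoint from the
#' remaining training records — the same blindness as the test fold.
#'
#' @param plan A `split_plan`.
#' @param table The `drug_response_table` the plan was built on.
#' @param fold Test fold id whose complement is split.
#' @param fraction Holdout fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `validation`.
#' @export
validation_holdout <- function(plan, table, fold, fraction, seed) {
  stopifnot(fraction > 0, fraction < 1)
  tr <- fold_indices(plan, fold)$train
  if (plan$mode == "drug_blind") {
    tr_drugs <- unique(table$drug_id[tr])
    n_val <- round(fraction * length(tr_drugs))
    if (n_val < 1 || n_val >= length(tr_drugs)) {
      stop("validation_holdout: fraction ", fraction, " leaves ",
           n_val, " of ", length(tr_drugs), " training drugs for validation")
    }
    val_drugs <- withr::with_seed(seed, sample(tr_drugs, n_val))
    val <- tr[table$drug_id[tr] %in% val_drugs]
  } else {
    n_val <- round(fraction * length(tr))
    if (n_val < 1 || n_val >= length(tr)) {
      stop("validation_holdout: fraction ", fraction,
           " leaves an empty train or validation set")
    }
    val <- withr::with_seed(seed, sample(tr, n_val))
  }
  list(train = setdiff(tr, val), validation = sort(val))
}

#' Check a split plan for leakage and partition defects
#'
#' Returns a character vector of violations (empty when the plan is sound):
#' every record in exactly one fold of `1:k`, no empty fold, and — in
#' drug-blind mode — no drug spanning folds and record folds induced by drug
#' folds. Reports rather than throws, so corrupted plans can be inspected.
#'
#' @param plan A `split_plan`.
#' @param table The `drug_response_table` the plan refers to.
#' @return Character vector of human-readable violations.
#' @export
validate_plan <- function(plan, table) {
  v <- character(0)
  f <- plan$fold_of_record
  if (length(f) != nrow(table)) {
    v <- c(v, sprintf("plan covers %d records but table has %d",
                      length(f), nrow(table)))
    return(v)
  }
  bad <- which(is.na(f) | f < 1 | f > plan$k)
  if (length(bad) > 0) {
    v <- c(v, sprintf("record %d assigned to invalid fold '%s'",
                      bad[1], as.character(f[bad[1]])))
  }
  empty <- setdiff(seq_len(plan$k), unique(f))
  if (length(empty) > 0) {
    v <- c(v, sprintf("fold %d is empty", empty))
  }
  if (plan$mode == "drug_blind") {
    span <- tapply(f, table$drug_id, function(x) length(unique(x)))
    leaky <- names(span)[span > 1]
    for (d in leaky) {
      v <- c(v, sprintf("drug '%s' has records in %d folds", d, span[[d]]))
    }
    if (!is.null(plan$fold_of_drug)) {
      induced <- unname(plan$fold_of_drug[table$drug_id])
      if (any(induced != f, na.rm = TRUE)) {
        i <- which(induced != f)[1]
        v <- c(v, sprintf(
          "record %d in fold %d but its drug '%s' is assigned fold %d",
          i, f[i], table$drug_id[i], induced[i]))
      }
    }
  }
  v
}

#' Serialize a split plan to a two-column text file
#'
#' Drug-blind plans store `drug_id -> fold`; random-pair plans store
#' `record_index -> fold`. A header line carries mode, k and seed so
#' [read_split_plan()] can restore the plan exactly.
#'
#' @param plan A `split_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s k=%d seed=%d", plan$mode, plan$k, plan$seed),
             con)
  if (plan$mode == "drug_blind") {
    writeLines("drug_id\tfold", con)
    writeLines(sprintf("%s\t%d", names(plan$fold_of_drug),
                       plan$fold_of_drug), con)
  } else {
    writeLines("record_index\tfold", con)
    writeLines(sprintf("%d\t%d", seq_along(plan$fold_of_record),
                       plan$fold_of_record), con)
  }
  invisible(path)
}

#' Restore a split plan written by [write_split_plan()]
#'
#' @param path Plan file.
#' @param table The `drug_response_table` the plan refers to (needed to
#'   re-induce record folds of a drug-blind plan).
#' @return A `split_plan`.
#' @export
read_split_plan <- function(path, table) {
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("mode=(\\S+) k=(\\d+) seed=(-?\\d+)", header))[[1]]
  if (length(m) != 4) stop("not a split plan file: ", path)
  mode <- m[2]; k <- as.integer(m[3]); seed <- as.integer(m[4])
  body <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                            stringsAsFactors = FALSE)
  if (mode == "drug_blind") {
    fod <- stats::setNames(as.integer(body$fold), as.character(body$drug_id))
    fold <- unname(fod[table$drug_id])
    new_split_plan(mode, k, fold, fod, seed)
  } else {
    fold <- integer(nrow(table))
    fold[body$record_index] <- body$fold
    new_split_plan(mode, k, fold, NULL, seed)
  }
}
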