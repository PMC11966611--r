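# Evaluation at two resolutions: bulk (pooled over all test pairs, the
# field's usual report) and drug-wise (each metric computed within a drug's
# pairs, then averaged with equal weight per drug). The drug-averaged view
# is insensitive to per-drug record counts and is where imbalance-aware
# training shows its effect; MOA-averaged metrics aggregate drugs sharing a
# mechanism of action.

METRIC_NAMES <- c("r2", "mse", "mae", "pearson", "spearman")

#' Coefficient of determination
#'
#' `R^2 = 1 - RSS/TSS = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, with
#' the reference mean taken over the evaluated set itself (the test fold for
#' bulk scoring, the drug's own pairs for drug-wise scoring). Unbounded
#' below; equals 1 only for a perfect fit. Returns `NA` when `y` has zero
#' variance (TSS = 0), for the caller to report as undefined.
#'
#' @param y Observed responses (length >= 2).
#' @param yhat Predictions, same length.
#' @return Scalar, `<= 1`, or `NA` for zero-variance `y`.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / tss
}

#' Bulk metrics over a set of pairs
#'
#' @param y,yhat Aligned numeric vectors of length >= 2.
#' @return Named numeric vector: `r2`, `mse`, `mae`, `pearson`, `spearman`.
#'   Correlations are `NA` when either vector is constant.
#' @export
bulk_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  safe_cor <- function(method) {
    if (stats::sd(y) == 0 || stats::sd(yhat) == 0) return(NA_real_)
    suppressWarnings(stats::cor(y, yhat, method = method))
  }
  c(r2 = r_squared(y, yhat),
    mse = mean((y - yhat)^2),
    mae = mean(abs(y - yhat)),
    pearson = safe_cor("pearson"),
    spearman = safe_cor("spearman"))
}

#' Drug-wise metrics and their equal-weight average
#'
#' Computes every metric within each drug's pairs, then averages over drugs
#' with equal weight. Drugs with fewer than `min_group_size` records or zero
#' response variance are excluded (with the reason recorded) rather than
#' contributing undefined values.
#'
#' @param y,yhat Aligned numeric vectors.
#' @param groups Drug label per pair.
#' @param min_group_size Minimum records for a drug to be scored.
#' @return List with `per_group` (data frame: drug, n, metrics),
#'   `group_averaged` (named vector, mean over included drugs; `NA` metrics
#'   dropped per-metric), and `excluded` (data frame: drug, reason).
#' @export
groupwise_metrics <- function(y, yhat, groups, min_group_size = 2) {
  stopifnot(length(y) == length(yhat), length(groups) == length(y))
  idx <- split(seq_along(y), as.character(groups))
  rows <- list(); excl <- list()
  for (d in names(idx)) {
    i <- idx[[d]]
    if (length(i) < min_group_size) {
      excl[[d]] <- sprintf("only %d record(s), need >= %d",
                           length(i), min_group_size)
      next
    }
    if (stats::sd(y[i]) == 0) {
      excl[[d]] <- "zero response variance"
      next
    }
    rows[[d]] <- c(n = length(i), bulk_metrics(y[i], yhat[i]))
  }
  per_group <- if (length(rows) > 0) {
    data.frame(drug_id = names(rows),
               do.call(rbind, rows), row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    data.frame(drug_id = character(0))
  }
  avg <- if (length(rows) > 0) {
    vapply(METRIC_NAMES,
           function(m) mean(per_group[[m]], na.rm = TRUE), numeric(1))
  } else {
    stats::setNames(rep(NA_real_, length(METRIC_NAMES)), METRIC_NAMES)
  }
  excluded <- data.frame(drug_id = names(excl),
                         reason = unlist(excl, use.names = FALSE),
                         stringsAsFactors = FALSE)
  list(per_group = per_group, group_averaged = avg, excluded = excluded)
}

#' Average per-drug metrics within mechanism-of-action groups
#'
#' @param per_group Per-drug metric data frame from [groupwise_metrics()].
#' @param moa Named character vector mapping drug id to MOA label.
#' @return List with `moa_averaged` (data frame: moa, n_drugs, metrics) and
#'   `missing_drugs` (drugs absent from the map, skipped).
#' @export
aggregate_by_moa <- function(per_group, moa) {
  missing <- setdiff(per_group$drug_id, names(moa))
  kept <- per_group[!(per_group$drug_id %in% missing), , drop = FALSE]
  if (nrow(kept) == 0) {
    return(list(moa_averaged = data.frame(moa = character(0)),
                missing_drugs = missing))
  }
  labels <- unname(moa[kept$drug_id])
  agg <- lapply(split(seq_len(nrow(kept)), labels), function(i) {
    c(n_drugs = length(i),
      vapply(METRIC_NAMES, function(m) mean(kept[[m]][i], na.rm = TRUE),
             numeric(1)))
  })
  out <- data.frame(moa = names(agg), do.call(rbind, agg),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(moa_averaged = out, missing_drugs = missing)
}

#' Full metrics report for one evaluation set
#'
#' @param y,yhat Aligned numeric vectors.
#' @param groups Drug label per pair.
#' @param moa Optional named MOA map; enables MOA-averaged metrics.
#' @param min_group_size Passed to [groupwise_metrics()].
#' @return A `metrics_report`: list with `bulk`, `per_group`,
#'   `group_averaged`, `moa_averaged` (or `NULL`), `excluded`.
#' @export
metrics_report <- function(y, yhat, groups, moa = NULL, min_group_size = 2) {
  gw <- groupwise_metrics(y, yhat, groups, min_group_size)
  moa_part <- if (!is.null(moa)) aggregate_by_moa(gw$per_group, moa)
  structure(list(
    bulk = bulk_metrics(y, yhat),
    per_group = gw$per_group,
    group_averaged = gw$group_averaged,
    moa_averaged = if (!is.null(moa_part)) moa_part$moa_averaged,
    moa_missing_drugs = if (!is.null(moa_part)) moa_part$missing_drugs,
    excluded = gw$excluded,
    n_pairs = length(y)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics over", x$n_pairs, "pairs\n  bulk:         ",
      paste(sprintf("%s=%.4f", names(x$bulk), x$bulk), collapse = "  "),
      "\n  drug-averaged:",
      paste(sprintf("%s=%.4f", names(x$group_averaged), x$group_averaged),
            collapse = "  "),
      sprintf("\n  (%d drugs scored, %d excluded)\n",
              nrow(x$per_group), nrow(x$excluded)))
  invisible(x)
}

#' Per-drug (or per-MOA) metric improvements between two reports
#'
#' `delta = metric(b) - metric(a)` for every drug scored in both reports;
#' positive deltas mean report `b` improved on report `a`. Errors if the
#' two reports score different drug sets.
#'
#' @param report_a,report_b `metrics_report` objects over the same drugs.
#' @param scope `"drug"` or `"moa"`.
#' @return Data frame (drug_id/moa, one delta column per metric), sortable
#'   for top-k improvement listings.
#' @export
improvement_deltas <- function(report_a, report_b, scope = c("drug", "moa")) {
  scope <- match.arg(scope)
  if (scope == "drug") {
    da <- report_a$per_group; db <- report_b$per_group; key <- "drug_id"
  } else {
    da <- report_a$moa_averaged; db <- report_b$moa_averaged; key <- "moa"
    if (is.null(da) || is.null(db)) {
      stop("improvement_deltas: reports carry no MOA-averaged metrics")
    }
  }
  only_a <- setdiff(da[[key]], db[[key]])
  only_b <- setdiff(db[[key]], da[[key]])
  if (length(only_a) + length(only_b) > 0) {
    stop("improvement_deltas: mismatched ", scope, " sets (",
         paste(c(only_a, only_b), collapse = ", "), ")")
  }
  db <- db[match(da[[key]], db[[key]]), , drop = FALSE]
  out <- da[key]
  for (m in METRIC_NAMES) out[[m]] <- db[[m]] - da[[m]]
  out
}

#' Largest improvements by one metric
#'
#' @param deltas Data frame from [improvement_deltas()].
#' @param metric Metric column to rank by.
#' @param k Number of rows to keep.
#' @return `deltas` rows with the `k` largest values of `metric`,
#'   descending.
#' @export
top_improvements <- function(deltas, metric = "r2", k = 10) {
  stopifnot(metric %in% names(deltas))
  ord <- order(deltas[[metric]], decreasing = TRUE)
  utils::head(deltas[ord, , drop = FALSE], k)
}

#' Flatten a metrics report into tidy long format
#'
#' One row per (scope, group, metric): scope `"bulk"`, `"drug"` or `"moa"`.
#'
#' @param report A `metrics_report`.
#' @param fold Optional fold id recorded in a leading column.
#' @return Long data frame: fold, scope, group, metric, value.
#' @export
tidy_metrics <- function(report, fold = NA) {
  rows <- data.frame(fold = fold, scope = "bulk", group = NA_character_,
                     metric = names(report$bulk),
                     value = unname(report$bulk),
                     stringsAsFactors = FALSE)
  rows <- rbind(rows, data.frame(
    fold = fold, scope = "drug_averaged", group = NA_character_,
    metric = names(report$group_averaged),
    value = unname(report$group_averaged), stringsAsFactors = FALSE))
  if (nrow(report$per_group) > 0) {
    for (m in METRIC_NAMES) {
      rows <- rbind(rows, data.frame(
        fold = fold, scope = "drug", group = report$per_group$drug_id,
        metric = m, value = report$per_group[[m]],
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(report$moa_averaged) && nrow(report$moa_averaged) > 0) {
    for (m in METRIC_NAMES) {
      rows <- rbind(rows, data.frame(
        fold = fold, scope = "moa", group = report$moa_averaged$moa,
        metric = m, value = report$moa_averaged[[m]],
        stringsAsFactors = FALSE))
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Aggregate tidy metrics across folds
#'
#' Reports the median (the headline cross-fold summary), mean and standard
#' deviation of each metric within each scope/group.
#'
#' @param tidy Long data frame from [tidy_metrics()], several folds bound
#'   together.
#' @return Data frame: scope, group, metric, median, mean, sd, n_folds.
#' @export
aggregate_folds <- function(tidy) {
  grp <- ifelse(is.na(tidy$group), "", tidy$group)
  key <- paste(tidy$scope, grp, tidy$metric, sep = "\r")
  agg <- lapply(split(seq_len(nrow(tidy)), key), function(i) {
    v <- tidy$value[i]
    data.frame(scope = tidy$scope[i[1]], group = tidy$group[i[1]],
               metric = tidy$metric[i[1]],
               median = stats::median(v, na.rm = TRUE),
               mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v),
               n_folds = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
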