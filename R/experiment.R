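# Experiment orchestration: cross-validated training/evaluation, the
# 2 samplers x 2 losses ablation grid, and the regularization-weight sweep.
# Every run is fully determined by its configs and seeds; when an output
# directory is given, the split plan, configs and metrics are written so a
# run can be reproduced and compared on the identical fixed split.

# Rebuild the response table carried inside an assembled dataset (range
# warnings were already raised, if due, when the data was first loaded).
dataset_table <- function(dataset) {
  suppressWarnings(drug_response_table(data.frame(
    sample_id = dataset$sample_id, drug_id = dataset$drug_id,
    response = dataset$response, stringsAsFactors = FALSE)))
}

#' Cross-validated training and evaluation of one configuration
#'
#' For each fold rotation: fit the reference regressor on the training
#' portion (optionally with a validation holdout for early stopping) and
#' score the held-out fold at bulk, per-drug, drug-averaged and (if a MOA
#' map is given) MOA-averaged resolution. The same `split_plan` can be
#' passed to several configurations so they are compared on a fixed split.
#'
#' @param dataset A `drp_dataset` from [assemble_dataset()].
#' @param plan A `split_plan` over the same records.
#' @param sampler A [sampler_config()].
#' @param loss A [loss_config()].
#' @param model A [model_config()]; its `input_dim` must match the dataset.
#' @param train A [train_config()].
#' @param moa Optional named MOA map.
#' @param validation_fraction Optional fraction for a per-fold holdout used
#'   for early stopping (drug-disjoint under drug-blind plans).
#' @param folds Subset of folds to run (default all).
#' @param out_dir Optional directory for artifacts (plan, configs, tidy
#'   metrics TSV, summary JSON).
#' @return List with `fold_reports` (one `metrics_report` per fold),
#'   `tidy` (long metrics with fold column), `summary`
#'   (median/mean/sd across folds), and `predictions` (per-record test
#'   predictions across folds).
#' @export
run_cv_experiment <- function(dataset, plan, sampler, loss, model, train,
                              moa = NULL, validation_fraction = NULL,
                              folds = seq_len(plan$k), out_dir = NULL) {
  stopifnot(inherits(plan, "split_plan"),
            length(plan$fold_of_record) == dataset$n_pairs)
  if (model$input_dim != ncol(dataset$features)) {
    stop("model input_dim = ", model$input_dim, " but dataset has ",
         ncol(dataset$features), " features")
  }
  table <- dataset_table(dataset)
  viol <- validate_plan(plan, table)
  if (length(viol) > 0) {
    stop("invalid split plan: ", paste(viol, collapse = "; "))
  }

  fold_reports <- list()
  tidy_all <- list()
  pred_all <- data.frame(record = integer(0), fold = integer(0),
                         yhat = numeric(0))
  for (f in folds) {
    ix <- fold_indices(plan, f)
    tr <- ix$train; te <- ix$test
    val <- NULL
    if (!is.null(validation_fraction)) {
      hv <- validation_holdout(plan, table, f, validation_fraction,
                               seed = plan$seed + f)
      tr <- hv$train; val <- hv$validation
    }
    net <- build_model(model)
    net <- train_model(net, dataset, tr, sampler, loss, train,
                       val_idx = val)
    yhat <- predict(net, dataset$features[te, , drop = FALSE])
    rep_f <- metrics_report(dataset$response[te], yhat,
                            dataset$drug_id[te], moa = moa)
    fold_reports[[as.character(f)]] <- rep_f
    tidy_all[[as.character(f)]] <- tidy_metrics(rep_f, fold = f)
    pred_all <- rbind(pred_all,
                      data.frame(record = te, fold = f, yhat = yhat))
  }
  tidy <- do.call(rbind, tidy_all)
  rownames(tidy) <- NULL
  out <- list(fold_reports = fold_reports, tidy = tidy,
              summary = aggregate_folds(tidy), predictions = pred_all,
              plan = plan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_split_plan(plan, file.path(out_dir, "split_plan.tsv"))
    jsonlite::write_json(
      list(sampler = unclass(sampler), loss = unclass(loss),
           model = unclass(model), train = unclass(train),
           validation_fraction = validation_fraction),
      file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(tidy, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' Drug-averaged metric pooled over all test folds
#'
#' In drug-blind CV each drug is tested in exactly one fold, so pooling the
#' per-fold per-drug metrics and averaging with equal weight per drug gives
#' the cross-validated drug-averaged score.
#'
#' @param result A [run_cv_experiment()] result.
#' @param metric Metric name.
#' @return Scalar mean over all scored drugs (NA values dropped).
#' @export
cv_drug_averaged <- function(result, metric = "r2") {
  per_drug <- do.call(rbind, lapply(result$fold_reports,
                                    function(r) r$per_group))
  if (is.null(per_drug) || nrow(per_drug) == 0) return(NA_real_)
  mean(per_drug[[metric]], na.rm = TRUE)
}

#' Sampler-by-loss ablation on one fixed split
#'
#' Trains the four cells {sequential, mixed} x {MSE, MOORLE} on the
#' identical split plan and model seed — only sampler and loss differ — and
#' tabulates the median-across-folds bulk metrics per cell plus per-drug
#' and per-MOA improvement deltas of MOORLE over MSE within each sampling
#' strategy.
#'
#' @param dataset,plan,model,train,moa As in [run_cv_experiment()].
#' @param batch_size,lambda,sampler_seed Sampler settings shared by cells.
#' @param a MOORLE regularization weight for the two MOORLE cells.
#' @param out_dir Optional artifact directory (one subdirectory per cell).
#' @return List with `cells` (named run results), `table` (4 rows x bulk
#'   metrics, medians across folds), and `deltas` (per-drug R² improvement
#'   of MOORLE over MSE per strategy).
#' @export
run_ablation <- function(dataset, plan, model, train, a = 3, moa = NULL,
                         batch_size = 64, lambda = 0.5, sampler_seed = 1,
                         out_dir = NULL) {
  grid <- expand.grid(strategy = c("sequential", "mixed"),
                      loss = c("mse", "moorle"),
                      stringsAsFactors = FALSE)
  cells <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- paste(grid$strategy[i], grid$loss[i], sep = "_")
    sampler <- sampler_config(grid$strategy[i], batch_size = batch_size,
                              lambda = lambda, seed = sampler_seed)
    lcfg <- loss_config(grid$loss[i], a = if (grid$loss[i] == "moorle") a
                        else 0)
    cells[[cell]] <- run_cv_experiment(
      dataset, plan, sampler, lcfg, model, train, moa = moa,
      out_dir = if (!is.null(out_dir)) file.path(out_dir, cell))
  }
  tab <- do.call(rbind, lapply(names(cells), function(cell) {
    s <- cells[[cell]]$summary
    bulk <- s[s$scope == "bulk", ]
    row <- stats::setNames(bulk$median, bulk$metric)[METRIC_NAMES]
    data.frame(cell = cell, t(row), stringsAsFactors = FALSE)
  }))
  deltas <- lapply(c("sequential", "mixed"), function(strat) {
    merged_report <- function(res) {
      pg <- do.call(rbind, lapply(res$fold_reports, function(r) r$per_group))
      rownames(pg) <- NULL
      rep <- list(per_group = pg,
                  moa_averaged = if (!is.null(moa))
                    aggregate_by_moa(pg, moa)$moa_averaged)
      class(rep) <- "metrics_report"
      rep
    }
    improvement_deltas(merged_report(cells[[paste0(strat, "_mse")]]),
                       merged_report(cells[[paste0(strat, "_moorle")]]),
                       scope = "drug")
  })
  names(deltas) <- c("sequential", "mixed")
  list(cells = cells, table = tab, deltas = deltas)
}

#' Sweep the MOORLE regularization weight
#'
#' Runs full CV with the MOORLE loss at each weight in `a_values` (a = 0 is
#' the unregularized baseline) and selects the best weight by validation
#' drug-averaged R²: per fold, a holdout (drug-disjoint under drug-blind
#' plans) is carved from the training portion, the model is trained on the
#' remainder at each candidate weight, and validation scores are averaged
#' across folds.
#'
#' @param dataset,plan,sampler,model,train,moa As in [run_cv_experiment()].
#' @param a_values Non-negative candidate weights.
#' @param validation_fraction Holdout fraction used for selection.
#' @param folds Folds used for validation-based selection (default all;
#'   fewer folds make the sweep cheaper at some selection variance).
#' @return List with `summary` (one row per a: validation drug-averaged R²
#'   and test bulk/drug-averaged medians), `best_a`, and `runs` (per-a CV
#'   results on the test folds).
#' @export
sweep_regularization <- function(dataset, plan, sampler, model, train,
                                 a_values = c(0, 0.5, 1, 2, 3, 4, 5, 6),
                                 validation_fraction = 0.2, moa = NULL,
                                 folds = seq_len(plan$k)) {
  stopifnot(length(a_values) > 0, all(a_values >= 0))
  table <- dataset_table(dataset)
  val_scores <- numeric(length(a_values))
  runs <- list()
  for (j in seq_along(a_values)) {
    a <- a_values[j]
    lcfg <- loss_config("moorle", a = a)
    per_fold <- numeric(0)
    for (f in folds) {
      hv <- validation_holdout(plan, table, f, validation_fraction,
                               seed = plan$seed + f)
      net <- build_model(model)
      net <- train_model(net, dataset, hv$train, sampler, lcfg, train)
      yhat <- predict(net,
                      dataset$features[hv$validation, , drop = FALSE])
      gw <- groupwise_metrics(dataset$response[hv$validation], yhat,
                              dataset$drug_id[hv$validation])
      per_fold <- c(per_fold, gw$group_averaged[["r2"]])
    }
    val_scores[j] <- mean(per_fold, na.rm = TRUE)
    runs[[as.character(a)]] <- run_cv_experiment(
      dataset, plan, sampler, lcfg, model, train, moa = moa, folds = folds)
  }
  best_a <- a_values[which.max(val_scores)]
  summary <- do.call(rbind, lapply(seq_along(a_values), function(j) {
    s <- runs[[as.character(a_values[j])]]$summary
    bulk <- s[s$scope == "bulk" & s$metric == "r2", ]
    data.frame(a = a_values[j],
               validation_drug_avg_r2 = val_scores[j],
               test_bulk_r2_median = bulk$median,
               test_drug_avg_r2 =
                 cv_drug_averaged(runs[[as.character(a_values[j])]]),
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, best_a = best_a, runs = runs,
       a_values = a_values)
}

#' Tuned-MOORLE versus plain-MSE comparison on one fixed split
#'
#' The headline workflow: pick the MOORLE regularization weight from a
#' small grid by validation drug-averaged R² (holdout carved from one
#' fold's training portion, drug-disjoint under drug-blind plans), then run
#' full CV with the tuned MOORLE loss and with the plain MSE loss on the
#' identical split, model and seeds, and compare their cross-validated
#' drug-averaged R².
#'
#' @param dataset,plan,sampler,model,train,moa As in [run_cv_experiment()].
#' @param a_grid Candidate regularization weights.
#' @param validation_fraction Holdout fraction for weight selection.
#' @param tuning_fold Fold whose training portion supplies the holdout.
#' @return List with `best_a`, `val_scores` (per candidate),
#'   `drug_avg_r2` (named: moorle, mse), `bulk` (named list of bulk metric
#'   medians per arm), and the two full run results.
#' @export
compare_tuned_moorle <- function(dataset, plan, sampler, model, train,
                                 a_grid = c(2, 3, 4),
                                 validation_fraction = 0.2,
                                 tuning_fold = 1, moa = NULL) {
  table <- dataset_table(dataset)
  hv <- validation_holdout(plan, table, tuning_fold, validation_fraction,
                           seed = plan$seed + tuning_fold)
  val_scores <- vapply(a_grid, function(a) {
    net <- build_model(model)
    net <- train_model(net, dataset, hv$train, sampler,
                       loss_config("moorle", a = a), train)
    yhat <- predict(net, dataset$features[hv$validation, , drop = FALSE])
    groupwise_metrics(dataset$response[hv$validation], yhat,
                      dataset$drug_id[hv$validation])$group_averaged[["r2"]]
  }, numeric(1))
  best_a <- a_grid[which.max(val_scores)]
  run_moorle <- run_cv_experiment(dataset, plan, sampler,
                                  loss_config("moorle", a = best_a),
                                  model, train, moa = moa)
  run_mse <- run_cv_experiment(dataset, plan, sampler, loss_config("mse"),
                               model, train, moa = moa)
  bulk_median <- function(run, metric) {
    s <- run$summary
    s$median[s$scope == "bulk" & s$metric == metric]
  }
  list(best_a = best_a,
       val_scores = stats::setNames(val_scores, a_grid),
       drug_avg_r2 = c(moorle = cv_drug_averaged(run_moorle),
                       mse = cv_drug_averaged(run_mse)),
       bulk = list(
         moorle = vapply(METRIC_NAMES, bulk_median, numeric(1),
                         run = run_moorle),
         mse = vapply(METRIC_NAMES, bulk_median, numeric(1),
                      run = run_mse)),
       run_moorle = run_moorle, run_mse = run_mse)
}
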