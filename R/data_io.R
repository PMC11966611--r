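#' Read a pair-input drug response table
#'
#' Reads a delimited text file of (sample, drug, response) records — the
#' pair-input dataset underlying drug response prediction. Each row is one
#' screening experiment: a biological sample (cell line) treated with a drug,
#' summarized by a continuous response such as the area under the
#' dose-response curve (AUC).
#'
#' Responses outside \[0, 1\] are accepted with a warning, since AUC-like
#' measures are conventionally but not necessarily bounded.
#'
#' @param path Path to a delimited file with a header row.
#' @param column_spec Named character vector mapping the roles `sample`,
#'   `drug` and `response` to column names in the file.
#' @param delim Field delimiter; tab by default, `","` accepted.
#' @return A `drug_response_table`: a data frame with columns `sample_id`,
#'   `drug_id`, `response`, preserving file row order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tdrug_id\tauc", "CL1\tD1\t0.52", "CL2\tD1\t0.61"), tf)
#' tab <- read_response_table(tf)
#' nrow(tab)
#' @export
read_response_table <- function(path,
                                column_spec = c(sample = "sample_id",
                                                drug = "drug_id",
                                                response = "auc"),
                                delim = "\t") {
  stopifnot(file.exists(path))
  needed <- c("sample", "drug", "response")
  if (!all(needed %in% names(column_spec))) {
    stop("column_spec must name columns for roles: ",
         paste(setdiff(needed, names(column_spec)), collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  missing <- setdiff(unname(column_spec[needed]), names(raw))
  if (length(missing) > 0) {
    stop("response table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  resp_chr <- raw[[column_spec[["response"]]]]
  resp <- suppressWarnings(as.numeric(resp_chr))
  bad <- which(is.na(resp) & !is.na(resp_chr))
  if (length(bad) > 0) {
    stop("non-numeric response at data row ", bad[1],
         " (value '", resp_chr[bad[1]], "')")
  }
  drug_response_table(data.frame(
    sample_id = raw[[column_spec[["sample"]]]],
    drug_id = raw[[column_spec[["drug"]]]],
    response = resp,
    stringsAsFactors = FALSE
  ))
}

#' Construct a drug response table from a data frame
#'
#' Validates the pair-input invariants: finite responses and at most one
#' record per (sample, drug) combination.
#'
#' @param records Data frame with columns `sample_id`, `drug_id`, `response`.
#' @return The validated data frame with class `drug_response_table`.
#' @export
drug_response_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "drug_id", "response") %in% names(records)))
  records$sample_id <- as.character(records$sample_id)
  records$drug_id <- as.character(records$drug_id)
  if (nrow(records) > 0 && any(!is.finite(records$response))) {
    stop("non-finite response at record ",
         which(!is.finite(records$response))[1])
  }
  key <- paste(records$sample_id, records$drug_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate (sample, drug) pair: (", records$sample_id[i], ", ",
         records$drug_id[i], ")")
  }
  out_of_range <- records$response < 0 | records$response > 1
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " response value(s) outside [0, 1]; kept as-is")
  }
  rownames(records) <- NULL
  class(records) <- c("drug_response_table", "data.frame")
  records
}

#' @export
print.drug_response_table <- function(x, ...) {
  cat("Drug response table: ", nrow(x), " pairs, ",
      length(unique(x$sample_id)), " samples, ",
      length(unique(x$drug_id)), " drugs\n", sep = "")
  utils::head(as.data.frame(x))
}

#' Drug identifiers observed in a response table
#' @param table A `drug_response_table`.
#' @return Character vector of distinct drug ids, in first-appearance order.
#' @export
drug_ids <- function(table) unique(table$drug_id)

#' Sample identifiers observed in a response table
#' @param table A `drug_response_table`.
#' @return Character vector of distinct sample ids, in first-appearance order.
#' @export
sample_ids <- function(table) unique(table$sample_id)

#' Write a drug response table
#'
#' @param table A `drug_response_table`.
#' @param path Output path.
#' @param column_spec Column names to use for the three roles.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path,
                                 column_spec = c(sample = "sample_id",
                                                 drug = "drug_id",
                                                 response = "auc"),
                                 delim = "\t") {
  out <- data.frame(table$sample_id, table$drug_id, table$response)
  names(out) <- unname(column_spec[c("sample", "drug", "response")])
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix
#'
#' Reads a delimited file holding per-entity features (e.g. gene expression
#' per cell line, molecular descriptors per drug): first column entity ids,
#' remaining columns named features. Set `entities_as_rows = FALSE` for
#' transposed files (features as rows).
#'
#' @param path Path to a delimited file.
#' @param entities_as_rows Logical; are rows entities (default) or features?
#' @param delim Field delimiter.
#' @return Numeric matrix, entities as rows (rownames = entity ids,
#'   colnames = feature names), all values finite.
#' @export
read_feature_matrix <- function(path, entities_as_rows = TRUE, delim = "\t") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           check.names = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate entity id: ", ids[duplicated(ids)][1])
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!entities_as_rows) m <- t(m)
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-finite value at entity '", rownames(m)[idx[1]],
         "', feature '", colnames(m)[idx[2]], "'")
  }
  m
}

#' Write a feature matrix
#' @param m Numeric matrix with entity rownames.
#' @param path Output path.
#' @param id_column Name for the leading id column.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path, id_column = "id", delim = "\t") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a drug-to-MOA mapping
#'
#' @param path Delimited file with columns `drug_id`, `moa`.
#' @param delim Field delimiter.
#' @return Named character vector: MOA label per drug id.
#' @export
read_moa_map <- function(path, delim = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           check.names = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("drug_id", "moa") %in% names(raw))) {
    stop("MOA map must have columns 'drug_id' and 'moa'")
  }
  if (anyDuplicated(raw$drug_id)) {
    stop("drug mapped to more than one MOA: ",
         raw$drug_id[duplicated(raw$drug_id)][1])
  }
  stats::setNames(as.character(raw$moa), as.character(raw$drug_id))
}

#' Join response pairs with sample and drug features
#'
#' Builds the model-ready dataset: for each (sample, drug) pair the feature
#' vector is the concatenation of the sample's features and the drug's
#' features, with the response as target and the drug id retained as group
#' label for the per-drug loss decomposition.
#'
#' @param table A `drug_response_table`.
#' @param sample_features Numeric matrix, samples as rows.
#' @param drug_features Numeric matrix, drugs as rows.
#' @return A `drp_dataset`: list with `features` (pairs x features matrix),
#'   `response`, `drug_id`, `sample_id` (aligned vectors), and dimensions.
#' @export
assemble_dataset <- function(table, sample_features, drug_features) {
  miss_s <- setdiff(unique(table$sample_id), rownames(sample_features))
  miss_d <- setdiff(unique(table$drug_id), rownames(drug_features))
  if (length(miss_s) + length(miss_d) > 0) {
    stop("ids in response table missing from feature matrices: ",
         paste(c(miss_s, miss_d), collapse = ", "))
  }
  n <- nrow(table)
  feats <- cbind(
    sample_features[table$sample_id, , drop = FALSE],
    drug_features[table$drug_id, , drop = FALSE]
  )
  rownames(feats) <- NULL
  colnames(feats) <- c(paste0("s.", colnames(sample_features)),
                       paste0("d.", colnames(drug_features)))
  structure(list(
    features = feats,
    response = table$response,
    drug_id = table$drug_id,
    sample_id = table$sample_id,
    n_pairs = n,
    n_sample_features = ncol(sample_features),
    n_drug_features = ncol(drug_features)
  ), class = "drp_dataset")
}

#' @export
print.drp_dataset <- function(x, ...) {
  cat("Assembled DRP dataset: ", x$n_pairs, " pairs x ",
      ncol(x$features), " features (",
      x$n_sample_features, " sample + ", x$n_drug_features, " drug), ",
      length(unique(x$drug_id)), " drugs\n", sep = "")
  invisible(x)
}
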