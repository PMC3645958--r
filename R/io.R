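# File I/O: delimited datasets, prediction tables, JSON model round-trip.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a sample-ID column plus data columns in ", path)
  df
}

#' Read a feature matrix and outcome from delimited files
#'
#' Both files are CSV or TSV (by extension) with a header row and the
#' sample ID in the first column. The outcome file has one outcome column;
#' rows are aligned to the feature matrix by sample ID, so row order need
#' not match. Non-numeric cells and ID mismatches are errors.
#'
#' @param features_path Path to the samples x features table.
#' @param outcome_path Path to the two-column (ID, outcome) table, or `NULL`
#'   to read features only.
#' @param outcome_column Alternatively, the name of a column inside the
#'   features file to use (and remove from) the feature matrix.
#' @return List with `x` (numeric matrix, rownames = IDs), `y` (or `NULL`)
#'   and `ids`.
#' @export
read_dataset <- function(features_path, outcome_path = NULL,
                         outcome_column = NULL) {
  df <- read_table_checked(features_path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated sample IDs in ", features_path)
  y <- NULL
  if (!is.null(outcome_column)) {
    if (!outcome_column %in% names(df)) {
      stop("outcome column '", outcome_column, "' not found")
    }
    y <- df[[outcome_column]]
    df <- df[, setdiff(names(df), outcome_column), drop = FALSE]
  }
  feat <- df[, -1L, drop = FALSE]
  for (j in seq_along(feat)) {
    v <- feat[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric value in column '", names(feat)[j], "', row ",
           if (length(bad)) bad[1] else "?", " of ", features_path)
    }
    if (anyNA(v)) {
      stop("missing value in column '", names(feat)[j], "', row ",
           which(is.na(v))[1], " of ", features_path)
    }
  }
  x <- as.matrix(feat)
  rownames(x) <- ids
  if (!is.null(outcome_path)) {
    ydf <- read_table_checked(outcome_path)
    yid <- as.character(ydf[[1L]])
    missing_ids <- setdiff(ids, yid)
    extra_ids <- setdiff(yid, ids)
    if (length(missing_ids) || length(extra_ids)) {
      stop("sample IDs differ between features and outcome files; ",
           "missing from outcome: ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           if (length(extra_ids)) paste0("; extra in outcome: ",
             paste(utils::head(extra_ids, 5), collapse = ", ")))
    }
    y <- ydf[[2L]][match(ids, yid)]
    if (!is.numeric(y)) stop("outcome must be numeric")
    if (anyNA(y)) stop("missing outcome values")
  }
  list(x = x, y = y, ids = ids)
}

#' Write predictions to a delimited file
#'
#' @param pred Numeric or integer predictions.
#' @param ids Sample IDs (same length).
#' @param path Output path (.csv or .tsv).
#' @export
write_predictions <- function(pred, ids, path) {
  stopifnot(length(pred) == length(ids))
  utils::write.table(data.frame(sample = ids, prediction = pred),
                     path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
}

#' Serialize a random GLM ensemble to JSON
#'
#' Stores the configuration, feature names and every bag's bootstrap
#' indices, subspace, selected terms and coefficients at full floating
#' point precision, so a reloaded model predicts bit-identically.
#'
#' @param model A trained `rglm` model.
#' @param path Output JSON path.
#' @export
write_rglm <- function(model, path) {
  stopifnot(inherits(model, "rglm"))
  doc <- list(
    format = "rglmens-model",
    version = 1L,
    config = model$config,
    n_samples = model$n_samples,
    n_features = model$n_features,
    feature_names = model$feature_names,
    y_summary = model$y_summary,
    thinned = inherits(model, "rglm_thinned"),
    threshold = if (inherits(model, "rglm_thinned")) model$threshold,
    bags = lapply(model$bags, function(b) list(
      bag = b$bag,
      subspace = b$subspace,
      candidate_terms = b$candidate_terms,
      selected_terms = b$selected_terms,
      # decimal strings with 17 significant digits: lossless for doubles
      coefficients = lapply(as.list(b$coefficients),
                            function(v) sprintf("%.17g", v)),
      aic = b$aic)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a serialized random GLM ensemble
#'
#' @param path JSON path written by [write_rglm()].
#' @return The reconstructed `rglm` model.
#' @export
read_rglm <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "rglmens-model")) {
    stop(path, " is not a serialized rglm model")
  }
  as_terms <- function(l) lapply(l, function(t) as.integer(unlist(t)))
  bags <- lapply(doc$bags, function(b) {
    coefs <- vapply(b$coefficients, function(v) as.numeric(v), numeric(1))
    list(bag = as.integer(unlist(b$bag)),
         oob = setdiff(seq_len(doc$n_samples), as.integer(unlist(b$bag))),
         subspace = as.integer(unlist(b$subspace)),
         candidate_terms = as_terms(b$candidate_terms),
         selected_terms = as_terms(b$selected_terms),
         coefficients = coefs,
         aic = if (is.null(b$aic)) NA_real_ else as.numeric(b$aic))
  })
  config <- doc$config
  config$n_bags <- as.integer(config$n_bags)
  config$n_features_in_bag <- as.integer(config$n_features_in_bag)
  config$n_candidate_covariates <- as.integer(config$n_candidate_covariates)
  config$max_interaction_order <- as.integer(config$max_interaction_order)
  config$seed <- as.integer(config$seed)
  out <- structure(list(config = config, bags = bags,
                        n_samples = as.integer(doc$n_samples),
                        n_features = as.integer(doc$n_features),
                        feature_names = as.character(unlist(doc$feature_names)),
                        y_summary = as.numeric(doc$y_summary)),
                   class = "rglm")
  if (isTRUE(doc$thinned)) {
    out$threshold <- as.integer(doc$threshold)
    class(out) <- c("rglm_thinned", "rglm")
  }
  out
}
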