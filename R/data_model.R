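#' Construct a selection dataset
#'
#' Bundles the per-individual measurements used in a phenotypic selection
#' analysis for one population-year: a small block of "standard" traits
#' (morphology, phenology) on which selection is estimated directly, a
#' larger block of composite-trait measurements (volatile emission rates)
#' destined for dimension reduction, and absolute fitness (typically fruit
#' count). Relative fitness -- individual absolute fitness divided by the
#' population mean -- is derived on construction and has mean 1.
#'
#' @param standard_traits Numeric matrix or data frame, one row per
#'   individual, named columns, on the original measurement scale.
#' @param volatiles Numeric matrix or data frame of composite-trait
#'   measurements (e.g. emission rate per flower), named columns.
#' @param absolute_fitness Nonnegative numeric vector (zeros are legal
#'   individual values).
#' @param dataset_id Character label for the population-year.
#' @param ids Optional individual identifiers; defaults to row numbers.
#' @param cleaning_log Optional list recording rows/columns dropped during
#'   loading; see [load_dataset()].
#' @param allow_negative_fitness Permit negative fitness values. Only the
#'   Gaussian synthetic-data generator uses this: its generative model adds
#'   Gaussian noise to relative fitness, which can occasionally dip below
#'   zero. File-based loading always rejects negative fitness.
#' @param validate Run invariant checks (default `TRUE`).
#'
#' @return An object of class `selection_dataset` with elements
#'   `standard_traits`, `volatiles` (numeric matrices), `absolute_fitness`,
#'   `relative_fitness`, `dataset_id`, `ids`, `n`, and `cleaning_log`.
#' @seealso [load_dataset()], [relative_fitness()], [simulate_dataset()]
#' @export
selection_dataset <- function(standard_traits, volatiles, absolute_fitness,
                              dataset_id = "dataset", ids = NULL,
                              cleaning_log = NULL,
                              allow_negative_fitness = FALSE,
                              validate = TRUE) {
  X <- as_named_matrix(standard_traits, "trait")
  Z <- as_named_matrix(volatiles, "volatile")
  w_abs <- as.numeric(absolute_fitness)
  n <- length(w_abs)
  if (nrow(X) != n || nrow(Z) != n)
    stop("standard_traits, volatiles and absolute_fitness must have matching rows",
         call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  ds <- structure(
    list(standard_traits = X, volatiles = Z,
         absolute_fitness = w_abs,
         relative_fitness = relative_fitness(w_abs,
                                             allow_negative = allow_negative_fitness),
         dataset_id = as.character(dataset_id)[1],
         ids = as.character(ids), n = n,
         cleaning_log = cleaning_log %||% empty_cleaning_log()),
    class = "selection_dataset")
  if (validate) validate_selection_dataset(ds)
  ds
}

#' @export
print.selection_dataset <- function(x, ...) {
  cat(sprintf("selection_dataset '%s': %d individuals, %d standard trait(s), %d volatile(s)\n",
              x$dataset_id, x$n, ncol(x$standard_traits), ncol(x$volatiles)))
  cat(sprintf("  mean absolute fitness %.3f; relative fitness range [%.3f, %.3f]\n",
              mean(x$absolute_fitness), min(x$relative_fitness),
              max(x$relative_fitness)))
  log <- x$cleaning_log
  if (log$n_rows_dropped > 0 || length(log$dropped_columns) > 0)
    cat(sprintf("  cleaning: %d row(s) dropped, %d zero-variance column(s) removed\n",
                log$n_rows_dropped, length(log$dropped_columns)))
  invisible(x)
}

validate_selection_dataset <- function(ds) {
  stopifnot(inherits(ds, "selection_dataset"))
  if (any(!is.finite(ds$standard_traits)) || any(!is.finite(ds$volatiles)) ||
      any(!is.finite(ds$absolute_fitness)))
    stop("dataset contains missing or non-finite values after cleaning",
         call. = FALSE)
  sds <- apply(ds$volatiles, 2, stats::sd)
  if (any(sds <= 0))
    stop("volatile column(s) with zero variance: ",
         paste(colnames(ds$volatiles)[sds <= 0], collapse = ", "),
         call. = FALSE)
  if (abs(mean(ds$relative_fitness) - 1) > 1e-12)
    stop("relative fitness does not average to 1", call. = FALSE)
  if (ds$n < ncol(ds$standard_traits) + 3)
    stop(sprintf("insufficient data: %d rows for %d standard trait(s); need at least %d",
                 ds$n, ncol(ds$standard_traits), ncol(ds$standard_traits) + 3),
         call. = FALSE)
  invisible(ds)
}

#' Relative fitness
#'
#' Divides absolute fitness by its population mean, so the result averages
#' exactly 1. Selection gradients are regression slopes of this quantity on
#' phenotype.
#'
#' @param absolute_fitness Nonnegative numeric vector with positive mean.
#' @param allow_negative Accept negative entries (used internally for
#'   Gaussian-simulated fitness).
#' @return Numeric vector of the same length with mean 1.
#' @examples
#' relative_fitness(c(2, 4, 6)) # 0.5, 1.0, 1.5
#' @export
relative_fitness <- function(absolute_fitness, allow_negative = FALSE) {
  w <- as.numeric(absolute_fitness)
  if (length(w) == 0) stop("fitness vector is empty", call. = FALSE)
  if (any(!is.finite(w))) stop("fitness contains non-finite values", call. = FALSE)
  if (!allow_negative && any(w < 0))
    stop("negative fitness values are not allowed", call. = FALSE)
  m <- mean(w)
  if (m <= 0)
    stop("degenerate fitness: population mean fitness is not positive",
         call. = FALSE)
  w / m
}

#' Load a selection dataset from delimited text
#'
#' Reads a comma- or tab-delimited file (auto-detected) with one header row
#' and one row per individual, assigns each column a role via `schema`,
#' then cleans: rows with a missing value in any used column are dropped
#' (listwise deletion), zero-variance volatile columns are removed with a
#' warning, and the result is validated. All drops are recorded in the
#' returned dataset's `cleaning_log`.
#'
#' @param path Path to the delimited text file.
#' @param schema A list assigning column roles. Required: `fitness` (single
#'   column name). Optional: `id`, `standard` (character vector of column
#'   names), `volatiles` (character vector), `standard_prefix` /
#'   `volatile_prefix` (columns are matched by name prefix instead of
#'   enumeration), and `ignore`. Columns given no role are ignored.
#'   Setting `allow_negative_fitness: true` accepts files whose fitness
#'   column is already on the relative scale with Gaussian noise (as
#'   written for Gaussian-simulated data); by default negative fitness is
#'   a data error, as fruit counts and mass proxies cannot be negative.
#' @param dataset_id Label; defaults to the file name.
#' @return A validated [selection_dataset()].
#' @export
load_dataset <- function(path, schema, dataset_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read_delimited(path)
  if (is.null(dataset_id))
    dataset_id <- tools::file_path_sans_ext(basename(path))

  if (is.null(schema$fitness) || !schema$fitness %in% names(raw))
    stop("schema error: fitness column '", schema$fitness %||% "<missing>",
         "' not present in ", path, call. = FALSE)

  std_cols <- resolve_role(raw, schema$standard, schema$standard_prefix,
                           exclude = schema$fitness)
  vol_cols <- resolve_role(raw, schema$volatiles, schema$volatile_prefix,
                           exclude = c(schema$fitness, std_cols))
  if (length(vol_cols) == 0)
    stop("schema error: no volatile columns resolved", call. = FALSE)

  used <- c(schema$fitness, std_cols, vol_cols)
  missing_cols <- setdiff(used, names(raw))
  if (length(missing_cols) > 0)
    stop("schema error: column(s) not present: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  for (cn in used) raw[[cn]] <- as.numeric(raw[[cn]])

  complete <- stats::complete.cases(raw[, used, drop = FALSE])
  n_dropped <- sum(!complete)
  clean <- raw[complete, , drop = FALSE]

  allow_neg <- isTRUE(schema$allow_negative_fitness)
  w_abs <- clean[[schema$fitness]]
  if (!allow_neg && any(w_abs < 0))
    stop("data error: negative fitness values in column '", schema$fitness,
         "'", call. = FALSE)

  Z <- as.matrix(clean[, vol_cols, drop = FALSE])
  vol_sd <- apply(Z, 2, stats::sd)
  dropped_cols <- vol_cols[vol_sd <= 0 | !is.finite(vol_sd)]
  if (length(dropped_cols) > 0) {
    warning("dropping zero-variance volatile column(s): ",
            paste(dropped_cols, collapse = ", "), call. = FALSE)
    Z <- Z[, setdiff(vol_cols, dropped_cols), drop = FALSE]
  }
  if (ncol(Z) == 0) stop("no volatile columns remain after cleaning",
                         call. = FALSE)

  X <- as.matrix(clean[, std_cols, drop = FALSE])
  if (nrow(clean) < length(std_cols) + 3)
    stop(sprintf("insufficient data: %d complete rows for %d standard trait(s)",
                 nrow(clean), length(std_cols)), call. = FALSE)

  ids <- if (!is.null(schema$id) && schema$id %in% names(clean))
    as.character(clean[[schema$id]]) else as.character(seq_len(nrow(clean)))

  log <- list(n_rows_in = nrow(raw), n_rows_dropped = n_dropped,
              dropped_columns = dropped_cols,
              source = normalizePath(path))
  message(sprintf("[rrsel] loaded %s: %d/%d rows kept, %d volatile column(s) dropped",
                  dataset_id, nrow(clean), nrow(raw), length(dropped_cols)))

  selection_dataset(X, Z, w_abs, dataset_id = dataset_id, ids = ids,
                    cleaning_log = log, allow_negative_fitness = allow_neg)
}

#' Write a selection dataset to delimited text
#'
#' Writes the schema [load_dataset()] reads: an id column, the absolute
#' fitness column, then standard-trait and volatile columns.
#'
#' @param dataset A [selection_dataset()].
#' @param path Output path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "selection_dataset"))
  df <- data.frame(individual_id = dataset$ids,
                   absolute_fitness = dataset$absolute_fitness,
                   dataset$standard_traits, dataset$volatiles,
                   check.names = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default schema for datasets written by [write_dataset()]
#'
#' @param standard,volatiles Column names for the two trait blocks.
#' @param allow_negative_fitness Accept a relative-scale fitness column
#'   with Gaussian noise (Gaussian-simulated datasets).
#' @return A schema list for [load_dataset()].
#' @export
dataset_schema <- function(standard, volatiles,
                           allow_negative_fitness = FALSE) {
  list(fitness = "absolute_fitness", id = "individual_id",
       standard = standard, volatiles = volatiles,
       allow_negative_fitness = allow_negative_fitness)
}

# --- internals ---------------------------------------------------------

empty_cleaning_log <- function() {
  list(n_rows_in = NA_integer_, n_rows_dropped = 0L,
       dropped_columns = character(0), source = NA_character_)
}

as_named_matrix <- function(x, stem) {
  m <- as.matrix(as.data.frame(x, check.names = FALSE))
  storage.mode(m) <- "double"
  if (is.null(colnames(m)))
    colnames(m) <- paste0(stem, "_", seq_len(ncol(m)))
  m
}

read_delimited <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

resolve_role <- function(df, explicit, prefix, exclude = character(0)) {
  if (!is.null(explicit)) return(setdiff(as.character(explicit), exclude))
  if (!is.null(prefix))
    return(setdiff(names(df)[startsWith(names(df), prefix)], exclude))
  character(0)
}

subset_rows <- function(dataset, idx) {
  # internal: keeps relative fitness as computed on the full dataset, so
  # CV folds share the response definition; bypasses the mean-1 check
  out <- dataset
  out$standard_traits <- dataset$standard_traits[idx, , drop = FALSE]
  out$volatiles <- dataset$volatiles[idx, , drop = FALSE]
  out$absolute_fitness <- dataset$absolute_fitness[idx]
  out$relative_fitness <- dataset$relative_fitness[idx]
  out$ids <- dataset$ids[idx]
  out$n <- length(idx)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
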