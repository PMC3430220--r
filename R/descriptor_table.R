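#' Construct and validate a descriptor table
#'
#' A descriptor table holds one row per molecule: an identifier, the Y-atom
#' type of the Y-NO bond, the train/test split flag, the experimental
#' homolysis BDE in kcal/mol, and the twelve canonical molecular
#' descriptors (see [canonical_descriptors()]).
#'
#' @param df A data.frame with columns `molecule_id`, `y_type`, `split`,
#'   `expt_bde` and one column per canonical descriptor.
#' @param require_train Demand at least two training rows (the default;
#'   pure prediction sets such as an extrapolation table may switch this
#'   off).
#' @return The validated data.frame with class `descriptor_table`, row order
#'   preserved.
#' @export
descriptor_table <- function(df, require_train = TRUE) {
  stopifnot(is.data.frame(df))
  required <- c("molecule_id", "y_type", "split", "expt_bde", canonical_descriptors())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("descriptor table is missing column(s): ", paste(missing, collapse = ", "))
  df$molecule_id <- as.character(df$molecule_id)
  if (anyDuplicated(df$molecule_id))
    stop("duplicate molecule_id: ",
         paste(unique(df$molecule_id[duplicated(df$molecule_id)]), collapse = ", "))
  if (!all(df$y_type %in% y_type_levels()))
    stop("y_type must be one of: ", paste(y_type_levels(), collapse = ", "))
  if (!all(df$split %in% c("train", "test")))
    stop("split must be 'train' or 'test'")
  num_cols <- c("expt_bde", canonical_descriptors())
  for (cn in num_cols) {
    v <- df[[cn]]
    if (!is.numeric(v))
      stop("column '", cn, "' is not numeric")
    if (anyNA(v) || any(!is.finite(v)))
      stop("column '", cn, "' contains missing or non-finite values")
  }
  if (require_train && sum(df$split == "train") < 2)
    stop("descriptor table needs at least 2 training rows")
  class(df) <- c("descriptor_table", "data.frame")
  df
}

#' Read a descriptor table from CSV
#'
#' Comma-separated, `.` decimal, UTF-8, header required. Any cell in a
#' numeric column that does not parse as a number, a missing canonical
#' column, or a duplicated molecule identifier raises a validation error
#' naming the offender.
#'
#' @param path Path to a CSV file.
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  required <- c("molecule_id", "y_type", "split", "expt_bde", canonical_descriptors())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("CSV '", path, "' is missing column(s): ", paste(missing, collapse = ", "))
  for (cn in c("expt_bde", canonical_descriptors())) {
    raw <- df[[cn]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw))
    if (length(bad) > 0)
      stop("non-numeric value '", raw[bad[1]], "' in column '", cn,
           "' (row ", bad[1], ")")
    df[[cn]] <- v
  }
  descriptor_table(df)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]: a written table reads back with
#' identical values at full precision.
#'
#' @param x A [descriptor_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(x, path) {
  stopifnot(inherits(x, "descriptor_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract the descriptor matrix of a table
#'
#' @param table A [descriptor_table()].
#' @param features Descriptor names to keep (default all twelve).
#' @return Numeric matrix, molecules x features, rownames = molecule ids.
#' @export
descriptor_matrix <- function(table, features = canonical_descriptors()) {
  stopifnot(all(features %in% canonical_descriptors()))
  m <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  rownames(m) <- table$molecule_id
  m
}
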