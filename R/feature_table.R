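#' Participant-by-feature table for one data view
#'
#' Light container used throughout the pipeline for the environment, symptom,
#' brain and covariate views: a numeric matrix with participant identifiers as
#' row names and feature names as column names, plus a view label.  Missing
#' values are encoded as `NA` in the matrix (the missingness mask is implicit).
#'
#' @param values numeric matrix (participants x features).
#' @param participant_ids character vector of unique participant identifiers;
#'   defaults to existing row names.
#' @param feature_names character vector of unique feature names; defaults to
#'   existing column names.
#' @param view_label short label such as `"environment"` or `"symptoms"`.
#'
#' @return An object of class `feature_table`: a list with elements `values`
#'   (named numeric matrix) and `view_label`.
#' @export
feature_table <- function(values, participant_ids = rownames(values),
                          feature_names = colnames(values),
                          view_label = "view") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(participant_ids)) {
    participant_ids <- paste0("P", seq_len(nrow(values)))
  }
  if (is.null(feature_names)) {
    feature_names <- paste0("V", seq_len(ncol(values)))
  }
  participant_ids <- as.character(participant_ids)
  feature_names <- as.character(feature_names)
  if (anyDuplicated(participant_ids)) {
    stop("duplicate participant IDs: ",
         paste(unique(participant_ids[duplicated(participant_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  stopifnot(length(participant_ids) == nrow(values),
            length(feature_names) == ncol(values))
  dimnames(values) <- list(participant_ids, feature_names)
  structure(list(values = values, view_label = view_label),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table '%s': %d participants x %d features (%d missing values)\n",
              x$view_label, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

# Accept either a feature_table or a plain matrix in numerical code.
ft_values <- function(x) {
  if (inherits(x, "feature_table")) x$values else as.matrix(x)
}

ft_ids <- function(x) {
  v <- ft_values(x)
  if (is.null(rownames(v))) paste0("P", seq_len(nrow(v))) else rownames(v)
}

#' Read a participant-by-feature table from delimited text
#'
#' The first column (or the column named by `id_col`) holds participant IDs;
#' all remaining columns are parsed as numeric features.  Non-numeric cells
#' become missing values and are counted in the `n_coerced` attribute.
#'
#' @param path file path.
#' @param fmt `"tsv"` or `"csv"`.
#' @param id_col name of the participant-ID column; default: first column.
#' @param view_label view label attached to the result.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, fmt = c("tsv", "csv"), id_col = NULL,
                               view_label = "view") {
  fmt <- match.arg(fmt)
  if (file.size(path) == 0) stop("empty file: ", path)
  df <- read.delim(path, sep = if (fmt == "tsv") "\t" else ",",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or malformed table: ", path)
  if (is.null(id_col)) id_col <- names(df)[1]
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate participant ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  feat <- df[setdiff(names(df), id_col)]
  n_coerced <- 0L
  values <- vapply(feat, function(col) {
    x <- suppressWarnings(as.numeric(col))
    n_coerced <<- n_coerced + sum(is.na(x) & !is.na(col) &
                                    !(trimws(as.character(col)) %in% c("NA", "")))
    x
  }, numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(ids, names(feat)))
  out <- feature_table(values, view_label = view_label)
  attr(out, "n_coerced") <- n_coerced
  out
}

#' Write a feature table as tab-separated text
#'
#' @param x a [feature_table] or numeric matrix with row names.
#' @param path output path.
#' @param id_col name used for the participant-ID column.
#' @export
write_feature_table <- function(x, path, id_col = "participant_id") {
  v <- ft_values(x)
  df <- data.frame(id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
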