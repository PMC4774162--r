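#' Read a delimited survival table
#'
#' Loads a CSV or TSV file (auto-detected from the extension; `.csv` is
#' comma-delimited, anything else tab-delimited) with one row per sample:
#' an observed follow-up time, an event indicator (1 = event observed,
#' 0 = right-censored), and the remaining numeric columns treated as
#' covariates (typically gene-expression values). An optional character
#' column supplies sample identifiers; when absent, identifiers
#' `s1, s2, ...` are generated.
#'
#' Validation is strict: non-positive or missing times, status values outside
#' \{0, 1\}, and non-numeric or missing covariate cells abort with a message
#' naming the offending row or column. Silent row dropping would distort the
#' censoring rate, so nothing is dropped.
#'
#' @param path Path to a delimited text file with a header row.
#' @param time_col,status_col Names of the time and status columns.
#' @return A tibble with columns `sample_id`, `time`, `status`, then one
#'   column per covariate, row order preserved.
#' @seealso [write_survival_table()], [simulate_survival()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' sim <- simulate_survival(n = 20, p = 5, n_informative = 2, seed = 1)
#' write_survival_table(sim$data, path)
#' read_survival_table(path)
read_survival_table <- function(path, time_col = "time", status_col = "status") {
  if (!file.exists(path)) stop("file not found: ", path)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(time_col, status_col)) {
    if (!col %in% names(raw)) {
      stop("column '", col, "' not found in ", path)
    }
  }
  other <- setdiff(names(raw), c(time_col, status_col))
  is_chr <- vapply(raw[other], function(x) !is.numeric(x), logical(1))
  id_col <- NULL
  if (any(is_chr)) {
    if (sum(is_chr) > 1) {
      stop("multiple non-numeric columns (",
           paste(other[is_chr], collapse = ", "),
           "); at most one identifier column is allowed")
    }
    id_col <- other[is_chr]
  }
  ids <- if (is.null(id_col)) paste0("s", seq_len(nrow(raw))) else as.character(raw[[id_col]])
  features <- setdiff(other, id_col)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids,
                   time = as.numeric(raw[[time_col]]),
                   status = raw[[status_col]]),
    raw[features]
  )
  validate_survival_data(out)
}

#' Write a survival table
#'
#' Inverse of [read_survival_table()]: writes `sample_id`, `time`, `status`
#' and covariate columns as CSV or TSV depending on the file extension.
#'
#' @param data A survival tibble as returned by [read_survival_table()].
#' @param path Output path; `.csv` writes comma-delimited, else tab-delimited.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(data, path) {
  data <- validate_survival_data(data)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(data, path, progress = FALSE)
  } else {
    readr::write_tsv(data, path, progress = FALSE)
  }
  invisible(path)
}

#' Validate a survival data frame
#'
#' Checks the contract shared by every fitting function: positive times,
#' status in \{0, 1\}, numeric complete covariates, unique feature names and
#' sample identifiers. Returns the data as a tibble (adding `sample_id` if
#' missing) or aborts with a message naming the offending row/column.
#'
#' @param data A data frame with columns `time`, `status` and covariates.
#' @return The validated tibble.
#' @export
validate_survival_data <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("time", "status") %in% names(data))) {
    stop("survival data must have 'time' and 'status' columns")
  }
  if (!"sample_id" %in% names(data)) {
    data <- dplyr::bind_cols(tibble::tibble(sample_id = paste0("s", seq_len(nrow(data)))), data)
  }
  data <- dplyr::relocate(data, "sample_id", "time", "status")
  if (anyDuplicated(data$sample_id)) stop("sample_id values must be unique")
  if (!is.numeric(data$time) || anyNA(data$time)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(data$time))))
    stop("non-numeric or missing time in row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  if (any(data$time <= 0)) {
    stop("non-positive time in row(s): ",
         paste(head(which(data$time <= 0), 5), collapse = ", "))
  }
  st <- data$status
  if (anyNA(st) || !all(st %in% c(0, 1))) {
    bad <- which(is.na(st) | !(st %in% c(0, 1)))
    stop("status must be 0 (censored) or 1 (event); offending row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  data$status <- as.integer(st)
  feats <- feature_names(data)
  if (anyDuplicated(feats)) stop("feature names must be unique")
  for (f in feats) {
    x <- data[[f]]
    if (!is.numeric(x)) stop("feature column '", f, "' is not numeric")
    if (anyNA(x)) {
      stop("missing value in feature '", f, "', row(s): ",
           paste(head(which(is.na(x)), 5), collapse = ", "))
    }
  }
  data
}

#' Covariate column names of a survival tibble
#'
#' @param data A survival tibble.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(data) {
  setdiff(names(data), c("sample_id", "time", "status"))
}

#' Covariate matrix of a survival tibble
#'
#' @param data A survival tibble.
#' @return Numeric matrix (samples x features) with sample_id rownames.
#' @export
feature_matrix <- function(data) {
  feats <- feature_names(data)
  X <- as.matrix(data[feats])
  storage.mode(X) <- "double"
  rownames(X) <- data$sample_id
  X
}
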