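#' Construct a feature table
#'
#' Container for an untargeted LC-HRMS feature matrix: samples in rows,
#' features in columns, missing cells meaning the feature was not detected
#' in that sample. Optionally carries per-feature mass (Da) and retention
#' time (min) for annotation matching.
#'
#' @param intensities Numeric matrix, samples x features, with row and
#'   column names; present values must be strictly positive, nondetects `NA`.
#' @param features Optional data frame with one row per feature; must
#'   contain `feature_id` matching the matrix column names, and may carry
#'   `mass` and `rt`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, features = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  if (ncol(intensities) > 0 &&
      (is.null(rownames(intensities)) || is.null(colnames(intensities)))) {
    stop("`intensities` needs sample (row) and feature (column) names",
         call. = FALSE)
  }
  if (ncol(intensities) == 0 && is.null(colnames(intensities))) {
    colnames(intensities) <- character(0)
  }
  if (anyDuplicated(colnames(intensities))) {
    stop("feature ids must be unique", call. = FALSE)
  }
  if (any(intensities <= 0, na.rm = TRUE)) {
    stop("present intensities must be strictly positive", call. = FALSE)
  }
  if (is.null(features)) {
    features <- data.frame(feature_id = colnames(intensities),
                           stringsAsFactors = FALSE)
  } else {
    if (!"feature_id" %in% names(features)) {
      stop("`features` must have a `feature_id` column", call. = FALSE)
    }
    features <- features[match(colnames(intensities), features$feature_id), ,
                         drop = FALSE]
    if (anyNA(features$feature_id)) {
      stop("`features` must describe every column of `intensities`",
           call. = FALSE)
    }
    rownames(features) <- NULL
  }
  structure(list(intensities = intensities, features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  d <- dim(x$intensities)
  det <- mean(!is.na(x$intensities))
  cat(sprintf("<feature_table> %d samples x %d features (%.1f%% detected)\n",
              d[1], d[2], 100 * det))
  invisible(x)
}

#' Read a feature table from delimited text
#'
#' Reads a samples-x-features CSV (first column = sample id, empty cells =
#' nondetect), optionally joining a feature-info CSV with mass and
#' retention time.
#'
#' @param path Path to the intensity CSV.
#' @param feature_info Optional path to a CSV with `feature_id`, `mass`, `rt`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, feature_info = NULL) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  info <- if (!is.null(feature_info)) {
    read.csv(feature_info, stringsAsFactors = FALSE)
  }
  feature_table(m, info)
}
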